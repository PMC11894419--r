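test_that("generated kinematics respect the metronome structure", {
  kin <- generate_kinematics(test_protocol, seed = 1, rate = 1000)
  expect_equal(max(kin$time), 8)
  expect_equal(kin$theta_trunk[1], 0)
  expect_equal(kin$theta_trunk[length(kin$theta_trunk)], 0)
  expect_true(all(kin$theta_trunk >= 0))
  # peaks near 75 degrees at the ends of phases 1 and 3
  peak <- 75 * pi / 180
  at <- function(t) kin$theta_trunk[which.min(abs(kin$time - t))]
  expect_equal(at(2), peak, tolerance = 0.05)
  expect_equal(at(6), peak, tolerance = 0.05)
  expect_lt(at(4), 0.05)
  # lumbar share
  expect_equal(kin$theta_l5s1, 0.5 * kin$theta_trunk)
  # exactly two box-state transitions
  expect_equal(sum(diff(kin$box_state) != 0), 2)
  # minimum-jerk endpoint velocities vanish at phase boundaries (jitter-free)
  prot0 <- protocol_config(jitter_deg = 0)
  k0 <- generate_kinematics(prot0, seed = 1, rate = 1000)
  for (tb in c(0, 2, 4, 6, 8)) {
    i <- which.min(abs(k0$time - tb))
    i <- min(max(i, 2), length(k0$time) - 1)
    vel <- (k0$theta_trunk[i + 1] - k0$theta_trunk[i - 1]) / (2 * k0$dt)
    expect_lt(abs(vel), 1e-3)
  }
})

test_that("activation distribution reconstructs the demanded moment", {
  kin <- generate_kinematics(test_protocol, seed = 5, rate = 100)
  box <- kin$box_state
  M_req <- top_down_id(kin$theta_trunk, test_subject$anthro, 15, box)
  d <- distribute_activations(M_req, default_surr, test_subject$params,
                              kin$theta_l5s1, kin$dt)
  lo <- emg_driven_moments(d$activations, default_surr,
                           test_subject$params, kin$theta_l5s1, kin$dt)
  ok <- !d$saturated & M_req > 1
  rel <- abs(lo$moments$M_total_Nm[ok] - M_req[ok]) / pmax(M_req[ok], 1)
  expect_lt(max(rel), 0.005)
  # a demand equal to the passive-only moment leaves extensors silent
  zero_act <- matrix(0, length(M_req), 8,
                     dimnames = list(NULL, names(default_surr)))
  M_pas <- emg_driven_moments(zero_act, default_surr, test_subject$params,
                              kin$theta_l5s1, kin$dt)$moments$M_passive_Nm
  d0 <- distribute_activations(M_pas, default_surr, test_subject$params,
                               kin$theta_l5s1, kin$dt, co_activation = 0)
  expect_true(all(d0$activations[, extensor_names] <= 1e-9))
  # bilateral symmetry of identical extensors
  expect_equal(d$activations[, "iliocostalis_l"],
               d$activations[, "iliocostalis_r"])
})

test_that("raw EMG round-trips through the envelope pipeline", {
  n <- 9000; fs <- 1000
  t <- (seq_len(n) - 1) / fs
  # smooth activation profile spanning [0.05, 0.95]; slow enough for the
  # causal 3 Hz envelope (group delay ~75 ms) to follow within tolerance
  prof <- 0.5 + 0.45 * sin(2 * pi * 0.15 * t)
  act <- matrix(rep(prof, 8), n, 8,
                dimnames = list(NULL, names(test_subject$params)))
  raw <- synthesize_raw_emg(act, test_subject, seed = 2, rate = fs)
  env <- normalize_mvc(envelope(raw), test_subject$mvc, fs)
  u <- map_channels(env)
  a <- excitation_to_activation(
    u, vapply(colnames(u), function(m) test_subject$params[[m]]$A, 0))
  ok <- t >= 1
  expect_lt(max(abs(a[ok, ] - act[ok, ])), 0.05)
  # zero activation stays at the noise floor
  act0 <- act * 0
  raw0 <- synthesize_raw_emg(act0, test_subject, seed = 2, rate = fs)
  env0 <- normalize_mvc(envelope(raw0), test_subject$mvc, fs)
  expect_lt(max(env0$data[t >= 1, ]), 0.03)
  # same seed, same signal
  raw_b <- synthesize_raw_emg(act, test_subject, seed = 2, rate = fs)
  expect_identical(raw$data, raw_b$data)
})

test_that("NOEXO trials have silent cables and assisted trials converge", {
  tr <- quick_trial("NOEXO")
  expect_true(all(tr$cable$F_desired_N == 0))
  expect_true(all(tr$cable$F_measured_N == 0))
  trn <- quick_trial("NMBC")
  expect_lte(trn$residual, 0.5)
  # fixed-point residuals contract monotonically
  expect_true(all(diff(trn$residual_history) < 0))
  # converged energy balance: biological + exosuit moment meets the demand
  ok <- !trn$saturated
  balance <- trn$loads$moments$M_total_Nm + trn$M_exo - trn$M_id
  expect_lt(max(abs(balance[ok])), 0.5 + max(trn$residual_history) * 1e-2)
})

test_that("zero compliance reproduces NOEXO activations under assistance", {
  s0 <- test_subject
  s0$compliance <- 0
  tr_no <- quick_trial("NOEXO", subject = s0)
  tr_as <- quick_trial("NMBC", subject = s0)
  expect_identical(tr_as$activations, tr_no$activations)
})

test_that("assisted NMBC lifting lowers extensor activation below NOEXO", {
  tr_no <- quick_trial("NOEXO", box_mass = 15)
  tr_as <- quick_trial("NMBC", box_mass = 15)
  expect_lt(mean(tr_as$activations[, extensor_names]),
            mean(tr_no$activations[, extensor_names]))
})

test_that("cohorts are reproducible, truncated and sized to the target stats", {
  co1 <- generate_cohort(10, test_protocol, seed = 42)
  co2 <- generate_cohort(10, test_protocol, seed = 42)
  expect_identical(co1, co2)
  masses <- vapply(co1, function(s) s$anthro$body_mass, 0)
  heights <- vapply(co1, function(s) 1.73 * s$anthro$L_t / 0.5, 0)
  expect_true(all(abs(masses - 67) <= 2 * 9))
  expect_true(all(abs(heights - 1.73) <= 2 * 0.07))
  expect_lt(abs(mean(masses) - 67), 9)
  # ground-truth scales sit inside the calibration bounds
  for (s in co1) {
    expect_true(all(s$truth_vector[1:4] >= 0.5 & s$truth_vector[1:4] <= 2.5))
    expect_true(all(s$truth_vector[7:10] > -3 & s$truth_vector[7:10] <= 0))
  }
})

test_that("trials persist as CSV bundles with JSON sidecars", {
  tr <- quick_trial(rate = 100)
  dir <- tempfile()
  sidecar <- write_trial(tr, dir)
  expect_true(file.exists(sidecar))
  meta <- jsonlite::read_json(sidecar)
  expect_equal(meta$subject, tr$subject_id)
  expect_equal(meta$seed, tr$seed)
  csv <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  expect_length(csv, 1)
  expect_equal(nrow(read.csv(csv)), length(tr$time))
})
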