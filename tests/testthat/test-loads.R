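anthro67 <- anthropometry(body_mass = 67)

test_that("EMG-driven moments match a brute-force summation on a small case", {
  mtus <- c("iliocostalis_l", "longissimus_lumbar_l", "rectus_abdominis_l")
  sur <- default_surr[mtus]
  pars <- default_pars[mtus]
  withr::with_seed(11, {
    theta <- runif(5, 0, 1)
    act <- matrix(runif(15), 5, 3, dimnames = list(NULL, mtus))
  })
  dt <- 0.01
  lo <- emg_driven_moments(act, sur, pars, theta, dt)
  # naive loop oracle
  expected <- numeric(5)
  for (m in mtus) {
    p <- pars[[m]]
    ev <- evaluate_surrogate(sur[[m]], theta)
    fk <- fiber_kinematics(ev$length, p)
    v <- fiber_velocity(fk$l_norm, dt, p)
    for (i in 1:5) {
      f <- mtu_force(act[i, m], fk$l_norm[i], v[i], fk$phi[i], p)
      expected[i] <- expected[i] + ev$moment_arm[i] * f$total
    }
  }
  expect_equal(lo$moments$M_total_Nm, expected, tolerance = 1e-12)
  expect_equal(lo$moments$M_total_Nm,
               lo$moments$M_active_Nm + lo$moments$M_passive_Nm,
               tolerance = 1e-9)
})

test_that("zero activation with slack fibres produces zero moment", {
  theta <- rep(0, 20)   # neutral: l_norm = 1, no passive force
  act <- matrix(0, 20, 8, dimnames = list(NULL, names(default_surr)))
  lo <- emg_driven_moments(act, default_surr, default_pars, theta, 0.01)
  expect_true(all(abs(lo$moments$M_total_Nm) < 1e-9))
  expect_error(emg_driven_moments(act, default_surr, default_pars,
                                  rep(0, 19), 0.01),
               "timebase mismatch")
})

test_that("active/passive moment decomposition holds on a realistic trial", {
  tr <- quick_trial()
  m <- tr$loads$moments
  expect_lt(max(abs(m$M_total_Nm - m$M_active_Nm - m$M_passive_Nm)), 1e-9)
})

test_that("compression reduces to gravity terms without muscle force", {
  n <- 4
  fake <- list(F_total = matrix(0, n, 1), c = 1)
  # upright, no box: superincumbent weight only (m_ub = 40.2 kg)
  comp <- compression_force(fake, rep(0, n), anthro67)
  expect_equal(comp$Fcomp_N, rep(40.2 * 9.81, n))
  expect_equal(comp$Fcomp_N[1], 394.4, tolerance = 1e-3)
  # holding a 15 kg box upright adds exactly its weight, 147.15 N
  comp_box <- compression_force(fake, rep(0, n), anthro67, 15, rep(TRUE, n))
  expect_equal(comp_box$Fcomp_N - comp$Fcomp_N, rep(15 * 9.81, n))
  expect_equal(comp_box$Fcomp_N[1] - comp$Fcomp_N[1], 147.15)
  # horizontal trunk: gravity term vanishes; single muscle with c = 1
  fake2 <- list(F_total = matrix(1000, 1, 1), c = 1)
  expect_equal(compression_force(fake2, pi / 2, anthro67)$Fcomp_N, 1000)
  # body-weight normalization
  expect_equal(comp$Fcomp_BW, comp$Fcomp_N / (67 * 9.81))
  expect_error(compression_force(fake, 0, anthro67, box_mass = -1), ">= 0")
})

test_that("top-down inverse dynamics matches closed-form arithmetic", {
  expect_equal(top_down_id(0, anthro67), 0)
  # upper-body term at 30 degrees: 40.2 * 9.81 * 0.25 * 0.5
  expect_equal(top_down_id(pi / 6, anthro67),
               40.2 * 9.81 * 0.25 * 0.5)
  expect_equal(top_down_id(pi / 6, anthro67), 49.30, tolerance = 1e-3)
  # 5 kg box term at 30 degrees: 5 * 9.81 * (0.5*0.5 + 0.3) = 26.98
  box_term <- top_down_id(pi / 6, anthro67, 5, TRUE) -
    top_down_id(pi / 6, anthro67)
  expect_equal(box_term, 5 * 9.81 * (0.5 * 0.5 + 0.3))
  expect_equal(box_term, 26.98, tolerance = 1e-3)
  # monotone in theta on [0, pi/2] for fixed box state
  th <- seq(0, pi / 2, length.out = 50)
  expect_true(all(diff(top_down_id(th, anthro67, 15, TRUE)) > 0))
  # optional inertial term
  expect_gt(top_down_id(0.5, anthro67, theta_ddot = 1),
            top_down_id(0.5, anthro67))
})

test_that("box-contact detection applies hysteresis on noisy crossings", {
  expect_true(all(!detect_box_contact(rep(0.4, 100), 0.5)))
  step <- c(rep(0.40, 50), rep(0.60, 50))
  st <- detect_box_contact(step, 0.5)
  expect_equal(which(diff(st) != 0), 50)
  # noise +-0.5 cm around the threshold: a single transition
  withr::with_seed(9, {
    noisy <- c(rep(0.45, 50),
               seq(0.45, 0.55, length.out = 100) + runif(100, -5e-3, 5e-3),
               rep(0.55, 50))
  })
  st2 <- detect_box_contact(noisy, 0.5)
  expect_equal(sum(diff(st2) != 0), 1)
})

test_that("load estimates export to CSV with the documented columns", {
  tr <- quick_trial(rate = 100)
  path <- tempfile(fileext = ".csv")
  write_load_estimates(tr$loads, path, tr$compression, tr$box_state)
  df <- read.csv(path)
  expect_named(df, c("time_s", "M_total_Nm", "M_active_Nm", "M_passive_Nm",
                     "Fcomp_N", "Fcomp_BW", "box_state"))
  expect_equal(nrow(df), length(tr$time))
})
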