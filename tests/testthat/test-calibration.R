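cal_trial <- function(subject, mass, seed) {
  tr <- generate_trial(subject, "NOEXO", mass, test_protocol, default_surr,
                       seed = seed, rate = 100)
  list(theta_l5s1 = tr$theta_l5s1, u = tr$u, M_id = tr$M_id, dt = tr$dt,
       box_mass = tr$box_mass)
}

test_that("the objective is the summed squared moment error", {
  cfg <- calibration_config()
  trials <- list(cal_trial(test_subject, 5, 21), cal_trial(test_subject, 15, 22))
  groups <- unique(sub("_(l|r)$", "", names(test_subject$params)))
  obj <- make_objective(trials, default_surr, test_subject$params, cfg)
  truth <- c(rep(1, 4), 1, 1,
             vapply(groups, function(g)
               test_subject$params[[paste0(g, "_l")]]$A, 0))
  # the subject's own parameters reproduce the reference: near-zero error
  f_truth <- obj(truth)
  peak_sq <- max(abs(trials[[2]]$M_id))^2
  expect_lt(f_truth, 1e-10 * peak_sq * length(trials[[1]]$M_id))
  # brute-force double loop oracle on the same candidate
  cand <- truth + c(rep(0.2, 4), 0, 0, rep(0.1, 4))
  p <- apply_param_vector(test_subject$params, cand, groups)
  sse <- 0
  for (tr in trials) {
    A <- vapply(colnames(tr$u), function(m) p[[m]]$A, 0)
    a <- excitation_to_activation(tr$u, A)
    lo <- emg_driven_moments(a, default_surr, p, tr$theta_l5s1, tr$dt)
    sse <- sse + sum((lo$moments$M_total_Nm - tr$M_id)^2)
  }
  expect_equal(obj(cand), sse, tolerance = 1e-9)
  # a constant 1 N m reference offset adds one unit per sample
  trials_off <- lapply(trials, function(tr) { tr$M_id <- tr$M_id + 1; tr })
  obj_off <- make_objective(trials_off, default_surr, test_subject$params, cfg)
  n_samples <- sum(vapply(trials, function(tr) length(tr$M_id), 0))
  # residual at the truth is ~0, so the objective is one unit per sample
  expect_equal(obj_off(truth), n_samples, tolerance = 1e-3)
  # out-of-bounds candidates get the penalty value
  expect_equal(obj(truth * 100), .Machine$double.xmax)
})

test_that("simulated annealing finds the optimum of a convex bowl", {
  fn <- function(x) sum((x - 0.7)^2)
  fit <- simulated_annealing(fn, c(0, 0), c(1, 1),
                             config = calibration_config(seed = 5))
  expect_lt(max(abs(fit$par - 0.7)), 1e-2)
  expect_lte(fit$evals, 20000)
  # best-so-far trace is non-increasing
  expect_true(all(diff(fit$trace) <= 1e-15))
})

test_that("simulated annealing is reproducible and respects a zero budget", {
  fn <- function(x) sum(x^2) + sin(10 * x[1])
  cfg <- calibration_config(seed = 9, max_evals = 2000)
  f1 <- simulated_annealing(fn, -1, 1, config = cfg)
  f2 <- simulated_annealing(fn, -1, 1, config = cfg)
  expect_identical(f1$par, f2$par)
  expect_identical(f1$trace, f2$trace)
  f3 <- simulated_annealing(fn, -1, 1, config = calibration_config(
    seed = 9, max_evals = 0))
  expect_equal(f3$par, 0)       # midpoint start returned untouched
  expect_true(f3$no_improvement)
})

test_that("calibration demands one repetition per weight condition", {
  trials <- list(cal_trial(test_subject, 5, 21))
  expect_error(
    calibrate(default_surr, default_pars, trials,
              calibration_config(max_evals = 10)),
    "15 kg")
})

test_that("starting at the truth, calibration stays at the noise floor", {
  trials <- list(cal_trial(test_subject, 5, 21),
                 cal_trial(test_subject, 15, 22))
  # baseline = the generating parameters themselves; tiny budget
  cal <- calibrate(default_surr, test_subject$params, trials,
                   calibration_config(max_evals = 400, seed = 4))
  expect_true(all(cal$rmse_pct_peak < 2))
  expect_true(all(cal$par >= param_bounds(
    calibration_config(), unique(sub("_(l|r)$", "",
                                     names(default_pars))))$lower))
})

test_that("two subjects calibrate independently under different seeds", {
  # moderate budgets: this checks independence and objective descent, not
  # full parameter recovery (that experiment runs in the acceptance suite)
  co <- generate_cohort(2, test_protocol, seed = 7)
  cals <- lapply(1:2, function(i) {
    trials <- list(cal_trial(co[[i]], 5, 40 + i), cal_trial(co[[i]], 15, 50 + i))
    calibrate(default_surr, default_pars, trials,
              calibration_config(max_evals = 3000, seed = 60 + i))
  })
  expect_false(identical(cals[[1]]$par, cals[[2]]$par))
  for (cal in cals) {
    expect_lte(cal$value, cal$trace[1])
    expect_true(all(diff(cal$trace) <= 1e-12))
    expect_true(all(cal$rmse_pct_peak < 100))
    expect_length(cal$boundary_pinned, 10L)
  }
})
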