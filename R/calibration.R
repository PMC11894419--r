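#' Calibration configuration
#'
#' Bounds and annealing schedule for EMG-driven model calibration. The
#' calibrated vector holds one maximum-isometric-force scale and one
#' activation shape factor per muscle group (bilateral pair), plus global
#' tendon-slack-length and optimal-fibre-length scales:
#' `c(F_scale[groups], lts_scale, lopt_scale, A[groups])`.
#'
#' @param F_max_scale,l_ts_scale,l_opt_scale,A_bounds two-element bounds.
#' @param t0 initial temperature; `NULL` scales it from the objective at the
#'   start point.
#' @param cooling geometric cooling factor per temperature level.
#' @param ns step-adjustment interval (cycles over all dimensions).
#' @param nt step adjustments per temperature level.
#' @param max_evals objective evaluation budget.
#' @param seed RNG seed, recorded in the result.
#' @param tol convergence tolerance on the objective (stop when the best
#'   objective improves by less than `tol` over a full temperature level,
#'   after at least 10 levels).
#' @return object of class `calibration_config`.
#' @export
calibration_config <- function(F_max_scale = c(0.5, 2.5),
                               l_ts_scale = c(0.95, 1.05),
                               l_opt_scale = c(0.975, 1.025),
                               A_bounds = c(-2.99, 0),
                               t0 = NULL, cooling = 0.85,
                               ns = 5, nt = 4,
                               max_evals = 20000, seed = 1,
                               tol = 1e-10) {
  chk <- function(b, nm) {
    if (length(b) != 2 || b[1] >= b[2]) {
      stop("calibration_config: degenerate bounds for ", nm)
    }
  }
  chk(F_max_scale, "F_max_scale"); chk(l_ts_scale, "l_ts_scale")
  chk(l_opt_scale, "l_opt_scale"); chk(A_bounds, "A_bounds")
  structure(list(F_max_scale = F_max_scale, l_ts_scale = l_ts_scale,
                 l_opt_scale = l_opt_scale, A_bounds = A_bounds,
                 t0 = t0, cooling = cooling, ns = ns, nt = nt,
                 max_evals = max_evals, seed = seed, tol = tol),
            class = "calibration_config")
}

# Muscle group of an MTU name: base name without the _l/_r side suffix.
mtu_group_of <- function(names) sub("_(l|r)$", "", names)

#' Apply a calibration parameter vector to an MTU parameter set
#'
#' @param params named list of [mtu_params()].
#' @param vec parameter vector
#'   `c(F_scale per group, lts_scale, lopt_scale, A per group)`.
#' @param groups character vector of group names fixing the vector layout;
#'   defaults to the unique groups of `params` in order.
#' @return modified parameter list.
#' @export
apply_param_vector <- function(params, vec, groups = NULL) {
  gs <- mtu_group_of(names(params))
  if (is.null(groups)) groups <- unique(gs)
  k <- length(groups)
  stopifnot(length(vec) == 2 * k + 2)
  F_scale <- stats::setNames(vec[seq_len(k)], groups)
  lts_scale <- vec[k + 1]
  lopt_scale <- vec[k + 2]
  A <- stats::setNames(vec[k + 2 + seq_len(k)], groups)
  out <- params
  for (m in names(params)) {
    g <- gs[match(m, names(params))]
    out[[m]]$F_max <- params[[m]]$F_max * F_scale[[g]]
    out[[m]]$l_ts <- params[[m]]$l_ts * lts_scale
    out[[m]]$l_opt <- params[[m]]$l_opt * lopt_scale
    out[[m]]$A <- A[[g]]
  }
  out
}

param_bounds <- function(config, groups) {
  k <- length(groups)
  lower <- c(rep(config$F_max_scale[1], k), config$l_ts_scale[1],
             config$l_opt_scale[1], rep(config$A_bounds[1], k))
  upper <- c(rep(config$F_max_scale[2], k), config$l_ts_scale[2],
             config$l_opt_scale[2], rep(config$A_bounds[2], k))
  nm <- c(paste0("F_scale.", groups), "lts_scale", "lopt_scale",
          paste0("A.", groups))
  list(lower = stats::setNames(lower, nm), upper = stats::setNames(upper, nm))
}

#' Calibration objective: summed squared moment error
#'
#' Builds the deterministic objective minimized during calibration: the sum
#' over calibration trials and samples of the squared difference between the
#' EMG-driven total L5/S1 moment and the inverse-dynamics reference moment.
#' Out-of-bounds parameter vectors return the largest finite value.
#'
#' @param trials list of calibration trials; each needs `theta_l5s1`,
#'   an excitation matrix `u` (samples x MTU), a reference moment `M_id`
#'   and `dt` (see [generate_trial()]).
#' @param surrogates,params model geometry surrogates and baseline
#'   parameters.
#' @param config a [calibration_config()] (for the bounds).
#' @return function mapping a parameter vector to a scalar >= 0.
#' @export
make_objective <- function(trials, surrogates, params, config) {
  groups <- unique(mtu_group_of(names(params)))
  b <- param_bounds(config, groups)
  pre <- lapply(trials, function(tr) {
    list(geom = precompute_geometry(surrogates, tr$theta_l5s1),
         u = as.matrix(tr$u)[, names(surrogates), drop = FALSE],
         M_id = tr$M_id, dt = tr$dt)
  })
  gs_per_mtu <- mtu_group_of(names(surrogates))
  k <- length(groups)
  function(vec) {
    if (any(vec < b$lower) || any(vec > b$upper)) {
      return(.Machine$double.xmax)
    }
    p <- apply_param_vector(params, vec, groups)
    A <- stats::setNames(vec[k + 2 + seq_len(k)], groups)[gs_per_mtu]
    sse <- 0
    for (tr in pre) {
      # matrix form of the exponential shaping (validated inputs)
      Am <- matrix(A, nrow(tr$u), ncol(tr$u), byrow = TRUE)
      a <- (exp(Am * tr$u) - 1) / (exp(Am) - 1)
      zero <- A == 0
      if (any(zero)) a[, zero] <- tr$u[, zero]
      core <- moments_core(a, tr$geom, p, tr$dt)
      sse <- sse + sum((core$M_total - tr$M_id)^2)
    }
    sse
  }
}

#' Bounded adaptive simulated annealing
#'
#' Corana-style simulated annealing: candidate moves perturb one coordinate
#' at a time with per-dimension step sizes that are adapted toward roughly
#' 50% acceptance, temperature is cooled geometrically, the search restarts
#' each level from the best-ever point, and the best-ever point is
#' returned. Fully reproducible for a fixed seed.
#'
#' @param fn objective function of a numeric vector; must be finite at `x0`.
#' @param lower,upper bounds (finite, `lower < upper`).
#' @param x0 start point; defaults to the midpoint of the bounds.
#' @param config a [calibration_config()] (annealing fields are used).
#' @return list with `par` (best point), `value`, `evals`, `trace`
#'   (best objective after each temperature level), `accepted`, `seed`,
#'   `no_improvement` flag.
#' @export
simulated_annealing <- function(fn, lower, upper, x0 = NULL,
                                config = calibration_config()) {
  d <- length(lower)
  stopifnot(length(upper) == d, all(lower < upper))
  if (is.null(x0)) x0 <- (lower + upper) / 2
  withr::with_seed(config$seed, {
    x <- pmin(pmax(x0, lower), upper)
    f <- fn(x)
    f_init <- f
    best_x <- x; best_f <- f
    evals <- 1L; accepted <- 0L
    if (config$max_evals < 2) {
      return(list(par = x, value = f, evals = evals,
                  trace = f, accepted = 0L, seed = config$seed,
                  no_improvement = TRUE))
    }
    t <- if (is.null(config$t0)) max(abs(f), 1e-8) else config$t0
    v <- (upper - lower) / 2
    trace <- c()
    level <- 0L
    repeat {
      level <- level + 1L
      level_best <- best_f
      for (adj in seq_len(config$nt)) {
        n_acc <- integer(d)
        for (cyc in seq_len(config$ns)) {
          for (i in seq_len(d)) {
            if (evals >= config$max_evals) break
            xp <- x
            xp[i] <- x[i] + stats::runif(1, -1, 1) * v[i]
            if (xp[i] < lower[i] || xp[i] > upper[i]) {
              xp[i] <- stats::runif(1, lower[i], upper[i])
            }
            fp <- fn(xp)
            evals <- evals + 1L
            if (fp <= f || stats::runif(1) < exp((f - fp) / t)) {
              x <- xp; f <- fp
              n_acc[i] <- n_acc[i] + 1L
              accepted <- accepted + 1L
              if (f < best_f) { best_f <- f; best_x <- x }
            }
          }
          if (evals >= config$max_evals) break
        }
        # Corana step adaptation toward ~50% acceptance per dimension
        ratio <- n_acc / config$ns
        up <- ratio > 0.6
        dn <- ratio < 0.4
        v[up] <- v[up] * (1 + 2 * (ratio[up] - 0.6) / 0.4)
        v[dn] <- v[dn] / (1 + 2 * (0.4 - ratio[dn]) / 0.4)
        v <- pmin(v, upper - lower)
        if (evals >= config$max_evals) break
      }
      trace <- c(trace, best_f)
      t <- t * config$cooling
      x <- best_x; f <- best_f
      if (evals >= config$max_evals) break
      if (level >= 10 && (level_best - best_f) < config$tol &&
          t < 1e-6 * max(abs(best_f), 1)) break
    }
    list(par = best_x, value = best_f, evals = evals, trace = trace,
         accepted = accepted, seed = config$seed,
         no_improvement = !(best_f < f_init))
  })
}

#' Calibrate an EMG-driven trunk model
#'
#' Tunes group-shared maximum-isometric-force scales, global tendon-slack
#' and optimal-fibre-length scales, and group activation shape factors by
#' simulated annealing so that EMG-driven total L5/S1 moments match the
#' inverse-dynamics reference, using one lifting repetition per weight
#' condition.
#'
#' @param surrogates,params model geometry and baseline parameters.
#' @param trials list of calibration trials (one repetition per weight
#'   condition; each carries `theta_l5s1`, `u`, `M_id`, `dt`, `box_mass`).
#' @param config a [calibration_config()].
#' @param required_masses weight conditions that must be present, kg.
#' @return object of class `calibration_result`: fields `params`
#'   (calibrated list), `par` (vector), `par_names`, `rmse_Nm`,
#'   `rmse_pct_peak` (per trial), `value`, `evals`, `trace`, `seed`,
#'   `boundary_pinned`.
#' @export
calibrate <- function(surrogates, params, trials,
                      config = calibration_config(),
                      required_masses = c(5, 15)) {
  masses <- vapply(trials, function(tr) tr$box_mass, 0)
  missing <- setdiff(required_masses, masses)
  if (length(missing)) {
    stop("calibrate: missing calibration trial(s) for weight condition(s) ",
         paste(missing, collapse = ", "), " kg; trials for each of {",
         paste(required_masses, collapse = ", "), "} kg are required")
  }
  groups <- unique(mtu_group_of(names(params)))
  b <- param_bounds(config, groups)
  obj <- make_objective(trials, surrogates, params, config)
  k <- length(groups)
  x0 <- c(rep(1, k), 1, 1,
          vapply(groups, function(g) {
            params[[grep(g, names(params), fixed = TRUE)[1]]]$A
          }, 0))
  x0 <- pmin(pmax(x0, b$lower), b$upper)
  fit <- simulated_annealing(obj, b$lower, b$upper, x0 = x0, config = config)
  cal_params <- apply_param_vector(params, fit$par, groups)
  rmse <- vapply(trials, function(tr) {
    lo <- emg_driven_moments(
      excitation_to_activation(
        as.matrix(tr$u)[, names(surrogates), drop = FALSE],
        vapply(names(surrogates), function(m) cal_params[[m]]$A, 0)),
      surrogates, cal_params, tr$theta_l5s1, tr$dt)
    sqrt(mean((lo$moments$M_total_Nm - tr$M_id)^2))
  }, 0)
  peak <- vapply(trials, function(tr) max(abs(tr$M_id)), 0)
  pinned <- abs(fit$par - b$lower) < 1e-6 | abs(fit$par - b$upper) < 1e-6
  structure(list(params = cal_params, par = fit$par,
                 par_names = names(b$lower),
                 rmse_Nm = rmse, rmse_pct_peak = 100 * rmse / peak,
                 value = fit$value, evals = fit$evals, trace = fit$trace,
                 seed = config$seed, boundary_pinned = pinned),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(
    "<calibration_result> objective %.3g after %d evaluations (seed %d)\n",
    x$value, x$evals, x$seed))
  cat("  per-trial moment RMSE: ",
      paste(sprintf("%.2f N m (%.1f%% of peak)", x$rmse_Nm, x$rmse_pct_peak),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Write a calibration report as JSON
#'
#' @param result a `calibration_result`.
#' @param path output path.
#' @export
write_calibration_report <- function(result, path) {
  jsonlite::write_json(
    list(parameters = stats::setNames(as.list(result$par), result$par_names),
         rmse_Nm = result$rmse_Nm,
         rmse_pct_peak = result$rmse_pct_peak,
         objective = result$value, evaluations = result$evals,
         seed = result$seed,
         boundary_pinned = stats::setNames(as.list(result$boundary_pinned),
                                           result$par_names)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
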