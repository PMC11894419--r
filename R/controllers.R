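#' NMBC controller configuration
#'
#' The neuro-mechanical model-based controller commands a total cable force
#' proportional to the low-pass-filtered, delayed *active* component of the
#' estimated L5/S1 moment:
#' \deqn{F(t) = \mathrm{clamp}\!\left(\frac{SR \cdot
#'   \mathrm{LPF}(M_{active})(t - \tau)}{d_{cable}},\; 0,\; 2 F_{ceil}\right)}
#' with support ratio `SR = 0.2`, cable moment arm `d_cable = 0.08` m,
#' electromechanical delay `tau = 80` ms and a second-order Butterworth
#' low-pass at 10 Hz. The per-cable ceiling (445 N, from a 45.35 kg load
#' cell rating) caps each of the two cables; desired force is the two-cable
#' total, split equally.
#'
#' @param support_ratio assistance gain SR in (0, 1].
#' @param d_cable cable moment arm about L5/S1, m.
#' @param delay_s electromechanical delay, s.
#' @param lp_cutoff low-pass cutoff, Hz.
#' @param cable_ceiling per-cable force ceiling, N.
#' @return object of class `nmbc_config`.
#' @export
nmbc_config <- function(support_ratio = 0.20, d_cable = 0.08,
                        delay_s = 0.080, lp_cutoff = 10,
                        cable_ceiling = 445) {
  stopifnot(support_ratio > 0, support_ratio <= 1, d_cable > 0,
            delay_s >= 0, cable_ceiling > 0)
  structure(list(support_ratio = support_ratio, d_cable = d_cable,
                 delay_s = delay_s, lp_cutoff = lp_cutoff,
                 cable_ceiling = cable_ceiling),
            class = "nmbc_config")
}

#' TIBC controller configuration
#'
#' The trunk-inclination-based controller commands a cable force
#' proportional to trunk inclination, with no knowledge of the lifted load:
#' \eqn{F(t) = \mathrm{clamp}(k \max(\theta(t), 0), 0, 2F_{ceil})}.
#' The gain `k` is set by [tibc_tune()].
#'
#' @param k gain, N/rad (> 0 once tuned; `NA` before tuning).
#' @param theta_ref reference tuning inclination, rad (default 30 degrees).
#' @param tune_box_mass tuning load, kg.
#' @param cable_ceiling per-cable ceiling, N.
#' @return object of class `tibc_config`.
#' @export
tibc_config <- function(k = NA_real_, theta_ref = 30 * pi / 180,
                        tune_box_mass = 5, cable_ceiling = 445) {
  structure(list(k = k, theta_ref = theta_ref,
                 tune_box_mass = tune_box_mass,
                 cable_ceiling = cable_ceiling),
            class = "tibc_config")
}

delay_samples <- function(x, delay_s, sample_rate) {
  shift_exact <- delay_s * sample_rate
  shift <- round(shift_exact)
  if (abs(shift_exact - shift) > 0.4) {
    warning(sprintf(
      "delay of %.4f s is %.2f samples at %g Hz; using nearest-sample shift of %d",
      delay_s, shift_exact, sample_rate, shift))
  }
  if (shift <= 0) return(x)
  c(rep(0, shift), x[seq_len(length(x) - shift)])
}

#' NMBC desired cable force
#'
#' @param M_active active L5/S1 moment series, N m (extension-positive).
#' @param cfg an [nmbc_config()].
#' @param sample_rate series sampling rate, Hz (>= 100).
#' @return desired total (two-cable) force series, N.
#' @export
nmbc_desired_force <- function(M_active, cfg = nmbc_config(),
                               sample_rate = 1000) {
  if (sample_rate < 100) {
    stop("nmbc_desired_force: sample_rate must be >= 100 Hz")
  }
  filt <- butter_causal(M_active, 2, cfg$lp_cutoff, sample_rate, "low")
  scaled <- cfg$support_ratio * filt / cfg$d_cable
  delayed <- delay_samples(scaled, cfg$delay_s, sample_rate)
  pmin(pmax(delayed, 0), 2 * cfg$cable_ceiling)
}

#' Tune the TIBC gain against the quasi-static moment model
#'
#' Sets the gain so that at the reference pose (default: holding a 5 kg box
#' at 30 degrees of trunk inclination) TIBC delivers the same force an NMBC
#' would for the corresponding static moment:
#' \deqn{k = \frac{SR \cdot M_{static}(\theta_{ref}, m_{box})}
#'   {d_{cable}\,\theta_{ref}}.}
#'
#' @param anthro an [anthropometry()].
#' @param cfg a [tibc_config()] draft.
#' @param nmbc an [nmbc_config()] supplying `SR` and `d_cable`.
#' @return the `tibc_config` with `k` set.
#' @export
tibc_tune <- function(anthro, cfg = tibc_config(), nmbc = nmbc_config()) {
  M_static <- top_down_id(cfg$theta_ref, anthro,
                          box_mass = cfg$tune_box_mass, box_state = TRUE)
  if (M_static <= 0) {
    stop("tibc_tune: static reference moment is not positive (",
         format(M_static), " N m)")
  }
  cfg$k <- nmbc$support_ratio * M_static / (nmbc$d_cable * cfg$theta_ref)
  cfg
}

#' TIBC desired cable force
#'
#' Memoryless in the inclination angle; identical kinematics give identical
#' forces regardless of the load carried.
#'
#' @param theta trunk inclination series, rad.
#' @param cfg a tuned [tibc_config()].
#' @return desired total (two-cable) force series, N.
#' @export
tibc_desired_force <- function(theta, cfg) {
  if (is.na(cfg$k) || cfg$k <= 0) {
    stop("tibc_desired_force: gain k is not tuned; call tibc_tune() first")
  }
  pmin(cfg$k * pmax(theta, 0), 2 * cfg$cable_ceiling)
}

#' First-order actuator tracking plant
#'
#' Discrete first-order lag with optional seeded Gaussian measurement
#' noise, floored at zero:
#' \deqn{y[n] = y[n-1] + \frac{dt}{\tau_{lag} + dt}(u[n] - y[n-1]) +
#'   \epsilon[n].}
#' With zero lag and zero noise the plant is the identity.
#'
#' @param desired desired force series, N.
#' @param dt sample interval, s.
#' @param lag_s lag time constant, s (>= 0).
#' @param noise_sd measurement noise standard deviation, N.
#' @param seed RNG seed for the noise realization.
#' @return measured force series, N.
#' @export
actuator_track <- function(desired, dt, lag_s = 0.02, noise_sd = 0,
                           seed = 1) {
  stopifnot(lag_s >= 0, dt > 0)
  alpha <- dt / (lag_s + dt)
  n <- length(desired)
  y <- numeric(n)
  prev <- 0
  for (i in seq_len(n)) {
    prev <- prev + alpha * (desired[i] - prev)
    y[i] <- prev
  }
  if (noise_sd > 0) {
    y <- y + withr::with_seed(seed, stats::rnorm(n, 0, noise_sd))
  }
  pmax(y, 0)
}

#' Assemble a cable command record
#'
#' @param time_s time vector, s.
#' @param desired,measured total-force series, N.
#' @return data frame `time_s, F_desired_N, F_measured_N, F_per_cable_N`
#'   (class `cable_command`); the per-cable force is half the desired total
#'   (symmetric split).
#' @export
cable_command <- function(time_s, desired, measured) {
  structure(data.frame(time_s = time_s, F_desired_N = desired,
                       F_measured_N = measured,
                       F_per_cable_N = desired / 2),
            class = c("cable_command", "data.frame"))
}
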