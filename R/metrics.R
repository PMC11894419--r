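#' Phase windows of the normalized lifting cycle
#'
#' Fractions of the time-normalized cycle: lowering (bending over) spans
#' 1-25% and 60-75%, lifting (raising up) 25-40% and 75-100%, erect stance
#' 40-60%. Sample assignment is half-open \[a, b), with the 100% endpoint
#' included in its window.
#'
#' @return named list of lists of `c(lo, hi)` percent intervals.
#' @export
phase_windows <- function() {
  list(lowering = list(c(1, 25), c(60, 75)),
       lifting = list(c(25, 40), c(75, 100)),
       erect = list(c(40, 60)))
}

#' Human-exosuit work-loop area
#'
#' Signed shoelace integral of mass-normalized cable force over trunk
#' inclination around one closed lifting cycle, in N rad/kg. The sign
#' convention is positive when the force during the raising (decreasing
#' inclination) half exceeds the force during bending at the same angle —
#' i.e. a controller that works *with* the lift has a positive loop; any
#' memoryless force law has zero area.
#'
#' @param force total cable force series, N.
#' @param theta trunk inclination series, rad; first and last samples must
#'   agree within 1 degree (closed cycle).
#' @param body_mass subject mass, kg.
#' @return scalar area, N rad/kg.
#' @export
work_loop_area <- function(force, theta, body_mass) {
  stopifnot(length(force) == length(theta), body_mass > 0)
  n <- length(theta)
  if (abs(theta[1] - theta[n]) > pi / 180) {
    stop(sprintf(
      "work_loop_area: open trajectory (|theta_first - theta_last| = %.2f deg); crop the series to one closed cycle",
      abs(theta[1] - theta[n]) * 180 / pi))
  }
  closing <- (force[1] + force[n]) / 2 * (theta[1] - theta[n])
  -(pracma::trapz(theta, force) + closing) / body_mass
}

#' Force-tracking RMSE
#'
#' Root mean squared error between desired and measured cable force,
#' normalized to body mass (N/kg).
#'
#' @param desired,measured force series, N (equal length).
#' @param body_mass subject mass, kg.
#' @return scalar RMSE, N/kg.
#' @export
tracking_rmse <- function(desired, measured, body_mass) {
  if (length(desired) != length(measured)) {
    stop("tracking_rmse: length mismatch (", length(desired), " vs ",
         length(measured), ")")
  }
  sqrt(mean((desired - measured)^2)) / body_mass
}

#' Phase-resolved mean and peak of a cycle series
#'
#' Normalizes the cycle to 0-100% by time and reports mean and peak within
#' each phase window plus the whole cycle. Samples inside an optional
#' settling head (causal-filter transient) are excluded.
#'
#' @param series numeric series over one cycle.
#' @param time time vector, s (same length).
#' @param windows a [phase_windows()] list.
#' @param settle_s head duration excluded from statistics, s.
#' @return data frame with columns `phase`, `mean`, `peak`.
#' @export
phase_stats <- function(series, time, windows = phase_windows(),
                        settle_s = 0) {
  n <- length(series)
  if (n < 10L) stop("phase_stats: cycle shorter than 10 samples")
  stopifnot(length(time) == n)
  frac <- 100 * (time - time[1]) / (time[n] - time[1])
  keep <- time - time[1] >= settle_s
  in_window <- function(iv) {
    sel <- frac >= iv[1] & (frac < iv[2] | (iv[2] >= 100 & frac <= 100))
    sel & keep
  }
  rows <- lapply(names(windows), function(ph) {
    sel <- Reduce(`|`, lapply(windows[[ph]], in_window))
    data.frame(phase = ph, mean = mean(series[sel]),
               peak = max(series[sel]))
  })
  rows <- c(rows, list(data.frame(phase = "cycle",
                                  mean = mean(series[keep]),
                                  peak = max(series[keep]))))
  do.call(rbind, rows)
}

#' Percent reduction relative to a reference
#'
#' `100 * (reference - assisted) / reference`; the reference must be
#' positive.
#'
#' @param reference unassisted value (> 0).
#' @param assisted assisted value.
#' @return percent reduction (positive = assisted is lower).
#' @export
percent_reduction <- function(reference, assisted) {
  if (any(reference <= 0)) {
    stop("percent_reduction: reference must be > 0")
  }
  100 * (reference - assisted) / reference
}

#' Cumulative lumbosacral compression
#'
#' Trapezoidal time-integral of compression force over the first
#' `n_cycles` lifting cycles, in kN s.
#'
#' @param F_comp compression force series, N, covering at least `n_cycles`
#'   concatenated cycles.
#' @param time time vector, s.
#' @param n_cycles number of cycles to integrate (e.g. 1, 5, 10).
#' @param cycle_s duration of one cycle, s.
#' @return scalar cumulative compression, kN s.
#' @export
cumulative_compression <- function(F_comp, time, n_cycles,
                                   cycle_s = 8) {
  t_end <- n_cycles * cycle_s
  if (max(time) < t_end - 1e-9) {
    stop(sprintf(
      "cumulative_compression: series covers %.1f s but %d cycles need %.1f s",
      max(time), n_cycles, t_end))
  }
  sel <- time <= t_end + 1e-9
  pracma::trapz(time[sel], F_comp[sel]) / 1000
}

#' Summed mean and peak normalized EMG
#'
#' Per-channel mean and peak of the normalized envelopes within each phase
#' window, summed across channels (left + right), as used to report total
#' muscle-activity reductions.
#'
#' @param envelopes (samples x channels) normalized envelope matrix.
#' @param time time vector, s.
#' @param windows a [phase_windows()].
#' @param settle_s settling head excluded from statistics, s.
#' @return data frame `phase`, `sum_mean`, `sum_peak`.
#' @export
emg_summary <- function(envelopes, time, windows = phase_windows(),
                        settle_s = 0) {
  envelopes <- as.matrix(envelopes)
  per_ch <- lapply(seq_len(ncol(envelopes)), function(j) {
    phase_stats(envelopes[, j], time, windows, settle_s)
  })
  out <- per_ch[[1]][, "phase", drop = FALSE]
  out$sum_mean <- Reduce(`+`, lapply(per_ch, `[[`, "mean"))
  out$sum_peak <- Reduce(`+`, lapply(per_ch, `[[`, "peak"))
  out
}

#' Per-trial outcome metrics
#'
#' Computes the full outcome set for one `lifting_trial`: work-loop area,
#' tracking RMSE, mass-normalized mean/peak moment, mean/peak compression
#' in body weights, summed mean/peak normalized EMG (whole cycle and per
#' phase), using the trial's settling window.
#'
#' @param trial a `lifting_trial` from [generate_trial()].
#' @return one-row data frame of whole-cycle metrics with the per-phase
#'   tables attached as attributes `moment_phases`, `compression_phases`,
#'   `emg_phases`.
#' @export
trial_metrics <- function(trial) {
  bm <- trial$anthro$body_mass
  mom <- phase_stats(trial$loads$moments$M_total_Nm / bm, trial$time,
                     settle_s = trial$settle_s)
  comp <- phase_stats(trial$compression$Fcomp_BW, trial$time,
                      settle_s = trial$settle_s)
  emg <- emg_summary(trial$u, trial$time, settle_s = trial$settle_s)
  cyc <- function(df, col) df[df$phase == "cycle", col]
  out <- data.frame(
    subject = trial$subject_id, condition = trial$condition,
    box_mass = trial$box_mass, seed = trial$seed,
    work_loop_Nradkg = work_loop_area(trial$cable$F_measured_N,
                                      trial$theta_trunk, bm),
    tracking_rmse_Nkg = tracking_rmse(trial$cable$F_desired_N,
                                      trial$cable$F_measured_N, bm),
    mean_moment_Nmkg = cyc(mom, "mean"), peak_moment_Nmkg = cyc(mom, "peak"),
    mean_comp_BW = cyc(comp, "mean"), peak_comp_BW = cyc(comp, "peak"),
    sum_mean_emg = cyc(emg, "sum_mean"), sum_peak_emg = cyc(emg, "sum_peak"),
    mean_force_N = mean(trial$cable$F_desired_N[trial$time >= trial$settle_s]),
    stringsAsFactors = FALSE)
  attr(out, "moment_phases") <- mom
  attr(out, "compression_phases") <- comp
  attr(out, "emg_phases") <- emg
  out
}
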