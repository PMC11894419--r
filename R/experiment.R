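#' Experiment run configuration
#'
#' Settings for a full synthetic experiment: cohort size, repetitions,
#' model execution rate, conditions, weights, calibration budget and
#' output location. `ci_run_config()` is a reduced preset (2 subjects,
#' 2 repetitions, 100 Hz, smaller annealing budget) sized for continuous
#' integration.
#'
#' @param n_subjects cohort size.
#' @param reps repetitions per condition.
#' @param rate model execution rate, Hz.
#' @param conditions subset of `c("NOEXO", "NMBC", "TIBC")`.
#' @param box_masses weight conditions, kg.
#' @param seed global seed; all per-trial seeds derive from it.
#' @param use_ground_truth skip calibration and execute the model with the
#'   generating parameters.
#' @param sa_max_evals simulated-annealing budget per subject.
#' @param out_dir artifact directory (`NULL`: keep results in memory only).
#' @param write_trials also persist every trial as CSV + JSON sidecar.
#' @param protocol a [protocol_config()]; its `reps` field is overridden by
#'   `reps`.
#' @return object of class `run_config`.
#' @export
run_config <- function(n_subjects = 10, reps = 10, rate = 1000,
                       conditions = c("NOEXO", "NMBC", "TIBC"),
                       box_masses = c(5, 15), seed = 42,
                       use_ground_truth = FALSE, sa_max_evals = 20000,
                       out_dir = NULL, write_trials = FALSE,
                       protocol = protocol_config()) {
  conditions <- match.arg(conditions, c("NOEXO", "NMBC", "TIBC"),
                          several.ok = TRUE)
  if (!"NOEXO" %in% conditions) {
    stop("run_config: NOEXO must be included (reductions are relative to it)")
  }
  protocol$reps <- reps
  structure(list(n_subjects = n_subjects, reps = reps, rate = rate,
                 conditions = conditions, box_masses = box_masses,
                 seed = seed, use_ground_truth = use_ground_truth,
                 sa_max_evals = sa_max_evals, out_dir = out_dir,
                 write_trials = write_trials, protocol = protocol),
            class = "run_config")
}

#' @rdname run_config
#' @param ... overrides passed to [run_config()].
#' @export
ci_run_config <- function(...) {
  defaults <- list(n_subjects = 2, reps = 2, rate = 100,
                   use_ground_truth = FALSE, sa_max_evals = 4000)
  do.call(run_config, utils::modifyList(defaults, list(...)))
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  keep <- config[setdiff(names(config), "out_dir")]
  jsonlite::write_json(keep, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_log <- function(label, expr) {
  t0 <- proc.time()["elapsed"]
  res <- force(expr)
  message(sprintf("[exolift] %-12s %.1f s", label,
                  proc.time()["elapsed"] - t0))
  res
}

#' Run a full synthetic exosuit experiment
#'
#' Generates a virtual cohort, calibrates each subject's EMG-driven model
#' on the first repetition of each weight condition (unless
#' `use_ground_truth`), simulates all condition x weight x repetition
#' trials with shared per-repetition kinematics (so controller effects are
#' isolated), and assembles the outcome metrics with percent reductions
#' relative to NOEXO. Idempotent for a fixed seed.
#'
#' @param config a [run_config()].
#' @return object of class `metrics_report`: fields `per_trial` (tidy data
#'   frame), `summary` (condition x weight means across subjects),
#'   `reductions` (per subject and pooled, vs NOEXO), `cumulative`
#'   (kN s after 1/5/10 cycles where repetitions allow), `calibration`
#'   (per-subject RMSE summaries or `NULL`), `config_hash`, `seed`.
#' @export
run_experiment <- function(config = run_config()) {
  hash <- config_hash(config)
  protocol <- config$protocol
  surrogates <- stage_log("geometry", {
    fit_all_surrogates(build_reference_geometry())
  })
  cohort <- stage_log("cohort", {
    generate_cohort(config$n_subjects, protocol, seed = config$seed)
  })
  base_params <- default_mtu_params()
  nmbc <- nmbc_config()

  trial_seed <- function(si, mi, rep) {
    derive_seed(config$seed, si * 10000 + mi * 1000 + rep)
  }

  per_trial <- list()
  cumulative <- list()
  calibration <- list()
  for (si in seq_along(cohort)) {
    subject <- cohort[[si]]
    tibc <- tibc_tune(subject$anthro, tibc_config(), nmbc)
    exec_params <- if (config$use_ground_truth) {
      subject$params
    } else {
      cal_trials <- lapply(seq_along(config$box_masses), function(mi) {
        tr <- generate_trial(subject, "NOEXO", config$box_masses[mi],
                             protocol, surrogates,
                             seed = trial_seed(si, mi, 1),
                             rate = config$rate, nmbc = nmbc, tibc = tibc)
        list(theta_l5s1 = tr$theta_l5s1, u = tr$u, M_id = tr$M_id,
             dt = tr$dt, box_mass = tr$box_mass)
      })
      cal <- stage_log(paste0("calibrate ", subject$id), {
        calibrate(surrogates, base_params, cal_trials,
                  calibration_config(max_evals = config$sa_max_evals,
                                     seed = derive_seed(config$seed, si)),
                  required_masses = config$box_masses)
      })
      calibration[[subject$id]] <- data.frame(
        subject = subject$id, rmse_Nm = mean(cal$rmse_Nm),
        rmse_pct_peak = mean(cal$rmse_pct_peak), evals = cal$evals)
      cal$params
    }
    for (mi in seq_along(config$box_masses)) {
      mass <- config$box_masses[mi]
      for (cond in config$conditions) {
        comp_all <- numeric(0)
        time_all <- numeric(0)
        for (rep in seq_len(config$reps)) {
          trial <- generate_trial(subject, cond, mass, protocol,
                                  surrogates,
                                  seed = trial_seed(si, mi, rep),
                                  rate = config$rate, nmbc = nmbc,
                                  tibc = tibc, exec_params = exec_params)
          per_trial[[length(per_trial) + 1L]] <-
            cbind(trial_metrics(trial), rep = rep)
          offset <- (rep - 1) * protocol$cycle_s
          # drop the duplicated joint sample when concatenating cycles
          comp_all <- c(comp_all, trial$compression$Fcomp_N[
            if (rep == 1) TRUE else -1])
          time_all <- c(time_all, (trial$time + offset)[
            if (rep == 1) TRUE else -1])
          if (config$write_trials && !is.null(config$out_dir)) {
            write_trial(trial, file.path(config$out_dir, "trials"))
          }
        }
        for (nc in c(1, 5, 10)) {
          if (nc <= config$reps) {
            cumulative[[length(cumulative) + 1L]] <- data.frame(
              subject = subject$id, condition = cond, box_mass = mass,
              n_cycles = nc,
              kNs = cumulative_compression(comp_all, time_all, nc,
                                           protocol$cycle_s))
          }
        }
      }
    }
  }
  per_trial <- do.call(rbind, per_trial)
  cumulative <- do.call(rbind, cumulative)
  calibration <- if (length(calibration)) do.call(rbind, calibration) else NULL

  agg_cols <- c("work_loop_Nradkg", "tracking_rmse_Nkg", "mean_moment_Nmkg",
                "peak_moment_Nmkg", "mean_comp_BW", "peak_comp_BW",
                "sum_mean_emg", "sum_peak_emg", "mean_force_N")
  summary <- stats::aggregate(per_trial[agg_cols],
                              per_trial[c("condition", "box_mass")], mean)

  subj_means <- stats::aggregate(
    per_trial[agg_cols], per_trial[c("subject", "condition", "box_mass")],
    mean)
  red_cols <- c("mean_moment_Nmkg", "peak_moment_Nmkg", "mean_comp_BW",
                "peak_comp_BW", "sum_mean_emg", "sum_peak_emg")
  reductions <- list()
  for (cond in setdiff(config$conditions, "NOEXO")) {
    for (mass in config$box_masses) {
      ref <- subj_means[subj_means$condition == "NOEXO" &
                          subj_means$box_mass == mass, ]
      ass <- subj_means[subj_means$condition == cond &
                          subj_means$box_mass == mass, ]
      ass <- ass[match(ref$subject, ass$subject), ]
      for (col in red_cols) {
        reductions[[length(reductions) + 1L]] <- data.frame(
          subject = ref$subject, condition = cond, box_mass = mass,
          metric = col,
          reduction_pct = percent_reduction(ref[[col]], ass[[col]]))
      }
      # cumulative-compression reductions at the largest available horizon
      nmax <- max(cumulative$n_cycles)
      cref <- cumulative[cumulative$condition == "NOEXO" &
                           cumulative$box_mass == mass &
                           cumulative$n_cycles == nmax, ]
      cass <- cumulative[cumulative$condition == cond &
                           cumulative$box_mass == mass &
                           cumulative$n_cycles == nmax, ]
      cass <- cass[match(cref$subject, cass$subject), ]
      reductions[[length(reductions) + 1L]] <- data.frame(
        subject = cref$subject, condition = cond, box_mass = mass,
        metric = sprintf("cumulative_%dcycles_kNs", nmax),
        reduction_pct = percent_reduction(cref$kNs, cass$kNs))
    }
  }
  reductions <- do.call(rbind, reductions)
  pooled <- stats::aggregate(reductions["reduction_pct"],
                             reductions[c("condition", "box_mass", "metric")],
                             mean)

  report <- structure(
    list(per_trial = per_trial, summary = summary,
         reductions = reductions, pooled_reductions = pooled,
         cumulative = cumulative, calibration = calibration,
         config_hash = hash, seed = config$seed),
    class = "metrics_report")
  if (!is.null(config$out_dir)) write_metrics_report(report, config$out_dir)
  report
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> seed %d, config %s\n", x$seed,
              substr(x$config_hash, 1, 8)))
  print(x$summary, digits = 3)
  invisible(x)
}

#' Write a metrics report to disk
#'
#' Emits `metrics_report.json` plus tidy CSVs (`per_trial.csv`,
#' `reductions.csv`, `cumulative.csv`); every file carries the config hash
#' and seed.
#'
#' @param report a `metrics_report`.
#' @param dir output directory.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(config_hash = report$config_hash, seed = report$seed,
         summary = report$summary, pooled_reductions =
           report$pooled_reductions, cumulative = report$cumulative,
         calibration = report$calibration),
    file.path(dir, "metrics_report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows")
  stamp <- function(df) {
    df$config_hash <- report$config_hash
    df$seed <- report$seed
    df
  }
  utils::write.csv(stamp(report$per_trial),
                   file.path(dir, "per_trial.csv"), row.names = FALSE)
  utils::write.csv(stamp(report$reductions),
                   file.path(dir, "reductions.csv"), row.names = FALSE)
  utils::write.csv(stamp(report$cumulative),
                   file.path(dir, "cumulative.csv"), row.names = FALSE)
  invisible(dir)
}
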