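#' Lifting protocol configuration
#'
#' Encodes the study protocol the generator emulates: metronome-paced
#' (30 beats per minute, i.e. 2 s phases) stoop-lift repetitions with four
#' phases — (1) bending over to grab the box, (2) lifting to upright,
#' (3) bending over to place the box, (4) returning upright — with the box
#' resting on a 46.5 cm table, two weight conditions (5 and 15 kg) and 10
#' repetitions per condition.
#'
#' @param phase_s duration of each of the four phases, s.
#' @param peak_deg peak trunk inclination, degrees.
#' @param lambda lumbar share of trunk inclination (L5/S1 angle =
#'   `lambda * trunk inclination`).
#' @param box_masses weight conditions, kg.
#' @param reps repetitions per condition.
#' @param table_height box-contact threshold proxy, m.
#' @param emg_rate raw-EMG sampling rate, Hz.
#' @param kin_rate kinematic sampling rate, Hz (upsampled to the model rate
#'   before execution).
#' @param jitter_deg amplitude bound of the seeded smooth kinematic jitter,
#'   degrees.
#' @return object of class `protocol_config`.
#' @export
protocol_config <- function(phase_s = 2.0, peak_deg = 75, lambda = 0.5,
                            box_masses = c(5, 15), reps = 10,
                            table_height = 0.465, emg_rate = 1000,
                            kin_rate = 40, jitter_deg = 2) {
  stopifnot(phase_s > 0, peak_deg > 0, lambda > 0, lambda <= 1,
            all(box_masses >= 0), reps >= 1)
  structure(list(phase_s = phase_s, peak_deg = peak_deg, lambda = lambda,
                 box_masses = box_masses, reps = reps,
                 table_height = table_height, emg_rate = emg_rate,
                 kin_rate = kin_rate, jitter_deg = jitter_deg,
                 cycle_s = 4 * phase_s),
            class = "protocol_config")
}

# deterministic sub-seed derivation, kept below 2^31
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 7919 + k) %% 2147483647)
}

min_jerk <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

#' Generate stoop-lift kinematics
#'
#' Minimum-jerk trunk-inclination segments between upright (0) and the peak
#' inclination for each 2 s phase, zero endpoint velocity at every phase
#' boundary, with a small seeded smooth jitter (bounded, zero at the cycle
#' endpoints and scaled down near upright so inclination stays
#' non-negative). The L5/S1 angle is the lumbar share `lambda` of trunk
#' inclination. The box-marker height rests below the contact threshold on
#' the table and follows the hands while carried (phases 2-3).
#'
#' @param protocol a [protocol_config()].
#' @param seed RNG seed for the jitter.
#' @param rate output sampling rate, Hz; kinematics are generated at the
#'   protocol's `kin_rate` and upsampled by cubic spline.
#' @return list with `time` (s), `theta_trunk` (rad), `theta_l5s1` (rad),
#'   `box_height` (m), `box_state` (logical), `dt`, `rate`.
#' @export
generate_kinematics <- function(protocol = protocol_config(), seed = 1,
                                rate = 1000) {
  Tc <- protocol$cycle_s
  peak <- protocol$peak_deg * pi / 180
  tk <- seq(0, Tc, by = 1 / protocol$kin_rate)
  phase <- pmin(floor(tk / protocol$phase_s), 3)
  tau <- tk / protocol$phase_s - phase
  s <- min_jerk(tau)
  theta <- ifelse(phase %% 2 == 0, peak * s, peak * (1 - s))
  theta[length(theta)] <- 0
  jit <- withr::with_seed(seed, {
    amp <- stats::runif(3, 0, protocol$jitter_deg / 3) * pi / 180
    ph <- stats::runif(3, 0, 2 * pi)
    fr <- stats::runif(3, 0.3, 1.2)
    rowSums(sapply(1:3, function(i) amp[i] * sin(2 * pi * fr[i] * tk + ph[i])))
  })
  # zero at the endpoints, vanishing near upright: preserves closure and
  # non-negative inclination
  theta <- theta + jit * sin(pi * tk / Tc)^2 * (theta / peak)
  theta <- pmax(theta, 0)
  # upsample to the model rate
  t <- seq(0, Tc, by = 1 / rate)
  th <- stats::spline(tk, theta, xout = t, method = "fmm")$y
  th <- pmax(th, 0)
  th[1] <- 0; th[length(th)] <- 0
  # box: on the table during phases 1 and 4, carried in between
  carried <- t > protocol$phase_s & t <= 3 * protocol$phase_s
  h_rest <- protocol$table_height - 0.015
  box_height <- ifelse(carried,
                       protocol$table_height + 0.015 +
                         0.45 * (1 - th / peak),
                       h_rest)
  box_state <- detect_box_contact(box_height, protocol$table_height)
  list(time = t, theta_trunk = th, theta_l5s1 = protocol$lambda * th,
       box_height = box_height, box_state = box_state,
       dt = 1 / rate, rate = rate)
}

#' A virtual lifting subject
#'
#' Bundles anthropometry, ground-truth MTU parameters, per-channel MVC
#' scales, a baseline antagonist co-activation, and a compliance factor `c`
#' in \[0, 1\] describing how completely the subject offloads onto the
#' exosuit (1 = full quasi-static offloading, 0 = ignores the assistance).
#'
#' @param id subject identifier.
#' @param anthro an [anthropometry()].
#' @param params named list of ground-truth [mtu_params()].
#' @param mvc named per-channel MVC values, volts.
#' @param co_activation antagonist baseline activation.
#' @param compliance offloading compliance in \[0, 1\].
#' @param truth_vector optional generating parameter vector (for recovery
#'   experiments).
#' @return object of class `virtual_subject`.
#' @export
virtual_subject <- function(id, anthro, params, mvc,
                            co_activation = 0.02, compliance = 1.0,
                            truth_vector = NULL) {
  stopifnot(compliance >= 0, compliance <= 1)
  structure(list(id = id, anthro = anthro, params = params, mvc = mvc,
                 co_activation = co_activation, compliance = compliance,
                 truth_vector = truth_vector),
            class = "virtual_subject")
}

#' @export
print.virtual_subject <- function(x, ...) {
  cat(sprintf("<virtual_subject> %s: %.1f kg, compliance %.2f\n",
              x$id, x$anthro$body_mass, x$compliance))
  invisible(x)
}

#' Sample a virtual cohort
#'
#' Anthropometry is sampled from the target cohort statistics (body mass
#' 67 +/- 9 kg, height 1.73 +/- 0.07 m), truncated at +/- 2 SD; segment
#' lengths scale linearly with height. Ground-truth parameter scales are
#' sampled uniformly over the central half of the calibration bounds,
#' keeping subjects physiologically plausible while exercising the
#' calibrated range.
#'
#' @param n number of subjects (>= 1).
#' @param protocol a [protocol_config()] (carried for channel naming).
#' @param seed cohort RNG seed.
#' @param base_params baseline MTU parameters to scale
#'   ([default_mtu_params()]).
#' @param cal_config bounds source ([calibration_config()]).
#' @return list of [virtual_subject()]s.
#' @export
generate_cohort <- function(n, protocol = protocol_config(), seed = 42,
                            base_params = default_mtu_params(),
                            cal_config = calibration_config()) {
  stopifnot(n >= 1)
  groups <- unique(mtu_group_of(names(base_params)))
  k <- length(groups)
  central_half <- function(b) c(b[1] + diff(b) / 4, b[2] - diff(b) / 4)
  fb <- central_half(cal_config$F_max_scale)
  tb <- central_half(cal_config$l_ts_scale)
  ob <- central_half(cal_config$l_opt_scale)
  ab <- central_half(cal_config$A_bounds)
  rtrunc <- function(mu, sd) {
    repeat {
      x <- stats::rnorm(1, mu, sd)
      if (abs(x - mu) <= 2 * sd) return(x)
    }
  }
  lapply(seq_len(n), function(i) {
    withr::with_seed(derive_seed(seed, i), {
      mass <- rtrunc(67, 9)
      height <- rtrunc(1.73, 0.07)
      hs <- height / 1.73
      anthro <- anthropometry(body_mass = mass, d_ub = 0.25 * hs,
                              L_t = 0.50 * hs, d_reach = 0.30 * hs)
      vec <- c(stats::runif(k, fb[1], fb[2]),
               stats::runif(1, tb[1], tb[2]),
               stats::runif(1, ob[1], ob[2]),
               stats::runif(k, ab[1], ab[2]))
      params <- apply_param_vector(base_params, vec, groups)
      mvc <- stats::setNames(
        stats::runif(length(default_channel_map()), 5e-4, 2e-3),
        unlist(lapply(default_channel_map(), function(w) names(w)[1])))
      virtual_subject(id = sprintf("s%02d", i), anthro = anthro,
                      params = params, mvc = mvc, truth_vector = vec)
    })
  })
}

#' Distribute a required moment over ground-truth activations
#'
#' Inverse of the EMG-driven moment summation, used to make the synthetic
#' world self-consistent: flexors are held at the antagonist co-activation
#' baseline; the active extensor moment that remains after subtracting the
#' passive and flexor contributions is shared among extensors in closed
#' form (minimum-norm):
#' \deqn{a_i = M_a w_i / \textstyle\sum_j w_j^2, \qquad
#'   w_i = r_i F_{max,i} f_{L,i} f_{V,i} \cos\phi_i,}
#' where the force-velocity factor is known from kinematics alone under the
#' stiff-tendon assumption. Activations are clipped to \[0, 1\]; samples
#' where the demand exceeds total extensor capacity are flagged saturated.
#'
#' @param M_required extension-positive moment series, N m.
#' @param surrogates,params model geometry and ground-truth parameters.
#' @param theta_l5s1 L5/S1 angle series, rad.
#' @param dt sample interval, s.
#' @param co_activation flexor baseline activation.
#' @return list with `activations` (samples x MTU matrix) and `saturated`
#'   (logical series).
#' @export
distribute_activations <- function(M_required, surrogates, params,
                                   theta_l5s1, dt, co_activation = 0.02) {
  geom <- precompute_geometry(surrogates, theta_l5s1)
  mtus <- colnames(geom$L)
  grp <- vapply(surrogates, `[[`, "", "group")
  ext <- mtus[grp == "extensor"]
  flex <- mtus[grp == "flexor"]
  n <- length(M_required)
  kin <- lapply(mtus, function(m) {
    p <- params[[m]]
    fk <- fiber_kinematics(geom$L[, m], p)
    v <- fiber_velocity(fk$l_norm, dt, p)
    fc <- force_curves(fk$l_norm, v, p$gamma, p$k_pe, p$eps0)
    list(fk = fk, v = v, fc = fc, cosphi = cos(fk$phi))
  })
  names(kin) <- mtus
  # passive (elastic + damper, floored) moment of every MTU
  M_pas <- rowSums(sapply(mtus, function(m) {
    p <- params[[m]]
    geom$r[, m] * pmax(p$F_max * (kin[[m]]$fc$f_P + p$beta * kin[[m]]$v) *
                         kin[[m]]$cosphi, 0)
  }))
  # flexor active moment at the co-activation baseline
  M_flex <- if (length(flex)) {
    rowSums(sapply(flex, function(m) {
      p <- params[[m]]
      geom$r[, m] * p$F_max * co_activation * kin[[m]]$fc$f_L *
        kin[[m]]$fc$f_V * kin[[m]]$cosphi
    }))
  } else 0
  M_a <- M_required - M_pas - M_flex
  w <- sapply(ext, function(m) {
    p <- params[[m]]
    geom$r[, m] * p$F_max * kin[[m]]$fc$f_L * kin[[m]]$fc$f_V *
      kin[[m]]$cosphi
  })
  wsq <- rowSums(w^2)
  capacity <- rowSums(w)
  a_ext <- w * (pmax(M_a, 0) / pmax(wsq, .Machine$double.eps))
  saturated <- apply(a_ext, 1, max) > 1 | M_a > capacity
  a_ext <- pmin(pmax(a_ext, 0), 1)
  act <- matrix(co_activation, n, length(mtus),
                dimnames = list(NULL, mtus))
  act[, ext] <- a_ext
  list(activations = act, saturated = saturated)
}

#' Synthesize raw surface EMG from target activations
#'
#' The target envelope for each channel is the excitation obtained by
#' inverting the activation shaping. The raw signal is a seeded, band-limited
#' (in-band 100-200 Hz) zero-mean random-FM carrier — constant instantaneous
#' amplitude with a smoothly wandering frequency, normalized so its
#' rectified mean is one — amplitude-modulated by the excitation and scaled
#' by the channel MVC, plus an additive carrier at the noise floor (default
#' 2% MVC). The constant-amplitude carrier keeps the stochastic ripple of
#' the 3 Hz envelope negligible, so the construction round-trips through
#' the envelope pipeline to within the causal filter lag.
#'
#' @param activations (samples x MTU) target activation matrix at the EMG
#'   rate.
#' @param subject a [virtual_subject()] (MVC scales and shape factors).
#' @param seed RNG seed.
#' @param rate EMG sampling rate, Hz (> 600).
#' @param mapping channel map ([default_channel_map()]).
#' @param noise_floor additive noise level, fraction of MVC.
#' @return a [raw_emg()] object.
#' @export
synthesize_raw_emg <- function(activations, subject, seed = 1, rate = 1000,
                               mapping = default_channel_map(),
                               noise_floor = 0.02) {
  n <- nrow(activations)
  chans <- vapply(mapping, function(w) names(w)[1], "")
  raw <- matrix(0, n, length(chans),
                dimnames = list(NULL, unname(chans)))
  for (j in seq_along(mapping)) {
    m <- names(mapping)[j]
    A <- subject$params[[m]]$A
    u <- activation_to_excitation(activations[, m], A)
    mvc <- subject$mvc[[chans[j]]]
    make_carrier <- function(sub, centre, halfwidth) {
      withr::with_seed(sub, {
        # instantaneous frequency: smooth random walk inside the flat part
        # of the 30-300 Hz passband, so the rectified mean of the
        # band-passed carrier does not depend on the wander
        drift <- butter_causal(stats::runif(n, -1, 1), 2, 2, rate, "low")
        drift <- drift / max(abs(drift), .Machine$double.eps)
        freq <- centre + halfwidth * drift
        phase <- 2 * pi * cumsum(freq) / rate + stats::runif(1, 0, 2 * pi)
        c0 <- sin(phase)
        bp <- butter_causal(c0, 2, c(30, 300), rate, "pass")
        c0 / mean(abs(bp[-seq_len(min(n, rate))]))
      })
    }
    # the floor carrier lives in a disjoint frequency band: its beat with
    # the signal carrier then stays far above the 3 Hz envelope cutoff
    raw[, chans[j]] <- u * mvc * make_carrier(derive_seed(seed, j), 140, 35) +
      noise_floor * mvc * make_carrier(derive_seed(seed, 1000 + j), 245, 25)
  }
  raw_emg(raw, sample_rate = rate)
}

#' Generate one synthetic lifting trial
#'
#' Produces a complete, self-consistent trial for one condition. For NOEXO,
#' ground-truth activations satisfy the quasi-static inverse-dynamics
#' moment. For assisted conditions (NMBC, TIBC) the trial is the fixed
#' point of a whole-trial iteration: the controller's measured cable force
#' produces an exosuit moment `M_exo = F d_cable`; the human target becomes
#' `M_required - compliance * M_exo`; activations (and EMG) are regenerated
#' and the model re-executed until the exosuit moment changes by at most
#' 0.5 N m anywhere (at most 10 iterations).
#'
#' The model is executed the way the real-time pipeline would run it: at
#' rates above 700 Hz raw EMG is synthesized and passed through the full
#' envelope/normalization chain; at lower (CI) rates the model consumes the
#' true excitations directly.
#'
#' @param subject a [virtual_subject()].
#' @param condition `"NOEXO"`, `"NMBC"` or `"TIBC"`.
#' @param box_mass box mass, kg.
#' @param protocol a [protocol_config()].
#' @param surrogates geometry surrogates ([fit_all_surrogates()]).
#' @param seed trial seed.
#' @param rate model execution rate, Hz.
#' @param nmbc an [nmbc_config()].
#' @param tibc a tuned [tibc_config()] (required for TIBC; tuned
#'   automatically from the subject anthropometry when `NA`).
#' @param exec_params parameters used for *model execution* (e.g. a
#'   calibrated set); defaults to the subject's ground truth.
#' @param actuator_lag_s,actuator_noise_sd tracking-plant settings.
#' @param max_iter,tol_Nm fixed-point iteration controls.
#' @return object of class `lifting_trial`; see Details in the vignette.
#' @export
generate_trial <- function(subject, condition = c("NOEXO", "NMBC", "TIBC"),
                           box_mass, protocol = protocol_config(),
                           surrogates, seed = 1, rate = 1000,
                           nmbc = nmbc_config(), tibc = tibc_config(),
                           exec_params = NULL,
                           actuator_lag_s = 0.02, actuator_noise_sd = 0,
                           max_iter = 10, tol_Nm = 0.5) {
  condition <- match.arg(condition)
  if (is.null(exec_params)) exec_params <- subject$params
  kin <- generate_kinematics(protocol, seed = seed, rate = rate)
  dt <- kin$dt
  anthro <- subject$anthro
  M_req <- top_down_id(kin$theta_trunk, anthro, box_mass, kin$box_state)
  use_raw_emg <- rate > 700
  if (condition == "TIBC" && is.na(tibc$k)) {
    tibc <- tibc_tune(anthro, tibc, nmbc)
  }
  A_exec <- vapply(names(surrogates), function(m) exec_params[[m]]$A, 0)

  run_model <- function(M_target, iter) {
    dist <- distribute_activations(M_target, surrogates, subject$params,
                                   kin$theta_l5s1, dt,
                                   subject$co_activation)
    u_true <- activation_to_excitation(
      dist$activations,
      vapply(colnames(dist$activations),
             function(m) subject$params[[m]]$A, 0))
    if (use_raw_emg) {
      # carrier realization is frozen across fixed-point iterations so the
      # assisted iteration is a deterministic contraction
      raw <- synthesize_raw_emg(dist$activations, subject,
                                seed = derive_seed(seed, 100),
                                rate = rate)
      env <- normalize_mvc(envelope(raw), subject$mvc, rate)
      u_model <- map_channels(env)
    } else {
      raw <- NULL
      u_model <- u_true
    }
    a_model <- excitation_to_activation(
      u_model[, names(surrogates), drop = FALSE], as.numeric(A_exec))
    loads <- emg_driven_moments(a_model, surrogates, exec_params,
                                kin$theta_l5s1, dt)
    list(dist = dist, u_true = u_true, u_model = u_model, raw = raw,
         loads = loads)
  }

  if (condition == "NOEXO") {
    st <- run_model(M_req, 0)
    M_exo <- numeric(length(M_req))
    F_des <- F_meas <- numeric(length(M_req))
    iterations <- 1L
    residual <- 0
    residual_history <- numeric(0)
  } else {
    M_exo <- numeric(length(M_req))
    iterations <- 0L
    residual <- Inf
    residual_history <- numeric(0)
    repeat {
      iterations <- iterations + 1L
      st <- run_model(M_req - subject$compliance * M_exo, iterations)
      F_des <- if (condition == "NMBC") {
        nmbc_desired_force(st$loads$moments$M_active_Nm, nmbc, rate)
      } else {
        tibc_desired_force(kin$theta_trunk, tibc)
      }
      F_meas <- actuator_track(F_des, dt, actuator_lag_s,
                               actuator_noise_sd,
                               seed = derive_seed(seed, 500))
      M_exo_new <- F_meas * nmbc$d_cable
      residual <- max(abs(M_exo_new - M_exo))
      residual_history <- c(residual_history, residual)
      M_exo <- M_exo_new
      if (residual <= tol_Nm) break
      if (iterations >= max_iter) {
        stop(sprintf(
          "generate_trial: assisted fixed point did not converge in %d iterations (residual %.2f N m)",
          max_iter, residual))
      }
    }
  }
  comp <- compression_force(st$loads, kin$theta_trunk, anthro, box_mass,
                            kin$box_state)
  structure(
    list(subject_id = subject$id, condition = condition,
         box_mass = box_mass, seed = seed, rate = rate, dt = dt,
         time = kin$time, theta_trunk = kin$theta_trunk,
         theta_l5s1 = kin$theta_l5s1, box_height = kin$box_height,
         box_state = kin$box_state,
         M_id = M_req, u = st$u_model, u_true = st$u_true,
         activations = st$dist$activations, saturated = st$dist$saturated,
         raw_emg = st$raw, loads = st$loads, compression = comp,
         cable = cable_command(kin$time, F_des, F_meas),
         M_exo = M_exo, iterations = iterations, residual = residual,
         residual_history = residual_history,
         settle_s = 0.5,
         anthro = anthro),
    class = "lifting_trial")
}

#' @export
print.lifting_trial <- function(x, ...) {
  cat(sprintf(
    "<lifting_trial> %s %s %g kg, %.1f s at %g Hz (%d fixed-point iteration%s)\n",
    x$subject_id, x$condition, x$box_mass,
    max(x$time), x$rate, x$iterations, if (x$iterations == 1) "" else "s"))
  invisible(x)
}

#' Persist a trial as a CSV bundle with a JSON sidecar
#'
#' @param trial a `lifting_trial`.
#' @param dir output directory.
#' @return the sidecar path, invisibly.
#' @export
write_trial <- function(trial, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%s_%gkg_seed%d", trial$subject_id, trial$condition,
                  trial$box_mass, trial$seed)
  df <- data.frame(time_s = trial$time,
                   theta_trunk_rad = trial$theta_trunk,
                   theta_l5s1_rad = trial$theta_l5s1,
                   box_state = trial$box_state,
                   M_id_Nm = trial$M_id,
                   M_total_Nm = trial$loads$moments$M_total_Nm,
                   M_active_Nm = trial$loads$moments$M_active_Nm,
                   M_passive_Nm = trial$loads$moments$M_passive_Nm,
                   Fcomp_N = trial$compression$Fcomp_N,
                   Fcomp_BW = trial$compression$Fcomp_BW,
                   F_desired_N = trial$cable$F_desired_N,
                   F_measured_N = trial$cable$F_measured_N)
  utils::write.csv(df, file.path(dir, paste0(stem, ".csv")),
                   row.names = FALSE)
  sidecar <- file.path(dir, paste0(stem, ".json"))
  jsonlite::write_json(
    list(subject = trial$subject_id, condition = trial$condition,
         box_mass = trial$box_mass, seed = trial$seed, rate = trial$rate,
         iterations = trial$iterations, residual = trial$residual),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}
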