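#' Subject anthropometry for the trunk segment model
#'
#' Lumped-segment constants used by the top-down inverse-dynamics model and
#' the compression estimate: the superincumbent (upper-body) mass acts at a
#' distance `d_ub` from L5/S1 along the trunk, the hands carry the box at
#' the end of a trunk of length `L_t` plus a forward reach offset `d_reach`.
#'
#' @param body_mass total body mass, kg.
#' @param upper_body_mass_fraction fraction of body mass above L5/S1.
#' @param d_ub trunk centre-of-mass distance from L5/S1, m.
#' @param L_t trunk length, m.
#' @param d_reach forward hand-reach offset, m.
#' @param g gravitational acceleration, m/s^2.
#' @return object of class `anthropometry`.
#' @export
anthropometry <- function(body_mass = 67, upper_body_mass_fraction = 0.60,
                          d_ub = 0.25, L_t = 0.50, d_reach = 0.30,
                          g = 9.81) {
  stopifnot(body_mass > 0, upper_body_mass_fraction > 0,
            upper_body_mass_fraction < 1, d_ub > 0, L_t > 0, d_reach > 0,
            g > 0)
  structure(list(body_mass = body_mass,
                 upper_body_mass_fraction = upper_body_mass_fraction,
                 d_ub = d_ub, L_t = L_t, d_reach = d_reach, g = g,
                 m_ub = body_mass * upper_body_mass_fraction),
            class = "anthropometry")
}

#' @export
print.anthropometry <- function(x, ...) {
  cat(sprintf("<anthropometry> %.1f kg (upper body %.1f kg), trunk %.2f m\n",
              x$body_mass, x$m_ub, x$L_t))
  invisible(x)
}

# Evaluate all surrogates on an angle series: lengths, moment arms and axial
# projection coefficients as (samples x MTU) matrices. This is the part of
# the model that depends on kinematics only, so calibration precomputes it.
precompute_geometry <- function(surrogates, theta) {
  M <- length(surrogates)
  L <- r <- matrix(0, length(theta), M,
                   dimnames = list(NULL, names(surrogates)))
  for (m in names(surrogates)) {
    ev <- evaluate_surrogate(surrogates[[m]], theta)
    L[, m] <- ev$length
    r[, m] <- ev$moment_arm
  }
  cproj <- vapply(surrogates, `[[`, 0, "c")
  list(L = L, r = r, c = cproj)
}

# Core EMG-driven force/moment computation on precomputed geometry.
# activations: (samples x MTU) matrix; params: named list of mtu_params.
# Fully vectorized across samples and MTUs (the calibration objective runs
# through here tens of thousands of times); equivalence with the per-MTU
# public functions is pinned by a brute-force oracle test.
moments_core <- function(activations, geom, params, dt) {
  mtus <- colnames(geom$L)
  if (any(vapply(params[mtus], is.null, TRUE))) {
    stop("emg_driven_moments: no parameters for MTU '",
         mtus[vapply(params[mtus], is.null, TRUE)][1], "'")
  }
  n <- nrow(geom$L)
  pv <- function(field) vapply(params[mtus], `[[`, 0, field)
  l_opt <- pv("l_opt"); l_ts <- pv("l_ts"); F_max <- pv("F_max")
  h <- l_opt * sin(pv("phi_opt"))
  proj <- sweep(geom$L, 2, l_ts)
  if (any(proj <= 0)) {
    bad <- which(colSums(proj <= 0) > 0)[1]
    stop(sprintf(
      "degenerate-geometry error for '%s': MTU length %.4f m <= tendon slack length %.4f m",
      mtus[bad], min(geom$L[, bad]), l_ts[bad]))
  }
  l_fiber <- sqrt(proj^2 + matrix(h^2, n, length(mtus), byrow = TRUE))
  l_norm <- sweep(l_fiber, 2, l_opt, "/")
  cosphi <- proj / l_fiber
  # normalized fibre velocity: central differences + causal 6 Hz smoothing
  v <- rbind(l_fiber[2, ] - l_fiber[1, ],
             (l_fiber[3:n, , drop = FALSE] -
                l_fiber[1:(n - 2), , drop = FALSE]) / 2,
             l_fiber[n, ] - l_fiber[n - 1, ]) / dt
  v <- sweep(v, 2, pv("v_max") * l_opt, "/")
  fs <- 1 / dt
  if (6 < fs / 2) v <- butter_causal(v, 2, 6, fs, "low")
  # Hill curves, vectorized (constants shared per MTU column)
  gamma <- matrix(pv("gamma"), n, length(mtus), byrow = TRUE)
  k_pe <- matrix(pv("k_pe"), n, length(mtus), byrow = TRUE)
  eps0 <- matrix(pv("eps0"), n, length(mtus), byrow = TRUE)
  f_L <- exp(-(l_norm - 1)^2 / gamma)
  f_P <- (exp(k_pe * pmax(l_norm - 1, 0) / eps0) - 1) / (exp(k_pe) - 1)
  a_f <- 0.25; k_e <- 0.4 / (1 + 1 / a_f)
  f_V <- 1 + 0.4 * v / (v + k_e)            # eccentric branch
  neg <- v <= 0
  vn <- v[neg]
  f_V[neg] <- pmax(1 + vn, 0) / (1 - vn / a_f)
  Fm <- matrix(F_max, n, length(mtus), byrow = TRUE)
  beta <- matrix(pv("beta"), n, length(mtus), byrow = TRUE)
  F_act <- Fm * activations * f_L * f_V * cosphi
  F_pas <- pmax(Fm * (f_P + beta * v) * cosphi, 0)
  F_tot <- F_act + F_pas
  dimnames(F_tot) <- dimnames(F_act) <- dimnames(F_pas) <-
    list(NULL, mtus)
  list(F_total = F_tot, F_active = F_act, F_passive = F_pas,
       M_total = rowSums(geom$r * F_tot),
       M_active = rowSums(geom$r * F_act),
       M_passive = rowSums(geom$r * F_pas))
}

#' EMG-driven L5/S1 moments
#'
#' Projects stiff-tendon Hill-type MTU forces onto the lumbosacral joint
#' through the spline-surrogate moment arms:
#' \eqn{M_x(t) = \sum_i r_i(\theta(t)) F_{x,i}(t)} for each component
#' \eqn{x \in \{total, active, passive\}}. Flexor MTUs contribute through
#' negative moment arms. Extension-positive convention.
#'
#' @param activations (samples x MTU) matrix in \[0, 1\], columns named by
#'   MTU.
#' @param surrogates named list of geometry surrogates
#'   ([fit_all_surrogates()]).
#' @param params named list of [mtu_params()].
#' @param theta L5/S1 flexion angle series, rad, same length as the
#'   activation rows.
#' @param dt sample interval, s.
#' @return object of class `load_estimates`: data frame `moments`
#'   (`time_s`, `M_total_Nm`, `M_active_Nm`, `M_passive_Nm`) plus per-MTU
#'   force matrices `F_total`, `F_active`, `F_passive` (N).
#' @export
emg_driven_moments <- function(activations, surrogates, params, theta, dt) {
  activations <- as.matrix(activations)
  if (nrow(activations) != length(theta)) {
    stop("emg_driven_moments: timebase mismatch (", nrow(activations),
         " activation samples vs ", length(theta), " angle samples)")
  }
  miss <- setdiff(names(surrogates), colnames(activations))
  if (length(miss)) {
    stop("emg_driven_moments: no activation column for MTU(s) ",
         paste(miss, collapse = ", "))
  }
  geom <- precompute_geometry(surrogates, theta)
  core <- moments_core(activations[, colnames(geom$L), drop = FALSE],
                       geom, params, dt)
  structure(
    c(list(moments = data.frame(
        time_s = (seq_along(theta) - 1) * dt,
        M_total_Nm = core$M_total,
        M_active_Nm = core$M_active,
        M_passive_Nm = core$M_passive)),
      core[c("F_total", "F_active", "F_passive")],
      list(c = geom$c, dt = dt)),
    class = "load_estimates")
}

#' @export
print.load_estimates <- function(x, ...) {
  cat(sprintf("<load_estimates> %d samples, %d MTUs; peak M_total = %.1f N m\n",
              nrow(x$moments), ncol(x$F_total), max(x$moments$M_total_Nm)))
  invisible(x)
}

#' L5/S1 compression force
#'
#' Transparent axial-load surrogate: each MTU contributes a fixed fraction
#' `c_i` of its force to joint compression, and the superincumbent weight
#' (upper body plus the box while held) adds its trunk-axial gravity
#' component:
#' \deqn{F_{comp}(t) = \sum_i c_i F_{tot,i}(t) +
#'   (m_{ub} + s_{box}(t) m_{box})\, g \cos\theta(t),}
#' floored at zero. Also returned in body-weight (BW) multiples,
#' \eqn{BW = m_{body} g}.
#'
#' @param loads a `load_estimates` from [emg_driven_moments()] (or any list
#'   with `F_total` and `c`).
#' @param theta_trunk trunk inclination series, rad from vertical.
#' @param anthro an [anthropometry()].
#' @param box_mass box mass, kg (>= 0).
#' @param box_state logical series: box held in the hands.
#' @return data frame with `Fcomp_N` and `Fcomp_BW`.
#' @export
compression_force <- function(loads, theta_trunk, anthro, box_mass = 0,
                              box_state = FALSE) {
  if (box_mass < 0) stop("compression_force: box_mass must be >= 0")
  muscle <- as.numeric(loads$F_total %*% loads$c)
  m_held <- anthro$m_ub + as.numeric(box_state) * box_mass
  Fc <- pmax(muscle + m_held * anthro$g * cos(theta_trunk), 0)
  data.frame(Fcomp_N = Fc, Fcomp_BW = Fc / (anthro$body_mass * anthro$g))
}

#' Top-down quasi-static inverse-dynamics moment
#'
#' Gravity-only sagittal moment of the superincumbent mass and the box about
#' L5/S1:
#' \deqn{M_{ID}(t) = m_{ub} g\, d_{ub} \sin\theta(t) +
#'   s_{box}(t)\, m_{box} g\, (L_t \sin\theta(t) + d_{reach}).}
#' Box inertia is neglected and the load is lumped in the sagittal plane
#' (equal hands). An optional angular-acceleration term
#' \eqn{m_{ub} d_{ub}^2 \ddot\theta} can be enabled for non-metronome-paced
#' movements.
#'
#' @param theta trunk inclination series, rad.
#' @param anthro an [anthropometry()].
#' @param box_mass box mass, kg.
#' @param box_state logical series: box held.
#' @param theta_ddot optional angular acceleration, rad/s^2 (default off).
#' @return reference moment series, N m (extension-positive).
#' @export
top_down_id <- function(theta, anthro, box_mass = 0, box_state = FALSE,
                        theta_ddot = NULL) {
  M <- anthro$m_ub * anthro$g * anthro$d_ub * sin(theta) +
    as.numeric(box_state) * box_mass * anthro$g *
      (anthro$L_t * sin(theta) + anthro$d_reach)
  if (!is.null(theta_ddot)) {
    M <- M + anthro$m_ub * anthro$d_ub^2 * theta_ddot
  }
  M
}

#' Box contact detection with hysteresis
#'
#' The box is in the hands while its marker height exceeds the threshold;
#' a hysteresis band (default 1 cm) prevents chatter on noisy crossings:
#' contact turns on above `threshold + band/2` and off below
#' `threshold - band/2`.
#'
#' @param height box-marker height series, m.
#' @param threshold contact threshold, m (default: 46.5 cm table height).
#' @param band hysteresis band width, m.
#' @return logical contact series.
#' @export
detect_box_contact <- function(height, threshold = 0.465, band = 0.01) {
  hi <- threshold + band / 2
  lo <- threshold - band / 2
  state <- logical(length(height))
  cur <- height[1] > hi
  for (i in seq_along(height)) {
    if (!cur && height[i] > hi) cur <- TRUE
    else if (cur && height[i] < lo) cur <- FALSE
    state[i] <- cur
  }
  state
}

#' Export load estimates as CSV
#'
#' @param loads a `load_estimates`.
#' @param compression optional data frame from [compression_force()].
#' @param box_state optional logical series.
#' @param path output CSV path.
#' @export
write_load_estimates <- function(loads, path, compression = NULL,
                                 box_state = NULL) {
  df <- loads$moments
  if (!is.null(compression)) df <- cbind(df, compression)
  if (!is.null(box_state)) df$box_state <- box_state
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
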