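#' Hill-type MTU parameters
#'
#' Parameters of the stiff-tendon Hill-type musculo-tendon model: an active
#' contractile element in parallel with a passive elastic element and a
#' linear damper, behind a rigid tendon of slack length `l_ts`. The tendon
#' being stiff, all MTU length change is taken up by the fibre, whose
#' pennation follows the constant-thickness rule
#' \eqn{l_f \sin\phi = l_{opt}\sin\phi_{opt}}.
#'
#' @param name MTU name.
#' @param F_max maximum isometric force, N (> 0).
#' @param l_opt optimal fibre length, m (> 0).
#' @param l_ts tendon slack length, m (> 0).
#' @param phi_opt pennation angle at optimal fibre length, rad in \[0, pi/2).
#' @param beta linear damping coefficient, dimensionless (>= 0); the damper
#'   sits in parallel with the passive element, so its force is counted in
#'   the passive component.
#' @param v_max maximum contraction velocity, optimal fibre lengths per
#'   second.
#' @param gamma active force-length Gaussian width.
#' @param k_pe passive force-length exponential shape.
#' @param eps0 passive fibre strain at which passive force reaches `F_max`.
#' @param A activation shape factor for this MTU, in (-3, 0\].
#' @return object of class `mtu_params`.
#' @export
mtu_params <- function(name, F_max, l_opt, l_ts, phi_opt = 0,
                       beta = 0.1, v_max = 10,
                       gamma = 0.45, k_pe = 4.0, eps0 = 0.6, A = -1.5) {
  if (F_max <= 0 || l_opt <= 0 || l_ts <= 0) {
    stop("mtu_params: F_max, l_opt, l_ts must be positive for '", name, "'")
  }
  if (phi_opt < 0 || phi_opt >= pi / 2) {
    stop("mtu_params: phi_opt must lie in [0, pi/2) for '", name, "'")
  }
  if (beta < 0) stop("mtu_params: beta must be >= 0")
  structure(list(name = name, F_max = F_max, l_opt = l_opt, l_ts = l_ts,
                 phi_opt = phi_opt, beta = beta, v_max = v_max,
                 gamma = gamma, k_pe = k_pe, eps0 = eps0, A = A),
            class = "mtu_params")
}

#' Default MTU parameter set
#'
#' Reads the packaged Hill-type parameters for the 8-MTU reduced trunk
#' model. Tendon slack lengths are chosen so normalized fibre length is 1 at
#' the neutral L5/S1 angle.
#'
#' @param path optional alternative JSON parameter file (array of MTU
#'   entries plus shared defaults).
#' @return named list of [mtu_params()] objects.
#' @export
default_mtu_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_mtu_params.json",
                        package = "exolift")
  }
  cfg <- read_config(path)
  d <- cfg$defaults
  out <- lapply(cfg$mtus, function(m) {
    mtu_params(name = m$name, F_max = m$F_max, l_opt = m$l_opt,
               l_ts = m$l_ts, phi_opt = m$phi_opt,
               beta = if (is.null(m$beta)) d$beta else m$beta,
               v_max = if (is.null(m$v_max)) d$v_max else m$v_max,
               gamma = if (is.null(m$gamma)) d$gamma else m$gamma,
               k_pe = if (is.null(m$k_pe)) d$k_pe else m$k_pe,
               eps0 = if (is.null(m$eps0)) d$eps0 else m$eps0,
               A = if (is.null(m$A)) d$A else m$A)
  })
  names(out) <- vapply(cfg$mtus, `[[`, "", "name")
  out
}

#' Stiff-tendon fibre kinematics
#'
#' With a rigid tendon, the along-tendon fibre projection is
#' \eqn{L_{mtu} - l_{ts}} and the constant-thickness pennation rule gives
#' the closed form
#' \deqn{l_f = \sqrt{(L_{mtu} - l_{ts})^2 + (l_{opt}\sin\phi_{opt})^2}.}
#'
#' @param L_mtu MTU length(s), m; must exceed the tendon slack length.
#' @param params an [mtu_params()].
#' @return list with `l_norm` (fibre length / `l_opt`), `phi` (pennation,
#'   rad) and `l_fiber` (m).
#' @export
fiber_kinematics <- function(L_mtu, params) {
  if (any(L_mtu <= params$l_ts)) {
    stop(sprintf(
      "degenerate-geometry error for '%s': MTU length %.4f m <= tendon slack length %.4f m",
      params$name, min(L_mtu), params$l_ts))
  }
  h <- params$l_opt * sin(params$phi_opt)   # constant muscle thickness
  proj <- L_mtu - params$l_ts
  l_fiber <- sqrt(proj^2 + h^2)
  list(l_norm = l_fiber / params$l_opt,
       phi = atan2(h, proj),
       l_fiber = l_fiber)
}

#' Hill-type force curves
#'
#' Active force-length: Gaussian \eqn{f_L = \exp(-(\tilde l - 1)^2/\gamma)}.
#' Passive force-length: \eqn{f_P = (e^{k_{pe}(\tilde l - 1)/\epsilon_0} -
#' 1)/(e^{k_{pe}} - 1)} for \eqn{\tilde l > 1}, else 0 (so \eqn{f_P = 1} at
#' strain \eqn{\epsilon_0}). Force-velocity: classic Hill hyperbola on the
#' concentric side (\eqn{f_V(0) = 1}, \eqn{f_V(-1) = 0}, curvature constant
#' 0.25) and a saturating eccentric branch with plateau 1.4, with matched
#' slope at zero velocity (C1-continuous).
#'
#' @param l_norm normalized fibre length(s) (> 0).
#' @param v_norm normalized fibre velocity(ies), units of `v_max`
#'   (shortening negative).
#' @param gamma,k_pe,eps0 curve constants (see [mtu_params()]).
#' @return list with `f_L`, `f_P`, `f_V` (dimensionless).
#' @export
force_curves <- function(l_norm, v_norm = 0, gamma = 0.45, k_pe = 4.0,
                         eps0 = 0.6) {
  if (any(l_norm <= 0)) stop("force_curves: normalized fibre length must be > 0")
  f_L <- exp(-(l_norm - 1)^2 / gamma)
  f_P <- ifelse(l_norm > 1,
                (exp(k_pe * (l_norm - 1) / eps0) - 1) / (exp(k_pe) - 1),
                0)
  a_f <- 0.25                       # Hill curvature (a/F0)
  k_e <- 0.4 / (1 + 1 / a_f)        # eccentric scale: slope match at v = 0
  v <- v_norm
  f_V <- ifelse(v <= 0,
                pmax(1 + v, 0) / (1 - pmin(v, 0) / a_f),
                1 + 0.4 * v / (v + k_e))
  list(f_L = f_L, f_P = f_P, f_V = f_V)
}

#' MTU force with active/passive decomposition
#'
#' \deqn{F_{active} = F_{max}\, a\, f_L(\tilde l)\, f_V(\tilde v)\cos\phi}
#' \deqn{F_{passive} = \max(F_{max}(f_P(\tilde l) + \beta \tilde v)\cos\phi,\; 0)}
#' Total force is their sum; muscles (and cables) cannot push, so each
#' component is floored at zero.
#'
#' @param a activation(s) in \[0, 1\].
#' @param l_norm,v_norm,phi fibre state (see [fiber_kinematics()]).
#' @param params an [mtu_params()].
#' @return list with numeric `total`, `active`, `passive` (N).
#' @export
mtu_force <- function(a, l_norm, v_norm, phi, params) {
  if (any(a < -1e-12 | a > 1 + 1e-12)) {
    stop("mtu_force: activation must lie in [0, 1]")
  }
  a <- pmin(pmax(a, 0), 1)
  fc <- force_curves(l_norm, v_norm, params$gamma, params$k_pe, params$eps0)
  cosphi <- cos(phi)
  active <- params$F_max * a * fc$f_L * fc$f_V * cosphi
  passive <- pmax(params$F_max * (fc$f_P + params$beta * v_norm) * cosphi, 0)
  list(total = active + passive, active = active, passive = passive)
}

#' Normalized fibre velocity from a fibre-length series
#'
#' Central finite difference of fibre length, normalized by
#' `v_max * l_opt`, then causally low-pass filtered at 6 Hz (second-order
#' Butterworth) to suppress differentiation noise. Endpoint samples use
#' one-sided differences.
#'
#' @param l_norm normalized fibre-length series (uniformly sampled).
#' @param dt sample interval, s.
#' @param params an [mtu_params()].
#' @param lp_cutoff smoothing cutoff, Hz; `NA` disables smoothing.
#' @return normalized velocity series (units of `v_max`).
#' @export
fiber_velocity <- function(l_norm, dt, params, lp_cutoff = 6) {
  n <- length(l_norm)
  if (n < 3L) stop("fiber_velocity: need at least 3 samples")
  l_fiber <- l_norm * params$l_opt
  v <- numeric(n)
  v[2:(n - 1)] <- (l_fiber[3:n] - l_fiber[1:(n - 2)]) / (2 * dt)
  v[1] <- (l_fiber[2] - l_fiber[1]) / dt
  v[n] <- (l_fiber[n] - l_fiber[n - 1]) / dt
  v <- v / (params$v_max * params$l_opt)
  if (!is.na(lp_cutoff)) {
    fs <- 1 / dt
    if (lp_cutoff < fs / 2) v <- butter_causal(v, 2, lp_cutoff, fs, "low")
  }
  v
}
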