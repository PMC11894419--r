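#' Parametric trunk musculoskeletal geometry
#'
#' The reduced trunk model represents each musculo-tendon unit (MTU) crossing
#' the lumbosacral (L5/S1) joint by an analytic length law
#' \deqn{L(\theta) = L_0 - r_0\theta - r_1\theta^2/2}
#' with a moment arm linear in the flexion angle, \eqn{r(\theta) = r_0 +
#' r_1\theta}, so that the tendon-excursion identity \eqn{r(\theta) =
#' -dL/d\theta} holds exactly. Angles are L5/S1 flexion angles in radians
#' (flexion positive); moment arms are extension-positive, so back extensors
#' have \eqn{r_0 > 0} and abdominal flexors \eqn{r_0 < 0}.
#'
#' Each spec also carries an axial projection coefficient `c` in \[0, 1\]:
#' the fraction of MTU force that contributes to L5/S1 axial compression.
#'
#' @param name MTU name (suffix `_l`/`_r` conventionally marks the side).
#' @param group `"extensor"` or `"flexor"`.
#' @param side `"left"` or `"right"`.
#' @param L0 reference MTU length at the neutral angle, metres (> 0).
#' @param r0 moment arm at the neutral angle, metres; > 0 for extensors,
#'   < 0 for flexors.
#' @param r1 moment-arm slope, metres/radian.
#' @param c axial projection coefficient, dimensionless in \[0, 1\].
#' @param domain working angle range, radians, used to check positivity.
#' @return An object of class `mtu_geometry_spec`.
#' @seealso [build_reference_geometry()], [fit_surrogate()]
#' @export
mtu_geometry_spec <- function(name, group = c("extensor", "flexor"),
                              side = c("left", "right"),
                              L0, r0, r1 = 0, c = 0.95,
                              domain = c(-0.2, 1.3)) {
  group <- match.arg(group)
  side <- match.arg(side)
  if (!is.numeric(L0) || length(L0) != 1L || L0 <= 0) {
    stop("geometry configuration error: L0 must be a positive length (got ",
         format(L0), ") for MTU '", name, "'")
  }
  if (group == "extensor" && r0 <= 0) {
    stop("geometry configuration error: extensor '", name,
         "' requires r0 > 0 (extension-positive convention)")
  }
  if (group == "flexor" && r0 >= 0) {
    stop("geometry configuration error: flexor '", name, "' requires r0 < 0")
  }
  if (c < 0 || c > 1) {
    stop("geometry configuration error: axial projection c must lie in [0, 1]")
  }
  spec <- structure(
    list(name = name, group = group, side = side,
         L0 = L0, r0 = r0, r1 = r1, c = c, domain = as.numeric(domain)),
    class = "mtu_geometry_spec")
  lmin <- min(mtu_length(spec, seq(domain[1], domain[2], length.out = 101)))
  if (lmin <= 0) {
    stop("geometry configuration error: MTU '", name,
         "' has non-positive length within the working domain")
  }
  spec
}

#' @export
print.mtu_geometry_spec <- function(x, ...) {
  cat(sprintf("<mtu_geometry_spec> %s (%s, %s)\n", x$name, x$group, x$side))
  cat(sprintf("  L0 = %.4f m, r(theta) = %.4f %+.4f*theta m, c = %.2f\n",
              x$L0, x$r0, x$r1, x$c))
  invisible(x)
}

#' Analytic MTU length and moment arm
#'
#' Closed-form evaluation of the reference geometry; the spline surrogates in
#' [fit_surrogate()] are checked against these laws.
#'
#' @param spec an [mtu_geometry_spec()].
#' @param theta L5/S1 flexion angle(s), radians.
#' @return numeric vector of lengths (m) or moment arms (m).
#' @export
mtu_length <- function(spec, theta) {
  spec$L0 - spec$r0 * theta - spec$r1 * theta^2 / 2
}

#' @rdname mtu_length
#' @export
mtu_moment_arm <- function(spec, theta) {
  spec$r0 + spec$r1 * theta
}

#' Build the reference trunk geometry
#'
#' Constructs the default bilateral 8-MTU geometry (iliocostalis, longissimus
#' lumbar part, longissimus thoracic part, rectus abdominis, left and right)
#' or a geometry from a user configuration. The configuration is a list of
#' per-muscle entries `{name, group, L0, r0, r1, c}`; each entry is mirrored
#' into identical left/right specs.
#'
#' @param config list of per-muscle entries, or `NULL` for the packaged
#'   default (see [default_geometry_config()]).
#' @return list of [mtu_geometry_spec()] objects (class `mtu_geometry`),
#'   ordered left/right per muscle.
#' @export
build_reference_geometry <- function(config = NULL) {
  if (is.null(config)) config <- default_geometry_config()
  muscles <- config$muscles
  if (is.null(muscles) || length(muscles) == 0L) {
    stop("geometry configuration error: empty muscle list")
  }
  groups <- vapply(muscles, `[[`, "", "group")
  if (sum(groups == "extensor") < 2L || sum(groups == "flexor") < 1L) {
    stop("geometry configuration error: need at least 2 extensor groups ",
         "and 1 flexor group")
  }
  domain <- if (is.null(config$domain)) c(-0.2, 1.3) else as.numeric(config$domain)
  specs <- list()
  for (m in muscles) {
    for (side in c("left", "right")) {
      suffix <- if (side == "left") "_l" else "_r"
      specs[[paste0(m$name, suffix)]] <- mtu_geometry_spec(
        name = paste0(m$name, suffix), group = m$group, side = side,
        L0 = m$L0, r0 = m$r0, r1 = if (is.null(m$r1)) 0 else m$r1,
        c = if (is.null(m$c)) ifelse(m$group == "extensor", 0.95, 0.90) else m$c,
        domain = domain)
    }
  }
  structure(specs, class = "mtu_geometry", domain = domain)
}

#' Default geometry configuration
#'
#' Reads the packaged per-muscle geometry constants (JSON under
#' `inst/extdata`). The muscle set mirrors the surface-EMG montage used for
#' trunk studies: iliocostalis (IL), longissimus thoracis pars lumborum
#' (LTpL) and pars thoracis (LTpT) as extensors, rectus abdominis (RA) as
#' flexor, all bilateral.
#'
#' @param path optional path to an alternative JSON/YAML config.
#' @return list with elements `muscles` and `domain`.
#' @export
default_geometry_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_geometry.json", package = "exolift")
  }
  read_config(path)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
}

#' Fit a cubic spline surrogate of MTU length and moment arm
#'
#' Samples the analytic geometry on an angle grid and fits interpolating
#' cubic splines (Forsythe-Malcolm-Moler end conditions, which reproduce
#' polynomials up to degree 3 exactly) through \eqn{(\theta, L)} and
#' \eqn{(\theta, r)}. Evaluation outside the fitted domain is a hard error:
#' spline tails are meaningless and real-time use must stay inside the
#' working range.
#'
#' @param spec an [mtu_geometry_spec()].
#' @param grid angle samples, radians; at least 10 points spanning the
#'   working domain.
#' @return object of class `geometry_surrogate` with fields `name`, `group`,
#'   `degree`, `knots`, `length_values`, `moment_arm_values`, `domain`, `c`.
#' @export
fit_surrogate <- function(spec, grid = seq(spec$domain[1], spec$domain[2],
                                           length.out = 50)) {
  grid <- sort(unique(as.numeric(grid)))
  if (length(grid) < 4L) {
    stop("surrogate fitting error: need at least degree + 1 = 4 grid points")
  }
  if (length(grid) < 10L) {
    stop("surrogate fitting error: need >= 10 grid points spanning the domain")
  }
  structure(
    list(name = spec$name, group = spec$group, side = spec$side,
         degree = 3L, knots = grid,
         length_values = mtu_length(spec, grid),
         moment_arm_values = mtu_moment_arm(spec, grid),
         domain = range(grid), c = spec$c),
    class = "geometry_surrogate")
}

surrogate_funs <- function(surrogate) {
  list(
    length = stats::splinefun(surrogate$knots, surrogate$length_values,
                              method = "fmm"),
    moment_arm = stats::splinefun(surrogate$knots, surrogate$moment_arm_values,
                                  method = "fmm"))
}

#' Evaluate a geometry surrogate
#'
#' @param surrogate a `geometry_surrogate` from [fit_surrogate()].
#' @param theta angle(s) within the fitted domain, radians.
#' @return list with numeric vectors `length` (m) and `moment_arm` (m).
#' @export
evaluate_surrogate <- function(surrogate, theta) {
  bad <- theta < surrogate$domain[1] | theta > surrogate$domain[2]
  if (any(bad)) {
    stop(sprintf(
      "surrogate domain error for '%s': angle %.4f rad outside [%.4f, %.4f]",
      surrogate$name, theta[which(bad)[1]],
      surrogate$domain[1], surrogate$domain[2]))
  }
  f <- surrogate_funs(surrogate)
  list(length = f$length(theta), moment_arm = f$moment_arm(theta))
}

#' Fit surrogates for a whole geometry
#'
#' @param geometry an `mtu_geometry` list from [build_reference_geometry()].
#' @param n_grid number of fitting-grid points per MTU.
#' @return named list of `geometry_surrogate` objects.
#' @export
fit_all_surrogates <- function(geometry, n_grid = 50) {
  domain <- attr(geometry, "domain")
  grid <- seq(domain[1], domain[2], length.out = n_grid)
  lapply(geometry, fit_surrogate, grid = grid)
}

#' Serialize / restore a geometry surrogate
#'
#' Surrogates are stored as plain JSON (degree, knots, sampled values,
#' domain) so they can be exchanged with other tools.
#'
#' @param surrogate a `geometry_surrogate`.
#' @param path file path to write to / read from.
#' @return `read_surrogate` returns a `geometry_surrogate`.
#' @export
write_surrogate <- function(surrogate, path) {
  jsonlite::write_json(unclass(surrogate), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_surrogate
#' @export
read_surrogate <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$degree <- as.integer(x$degree)
  structure(x, class = "geometry_surrogate")
}
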