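#' Raw multi-channel EMG container
#'
#' @param channels numeric matrix (samples x channels) with column names, or
#'   a data frame of channel columns; volts, arbitrary scale.
#' @param sample_rate sampling rate in Hz. Must exceed twice the upper
#'   band-pass edge (600 Hz for the default 30-300 Hz band).
#' @return object of class `raw_emg` with fields `data`, `sample_rate`,
#'   `time`.
#' @export
raw_emg <- function(channels, sample_rate = 1000) {
  data <- as.matrix(channels)
  if (is.null(colnames(data))) {
    stop("raw_emg: channels must be named")
  }
  if (sample_rate <= 2 * 300) {
    stop("raw_emg: sample_rate must exceed 600 Hz (twice the 300 Hz ",
         "band-pass edge); got ", sample_rate)
  }
  structure(list(data = data, sample_rate = sample_rate,
                 time = (seq_len(nrow(data)) - 1L) / sample_rate),
            class = "raw_emg")
}

#' @export
print.raw_emg <- function(x, ...) {
  cat(sprintf("<raw_emg> %d channels, %.2f s at %g Hz\n",
              ncol(x$data), nrow(x$data) / x$sample_rate, x$sample_rate))
  invisible(x)
}

# Butterworth designs are cached: calibration evaluates the same filters
# hundreds of thousands of times.
.butter_cache <- new.env(parent = emptyenv())

butter_coefs <- function(order, cutoff_hz, fs, type) {
  key <- paste(order, paste(cutoff_hz, collapse = "_"), fs, type, sep = "|")
  hit <- .butter_cache[[key]]
  if (!is.null(hit)) return(hit)
  w <- cutoff_hz / (fs / 2)
  if (any(w >= 1)) {
    stop("filter parameter error: cutoff ", paste(cutoff_hz, collapse = "-"),
         " Hz at or above the Nyquist frequency (fs = ", fs, " Hz)")
  }
  if (any(w <= 0)) stop("filter parameter error: cutoff must be positive")
  bf <- signal::butter(order, w, type = type)
  co <- list(b = as.numeric(bf$b), a = as.numeric(bf$a))
  assign(key, co, envir = .butter_cache)
  co
}

# Causal IIR filtering with zero initial conditions; works column-wise on
# matrices. Lean replacement for signal::filter (avoids ts conversions).
iir_causal <- function(x, b, a) {
  xm <- as.matrix(x)
  n <- nrow(xm)
  k <- length(b)
  y <- stats::filter(xm, b, method = "convolution", sides = 1)
  y <- matrix(as.numeric(y), n, ncol(xm))
  if (k > 1) {                       # fill the NA head (zero-padded input)
    for (i in seq_len(min(k - 1, n))) {
      j <- seq_len(i)
      y[i, ] <- colSums(b[j] * xm[i - j + 1, , drop = FALSE])
    }
  }
  if (length(a) > 1) {
    y <- stats::filter(y, -a[-1], method = "recursive")
    y <- matrix(as.numeric(y), n, ncol(xm))
  }
  if (is.matrix(x)) { dimnames(y) <- dimnames(x); y } else as.numeric(y)
}

butter_causal <- function(x, order, cutoff_hz, fs, type) {
  co <- butter_coefs(order, cutoff_hz, fs, type)
  iir_causal(x, co$b, co$a)
}

#' EMG linear envelope (causal filter chain)
#'
#' Implements the standard envelope chain of real-time EMG-driven pipelines:
#' second-order Butterworth band-pass (default 30-300 Hz), full-wave
#' rectification, second-order Butterworth low-pass (default 3 Hz). All
#' filters are causal (forward-only), as in an on-line controller; the phase
#' lag of the chain is part of the modelled behaviour. Initial conditions are
#' zero, so the first ~0.5 s of output is a settling transient.
#'
#' @param raw a [raw_emg()] object.
#' @param band band-pass edges `c(low, high)` in Hz.
#' @param lp_cutoff low-pass cutoff in Hz.
#' @return numeric matrix of non-negative envelope values, same dimensions
#'   and column names as the input.
#' @export
envelope <- function(raw, band = c(30, 300), lp_cutoff = 3) {
  stopifnot(inherits(raw, "raw_emg"))
  fs <- raw$sample_rate
  out <- apply(raw$data, 2, function(x) {
    bp <- butter_causal(x, 2, band, fs, "pass")
    butter_causal(abs(bp), 2, lp_cutoff, fs, "low")
  })
  out <- pmax(out, 0)
  dimnames(out) <- dimnames(raw$data)
  out
}

#' MVC normalization of EMG envelopes
#'
#' Divides each envelope channel by its maximum-voluntary-contraction value
#' and clips to \[0, 1\]. The number of clipped samples is recorded per
#' channel so saturated normalization is visible.
#'
#' @param env envelope matrix (samples x channels) from [envelope()].
#' @param mvc named numeric vector of per-channel MVC maxima (> 0), in the
#'   same units as the envelopes.
#' @param sample_rate sampling rate of `env`, Hz (carried for downstream use).
#' @return object of class `emg_envelope`: fields `data` (normalized matrix
#'   in \[0,1\]), `mvc_values`, `clip_counts`, `sample_rate`.
#' @export
normalize_mvc <- function(env, mvc, sample_rate = 1000) {
  env <- as.matrix(env)
  chans <- colnames(env)
  if (is.null(names(mvc))) names(mvc) <- chans
  missing <- setdiff(chans, names(mvc))
  if (length(missing)) {
    stop("normalize_mvc: no MVC value for channel(s) ",
         paste(missing, collapse = ", "))
  }
  bad <- names(mvc)[mvc <= 0]
  if (length(bad)) {
    stop("normalize_mvc: MVC must be > 0; offending channel(s): ",
         paste(bad, collapse = ", "))
  }
  norm <- sweep(env, 2, mvc[chans], "/")
  clip_counts <- colSums(norm > 1)
  norm <- pmin(pmax(norm, 0), 1)
  structure(list(data = norm, mvc_values = mvc[chans],
                 clip_counts = clip_counts, sample_rate = sample_rate),
            class = "emg_envelope")
}

#' @export
print.emg_envelope <- function(x, ...) {
  cat(sprintf("<emg_envelope> %d channels, %d samples at %g Hz; %d clipped\n",
              ncol(x$data), nrow(x$data), x$sample_rate, sum(x$clip_counts)))
  invisible(x)
}

#' Default EMG-channel-to-MTU mapping
#'
#' One surface channel per namesake MTU (IL, LTpL, LTpT, RA; left and
#' right), weight 1.
#'
#' @param path optional alternative mapping JSON
#'   (`{mtu: {channel: weight}}`).
#' @return named list: per MTU, a named numeric vector of channel weights.
#' @export
default_channel_map <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "default_channel_map.json",
                        package = "exolift")
  }
  raw <- read_config(path)$map
  lapply(raw, function(w) unlist(w))
}

#' Allocate EMG envelopes to model MTUs
#'
#' Computes per-MTU neural excitations as weighted sums of normalized
#' envelope channels: \eqn{u_m(t) = \sum_{ch} w_{ch} e_{ch}(t)} with
#' non-negative weights summing to one per MTU.
#'
#' @param env an [emg_envelope] object (normalized).
#' @param mapping per-MTU named weight vectors; see [default_channel_map()].
#' @return numeric matrix (samples x MTUs) of excitations in \[0, 1\].
#' @export
map_channels <- function(env, mapping = default_channel_map()) {
  data <- env$data
  out <- matrix(0, nrow(data), length(mapping),
                dimnames = list(NULL, names(mapping)))
  for (m in names(mapping)) {
    w <- mapping[[m]]
    if (length(w) == 0L) {
      stop("channel mapping configuration error: MTU '", m,
           "' receives no channel")
    }
    missing <- setdiff(names(w), colnames(data))
    if (length(missing)) {
      stop("channel mapping configuration error: MTU '", m,
           "' references unknown channel(s) ", paste(missing, collapse = ", "))
    }
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
      stop("channel mapping configuration error: weights for '", m,
           "' must be >= 0 and sum to 1")
    }
    out[, m] <- data[, names(w), drop = FALSE] %*% w
  }
  out
}

#' Nonlinear excitation-to-activation shaping
#'
#' Exponential shaping of the EMG-force relationship:
#' \deqn{a = \frac{e^{Au} - 1}{e^{A} - 1}, \quad A \in (-3, 0),}
#' reducing to the identity at \eqn{A = 0}. Endpoint-exact (a(0) = 0,
#' a(1) = 1), strictly increasing and concave for negative shape factors.
#'
#' @param u excitation in \[0, 1\] (vector or matrix).
#' @param A shape factor in (-3, 0\]; scalar, or one value per column of `u`.
#' @return activations, same shape as `u`.
#' @export
excitation_to_activation <- function(u, A = -1.5) {
  if (any(u < -1e-12 | u > 1 + 1e-12, na.rm = TRUE)) {
    stop("excitation_to_activation: excitations must be MVC-normalized to ",
         "[0, 1]; range found [", format(min(u)), ", ", format(max(u)), "]")
  }
  if (any(A <= -3 | A > 0)) {
    stop("excitation_to_activation: shape factor A must lie in (-3, 0]")
  }
  u <- pmin(pmax(u, 0), 1)
  shape_one <- function(ui, Ai) {
    if (Ai == 0) ui else (exp(Ai * ui) - 1) / (exp(Ai) - 1)
  }
  if (is.matrix(u) && length(A) == ncol(u)) {
    out <- u
    for (j in seq_len(ncol(u))) out[, j] <- shape_one(u[, j], A[j])
    out
  } else if (length(A) == 1L) {
    shape_one(u, A)
  } else {
    stop("excitation_to_activation: A must be scalar or one value per column")
  }
}

#' Invert the activation shaping
#'
#' Used by the synthetic-trial generator to turn target activations into the
#' envelope levels that must be synthesized.
#'
#' @param a activations in \[0, 1\].
#' @param A shape factor in (-3, 0\].
#' @return excitations u in \[0, 1\].
#' @export
activation_to_excitation <- function(a, A = -1.5) {
  if (any(A <= -3 | A > 0)) stop("activation_to_excitation: A in (-3, 0]")
  a <- pmin(pmax(a, 0), 1)
  inv_one <- function(ai, Ai) {
    if (Ai == 0) ai else log(1 + ai * (exp(Ai) - 1)) / Ai
  }
  if (is.matrix(a) && length(A) == ncol(a)) {
    out <- a
    for (j in seq_len(ncol(a))) out[, j] <- inv_one(a[, j], A[j])
    out
  } else {
    inv_one(a, A[1])
  }
}
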