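make_raw <- function(x, fs = 1000, name = "ch1") {
  raw_emg(matrix(x, ncol = 1, dimnames = list(NULL, name)), fs)
}

test_that("envelope of silence is silence and output is non-negative", {
  env <- envelope(make_raw(numeric(2000)))
  expect_true(all(env == 0))
  withr::with_seed(1, {
    env2 <- envelope(make_raw(rnorm(2000)))
    expect_true(all(env2 >= 0))
  })
})

test_that("steady envelope of a passband sine matches the rectified-sine mean", {
  fs <- 1000
  t <- seq(0, 4 - 1/fs, by = 1/fs)
  x <- sin(2 * pi * 150 * t)
  env <- envelope(make_raw(x))
  # oracle: mean of |sin| is 2/pi, scaled by the band-pass gain at 150 Hz
  bf <- signal::butter(2, c(30, 300) / (fs / 2), type = "pass")
  H <- function(f) {
    z <- exp(-1i * 2 * pi * f / fs)
    abs(sum(bf$b * z^(0:(length(bf$b) - 1))) /
          sum(bf$a * z^(0:(length(bf$a) - 1))))
  }
  expected <- 2 / pi * H(150)
  steady <- mean(env[2000:4000])
  expect_lt(abs(steady - expected) / expected, 0.05)
})

test_that("3 Hz low-pass attenuates a 10 Hz modulation >= 20 dB relative to 1 Hz", {
  fs <- 1000
  t <- seq(0, 20 - 1/fs, by = 1/fs)
  demod_amp <- function(fmod) {
    subj_act <- 0.5 + 0.4 * sin(2 * pi * fmod * t)
    act <- matrix(subj_act, ncol = 1,
                  dimnames = list(NULL, "iliocostalis_l"))
    raw <- synthesize_raw_emg(act, test_subject, seed = 11, rate = fs,
                              mapping = default_channel_map()["iliocostalis_l"],
                              noise_floor = 0)
    env <- envelope(raw)[, 1]
    sel <- t >= 4          # settled
    # coherent demodulation at the modulation frequency
    2 * abs(mean(env[sel] * exp(-1i * 2 * pi * fmod * t[sel])))
  }
  a1 <- demod_amp(1)
  a10 <- demod_amp(10)
  expect_gte(20 * log10(a1 / a10), 20)
})

test_that("MVC normalization divides, clips at 1 and counts clipped samples", {
  env <- matrix(c(0.5, 0.5, 0.5, 0.6, 0.6, 0.6), ncol = 2,
                dimnames = list(NULL, c("a", "b")))
  ne <- normalize_mvc(env, c(a = 0.5, b = 0.6))
  expect_true(all(ne$data == 1))
  expect_equal(unname(ne$clip_counts), c(0, 0))

  env2 <- matrix(c(0.6, 0.6, 0.6, 0.1), ncol = 1,
                 dimnames = list(NULL, "a"))
  ne2 <- normalize_mvc(env2, c(a = 0.5))
  expect_equal(unname(ne2$clip_counts), 3)
  expect_equal(as.numeric(ne2$data), c(1, 1, 1, 0.2))

  expect_true(all(normalize_mvc(env * 0, c(a = 1, b = 1))$data == 0))
  expect_error(normalize_mvc(env, c(a = 0.5, b = 0)), "b")
})

test_that("channel mapping forms the stated weighted sums", {
  env <- normalize_mvc(
    matrix(c(0.2, 0.2, 0.4, 0.4), ncol = 2,
           dimnames = list(NULL, c("c1", "c2"))),
    c(c1 = 1, c2 = 1))
  # identity mapping
  u1 <- map_channels(env, list(m1 = c(c1 = 1)))
  expect_equal(as.numeric(u1), c(0.2, 0.2))
  # 50/50 mixture of (0.2, 0.4) is 0.3
  u2 <- map_channels(env, list(m = c(c1 = 0.5, c2 = 0.5)))
  expect_equal(as.numeric(u2), c(0.3, 0.3))
  expect_error(map_channels(env, list(m = numeric(0))), "no channel")
  expect_error(map_channels(env, list(m = c(c1 = 0.5, c2 = 0.4))),
               "sum to 1")
  # default table: each measured muscle drives its namesake MTU
  map <- default_channel_map()
  expect_setequal(names(map), names(default_pars))
  expect_true(all(vapply(map, function(w) length(w) == 1 && w == 1, TRUE)))
  expect_match(names(map$longissimus_lumbar_l), "LTpL_L")
})

test_that("activation shaping is endpoint-exact, matches the closed form, and is concave", {
  expect_equal(excitation_to_activation(0.5, A = 0), 0.5)
  for (A in c(-0.5, -1.5, -2.9)) {
    expect_equal(excitation_to_activation(0, A), 0)
    expect_equal(excitation_to_activation(1, A), 1)
  }
  expect_equal(excitation_to_activation(0.5, A = -2),
               (exp(-1) - 1) / (exp(-2) - 1), tolerance = 1e-12)
  expect_equal(excitation_to_activation(0.5, A = -2), 0.7311,
               tolerance = 1e-4)
  # strictly increasing and concave on a grid for A < 0
  u <- seq(0, 1, by = 0.01)
  for (A in c(-0.5, -1.5, -2.9)) {
    a <- excitation_to_activation(u, A)
    expect_true(all(diff(a) > 0))
    expect_true(all(diff(diff(a)) < 1e-12))
  }
  expect_error(excitation_to_activation(1.2, -1), "normalized")
  expect_error(excitation_to_activation(0.5, -3.5), "\\(-3, 0\\]")
  # inverse round trip
  a <- excitation_to_activation(u, -1.5)
  expect_equal(activation_to_excitation(a, -1.5), u, tolerance = 1e-12)
})

test_that("the full envelope chain is deterministic", {
  withr::with_seed(5, x <- rnorm(3000))
  r <- make_raw(x)
  e1 <- normalize_mvc(envelope(r), c(ch1 = 0.5))
  e2 <- normalize_mvc(envelope(r), c(ch1 = 0.5))
  expect_identical(e1$data, e2$data)
})

test_that("raw EMG containers enforce the sampling-rate precondition", {
  expect_error(raw_emg(matrix(0, 10, 1, dimnames = list(NULL, "a")), 500),
               "600 Hz")
  expect_error(envelope(make_raw(numeric(100)), band = c(30, 600)),
               "Nyquist")
})
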