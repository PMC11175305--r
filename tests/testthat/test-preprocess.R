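cfg4 <- signal_config()

test_that("bandpass rejects DC, passes in-band tones at the designed gain", {
  n <- 4000
  t <- seq_len(n) / cfg4$fs
  # zero in, zero out
  zero <- emg_record(t, matrix(0, n, 4))
  expect_equal(emg_bandpass(zero, cfg4)$signals, matrix(0, n, 4))
  # DC offset decays to zero (0 Hz is outside the passband)
  dc <- emg_record(t, matrix(1, n, 4))
  out <- emg_bandpass(dc, cfg4)$signals[, 1]
  expect_lt(max(abs(out[(n - 200):n])), 1e-3)
  # 50 Hz tone: steady-state amplitude matches |H| evaluated directly from
  # the filter polynomials with complex arithmetic (independent of the
  # time-domain filtering path)
  f0 <- 50
  x <- sin(2 * pi * f0 * t)
  y <- emg_bandpass(emg_record(t, cbind(x, x, x, x)), cfg4)$signals[, 1]
  bf <- signal::butter(2, c(cfg4$fc_low, cfg4$fc_high) / (cfg4$fs / 2),
                       type = "pass")
  z <- exp(1i * 2 * pi * f0 / cfg4$fs)
  gain <- abs(sum(bf$b * z^-(seq_along(bf$b) - 1)) /
                sum(bf$a * z^-(seq_along(bf$a) - 1)))
  # steady-state amplitude by DFT projection over the last 100 cycles
  keep <- (n - 2000 + 1):n
  amp <- 2 * Mod(mean(y[keep] * exp(-1i * 2 * pi * f0 * t[keep])))
  expect_equal(amp, gain, tolerance = 1e-3)
})

test_that("causal filtering equals a direct difference-equation evaluation", {
  set.seed(1)
  x <- rnorm(100)
  bf <- signal::butter(2, c(1, 250) / 500, type = "pass")
  y_pkg <- emg_bandpass(emg_record(seq_len(100) / 1000,
                                   cbind(x, x, x, x)),
                        cfg4)$signals[, 1]
  # hand-rolled direct-form II transposed difference equation
  b <- bf$b; a <- bf$a
  y <- numeric(100)
  for (i in seq_len(100)) {
    acc <- 0
    for (k in seq_along(b)) if (i - k + 1 >= 1) acc <- acc + b[k] * x[i - k + 1]
    for (k in 2:length(a)) if (i - k + 1 >= 1) acc <- acc - a[k] * y[i - k + 1]
    y[i] <- acc / a[1]
  }
  expect_lt(max(abs(y - y_pkg)), 1e-9)
})

test_that("rectified smoothing recovers constant amplitudes", {
  n <- 6000
  t <- seq_len(n) / cfg4$fs
  steady <- (n - 100):n
  for (sig in list(matrix(0.8, n, 4), matrix(-0.8, n, 4))) {
    env <- emg_envelope(emg_record(t, sig), cfg4)
    expect_equal(mean(env$envelope[steady, 1]), 0.8, tolerance = 1e-3)
  }
  sq <- matrix(rep(c(0.8, -0.8), length.out = n), n, 4)
  env <- emg_envelope(emg_record(t, sq), cfg4)
  expect_equal(mean(env$envelope[steady, 1]), 0.8, tolerance = 1e-3)
})

test_that("calibration extracts rest means and per-channel voluntary maxima", {
  mk_env <- function(env_mat) {
    structure(list(t = seq_len(nrow(env_mat)) / 1000, envelope = env_mat,
                   rest_baseline = NULL, max_level = NULL, settle_n = 0L),
              class = "envelope_record")
  }
  rest <- mk_env(matrix(0.1, 100, 2))
  vol <- mk_env(cbind(c(rep(0.2, 50), rep(1.1, 50)),
                      c(rep(0.5, 30), rep(0.2, 70))))
  cal <- emg_calibrate(rest, vol)
  expect_equal(cal$rest_baseline, c(0.1, 0.1))
  expect_equal(cal$max_level, c(1.1, 0.5))
  # voluntary identical to rest -> failure
  expect_error(emg_calibrate(rest, rest), "calibration failure")
})

test_that("envelope normalization follows the baseline/maximum form", {
  mk_env <- function(env_mat, rest, mx) {
    structure(list(t = seq_len(nrow(env_mat)) / 1000, envelope = env_mat,
                   rest_baseline = rest, max_level = mx, settle_n = 0L),
              class = "envelope_record")
  }
  env <- mk_env(matrix(c(0.6, 0.1, 1.1, 0.05), 4, 1), 0.1, 1.1)
  ep <- emg_normalize(env)
  expect_equal(as.numeric(ep), c(0.5, 0, 1, 0))  # last clipped at 0
  # scale covariance: scaling E, E^st, E^max jointly leaves E' unchanged
  k <- 3.7
  env_k <- mk_env(matrix(c(0.6, 0.1, 1.1, 0.05) * k, 4, 1), 0.1 * k, 1.1 * k)
  expect_equal(emg_normalize(env_k), ep)
})

test_that("coordination features sum to one and ignore intensity", {
  fv <- feature_vector(rbind(c(0.2, 0.2, 0.2, 0.2), c(0.3, 0.1, 0, 0)))
  expect_equal(fv$x[1, ], rep(0.25, 4))
  expect_equal(fv$x[2, ], c(0.75, 0.25, 0, 0))
  expect_false(any(fv$sub_threshold))
  # degenerate rest sample: uniform fallback, flagged
  fv0 <- feature_vector(matrix(0, 1, 4))
  expect_equal(fv0$x[1, ], rep(0.25, 4))
  expect_true(fv0$sub_threshold[1])
  # intensity invariance and sum-to-one over random non-negative inputs
  set.seed(5)
  e <- matrix(runif(200, 0.01, 2), 50, 4)
  f1 <- feature_vector(e)$x
  f2 <- feature_vector(2.5 * e)$x
  expect_equal(f1, f2, tolerance = 1e-12)
  expect_true(all(abs(rowSums(f1) - 1) < 1e-9))
  expect_true(all(f1 >= 0 & f1 <= 1))
})

test_that("activation level is the channel mean", {
  expect_equal(activation_level(matrix(1, 1, 4)), 1)
  expect_equal(activation_level(matrix(c(0.2, 0.4, 0.6, 0.8), 1, 4)), 0.5)
  expect_equal(activation_level(matrix(0, 1, 4)), 0)
})

test_that("activation gate requires a sustained supra-threshold run", {
  expect_false(any(activation_gate(rep(0, 100), 0.2, 25)))
  g <- activation_gate(rep(0.5, 100), 0.2, 25)
  expect_false(any(g[1:24]))
  expect_true(all(g[25:100]))
  # single-sample spike never opens a debounced gate
  f <- rep(0, 100); f[50] <- 1
  expect_false(any(activation_gate(f, 0.2, 25)))
  # brute-force scan oracle on a random series
  set.seed(2)
  f <- runif(300)
  deb <- 7L
  g <- activation_gate(f, 0.5, deb)
  oracle <- vapply(seq_along(f), function(i) {
    i >= deb && all(f[(i - deb + 1):i] >= 0.5)
  }, TRUE)
  expect_equal(g, oracle)
})

test_that("full chain yields sum-to-one features on gated samples", {
  fx <- emg_fixture()
  g <- generate_emg(fx$spec, 2, seed = 31, duration = 1)
  ft <- emg_features(g$record, fx$cfg, fx$cal)
  expect_true(any(ft$gate))
  gated <- ft$x[ft$gate, , drop = FALSE]
  expect_true(all(abs(rowSums(gated) - 1) < 1e-9))
  expect_true(all(gated >= 0 & gated <= 1))
})
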