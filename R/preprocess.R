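#' Multichannel raw EMG record
#'
#' @param t Numeric vector of timestamps in s, uniformly sampled.
#' @param signals Numeric matrix, one column per channel.
#' @return Object of class `"emg_record"`.
#' @export
emg_record <- function(t, signals) {
  signals <- as.matrix(signals)
  if (length(t) != nrow(signals)) {
    stop("t and signals must have the same number of samples", call. = FALSE)
  }
  structure(list(t = as.numeric(t), signals = signals), class = "emg_record")
}

# second-order Butterworth section applied causally (single pass, zero
# initial state). Group delay is nonzero by design: the chain is online.
.butter_causal <- function(x, filt) {
  as.numeric(signal::filter(filt, x))
}

#' Bandpass-filter a raw EMG record
#'
#' Applies a causal second-order Butterworth bandpass (`fc_low`, `fc_high`)
#' to every channel. Single-pass (not zero-phase) filtering is used because
#' the chain emulates an online system; the group delay is inherited by all
#' downstream features.
#'
#' @param raw An [emg_record()].
#' @param cfg A [signal_config()].
#' @return Filtered `"emg_record"` of the same length.
#' @export
emg_bandpass <- function(raw, cfg) {
  stopifnot(inherits(raw, "emg_record"), inherits(cfg, "signal_config"))
  if (cfg$fc_high >= cfg$fs / 2) {
    stop("invalid config: fc_high must be below Nyquist", call. = FALSE)
  }
  bf <- signal::butter(2, c(cfg$fc_low, cfg$fc_high) / (cfg$fs / 2),
                       type = "pass")
  filtered <- apply(raw$signals, 2, .butter_causal, filt = bf)
  emg_record(raw$t, filtered)
}

#' Rectify and smooth a filtered EMG record into an amplitude envelope
#'
#' Full-wave rectification followed by a causal second-order low-pass
#' Butterworth filter at `fc_smooth` extracts the amplitude envelope
#' `E_l(t)` per channel. Calibration baselines are unset until
#' [emg_calibrate()] fills them.
#'
#' @param filtered An [emg_record()] (normally the output of [emg_bandpass()]).
#' @param cfg A [signal_config()].
#' @return Object of class `"envelope_record"` with fields `t`, `envelope`
#'   (matrix), `rest_baseline`, `max_level` (both `NULL` until calibrated),
#'   and `settle_n` (number of initial samples within the filter settle-in
#'   period, three time constants of the smoothing filter).
#' @export
emg_envelope <- function(filtered, cfg) {
  stopifnot(inherits(filtered, "emg_record"), inherits(cfg, "signal_config"))
  lf <- signal::butter(2, cfg$fc_smooth / (cfg$fs / 2), type = "low")
  env <- apply(abs(filtered$signals), 2, .butter_causal, filt = lf)
  settle_n <- min(nrow(env), ceiling(3 / (2 * pi * cfg$fc_smooth) * cfg$fs))
  structure(
    list(t = filtered$t, envelope = env, rest_baseline = NULL,
         max_level = NULL, settle_n = settle_n),
    class = "envelope_record"
  )
}

#' Calibrate rest baselines and voluntary maxima
#'
#' Computes, per channel, the rest level `E_l^st` as the mean envelope over
#' the rest recording and the voluntary maximum `E_l^max` as the peak
#' envelope during a voluntary performance of the target motions. Both
#' recordings must have passed through the same preprocessing. Samples within
#' the filter settle-in period are excluded from the statistics.
#'
#' @param rest An `"envelope_record"` recorded at rest.
#' @param voluntary_max An `"envelope_record"` recorded during voluntary
#'   maximal performance of the motions.
#' @return A copy of `voluntary_max`'s calibration slots as a list with
#'   `rest_baseline` and `max_level` per channel.
#' @export
emg_calibrate <- function(rest, voluntary_max) {
  stopifnot(inherits(rest, "envelope_record"),
            inherits(voluntary_max, "envelope_record"))
  settled <- function(rec) {
    drop_n <- min(rec$settle_n, nrow(rec$envelope) - 1L)
    if (drop_n > 0) rec$envelope[-seq_len(drop_n), , drop = FALSE]
    else rec$envelope
  }
  e_st <- colMeans(settled(rest))
  e_max <- apply(settled(voluntary_max), 2, max)
  if (any(e_max <= e_st)) {
    bad <- which(e_max <= e_st)
    stop(sprintf(
      "calibration failure: voluntary maximum does not exceed rest baseline on channel(s) %s",
      paste(bad, collapse = ", ")), call. = FALSE)
  }
  list(rest_baseline = unname(e_st), max_level = unname(e_max))
}

#' Attach calibration baselines to an envelope record
#'
#' @param env An `"envelope_record"`.
#' @param calibration List with `rest_baseline` and `max_level` (from
#'   [emg_calibrate()]).
#' @return Calibrated `"envelope_record"`.
#' @export
set_calibration <- function(env, calibration) {
  stopifnot(inherits(env, "envelope_record"))
  if (length(calibration$rest_baseline) != ncol(env$envelope) ||
      length(calibration$max_level) != ncol(env$envelope)) {
    stop("calibration channel count mismatch", call. = FALSE)
  }
  env$rest_baseline <- calibration$rest_baseline
  env$max_level <- calibration$max_level
  env
}

#' Normalize a calibrated envelope
#'
#' Per channel, `E'_l(t) = (E_l(t) - E_l^st) / (E_l^max - E_l^st)`, clipped
#' below at 0 (values below the rest baseline carry no contraction
#' information and would break the non-negativity the coordination features
#' assume).
#'
#' @param env A calibrated `"envelope_record"`.
#' @return Numeric matrix `E'` with one column per channel, values >= 0.
#' @export
emg_normalize <- function(env) {
  stopifnot(inherits(env, "envelope_record"))
  if (is.null(env$rest_baseline) || is.null(env$max_level)) {
    stop("envelope record is not calibrated; run emg_calibrate first",
         call. = FALSE)
  }
  scaled <- sweep(env$envelope, 2, env$rest_baseline, `-`)
  scaled <- sweep(scaled, 2, env$max_level - env$rest_baseline, `/`)
  pmax(scaled, 0)
}

#' Coordination feature vectors from normalized envelopes
#'
#' Each sample's channel vector is divided by its sum so that the feature
#' vector `x(t)` sums to 1, separating the muscle-coordination *pattern*
#' from overall contraction intensity. When the channel sum falls below
#' `eps` the ratio is undefined (rest); such samples are returned as the
#' uniform vector `1/L` and flagged sub-threshold — the activation gate is
#' responsible for ignoring them.
#'
#' @param e_prime Numeric matrix (or vector) of normalized envelopes, >= 0.
#' @param eps Sub-threshold guard on the channel sum.
#' @return List with `x` (matrix of feature vectors, rows sum to 1) and
#'   `sub_threshold` (logical vector).
#' @export
feature_vector <- function(e_prime, eps = 1e-6) {
  if (is.null(dim(e_prime))) e_prime <- matrix(e_prime, nrow = 1)
  if (any(e_prime < 0)) stop("normalized envelopes must be >= 0", call. = FALSE)
  L <- ncol(e_prime)
  s <- rowSums(e_prime)
  sub <- s < eps
  x <- e_prime / ifelse(s < eps, 1, s)
  x[sub, ] <- 1 / L
  list(x = x, sub_threshold = sub)
}

#' Muscle activation level
#'
#' `F(t) = (1/L) sum_l E'_l(t)`: the mean normalized envelope across
#' channels, measuring overall contraction intensity on a 0--1 scale
#' (1 = every channel at its voluntary maximum).
#'
#' @param e_prime Numeric matrix (or vector) of normalized envelopes.
#' @return Numeric vector `F(t)`.
#' @export
activation_level <- function(e_prime) {
  if (is.null(dim(e_prime))) e_prime <- matrix(e_prime, nrow = 1)
  if (any(e_prime < 0)) stop("normalized envelopes must be >= 0", call. = FALSE)
  rowMeans(e_prime)
}

#' Activation gate from the muscle activation level
#'
#' The system drive gate is true at sample `t` iff `F >= threshold` for
#' `debounce_samples` consecutive samples ending at `t`. The debounce
#' suppresses single-sample noise spikes.
#'
#' @param f Numeric activation-level series.
#' @param threshold Positive activation threshold.
#' @param debounce_samples Number of consecutive supra-threshold samples
#'   required (>= 1).
#' @return Logical gate series, same length as `f`.
#' @export
activation_gate <- function(f, threshold, debounce_samples = 1L) {
  if (threshold <= 0) stop("threshold must be > 0", call. = FALSE)
  debounce_samples <- max(1L, as.integer(debounce_samples))
  above <- f >= threshold
  # run length of consecutive TRUE ending at each sample
  run <- integer(length(above))
  cur <- 0L
  for (i in seq_along(above)) {
    cur <- if (above[i]) cur + 1L else 0L
    run[i] <- cur
  }
  run >= debounce_samples
}

#' Full preprocessing chain: raw EMG to gated feature sequence
#'
#' Convenience wrapper running bandpass, rectification/smoothing,
#' normalization against a supplied calibration, coordination features,
#' activation level and gate.
#'
#' @param raw An [emg_record()].
#' @param cfg A [signal_config()].
#' @param calibration Output of [emg_calibrate()].
#' @return Object of class `"feature_sequence"`: list with `t`, `x` (feature
#'   matrix), `activation` (`F(t)`), `gate` (logical), `sub_threshold`.
#' @export
emg_features <- function(raw, cfg, calibration) {
  env <- set_calibration(emg_envelope(emg_bandpass(raw, cfg), cfg), calibration)
  ep <- emg_normalize(env)
  fv <- feature_vector(ep)
  f <- activation_level(ep)
  debounce <- max(1L, as.integer(round(cfg$debounce_ms / 1000 * cfg$fs)))
  g <- activation_gate(f, cfg$gate_threshold, debounce)
  structure(
    list(t = raw$t, x = fv$x, activation = f, gate = g,
         sub_threshold = fv$sub_threshold),
    class = "feature_sequence"
  )
}
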