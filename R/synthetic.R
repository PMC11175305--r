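#' Specification for synthetic multichannel EMG
#'
#' Describes the generator for surrogate surface EMG: per-class
#' muscle-coordination patterns (rows summing to 1), a rest baseline and
#' activation amplitude per channel, slow multiplicative envelope noise, and
#' a band-limited noise carrier (interference-pattern surrogate). The
#' default four patterns emulate a four-muscle wrist montage where each
#' movement is dominated by one muscle with partial co-activation of its
#' neighbour.
#'
#' @param patterns C x L matrix of coordination patterns, rows sum to 1.
#' @param rest Per-channel rest envelope level (recycled), arbitrary units.
#' @param amplitude Peak activation envelope amplitude, arbitrary units.
#' @param noise_sd SD of the slow multiplicative envelope noise
#'   (dimensionless, relative to the activation envelope).
#' @param carrier_band Bandpass band of the noise carrier, Hz.
#' @param duration Recording duration, s.
#' @param fs Sampling frequency, Hz.
#' @param ramp Activation onset/offset ramp time, s.
#' @return Object of class `"emg_gen_spec"`.
#' @export
emg_gen_spec <- function(patterns = NULL, rest = 0.05, amplitude = 1,
                         noise_sd = 0.1, carrier_band = c(20, 450),
                         duration = 0.5, fs = 1000, ramp = 0.1) {
  if (is.null(patterns)) {
    base <- c(0.6, 0.2, 0.1, 0.1)
    patterns <- t(vapply(0:3, function(s) base[((0:3 - s) %% 4) + 1],
                         numeric(4)))
  }
  patterns <- as.matrix(patterns)
  if (any(abs(rowSums(patterns) - 1) > 1e-9)) {
    stop("pattern rows must sum to 1", call. = FALSE)
  }
  stopifnot(noise_sd >= 0, amplitude > 0, duration > 0, fs > 2 * carrier_band[2])
  structure(
    list(patterns = patterns, rest = rep_len(rest, ncol(patterns)),
         amplitude = amplitude, noise_sd = noise_sd,
         carrier_band = carrier_band, duration = duration, fs = fs,
         ramp = ramp),
    class = "emg_gen_spec"
  )
}

# unit-mean-|.| band-limited noise carrier
.emg_carrier <- function(n, band, fs) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  x <- as.numeric(signal::filter(bf, stats::rnorm(n + 500)))[-(1:500)]
  x / (stats::sd(x) * sqrt(2 / pi))
}

# smooth ramp-hold-(ramp) activation profile on [0, 1]
.activation_shape <- function(n, fs, ramp, release = FALSE) {
  t <- seq_len(n) / fs
  s <- pmin(t / ramp, 1)
  s <- 0.5 - 0.5 * cos(pi * s)
  if (release) {
    tail_t <- (n / fs) - t
    r <- pmin(tail_t / ramp, 1)
    s <- s * (0.5 - 0.5 * cos(pi * r))
  }
  s
}

#' Generate a synthetic EMG recording for one motion class
#'
#' Per channel, the signal is amplitude-modulated band-limited noise whose
#' modulation envelope is `rest_l + amplitude * pattern[class, l] * shape(t)`
#' times slow multiplicative noise. The carrier is normalized so the
#' expected rectified level equals the modulation envelope, making the
#' preprocessing chain's envelope an estimate of the designed one.
#' `class_id = 0` (or `NA`) produces a rest recording.
#'
#' @param spec An [emg_gen_spec()].
#' @param class_id Motion class (row of `spec$patterns`), or 0/`NA` for
#'   rest.
#' @param seed Integer seed; output is bytewise-reproducible given the seed.
#' @param duration Optional duration override, s.
#' @return List with `record` (an [emg_record()]), `class_id`, `active`
#'   (logical per-sample ground-truth activation labels), and `envelope`
#'   (the designed modulation envelope matrix).
#' @export
generate_emg <- function(spec, class_id, seed, duration = NULL) {
  stopifnot(inherits(spec, "emg_gen_spec"))
  set.seed(as.integer(seed))
  dur <- if (is.null(duration)) spec$duration else duration
  n <- as.integer(round(dur * spec$fs))
  L <- ncol(spec$patterns)
  t <- seq_len(n) / spec$fs
  rest_only <- is.na(class_id) || class_id == 0
  shape <- if (rest_only) numeric(n) else
    .activation_shape(n, spec$fs, spec$ramp)
  pat <- if (rest_only) numeric(L) else spec$patterns[class_id, ]
  # slow multiplicative envelope noise, shared low-pass at 5 Hz
  env <- matrix(NA_real_, n, L)
  sig <- matrix(NA_real_, n, L)
  lf <- signal::butter(2, 5 / (spec$fs / 2), type = "low")
  for (l in seq_len(L)) {
    noise <- if (spec$noise_sd > 0) {
      raw <- stats::rnorm(n + 500)
      sm <- as.numeric(signal::filter(lf, raw))[-(1:500)]
      1 + sm / stats::sd(sm) * spec$noise_sd
    } else rep(1, n)
    m <- spec$rest[l] + spec$amplitude * pat[l] * shape * pmax(noise, 0)
    m <- pmax(m, 0)
    env[, l] <- m
    sig[, l] <- m * .emg_carrier(n, spec$carrier_band, spec$fs)
  }
  list(record = emg_record(t, sig),
       class_id = if (rest_only) NA_integer_ else as.integer(class_id),
       active = shape > 0.5, envelope = env)
}

#' Generate calibration recordings (rest + voluntary maxima)
#'
#' Produces a rest recording and a voluntary recording in which each motion
#' class is performed in turn (sustained activation), suitable for
#' [emg_calibrate()]. Durations default to 2 s of rest and 1 s per class so
#' the envelope filter settles.
#'
#' @param spec An [emg_gen_spec()].
#' @param seed Integer seed.
#' @param rest_duration Rest recording duration, s.
#' @param per_class_duration Duration of each class's voluntary segment, s.
#' @return List with `rest` and `voluntary` [emg_record()]s.
#' @export
generate_calibration_recordings <- function(spec, seed, rest_duration = 2,
                                            per_class_duration = 1) {
  stopifnot(inherits(spec, "emg_gen_spec"))
  rest <- generate_emg(spec, 0, seed = seed, duration = rest_duration)
  C <- nrow(spec$patterns)
  segs <- lapply(seq_len(C), function(cc) {
    generate_emg(spec, cc, seed = seed + cc, duration = per_class_duration)
  })
  sig <- do.call(rbind, lapply(segs, function(s) s$record$signals))
  t <- seq_len(nrow(sig)) / spec$fs
  list(rest = rest$record, voluntary = emg_record(t, sig))
}

#' Synthetic subject skill
#'
#' Parameterizes a simulated subject's pointing behaviour: a systematic
#' endpoint bias, isotropic endpoint noise, a half-sine lateral bow
#' (path curvature), additive sinusoidal tremor, and the movement duration.
#' Per-session multiplicative decay factors (in `(0, 1]`) model motor
#' learning: each training session multiplies the error-like parameters by
#' their factor, and the duration relaxes toward `duration_target` by its
#' factor.
#'
#' @param endpoint_bias 2-vector systematic endpoint offset, degrees.
#' @param endpoint_noise_sd SD of isotropic endpoint noise per axis,
#'   degrees.
#' @param curvature Lateral half-sine bow amplitude, degrees.
#' @param tremor_amplitude Additive tremor amplitude, degrees.
#' @param tremor_freq Tremor frequency, Hz (physiological range ~8-12 Hz).
#' @param duration Movement duration, s.
#' @param duration_target Duration the subject converges to with training,
#'   s.
#' @param fs Trajectory sampling rate, Hz.
#' @param decay Named list of per-session multiplicative decay factors for
#'   `bias`, `noise`, `curvature`, `tremor`, `duration` (fraction of the
#'   remaining duration gap retained per session).
#' @return Object of class `"subject_skill"`.
#' @export
subject_skill <- function(endpoint_bias = c(2, 1), endpoint_noise_sd = 2,
                          curvature = 5, tremor_amplitude = 0.4,
                          tremor_freq = 9, duration = 2.8,
                          duration_target = 2.8, fs = 1000,
                          decay = list(bias = 0.9, noise = 0.9,
                                       curvature = 0.92, tremor = 0.95,
                                       duration = 0.85)) {
  stopifnot(endpoint_noise_sd >= 0, curvature >= 0, tremor_amplitude >= 0,
            duration > 0)
  dk <- unlist(decay)
  if (any(dk <= 0 | dk > 1)) {
    stop("decay factors must lie in (0, 1]", call. = FALSE)
  }
  structure(
    list(endpoint_bias = endpoint_bias, endpoint_noise_sd = endpoint_noise_sd,
         curvature = curvature, tremor_amplitude = tremor_amplitude,
         tremor_freq = tremor_freq, duration = duration,
         duration_target = duration_target, fs = fs, decay = decay),
    class = "subject_skill"
  )
}

#' Advance a subject skill by training sessions
#'
#' Applies the per-session multiplicative decay `n_sessions` times.
#'
#' @param skill A [subject_skill()].
#' @param n_sessions Number of training sessions.
#' @return The evolved `"subject_skill"`.
#' @export
evolve_skill <- function(skill, n_sessions = 1) {
  stopifnot(inherits(skill, "subject_skill"), n_sessions >= 0)
  d <- skill$decay
  k <- n_sessions
  skill$endpoint_bias <- skill$endpoint_bias * d$bias^k
  skill$endpoint_noise_sd <- skill$endpoint_noise_sd * d$noise^k
  skill$curvature <- skill$curvature * d$curvature^k
  skill$tremor_amplitude <- skill$tremor_amplitude * d$tremor^k
  skill$duration <- skill$duration_target +
    (skill$duration - skill$duration_target) * d$duration^k
  skill
}

#' Generate one pointing trial from a subject skill
#'
#' The trial is a minimum-jerk backbone from `start` to
#' `target + bias + endpoint noise`, plus a half-sine lateral bow of the
#' curvature amplitude (peaking mid-movement, zero at both ends) and
#' additive sinusoidal tremor with a random phase on both task axes.
#'
#' @param skill A [subject_skill()].
#' @param start Task start point, 2-vector (degrees).
#' @param target Task target point, 2-vector (degrees).
#' @param seed Integer seed.
#' @return A [trial_trajectory()] whose `start`/`target` are the task's.
#' @export
generate_trial <- function(skill, start, target, seed) {
  stopifnot(inherits(skill, "subject_skill"))
  set.seed(as.integer(seed))
  noise <- stats::rnorm(2, 0, skill$endpoint_noise_sd)
  endpoint <- target + skill$endpoint_bias + noise
  bb <- minimum_jerk(start, endpoint, skill$duration, fs_out = skill$fs,
                     limit = Inf)
  tau <- bb$t / skill$duration
  d <- target - start
  u <- d / sqrt(sum(d^2))
  perp_u <- c(-u[2], u[1])
  bow <- skill$curvature * sin(pi * tau)
  p <- bb$p + outer(bow, perp_u)
  if (skill$tremor_amplitude > 0) {
    ph <- stats::runif(2, 0, 2 * pi)
    tm <- cbind(sin(2 * pi * skill$tremor_freq * bb$t + ph[1]),
                sin(2 * pi * skill$tremor_freq * bb$t + ph[2]))
    # tremor fades in/out with the movement so endpoints stay interpretable
    fade <- sin(pi * tau)
    p <- p + skill$tremor_amplitude * tm * fade
  }
  trial_trajectory(bb$t, p, start, target)
}

#' Generate a noisy FES calibration curve
#'
#' Samples the sigmoid current-angle model at a stepwise-increasing current
#' ladder and adds Gaussian measurement noise to the angles.
#'
#' @param params List with `b`, `c`, `d` (true model).
#' @param currents Current ladder, mA (strictly increasing).
#' @param noise_sd Angle noise SD, degrees.
#' @param seed Integer seed.
#' @return Data frame with columns `current_mA`, `angle_deg`.
#' @export
generate_fes_calibration <- function(params, currents = seq(0, 20, by = 1),
                                     noise_sd = 0, seed = 1) {
  set.seed(as.integer(seed))
  theta <- fes_angle(currents, params)
  if (noise_sd > 0) theta <- theta + stats::rnorm(length(theta), 0, noise_sd)
  data.frame(current_mA = currents, angle_deg = theta)
}
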