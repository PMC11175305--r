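#' Pointing trial trajectory
#'
#' A recorded 2-DOF pointing movement with its task geometry: uniformly
#' sampled angle series, shared start point, and target point.
#'
#' @param t Timestamps in s (uniform).
#' @param p n x 2 matrix of joint angles (degrees).
#' @param start Task start point, 2-vector (degrees).
#' @param target Task target point, 2-vector (degrees).
#' @return Object of class `"trial"`.
#' @export
trial_trajectory <- function(t, p, start, target) {
  p <- as.matrix(p)
  stopifnot(length(t) == nrow(p), ncol(p) == 2,
            length(start) == 2, length(target) == 2)
  if (sqrt(sum((target - start)^2)) == 0) {
    stop("start and target must differ", call. = FALSE)
  }
  fs <- 1 / stats::median(diff(t))
  structure(list(t = as.numeric(t), p = p, start = as.numeric(start),
                 target = as.numeric(target), fs = fs),
            class = "trial")
}

#' Decompose a trial into parallel and perpendicular components
#'
#' Projects the displacement from the start point onto the unit vector
#' pointing from start to target (parallel component `P_par`) and its
#' orthogonal complement (perpendicular component `P_perp`; sign by the
#' right-hand convention: positive to the left of the movement direction).
#' At every sample `P_par^2 + P_perp^2 = |P - start|^2`.
#'
#' @param trial A [trial_trajectory()].
#' @return Object of class `"decomposed_trial"`: list with `t`, `par`,
#'   `perp`, `fs`, `path_length` (the start-target distance, degrees).
#' @export
decompose <- function(trial) {
  stopifnot(inherits(trial, "trial"))
  d <- trial$target - trial$start
  len <- sqrt(sum(d^2))
  if (len == 0) stop("zero-length movement direction", call. = FALSE)
  u <- d / len
  rel <- sweep(trial$p, 2, trial$start, `-`)
  par <- rel[, 1] * u[1] + rel[, 2] * u[2]
  perp <- u[1] * rel[, 2] - u[2] * rel[, 1]
  structure(list(t = trial$t, par = par, perp = perp, fs = trial$fs,
                 path_length = len),
            class = "decomposed_trial")
}

#' Endpoint error
#'
#' Euclidean distance between the target point and the final trajectory
#' sample; smaller is more accurate.
#'
#' @param trial A [trial_trajectory()].
#' @return Endpoint error in degrees.
#' @export
endpoint_error <- function(trial) {
  stopifnot(inherits(trial, "trial"))
  endp <- trial$p[nrow(trial$p), ]
  sqrt(sum((trial$target - endp)^2))
}

#' Maximum lateral deviation
#'
#' Largest absolute excursion orthogonal to the start-to-target direction;
#' smaller means a straighter path.
#'
#' @param decomp A [decompose()]d trial.
#' @return Maximum lateral deviation in degrees.
#' @export
max_lateral_deviation <- function(decomp) {
  stopifnot(inherits(decomp, "decomposed_trial"))
  max(abs(decomp$perp))
}

#' Endpoint spread over repeated trials
#'
#' Movement-reproducibility index over `M >= 2` trials sharing a task: each
#' trial's endpoint is expressed in parallel/perpendicular task coordinates,
#' `e(i)` is its distance from the mean endpoint, and the index is the mean
#' of the `e(i)` (the mean distance to the mean endpoint, not a conventional
#' standard deviation).
#'
#' @param trials List of [trial_trajectory()] objects with common
#'   start/target.
#' @return Endpoint spread `s` in degrees.
#' @export
endpoint_sd <- function(trials) {
  if (length(trials) < 2) stop("at least 2 trials are required", call. = FALSE)
  ends <- t(vapply(trials, function(tr) {
    dc <- decompose(tr)
    n <- length(dc$par)
    c(dc$par[n], dc$perp[n])
  }, numeric(2)))
  ctr <- colMeans(ends)
  mean(sqrt((ends[, 1] - ctr[1])^2 + (ends[, 2] - ctr[2])^2))
}

# linear time-resampling of a series to n points
.resample_series <- function(x, n) {
  if (length(x) == n) return(x)
  stats::approx(seq(0, 1, length.out = length(x)), x,
                xout = seq(0, 1, length.out = n))$y
}

#' Orbit correlation coefficient
#'
#' Trajectory-stability index: the mean Pearson correlation between the
#' parallel-displacement time series of all pairs of trials. Trials of
#' unequal length are linearly time-resampled to the longest trial's length
#' first. The double sum over ordered pairs equals the unordered-pair mean
#' because Pearson correlation is symmetric. Pairs involving a
#' zero-variance series are excluded with a warning.
#'
#' @param trials List of `M >= 2` [trial_trajectory()] objects.
#' @return `r_orbit` in `[-1, 1]`.
#' @export
orbit_correlation <- function(trials) {
  M <- length(trials)
  if (M < 2) stop("at least 2 trials are required", call. = FALSE)
  pars <- lapply(trials, function(tr) decompose(tr)$par)
  n <- max(lengths(pars))
  pars <- lapply(pars, .resample_series, n = n)
  vars <- vapply(pars, stats::var, 1)
  rs <- c()
  dropped <- 0L
  for (i in seq_len(M - 1)) {
    for (j in (i + 1):M) {
      if (vars[i] == 0 || vars[j] == 0) {
        dropped <- dropped + 1L
        next
      }
      rs <- c(rs, stats::cor(pars[[i]], pars[[j]]))
    }
  }
  if (dropped > 0) {
    warning(dropped, " pair(s) excluded for zero variance", call. = FALSE)
  }
  if (length(rs) == 0) {
    stop("all trial pairs excluded (zero-variance series)", call. = FALSE)
  }
  mean(rs)
}

# third derivative by the 7-point central stencil (exact through degree 6
# in the interior), with odd-reflection padding at the ends
.third_derivative <- function(f, h) {
  n <- length(f)
  if (n < 7) stop("too-short trajectory: need >= 7 samples", call. = FALSE)
  pad_l <- 2 * f[1] - f[4:2]
  pad_r <- 2 * f[n] - f[(n - 1):(n - 3)]
  g <- c(pad_l, f, pad_r)
  i <- seq_len(n) + 3L
  (g[i - 3] - 8 * g[i - 2] + 13 * g[i - 1] -
      13 * g[i + 1] + 8 * g[i + 2] - g[i + 3]) / (8 * h^3)
}

# first derivative by central differences, one-sided at the ends
.first_derivative <- function(f, h) {
  n <- length(f)
  if (n < 3) stop("too-short trajectory", call. = FALSE)
  d <- numeric(n)
  d[2:(n - 1)] <- (f[3:n] - f[1:(n - 2)]) / (2 * h)
  d[1] <- (-3 * f[1] + 4 * f[2] - f[3]) / (2 * h)
  d[n] <- (3 * f[n] - 4 * f[n - 1] + f[n - 2]) / (2 * h)
  d
}

#' Jerk cost
#'
#' Smoothness index `(1/2) integral (d^3 P_par / dt^3)^2 dt` over the
#' supplied window: half the integrated squared third derivative of the
#' parallel displacement. Lower is smoother; a minimum-jerk movement of
#' amplitude `A` and duration `T` has the closed-form cost
#' `360 A^2 / T^5`. The third derivative uses 7-point central differences
#' with odd-reflection padding; integration is trapezoidal. An optional
#' low-pass pre-smoothing (for noisy measured data) is available and off by
#' default so analytic trajectories are untouched.
#'
#' @param decomp A [decompose()]d trial.
#' @param smooth_fc Optional low-pass cutoff (Hz) applied to `P_par` before
#'   differentiation; `NULL` (default) disables it.
#' @return Jerk cost in deg^2 s^-5.
#' @export
jerk_cost <- function(decomp, smooth_fc = NULL) {
  stopifnot(inherits(decomp, "decomposed_trial"))
  f <- decomp$par
  h <- 1 / decomp$fs
  if (!is.null(smooth_fc)) {
    bf <- signal::butter(2, smooth_fc / (decomp$fs / 2), type = "low")
    f <- as.numeric(signal::filtfilt(bf, f))
  }
  j3 <- .third_derivative(f, h)
  # trapezoidal quadrature
  0.5 * sum((j3[-1]^2 + j3[-length(j3)]^2) / 2) * h
}

#' Normalized mean velocity
#'
#' Smoothness index `mean(v_par) / max(v_par)` over the supplied window,
#' where `v_par` is the parallel velocity by central differences. Equals 1
#' for constant-velocity motion and `8/15` for a minimum-jerk profile;
#' higher is smoother (less peaked velocity).
#'
#' @param decomp A [decompose()]d trial.
#' @return `v_norm` in `(0, 1]`.
#' @export
normalized_mean_velocity <- function(decomp) {
  stopifnot(inherits(decomp, "decomposed_trial"))
  v <- .first_derivative(decomp$par, 1 / decomp$fs)
  pk <- max(v)
  if (pk <= 0) stop("zero peak velocity", call. = FALSE)
  mean(v) / pk
}

#' Reaching time
#'
#' Duration from movement onset to arrival. Onset is the first sample where
#' the parallel velocity exceeds `onset_frac` of its peak; arrival is the
#' first sample from which the 2-DOF position stays within
#' `arrival_radius` of the movement endpoint for at least `dwell_ms`.
#'
#' @param trial A [trial_trajectory()].
#' @param onset_frac Onset threshold as a fraction of peak parallel
#'   velocity.
#' @param arrival_radius Arrival radius around the endpoint, degrees.
#' @param dwell_ms Dwell time required inside the arrival radius, ms.
#' @return Reaching time in s.
#' @export
reaching_time <- function(trial, onset_frac = 0.05, arrival_radius = 2,
                          dwell_ms = 100) {
  stopifnot(inherits(trial, "trial"))
  dc <- decompose(trial)
  v <- .first_derivative(dc$par, 1 / dc$fs)
  pk <- max(v)
  if (pk <= 0) stop("onset never detected: no forward movement", call. = FALSE)
  onset_i <- which(v > onset_frac * pk)[1]
  if (is.na(onset_i)) stop("onset never detected", call. = FALSE)
  endp <- trial$p[nrow(trial$p), ]
  dist_end <- sqrt(rowSums(sweep(trial$p, 2, endp, `-`)^2))
  inside <- dist_end <= arrival_radius
  dwell_n <- max(1L, as.integer(round(dwell_ms / 1000 * dc$fs)))
  n <- length(inside)
  # arrival = start of the first inside-run of length >= dwell_n, or of a
  # final run reaching the end of the record (dwell truncated by recording)
  arrival_i <- NA_integer_
  run <- 0L
  for (i in seq_len(n)) {
    run <- if (inside[i]) run + 1L else 0L
    if (run >= dwell_n) { arrival_i <- i - run + 1L; break }
  }
  if (is.na(arrival_i)) {
    if (inside[n]) arrival_i <- n - run + 1L
    else stop("arrival never detected", call. = FALSE)
  }
  trial$t[arrival_i] - trial$t[onset_i]
}

#' Full metric report for a set of trials
#'
#' Computes the six evaluation indices plus reaching time for a set of
#' trials sharing a task: per-trial endpoint error, maximum lateral
#' deviation, jerk cost, normalized mean velocity and reaching time, and
#' the set-level endpoint spread and orbit correlation. Per-trial jerk cost
#' and normalized mean velocity are evaluated over the onset-to-arrival
#' movement window by default (`window = "movement"`); `window = "full"`
#' uses the whole recording.
#'
#' @param trials List of [trial_trajectory()] objects.
#' @param window `"movement"` or `"full"`.
#' @param smooth_fc Optional pre-smoothing cutoff for [jerk_cost()].
#' @param onset_frac,arrival_radius,dwell_ms Passed to [reaching_time()].
#' @return Object of class `"metric_report"`: list with `per_trial` (data
#'   frame `e, e_perp_max, jc, v_norm, reaching_time`) and `set` (list
#'   `s, r_orbit`, `NA` when `M < 2`).
#' @export
metric_report <- function(trials, window = c("movement", "full"),
                          smooth_fc = NULL, onset_frac = 0.05,
                          arrival_radius = 2, dwell_ms = 100) {
  window <- match.arg(window)
  if (inherits(trials, "trial")) trials <- list(trials)
  per <- lapply(trials, function(tr) {
    dc <- decompose(tr)
    rt <- tryCatch(reaching_time(tr, onset_frac, arrival_radius, dwell_ms),
                   error = function(e) NA_real_)
    dcw <- dc
    if (window == "movement" && !is.na(rt)) {
      v <- .first_derivative(dc$par, 1 / dc$fs)
      onset_i <- which(v > onset_frac * max(v))[1]
      arrival_i <- onset_i + as.integer(round(rt * dc$fs))
      arrival_i <- min(arrival_i, length(dc$par))
      if (arrival_i - onset_i + 1L >= 7L) {
        dcw <- structure(list(t = dc$t[onset_i:arrival_i],
                              par = dc$par[onset_i:arrival_i],
                              perp = dc$perp[onset_i:arrival_i],
                              fs = dc$fs, path_length = dc$path_length),
                         class = "decomposed_trial")
      }
    }
    data.frame(
      e = endpoint_error(tr),
      e_perp_max = max_lateral_deviation(dc),
      jc = jerk_cost(dcw, smooth_fc = smooth_fc),
      v_norm = tryCatch(normalized_mean_velocity(dcw),
                        error = function(e) NA_real_),
      reaching_time = rt)
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  set <- list(s = NA_real_, r_orbit = NA_real_)
  if (length(trials) >= 2) {
    set$s <- endpoint_sd(trials)
    set$r_orbit <- orbit_correlation(trials)
  }
  structure(list(per_trial = per, set = set, n_trials = length(trials),
                 window = window),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("Pointing metric report (%d trial(s), %s window)\n",
              x$n_trials, x$window))
  cat("Per-trial means:\n")
  m <- colMeans(x$per_trial, na.rm = TRUE)
  cat(sprintf("  endpoint error e        = %.3f deg\n", m["e"]))
  cat(sprintf("  max lateral dev e_perp  = %.3f deg\n", m["e_perp_max"]))
  cat(sprintf("  jerk cost jc            = %.3f deg^2 s^-5\n", m["jc"]))
  cat(sprintf("  normalized mean vel     = %.3f\n", m["v_norm"]))
  cat(sprintf("  reaching time           = %.3f s\n", m["reaching_time"]))
  if (x$n_trials >= 2) {
    cat(sprintf("Set-level: endpoint spread s = %.3f deg, orbit correlation r = %.3f\n",
                x$set$s, x$set$r_orbit))
  }
  invisible(x)
}
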