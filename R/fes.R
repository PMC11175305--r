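#' Sigmoid current-joint-angle model: forward map
#'
#' Steady-state joint angle produced by a stimulation current `I` under the
#' logistic model `theta = d / (1 + exp(b (c - I)))`, where `b` (1/mA)
#' controls the rapidity of the rise, `c` (mA) is the half-maximum current,
#' and `d` (degrees) the saturation angle. Strictly increasing in `I` for
#' `b > 0`.
#'
#' @param current Stimulation current(s), mA.
#' @param params List or `"fes_model"` with elements `b`, `c`, `d`.
#' @return Joint angle(s) in degrees.
#' @export
fes_angle <- function(current, params) {
  p <- .fes_params(params)
  p$d / (1 + exp(p$b * (p$c - current)))
}

#' Sigmoid current-joint-angle model: inverse map
#'
#' Current required for a target steady-state angle:
#' `I = c - (1/b) log(d / theta - 1)`. The logarithm diverges at 0 and `d`,
#' so angles are clipped into `[eps d, (1 - eps) d]` (with a warning) before
#' inversion; set `clip = FALSE` to raise a domain error instead.
#'
#' @param angle Target angle(s), degrees.
#' @param params List or `"fes_model"` with `b`, `c`, `d`.
#' @param eps Relative clipping margin near 0 and `d`.
#' @param clip Clip out-of-domain angles (default) or error.
#' @return Current(s) in mA.
#' @export
fes_current <- function(angle, params, eps = 1e-3, clip = TRUE) {
  p <- .fes_params(params)
  lo <- eps * p$d; hi <- (1 - eps) * p$d
  out_of_domain <- angle < lo | angle > hi
  if (any(out_of_domain)) {
    if (!clip) stop("angle outside (0, d): inverse undefined", call. = FALSE)
    warning(sprintf("%d angle(s) clipped into [%.3g, %.3g] before inversion",
                    sum(out_of_domain), lo, hi), call. = FALSE)
    angle <- pmin(pmax(angle, lo), hi)
  }
  p$c - (1 / p$b) * log(p$d / angle - 1)
}

.fes_params <- function(params) {
  if (inherits(params, "fes_model")) params <- params$params
  stopifnot(is.numeric(params$b), is.numeric(params$c), is.numeric(params$d))
  if (params$b <= 0 || params$d <= 0) {
    stop("invalid FES parameters: need b > 0 and d > 0", call. = FALSE)
  }
  params
}

#' Fit the sigmoid current-angle model to a calibration curve
#'
#' Nonlinear least squares of `theta = d / (1 + exp(b (c - I)))` to measured
#' (current, steady-state angle) pairs from a stepwise current-increase
#' calibration. Fitting uses Levenberg-Marquardt ([minpack.lm::nlsLM]) with
#' data-driven starting values: `d0 = 1.05 * max(angle)`, `c0` at the
#' current reaching half of the maximum angle, and `b0` from the local slope
#' there; `b` and `d` are bounded below at small positive values.
#'
#' @param current Calibration currents, mA, strictly increasing, >= 4 points.
#' @param angle Steady-state angles, degrees.
#' @param muscle Optional label for the calibrated muscle/direction.
#' @return Object of class `"fes_model"`: list with `params` (`b`, `c`,
#'   `d`), `residual_norm`, `fitted`, `data`, `muscle`, and the underlying
#'   `nls` fit. Methods: `coef`, `predict`, `print`.
#' @export
fes_fit <- function(current, angle, muscle = NA_character_) {
  if (length(current) != length(angle)) {
    stop("current and angle must have equal length", call. = FALSE)
  }
  if (length(current) < 4) {
    stop("at least 4 calibration points are required", call. = FALSE)
  }
  if (any(diff(current) <= 0)) {
    stop("calibration currents must be strictly increasing", call. = FALSE)
  }
  if (diff(range(angle)) < 1e-9) {
    stop("fit failure: flat calibration curve (d unidentifiable)",
         call. = FALSE)
  }
  d0 <- 1.05 * max(angle)
  half <- d0 / 2
  i_half <- which.min(abs(angle - half))
  c0 <- current[i_half]
  # logistic slope at c is b*d/4; estimate slope locally around c0
  lo <- max(1, i_half - 1); hi <- min(length(current), i_half + 1)
  slope <- (angle[hi] - angle[lo]) / (current[hi] - current[lo])
  b0 <- max(4 * abs(slope) / d0, 1e-3)
  dat <- data.frame(I = current, theta = angle)
  fit <- tryCatch(
    minpack.lm::nlsLM(theta ~ d / (1 + exp(b * (cc - I))), data = dat,
                      start = list(b = b0, cc = c0, d = d0),
                      lower = c(b = 1e-6, cc = -Inf, d = 1e-6),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) stop("fit failure: ", conditionMessage(e),
                             call. = FALSE)
  )
  cf <- stats::coef(fit)
  params <- list(b = unname(cf["b"]), c = unname(cf["cc"]),
                 d = unname(cf["d"]))
  res <- stats::resid(fit)
  structure(
    list(params = params, residual_norm = sqrt(sum(res^2)),
         fitted = stats::fitted(fit), data = dat, muscle = muscle,
         fit = fit),
    class = "fes_model"
  )
}

#' @export
print.fes_model <- function(x, ...) {
  cat("FES current-joint angle model: theta = d / (1 + exp(b (c - I)))\n")
  if (!is.na(x$muscle)) cat("  muscle:", x$muscle, "\n")
  cat(sprintf("  b = %.4g /mA, c = %.4g mA, d = %.4g deg\n",
              x$params$b, x$params$c, x$params$d))
  cat(sprintf("  calibration: %d points, residual norm %.4g deg\n",
              nrow(x$data), x$residual_norm))
  invisible(x)
}

#' @export
coef.fes_model <- function(object, ...) {
  c(b = object$params$b, c = object$params$c, d = object$params$d)
}

#' @export
predict.fes_model <- function(object, newdata = NULL, ...) {
  current <- if (is.null(newdata)) object$data$I else
    if (is.list(newdata)) newdata$I else newdata
  fes_angle(current, object)
}

#' Open-loop stimulation command series for a trajectory
#'
#' Converts a commanded 2-DOF trajectory into per-sample stimulation
#' commands: at each sample the active muscle is chosen from the current
#' movement direction (the axis and sign of the displacement from the
#' start), the direction-aligned angle magnitude is inverted through that
#' muscle's calibrated model, and the resulting current is emitted open loop
#' (no feedback on the realized angle). Only the steady-state current-angle
#' map is used; stimulation dynamics are not modelled.
#'
#' @param traj A `"trajectory"`.
#' @param params_by_muscle Named list of `"fes_model"` objects (or `b,c,d`
#'   lists), one per muscle label.
#' @param direction_map Named list mapping direction labels `"x+"`, `"x-"`,
#'   `"y+"`, `"y-"` to muscle labels present in `params_by_muscle`.
#' @param pulse Pulse settings, default [fes_pulse_defaults()].
#' @param eps Clipping margin passed to [fes_current()].
#' @return Data frame `time, muscle, angle_deg, current_mA,
#'   pulse_frequency, pulse_width_ms`.
#' @export
stimulation_series <- function(traj, params_by_muscle, direction_map,
                               pulse = fes_pulse_defaults(), eps = 1e-3) {
  p0 <- traj$p[1, ]
  disp <- sweep(traj$p, 2, p0, `-`)
  n <- nrow(disp)
  axis <- ifelse(abs(disp[, 1]) >= abs(disp[, 2]), 1L, 2L)
  sgn <- ifelse(axis == 1L, sign(disp[, 1]), sign(disp[, 2]))
  # samples with (near-)zero displacement take the movement's overall
  # direction rather than an arbitrary axis
  overall <- disp[n, ]
  ax_all <- if (abs(overall[1]) >= abs(overall[2])) 1L else 2L
  sg_all <- if (sign(overall[ax_all]) < 0) -1 else 1
  still <- rowSums(abs(disp)) < 1e-12
  axis[still] <- ax_all
  sgn[still] <- sg_all
  sgn[sgn == 0] <- sg_all
  dir_label <- paste0(c("x", "y")[axis], ifelse(sgn > 0, "+", "-"))
  missing_dir <- setdiff(unique(dir_label), names(direction_map))
  if (length(missing_dir) > 0) {
    stop("unknown direction(s): ", paste(missing_dir, collapse = ", "),
         call. = FALSE)
  }
  muscle <- unlist(direction_map[dir_label], use.names = FALSE)
  magnitude <- abs(disp[cbind(seq_len(n), axis)])
  current <- numeric(n)
  clipped <- FALSE
  for (mu in unique(muscle)) {
    sel <- muscle == mu
    current[sel] <- withCallingHandlers(
      fes_current(magnitude[sel], params_by_muscle[[mu]], eps = eps),
      warning = function(w) {
        clipped <<- TRUE
        invokeRestart("muffleWarning")
      })
  }
  out <- data.frame(time = traj$t, muscle = muscle,
                    angle_deg = magnitude, current_mA = current,
                    pulse_frequency = pulse$pulse_frequency,
                    pulse_width_ms = pulse$pulse_width_ms)
  attr(out, "clipped") <- clipped
  if (clipped) {
    warning("some commanded angles were clipped to the invertible range",
            call. = FALSE)
  }
  out
}
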