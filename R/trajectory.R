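#' Minimum-jerk reference trajectory
#'
#' Generates the quintic minimum-jerk trajectory between two 2-DOF joint
#' configurations: `P(tau) = P0 + (PT - P0) (6 tau^5 - 15 tau^4 + 10 tau^3)`
#' with `tau = t / T`. This profile minimizes the integrated squared jerk
#' (third time derivative of position) among all trajectories with zero
#' boundary velocity and acceleration, and is the standard normative model
#' of smooth human reaching. Its closed-form jerk cost is
#' `(1/2) * 720 * A^2 / T^5 = 360 A^2 / T^5` per axis of amplitude `A`.
#'
#' @param p0 Start configuration, numeric 2-vector (degrees).
#' @param pt Target configuration, numeric 2-vector (degrees).
#' @param duration Movement duration `T` in s (> 0).
#' @param fs_out Output sampling frequency in Hz.
#' @param limit Per-axis magnitude limit in degrees; specs exceeding it
#'   raise a validation error (mirrors the +/-45 degree actuator range).
#' @return Object of class `"trajectory"`: list with `t` (s) and `p`
#'   (n x 2 matrix, degrees), endpoints included.
#' @export
minimum_jerk <- function(p0, pt, duration, fs_out = 1000, limit = 45) {
  if (duration <= 0) stop("invalid spec: duration must be > 0", call. = FALSE)
  p0 <- as.numeric(p0); pt <- as.numeric(pt)
  stopifnot(length(p0) == 2, length(pt) == 2)
  if (any(abs(c(p0, pt)) > limit)) {
    stop(sprintf("trajectory endpoint outside +/-%g degree range", limit),
         call. = FALSE)
  }
  t <- seq(0, duration, by = 1 / fs_out)
  if (t[length(t)] < duration) t <- c(t, duration)
  tau <- t / duration
  s <- 6 * tau^5 - 15 * tau^4 + 10 * tau^3
  p <- cbind(p0[1] + (pt[1] - p0[1]) * s,
             p0[2] + (pt[2] - p0[2]) * s)
  structure(list(t = t, p = p), class = "trajectory")
}

#' Endpoint velocity and acceleration of a sampled trajectory
#'
#' Numerical first and second derivatives at both ends (one-sided
#' second-order differences). For a minimum-jerk trajectory both vanish as
#' the sampling rate grows, since the analytic boundary derivatives are
#' exactly zero.
#'
#' @param traj A `"trajectory"`.
#' @return List with `velocity` and `acceleration`, each a 2 x 2 matrix
#'   (rows = start/end, columns = axes), units deg/s and deg/s^2.
#' @export
boundary_derivatives <- function(traj) {
  t <- traj$t; p <- traj$p
  n <- length(t)
  if (n < 4) stop("trajectory too short", call. = FALSE)
  h <- t[2] - t[1]
  d1 <- function(f) c((-3 * f[1] + 4 * f[2] - f[3]) / (2 * h),
                      (3 * f[n] - 4 * f[n - 1] + f[n - 2]) / (2 * h))
  d2 <- function(f) c((2 * f[1] - 5 * f[2] + 4 * f[3] - f[4]) / h^2,
                      (2 * f[n] - 5 * f[n - 1] + 4 * f[n - 2] - f[n - 3]) / h^2)
  list(velocity = rbind(start = c(d1(p[, 1])[1], d1(p[, 2])[1]),
                        end = c(d1(p[, 1])[2], d1(p[, 2])[2])),
       acceleration = rbind(start = c(d2(p[, 1])[1], d2(p[, 2])[1]),
                            end = c(d2(p[, 1])[2], d2(p[, 2])[2])))
}

#' Instruction-mode trajectory for a decision event
#'
#' Looks up the decided class's target and generates the minimum-jerk
#' instruction trajectory from the current position, of duration
#' `t_instruct`.
#'
#' @param class_id Decided motion class.
#' @param schedule A [mode_schedule()].
#' @param current Current 2-DOF position (degrees); instruction starts here.
#' @param fs_out Output sampling frequency in Hz.
#' @return A `"trajectory"` ending at the class target.
#' @export
instruct <- function(class_id, schedule, current = c(0, 0), fs_out = 1000) {
  stopifnot(inherits(schedule, "mode_schedule"))
  key <- as.character(class_id)
  if (!key %in% names(schedule$target_map)) {
    stop("unknown class: no target mapped for class ", class_id,
         call. = FALSE)
  }
  minimum_jerk(current, schedule$target_map[[key]], schedule$t_instruct,
               fs_out = fs_out)
}

#' Write / read trajectory CSV
#'
#' Columns `time, angle_x, angle_y` in s and degrees; X is
#' flexion--extension (flexion positive), Y radial--ulnar deviation (radial
#' positive).
#'
#' @param traj A `"trajectory"` (or anything with `t` and 2-column `p`).
#' @param path File path.
#' @return `path` (write) or a `"trajectory"` (read).
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(
    data.frame(time = traj$t, angle_x = traj$p[, 1], angle_y = traj$p[, 2]),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  d <- utils::read.csv(path)
  structure(list(t = d$time, p = cbind(d$angle_x, d$angle_y)),
            class = "trajectory")
}
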