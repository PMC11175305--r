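#' Read a multichannel EMG CSV
#'
#' Expects a header row and columns `time, ch1..chL` (time in s, amplitudes
#' in arbitrary units).
#'
#' @param path CSV file path.
#' @return An [emg_record()].
#' @export
read_emg_csv <- function(path) {
  d <- utils::read.csv(path)
  if (names(d)[1] != "time") {
    stop("first column must be 'time'", call. = FALSE)
  }
  emg_record(d$time, as.matrix(d[, -1, drop = FALSE]))
}

#' Write an EMG record to CSV
#'
#' @param record An [emg_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_emg_csv <- function(record, path) {
  sig <- record$signals
  colnames(sig) <- paste0("ch", seq_len(ncol(sig)))
  utils::write.csv(data.frame(time = record$t, sig), path, row.names = FALSE)
  invisible(path)
}

#' Write a gated feature sequence to CSV
#'
#' Columns `time, x1..xL, F, gate`.
#'
#' @param features A `"feature_sequence"` from [emg_features()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_csv <- function(features, path) {
  x <- features$x
  colnames(x) <- paste0("x", seq_len(ncol(x)))
  utils::write.csv(
    data.frame(time = features$t, x, F = features$activation,
               gate = features$gate),
    path, row.names = FALSE)
  invisible(path)
}

#' Write / read an EMG calibration (rest baselines and maxima) as JSON
#'
#' @param calibration Output of [emg_calibrate()].
#' @param path JSON path.
#' @return `path` (write) / calibration list (read).
#' @export
write_calibration_json <- function(calibration, path) {
  per_ch <- lapply(seq_along(calibration$rest_baseline), function(l) {
    list(rest = calibration$rest_baseline[l],
         max = calibration$max_level[l])
  })
  names(per_ch) <- paste0("ch", seq_along(per_ch))
  jsonlite::write_json(per_ch, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(rest_baseline = vapply(obj, `[[`, 1, "rest"),
       max_level = vapply(obj, `[[`, 1, "max"))
}

#' Read an FES calibration CSV (`current_mA, angle_deg`)
#'
#' @param path CSV path.
#' @return Data frame with `current_mA` and `angle_deg`.
#' @export
read_fes_calibration_csv <- function(path) {
  d <- utils::read.csv(path)
  stopifnot(all(c("current_mA", "angle_deg") %in% names(d)))
  d
}

#' Write fitted FES parameters per muscle as JSON
#'
#' @param models Named list of `"fes_model"` objects.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_fes_params_json <- function(models, path) {
  obj <- lapply(models, function(m) {
    c(m$params, list(residual = m$residual_norm))
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
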