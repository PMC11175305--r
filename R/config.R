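#' Signal-processing configuration
#'
#' Bundles the sampling and filtering parameters used throughout EMG
#' preprocessing. Defaults follow the standard montage for 2-DOF wrist
#' pointing: four bipolar channels sampled at 1000 Hz, a 1--250 Hz
#' second-order Butterworth bandpass, and a 1 Hz second-order low-pass for
#' envelope smoothing.
#'
#' @param fs Sampling frequency in Hz.
#' @param fc_low Bandpass low cutoff in Hz.
#' @param fc_high Bandpass high cutoff in Hz (must be below `fs/2`).
#' @param fc_smooth Low-pass smoothing cutoff in Hz for the envelope.
#' @param n_channels Number of EMG channels `L` (>= 2).
#' @param gate_threshold Activation-level threshold driving the system gate.
#' @param debounce_ms Time in ms the activation level must stay above
#'   threshold before the gate opens.
#' @return An object of class `"signal_config"` (a named list).
#' @export
signal_config <- function(fs = 1000, fc_low = 1, fc_high = 250,
                          fc_smooth = 1, n_channels = 4,
                          gate_threshold = 0.2, debounce_ms = 50) {
  if (fs <= 2 * fc_high) {
    stop("invalid config: fs must exceed 2 * fc_high (Nyquist)", call. = FALSE)
  }
  if (!(fc_low > 0 && fc_low < fc_high)) {
    stop("invalid config: need 0 < fc_low < fc_high", call. = FALSE)
  }
  if (fc_smooth <= 0) stop("invalid config: fc_smooth must be > 0", call. = FALSE)
  if (n_channels < 2) stop("invalid config: n_channels must be >= 2", call. = FALSE)
  structure(
    list(fs = fs, fc_low = fc_low, fc_high = fc_high, fc_smooth = fc_smooth,
         n_channels = n_channels, gate_threshold = gate_threshold,
         debounce_ms = debounce_ms),
    class = "signal_config"
  )
}

#' Recurrent network architecture configuration
#'
#' Architecture of the recurrent log-linearized Gaussian-mixture network
#' (R-LLGMN): `C` motion classes, `K` hidden states per class, `M` Gaussian
#' components per state, decisions made on windows of `seq_len` feature
#' samples of dimension `input_dim`. The expanded (quadratic) input dimension
#' is `H = 1 + L * (L + 3) / 2`.
#'
#' @param n_classes Number of motion classes `C`.
#' @param n_states Hidden states per class `K`.
#' @param n_components Gaussian components per state `M`.
#' @param seq_len Samples per decision window.
#' @param input_dim Feature dimension `L` (number of EMG channels).
#' @return An object of class `"network_config"`.
#' @export
network_config <- function(n_classes = 4, n_states = 2, n_components = 2,
                           seq_len = 50, input_dim = 4) {
  stopifnot(n_classes >= 1, n_states >= 1, n_components >= 1,
            seq_len >= 1, input_dim >= 1)
  L <- input_dim
  structure(
    list(n_classes = n_classes, n_states = n_states,
         n_components = n_components, seq_len = seq_len, input_dim = L,
         expanded_dim = 1L + (L * (L + 3L)) %/% 2L),
    class = "network_config"
  )
}

#' Instruction/training mode schedule
#'
#' Timing of the hybrid system's modes and the map from motion class to
#' 2-DOF target angle. Defaults follow the pointing task: 2 s passive
#' instruction, 3 s voluntary training window, 1 s terminal visual feedback,
#' and 20-degree targets in the four wrist directions (flexion = +X,
#' radial deviation = +Y).
#'
#' @param t_instruct Instruction-mode duration in s.
#' @param t_train Training-mode duration in s.
#' @param t_feedback Feedback duration in s.
#' @param target_map Named list mapping class id (as character) to a length-2
#'   numeric target `(x, y)` in degrees.
#' @param target_amplitude Amplitude used to build the default four-direction
#'   target map, degrees.
#' @return An object of class `"mode_schedule"`.
#' @export
mode_schedule <- function(t_instruct = 2, t_train = 3, t_feedback = 1,
                          target_map = NULL, target_amplitude = 20) {
  stopifnot(t_instruct > 0, t_train > 0, t_feedback > 0)
  if (is.null(target_map)) {
    a <- target_amplitude
    target_map <- list(`1` = c(a, 0),   # flexion
                       `2` = c(0, a),   # radial deviation
                       `3` = c(-a, 0),  # extension
                       `4` = c(0, -a))  # ulnar deviation
  }
  ok <- vapply(target_map, function(p) is.numeric(p) && length(p) == 2, TRUE)
  if (!all(ok)) stop("every target must be a numeric 2-vector", call. = FALSE)
  structure(
    list(t_instruct = t_instruct, t_train = t_train, t_feedback = t_feedback,
         target_map = target_map),
    class = "mode_schedule"
  )
}

#' Default stimulation pulse settings
#'
#' Fixed FES pulse parameters: 50 Hz pulse frequency and 0.2 ms pulse width.
#'
#' @return Named list with `pulse_frequency` (Hz) and `pulse_width_ms` (ms).
#' @export
fes_pulse_defaults <- function() {
  list(pulse_frequency = 50, pulse_width_ms = 0.2)
}
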