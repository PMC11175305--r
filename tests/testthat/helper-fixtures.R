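# Shared fixtures built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

# calibrated preprocessing for the default synthetic montage
emg_fixture <- function() {
  fixture("emg", function() {
    cfg <- signal_config()
    spec <- emg_gen_spec()
    cal_rec <- generate_calibration_recordings(spec, seed = 42)
    cal <- emg_calibrate(
      emg_envelope(emg_bandpass(cal_rec$rest, cfg), cfg),
      emg_envelope(emg_bandpass(cal_rec$voluntary, cfg), cfg))
    list(cfg = cfg, spec = spec, cal = cal)
  })
}

# a small trained classifier on two well-separated synthetic classes
small_model_fixture <- function() {
  fixture("small_model", function() {
    set.seed(99)
    ncfg <- network_config(n_classes = 2, n_states = 2, n_components = 2,
                           seq_len = 10, input_dim = 3)
    pat <- rbind(c(0.7, 0.2, 0.1), c(0.1, 0.2, 0.7))
    mk <- function(cls, n = 200) {
      x <- matrix(rep(pat[cls, ], each = n), n, 3) +
        matrix(stats::rnorm(n * 3, 0, 0.02), n, 3)
      x <- pmax(x, 1e-4)
      x / rowSums(x)
    }
    train <- list(mk(1), mk(2))
    model <- rllgmn(train, 1:2, ncfg, seed = 7, stride = 5, maxit = 60)
    list(ncfg = ncfg, pat = pat, mk = mk, model = model)
  })
}

# minimum-jerk reference trial toward the 20-degree flexion target
minjerk_trial_fixture <- function() {
  fixture("minjerk_trial", function() {
    tr <- minimum_jerk(c(0, 0), c(20, 0), 2, fs_out = 1000)
    trial_trajectory(tr$t, tr$p, c(0, 0), c(20, 0))
  })
}
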