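# emghybrid

Simulation and analysis of an EMG-driven hybrid rehabilitation workflow
for 2-DOF wrist pointing.

Upper-limb rehabilitation systems that combine an assistance robot with
functional electrical stimulation (FES) can teach both joint trajectories
and the muscle contractions that produce them. The workflow this package
implements estimates the user's *intended* movement from surface EMG and
only then instructs it: multichannel EMG is reduced to sum-to-one
muscle-coordination vectors

$$x_l(t) = \frac{E'_l(t)}{\sum_l E'_l(t)}, \qquad
E'_l(t) = \frac{E_l(t)-E^{st}_l}{E^{max}_l-E^{st}_l},$$

gated by the mean activation level $F(t)$; a recurrent log-linearized
Gaussian-mixture network (R-LLGMN — a trainable log-linear embedding of a
Gaussian-mixture hidden Markov model) converts 50-sample feature windows
into class posteriors; the decided class triggers a minimum-jerk
instruction trajectory
$P(\tau)=P_0+(P_T-P_0)(6\tau^5-15\tau^4+10\tau^3)$ and open-loop FES
currents from the inverted sigmoid current–angle model
$\theta = d/(1+e^{b(c-I)})$. Motor learning is quantified with a pointing
metric suite: endpoint error $e$, maximum lateral deviation
$e_{\perp,max}$, endpoint spread $s$, orbit correlation $r_{orbit}$, jerk
cost $j_c = \tfrac12\int (\dddot P_\parallel)^2 dt$, normalized mean
velocity $\bar v_{norm}$, and reaching time.

The package is aimed at researchers in biosignal processing and
neurorehabilitation engineering who want a fully seeded, data-free
re-implementation of this pipeline: every input (EMG, pointing trials, FES
calibration curves, whole training studies) is produced by built-in
generators with known ground truth.

## Worked example

Train a per-subject classifier on one 0.5 s synthetic recording per
movement, detect an intent decision from a fresh recording, instruct the
movement, and derive the stimulation command:

```r
library(emghybrid)

cfg  <- signal_config()          # 1000 Hz, 1-250 Hz bandpass, 1 Hz envelope
spec <- emg_gen_spec()           # 4-channel synthetic EMG montage

cal_rec <- generate_calibration_recordings(spec, seed = 42)
cal <- emg_calibrate(
  emg_envelope(emg_bandpass(cal_rec$rest, cfg), cfg),
  emg_envelope(emg_bandpass(cal_rec$voluntary, cfg), cfg))

train_x <- lapply(1:4, function(cc) {
  g <- generate_emg(spec, cc, seed = 100 + cc)   # 500 samples per movement
  emg_features(g$record, cfg, cal)$x
})
model <- rllgmn(train_x, 1:4, network_config(), seed = 1, maxit = 150)
model
#> Recurrent log-linearized Gaussian mixture network (R-LLGMN)
#>   classes C = 4, states K = 2, components M = 2, window T = 50
#>   input dim L = 4 (expanded H = 15), 32 units, 465 weights
#>   trained on 184 windows (stride 10), final NLL 36.34, training accuracy 0.897
#>   optimizer: gd, NOT converged
```

(`NOT converged` records that the run stopped at the 150-iteration cap;
held-out windows are nonetheless classified perfectly on this task.)

```r
g  <- generate_emg(spec, 2, seed = 500, duration = 1.5)  # radial deviation
ft <- emg_features(g$record, cfg, cal)
estimate_motion(ft, model)[, 1:3]
#>    time index class
#> 1 0.372   372     2
```

One decision event fires when the activation gate opens, correctly
identifying class 2 (radial deviation). Instruct it and compute the FES
command at arrival:

```r
traj <- instruct(2, mode_schedule(), fs_out = 1000)  # to (0, 20) in 2 s
fit  <- fes_fit(0:20, fes_angle(0:20, list(b = 0.5, c = 10, d = 40)))
cmd  <- stimulation_series(traj, list(radial_deviator = fit),
                           list(`y+` = "radial_deviator"))
tail(cmd[, 1:4], 1)
#>  time          muscle angle_deg current_mA
#>     2 radial_deviator        20         10
```

At the 20-degree target — half the 40-degree saturation angle — the
commanded current is exactly the half-maximum current `c = 10` mA.
Finally, score a simulated subject's pointing:

```r
sk <- subject_skill()
trials <- lapply(1:3, function(i) generate_trial(sk, c(0, 0), c(0, 20),
                                                 seed = i))
metric_report(trials)
#> Pointing metric report (3 trial(s), movement window)
#> Per-trial means:
#>   endpoint error e        = 1.122 deg
#>   max lateral dev e_perp  = 5.229 deg
#>   jerk cost jc            = 1897833179.568 deg^2 s^-5
#>   normalized mean vel     = 0.241
#>   reaching time           = 2.333 s
#> Set-level: endpoint spread s = 0.517 deg, orbit correlation r = 0.999
```

The large jerk cost is tremor-dominated (a 9 Hz tremor contributes of
order $(2\pi\cdot 9)^6$ to the squared third derivative); it falls as the
simulated subject's tremor decays with training. `run_experiment()`
simulates a full two-arm training study and `group_stats()` /
`report_render()` produce the comparison tables and figures; see the
methods vignette (`vignettes/emghybrid-methods.Rmd`) for the models,
assumptions and numerical choices.

A thin command-line front end is provided at
`inst/scripts/emghybrid-cli.R` (`make-fixtures`, `train-classifier`,
`fit-fes`, `metrics`, `simulate`).

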