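#' In-silico motor-learning experiment configuration
#'
#' Defines the simulated study: two arms (hybrid instruction vs. visual
#' feedback), each with its own subject-skill template and learning-rate
#' profile; pre-evaluation, alternating training/sequential-evaluation
#' sessions, post-evaluation, and an optional retention evaluation.
#' Evaluation trials are always generated from the subject's own skill
#' (no instruction or feedback); hybrid-arm *training* trials are the
#' instruction trajectory plus plant noise.
#'
#' @param n_subjects Subjects per group.
#' @param n_pre Pre-evaluation repetitions.
#' @param n_sessions Training sessions (each followed by one sequential
#'   evaluation).
#' @param n_post Post-evaluation repetitions.
#' @param retention Simulate a retention evaluation (`n_pre` repetitions).
#' @param directions Number of movement directions (classes).
#' @param target_amplitude Target angle amplitude, degrees.
#' @param schedule A [mode_schedule()].
#' @param skill_hybrid,skill_visual [subject_skill()] templates per arm.
#'   Defaults: identical starting skill; the hybrid arm's duration converges
#'   to `t_instruct` (it learns the instructed trajectory) while the visual
#'   arm keeps its own pace; the visual arm learns endpoint accuracy
#'   slightly faster early on but retains less.
#' @param retention_factor Named numeric: multiplier on the error-like skill
#'   parameters at retention (>= 1 models forgetting), per group.
#' @param plant_noise_sd SD of actuator/plant noise added to hybrid
#'   training trajectories, degrees.
#' @param seed Base seed; per-subject seeds are derived deterministically.
#' @return Object of class `"experiment_config"`.
#' @export
experiment_config <- function(n_subjects = 6, n_pre = 3, n_sessions = 20,
                              n_post = 3, retention = TRUE, directions = 4,
                              target_amplitude = 20,
                              schedule = mode_schedule(
                                target_amplitude = target_amplitude),
                              skill_hybrid = NULL, skill_visual = NULL,
                              retention_factor = c(hybrid = 1.0,
                                                   visual_feedback = 1.25),
                              plant_noise_sd = 0.3, seed = 1L) {
  stopifnot(n_subjects >= 1, n_pre >= 1, n_sessions >= 0, n_post >= 1,
            directions >= 1, target_amplitude > 0)
  if (length(schedule$target_map) < directions) {
    stop("schedule target_map must cover every direction", call. = FALSE)
  }
  if (is.null(skill_hybrid)) {
    skill_hybrid <- subject_skill(duration_target = schedule$t_instruct,
                                  decay = list(bias = 0.90, noise = 0.90,
                                               curvature = 0.92,
                                               tremor = 0.95,
                                               duration = 0.85))
  }
  if (is.null(skill_visual)) {
    skill_visual <- subject_skill(duration_target = 2.8,
                                  decay = list(bias = 0.86, noise = 0.93,
                                               curvature = 0.92,
                                               tremor = 0.95,
                                               duration = 1.0))
  }
  structure(
    list(n_subjects = n_subjects, n_pre = n_pre, n_sessions = n_sessions,
         n_post = n_post, retention = retention, directions = directions,
         target_amplitude = target_amplitude, schedule = schedule,
         skills = list(hybrid = skill_hybrid,
                       visual_feedback = skill_visual),
         retention_factor = retention_factor,
         plant_noise_sd = plant_noise_sd, seed = as.integer(seed)),
    class = "experiment_config"
  )
}

.eval_block <- function(skill, cfg, n_reps, seed0) {
  # one evaluation block: n_reps trials in each direction, no feedback
  out <- list()
  for (rep_i in seq_len(n_reps)) {
    for (dir_i in seq_len(cfg$directions)) {
      target <- cfg$schedule$target_map[[as.character(dir_i)]]
      tr <- generate_trial(skill, c(0, 0), target,
                           seed = seed0 + rep_i * 101L + dir_i)
      out[[length(out) + 1L]] <- list(rep = rep_i, direction = dir_i,
                                      trial = tr)
    }
  }
  out
}

.trial_metrics <- function(tr) {
  dc <- decompose(tr)
  rep_ <- metric_report(list(tr), window = "movement")
  rep_$per_trial
}

#' Run the simulated motor-learning experiment
#'
#' Simulates every subject in both arms through the experiment flow:
#' pre-evaluation, alternating training and sequential evaluation,
#' post-evaluation, and retention. Returns per-trial metrics, per-stage
#' set-level metrics (endpoint spread, orbit correlation), and per-subject
#' improvement ratios (post vs. pre, normalized to pre-training:
#' `100 (pre - post) / pre` for indices where lower is better, and
#' `100 (post - pre) / pre` for orbit correlation and normalized mean
#' velocity, where higher is better).
#'
#' @param cfg An [experiment_config()].
#' @return Object of class `"experiment_report"`: list with `per_trial`,
#'   `stage_sets`, `improvement`, `config`.
#' @export
run_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "experiment_config"))
  per_trial <- list()
  stage_sets <- list()
  trials_store <- list()  # (group, subject, phase, direction) -> trials
  add_rows <- function(group, subject, phase, session, block) {
    for (b in block) {
      m <- .trial_metrics(b$trial)
      per_trial[[length(per_trial) + 1L]] <<- cbind(
        data.frame(group = group, subject = subject, phase = phase,
                   session = session, direction = b$direction,
                   rep = b$rep),
        m)
      key <- paste(group, subject, phase, b$direction, sep = "|")
      trials_store[[key]] <<- c(trials_store[[key]], list(b$trial))
    }
  }
  groups <- names(cfg$skills)
  for (gi in seq_along(groups)) {
    group <- groups[gi]
    for (subject in seq_len(cfg$n_subjects)) {
      sseed <- cfg$seed * 10000L + gi * 1000L + subject * 17L
      skill <- cfg$skills[[group]]
      add_rows(group, subject, "pre", NA_integer_,
               .eval_block(skill, cfg, cfg$n_pre, sseed))
      for (ses in seq_len(cfg$n_sessions)) {
        if (group == "hybrid") {
          # training: instruction trajectories + plant noise, all directions
          for (dir_i in seq_len(cfg$directions)) {
            traj <- instruct(dir_i, cfg$schedule, current = c(0, 0),
                             fs_out = skill$fs)
            set.seed(sseed + 500000L + ses * 97L + dir_i)
            noisy <- traj$p + matrix(
              stats::rnorm(length(traj$p), 0, cfg$plant_noise_sd),
              ncol = 2)
            tr <- trial_trajectory(
              traj$t, noisy, c(0, 0),
              cfg$schedule$target_map[[as.character(dir_i)]])
            m <- .trial_metrics(tr)
            per_trial[[length(per_trial) + 1L]] <- cbind(
              data.frame(group = group, subject = subject,
                         phase = "training", session = ses,
                         direction = dir_i, rep = 1L),
              m)
          }
        }
        skill <- evolve_skill(skill, 1)
        add_rows(group, subject, "sequential", ses,
                 .eval_block(skill, cfg, 1L, sseed + ses * 211L))
      }
      add_rows(group, subject, "post", NA_integer_,
               .eval_block(skill, cfg, cfg$n_post, sseed + 777L))
      if (cfg$retention) {
        rskill <- skill
        rf <- cfg$retention_factor[[group]]
        rskill$endpoint_noise_sd <- rskill$endpoint_noise_sd * rf
        rskill$endpoint_bias <- rskill$endpoint_bias * rf
        rskill$curvature <- rskill$curvature * rf
        add_rows(group, subject, "retention", NA_integer_,
                 .eval_block(rskill, cfg, cfg$n_pre, sseed + 888L))
      }
    }
  }
  per_trial <- do.call(rbind, per_trial)
  rownames(per_trial) <- NULL

  # set-level metrics for multi-trial stages
  for (key in names(trials_store)) {
    trials <- trials_store[[key]]
    if (length(trials) < 2) next
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    stage_sets[[length(stage_sets) + 1L]] <- data.frame(
      group = parts[1], subject = as.integer(parts[2]), phase = parts[3],
      direction = as.integer(parts[4]),
      s = endpoint_sd(trials), r_orbit = orbit_correlation(trials))
  }
  stage_sets <- if (length(stage_sets)) do.call(rbind, stage_sets) else
    data.frame(group = character(0), subject = integer(0),
               phase = character(0), direction = integer(0),
               s = numeric(0), r_orbit = numeric(0))
  rownames(stage_sets) <- NULL

  improvement <- .improvement_table(per_trial, stage_sets)
  structure(
    list(per_trial = per_trial, stage_sets = stage_sets,
         improvement = improvement, config = cfg),
    class = "experiment_report"
  )
}

# improvement ratios normalized to pre-training, per subject and index
.improvement_table <- function(per_trial, stage_sets) {
  lower_better <- c("e", "e_perp_max", "jc")
  higher_better <- c("v_norm")
  ev <- per_trial[per_trial$phase %in% c("pre", "post"), ]
  rows <- list()
  for (key in unique(paste(ev$group, ev$subject))) {
    parts <- strsplit(key, " ")[[1]]
    g <- parts[1]; sj <- as.integer(parts[2])
    sub <- ev[ev$group == g & ev$subject == sj, ]
    pre <- sub[sub$phase == "pre", ]
    post <- sub[sub$phase == "post", ]
    vals <- list(group = g, subject = sj)
    for (idx in c(lower_better, higher_better)) {
      p0 <- mean(pre[[idx]], na.rm = TRUE)
      p1 <- mean(post[[idx]], na.rm = TRUE)
      vals[[idx]] <- if (idx %in% lower_better) 100 * (p0 - p1) / p0
        else 100 * (p1 - p0) / p0
    }
    ss <- stage_sets[stage_sets$group == g & stage_sets$subject == sj, ]
    s0 <- mean(ss$s[ss$phase == "pre"]); s1 <- mean(ss$s[ss$phase == "post"])
    r0 <- mean(ss$r_orbit[ss$phase == "pre"])
    r1 <- mean(ss$r_orbit[ss$phase == "post"])
    vals$s <- if (length(s0) && is.finite(s0)) 100 * (s0 - s1) / s0 else NA
    vals$r_orbit <- if (length(r0) && is.finite(r0)) 100 * (r1 - r0) / r0 else NA
    rows[[length(rows) + 1L]] <- as.data.frame(vals)
  }
  out <- do.call(rbind, rows)
  out[, c("group", "subject", "e", "e_perp_max", "s", "r_orbit", "jc",
          "v_norm")]
}

#' @export
print.experiment_report <- function(x, ...) {
  cfg <- x$config
  cat("Simulated motor-learning experiment\n")
  cat(sprintf("  %d subject(s) per group, %d pre / %d sessions / %d post%s\n",
              cfg$n_subjects, cfg$n_pre, cfg$n_sessions, cfg$n_post,
              if (cfg$retention) " + retention" else ""))
  cat(sprintf("  %d evaluation trials recorded\n",
              sum(x$per_trial$phase != "training")))
  cat("Mean improvement ratios (post vs. pre, % of pre):\n")
  agg <- stats::aggregate(
    x$improvement[, c("e", "e_perp_max", "s", "r_orbit", "jc", "v_norm")],
    by = list(group = x$improvement$group), FUN = mean, na.rm = TRUE)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Group statistics for an experiment report
#'
#' Intra-group stage comparisons (pre vs. post, pre vs. retention, post vs.
#' retention when present) per index via paired Wilcoxon signed-rank tests
#' across subjects with Bonferroni adjustment over the stage pairs, and
#' inter-group comparisons of the improvement ratios via Mann-Whitney U
#' (two-sample Wilcoxon) tests. Tests use the asymptotic (normal
#' approximation) p-value with `exact = FALSE` throughout so that ties
#' never change the method; with the small simulated cohorts this is the
#' documented choice, not a claim of optimality.
#'
#' @param report An [run_experiment()] report.
#' @return List with data frames `intra` (group, index, comparison, p,
#'   p_adjusted) and `inter` (index, U statistic, p).
#' @export
group_stats <- function(report) {
  stopifnot(inherits(report, "experiment_report"))
  pt <- report$per_trial
  idx_trial <- c("e", "e_perp_max", "jc", "v_norm")
  phases <- intersect(c("pre", "post", "retention"), unique(pt$phase))
  pairs <- utils::combn(phases, 2, simplify = FALSE)
  intra <- list()
  for (g in unique(pt$group)) {
    if (length(unique(pt$subject[pt$group == g])) < 2) {
      stop("insufficient group size for statistics in group ", g,
           call. = FALSE)
    }
    for (idx in idx_trial) {
      ps <- vapply(pairs, function(pr) {
        subj_mean <- function(ph) {
          sub <- pt[pt$group == g & pt$phase == ph, ]
          a <- stats::aggregate(sub[[idx]],
                                by = list(subject = sub$subject),
                                FUN = mean, na.rm = TRUE)
          a$x[order(a$subject)]
        }
        stats::wilcox.test(subj_mean(pr[1]), subj_mean(pr[2]),
                           paired = TRUE, exact = FALSE)$p.value
      }, 1)
      intra[[length(intra) + 1L]] <- data.frame(
        group = g, index = idx,
        comparison = vapply(pairs, paste, "", collapse = " vs "),
        p = ps, p_adjusted = stats::p.adjust(ps, method = "bonferroni"))
    }
  }
  intra <- do.call(rbind, intra)
  rownames(intra) <- NULL

  imp <- report$improvement
  groups <- unique(imp$group)
  inter <- NULL
  if (length(groups) == 2 &&
      all(table(imp$group) >= 2)) {
    idx_all <- c("e", "e_perp_max", "s", "r_orbit", "jc", "v_norm")
    inter <- do.call(rbind, lapply(idx_all, function(idx) {
      x <- imp[[idx]][imp$group == groups[1]]
      y <- imp[[idx]][imp$group == groups[2]]
      wt <- stats::wilcox.test(x, y, exact = FALSE)
      data.frame(index = idx, U = unname(wt$statistic), p = wt$p.value)
    }))
    rownames(inter) <- NULL
  }
  list(intra = intra, inter = inter)
}

#' Render an experiment report to files
#'
#' Writes CSV tables (per-trial metrics, stage set-level metrics,
#' improvement ratios, group comparisons) and summary figures: reaching
#' time per evaluation stage, sequential endpoint-error learning curves,
#' and a six-panel figure with one panel per evaluation index.
#'
#' @param report An [run_experiment()] report.
#' @param out_dir Output directory (created if needed).
#' @param stats Optional precomputed [group_stats()] result.
#' @return Character vector of written file paths, invisibly.
#' @export
report_render <- function(report, out_dir, stats = NULL) {
  stopifnot(inherits(report, "experiment_report"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory ", out_dir, call. = FALSE)
  }
  files <- c()
  wcsv <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wcsv(report$per_trial, "per_trial_metrics.csv")
  wcsv(report$stage_sets, "stage_set_metrics.csv")
  wcsv(report$improvement, "improvement_ratios.csv")
  if (is.null(stats)) {
    stats <- tryCatch(group_stats(report), error = function(e) NULL)
  }
  if (!is.null(stats)) {
    wcsv(stats$intra, "intra_group_comparisons.csv")
    if (!is.null(stats$inter)) wcsv(stats$inter, "inter_group_comparisons.csv")
  }
  pt <- report$per_trial
  ev <- pt[pt$phase != "training", ]
  if (nrow(ev) > 0) {
    # reaching time per stage
    path <- file.path(out_dir, "reaching_time.png")
    grDevices::png(path, width = 900, height = 500)
    graphics::boxplot(reaching_time ~ interaction(phase, group), data = ev,
                      las = 2, ylab = "reaching time [s]", xlab = "",
                      main = "Reaching time per evaluation stage")
    grDevices::dev.off()
    files <- c(files, path)
    # sequential learning curves
    seqd <- ev[ev$phase == "sequential", ]
    if (nrow(seqd) > 0) {
      path <- file.path(out_dir, "sequential_endpoint_error.png")
      grDevices::png(path, width = 900, height = 500)
      agg <- stats::aggregate(e ~ session + group, data = seqd, FUN = mean)
      graphics::plot(range(agg$session), range(agg$e), type = "n",
                     xlab = "session", ylab = "endpoint error [deg]",
                     main = "Sequential evaluation: endpoint error")
      for (g in unique(agg$group)) {
        sub <- agg[agg$group == g, ]
        graphics::lines(sub$session, sub$e,
                        col = if (g == "hybrid") 2 else 4, lwd = 2)
      }
      graphics::legend("topright", legend = unique(agg$group),
                       col = c(2, 4), lwd = 2, bty = "n")
      grDevices::dev.off()
      files <- c(files, path)
    }
    # six-panel index figure
    path <- file.path(out_dir, "evaluation_indices.png")
    grDevices::png(path, width = 1100, height = 700)
    old <- graphics::par(mfrow = c(2, 3))
    on.exit(graphics::par(old), add = TRUE)
    panel <- function(df, col, ylab) {
      graphics::boxplot(df[[col]] ~ interaction(df$phase, df$group),
                        las = 2, ylab = ylab, xlab = "", main = ylab)
    }
    stage_ev <- ev[ev$phase %in% c("pre", "post", "retention"), ]
    panel(stage_ev, "e", "endpoint error e [deg]")
    panel(stage_ev, "e_perp_max", "max lateral deviation [deg]")
    ss <- report$stage_sets
    if (nrow(ss) > 0) {
      graphics::boxplot(s ~ interaction(phase, group), data = ss, las = 2,
                        ylab = "endpoint spread s [deg]", xlab = "",
                        main = "endpoint spread s [deg]")
      graphics::boxplot(r_orbit ~ interaction(phase, group), data = ss,
                        las = 2, ylab = "orbit correlation", xlab = "",
                        main = "orbit correlation r")
    } else {
      graphics::plot.new(); graphics::plot.new()
    }
    panel(stage_ev, "jc", "jerk cost [deg^2/s^5]")
    panel(stage_ev, "v_norm", "normalized mean velocity")
    grDevices::dev.off()
    files <- c(files, path)
  } else {
    # headers-only CSVs already written above for an empty report
  }
  invisible(files)
}

#' Classifier benchmark on simulated subjects
#'
#' End-to-end identification benchmark of the motion-intent classifier:
#' for each simulated subject, generates calibration recordings and one
#' 0.5 s training recording per movement class (500 samples each at
#' 1000 Hz; 2000 samples for the four movements), preprocesses them into
#' coordination features, trains a per-subject R-LLGMN, then classifies
#' held-out gated feature windows from fresh recordings and reports the
#' identification accuracy.
#'
#' @param subject_seeds Integer seed per simulated subject.
#' @param noise_sd Envelope noise SD of the EMG generator.
#' @param n_test_windows Held-out decision windows per subject (split
#'   evenly across classes).
#' @param signal_cfg A [signal_config()].
#' @param net_cfg A [network_config()].
#' @param train_duration Training recording duration per movement, s.
#' @param maxit,stride Training settings passed to [rllgmn()].
#' @return List with `per_subject` (data frame `seed, n_train_samples,
#'   train_accuracy, accuracy`) and `mean_accuracy` (percent).
#' @export
classifier_benchmark <- function(subject_seeds = 1:5, noise_sd = 0.1,
                                 n_test_windows = 100,
                                 signal_cfg = signal_config(),
                                 net_cfg = network_config(),
                                 train_duration = 0.5,
                                 maxit = 150L, stride = 10L) {
  rows <- list()
  for (s in subject_seeds) {
    s <- as.integer(s)
    spec <- emg_gen_spec(noise_sd = noise_sd, duration = train_duration,
                         fs = signal_cfg$fs)
    cal_rec <- generate_calibration_recordings(spec, seed = s * 1000L + 1L)
    cal <- emg_calibrate(
      emg_envelope(emg_bandpass(cal_rec$rest, signal_cfg), signal_cfg),
      emg_envelope(emg_bandpass(cal_rec$voluntary, signal_cfg), signal_cfg))
    C <- net_cfg$n_classes
    train_x <- vector("list", C)
    n_train <- 0L
    for (cc in seq_len(C)) {
      g <- generate_emg(spec, cc, seed = s * 1000L + 10L + cc)
      ft <- emg_features(g$record, signal_cfg, cal)
      train_x[[cc]] <- ft$x
      n_train <- n_train + nrow(ft$x)
    }
    model <- rllgmn(train_x, seq_len(C), net_cfg, seed = s,
                    maxit = maxit, stride = stride)
    per_class <- ceiling(n_test_windows / C)
    wins <- list(); labs <- integer(0)
    for (cc in seq_len(C)) {
      g <- generate_emg(spec, cc, seed = s * 1000L + 100L + cc,
                        duration = 2)
      ft <- emg_features(g$record, signal_cfg, cal)
      ok <- which(ft$gate & seq_along(ft$gate) >= net_cfg$seq_len)
      sel <- ok[unique(round(seq(1, length(ok), length.out = per_class)))]
      wins <- c(wins, lapply(sel, function(i) {
        ft$x[(i - net_cfg$seq_len + 1L):i, , drop = FALSE]
      }))
      labs <- c(labs, rep(cc, length(sel)))
    }
    pred <- predict(model, wins, type = "class")
    rows[[length(rows) + 1L]] <- data.frame(
      seed = s, n_train_samples = n_train,
      train_accuracy = model$train_accuracy,
      accuracy = mean(pred == labs))
  }
  per_subject <- do.call(rbind, rows)
  list(per_subject = per_subject,
       mean_accuracy = 100 * mean(per_subject$accuracy))
}
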