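mk_trial <- function(p, start = c(0, 0), target = c(20, 0), fs = 1000) {
  trial_trajectory(seq_len(nrow(p)) / fs, p, start, target)
}

test_that("trajectory decomposition projects onto the task frame", {
  tr <- mk_trial(rbind(c(0, 0), c(10, 10), c(20, 0)))
  dc <- decompose(tr)
  expect_equal(dc$par, c(0, 10, 20))
  expect_equal(dc$perp, c(0, 10, 0))
  # norm reconstruction at every sample
  rel <- sweep(tr$p, 2, tr$start, `-`)
  expect_equal(dc$par^2 + dc$perp^2, rowSums(rel^2), tolerance = 1e-9)
  # straight line to target: zero perpendicular
  line <- cbind(seq(0, 20, length.out = 50), 0)
  expect_true(all(abs(decompose(mk_trial(line))$perp) < 1e-12))
  expect_error(trial_trajectory(1:3 / 1000, matrix(0, 3, 2), c(1, 1),
                                c(1, 1)),
               "differ")
})

test_that("endpoint error is the Euclidean miss distance", {
  line <- cbind(seq(0, 20, length.out = 50), 0)
  expect_equal(endpoint_error(mk_trial(line)), 0)
  p345 <- rbind(c(0, 0), c(17, 4))
  expect_equal(endpoint_error(mk_trial(p345)), 5)       # 3-4-5 triangle
  p2 <- rbind(c(0, 0), c(20, -2))
  expect_equal(endpoint_error(mk_trial(p2)), 2)
})

test_that("maximum lateral deviation captures the widest excursion", {
  line <- cbind(seq(0, 20, length.out = 50), 0)
  expect_equal(max_lateral_deviation(decompose(mk_trial(line))), 0)
  # semicircular arc from (0,0) to (20,0) through (10,10); odd sample
  # count so the apex is hit exactly
  th <- seq(pi, 0, length.out = 201)
  arc <- cbind(10 + 10 * cos(th), 10 * sin(th))
  expect_equal(max_lateral_deviation(decompose(mk_trial(arc))), 10,
               tolerance = 1e-9)
  # reflection about the movement axis leaves it unchanged
  arc_r <- cbind(arc[, 1], -arc[, 2])
  expect_equal(max_lateral_deviation(decompose(mk_trial(arc_r))), 10,
               tolerance = 1e-9)
})

test_that("endpoint spread is the mean distance to the mean endpoint", {
  line_to <- function(xy) mk_trial(rbind(c(0, 0), c(xy[1], xy[2])))
  same <- replicate(3, line_to(c(19, 1)), simplify = FALSE)
  expect_equal(endpoint_sd(same), 0)
  two <- list(line_to(c(19, 1)), line_to(c(21, -1)))
  expect_equal(endpoint_sd(two), sqrt(2))
  # appending the mean endpoint scales s by M/(M+1)
  three <- c(two, list(line_to(c(20, 0))))
  expect_equal(endpoint_sd(three), sqrt(2) * 2 / 3)
  expect_error(endpoint_sd(two[1]), "2 trials")
})

test_that("orbit correlation averages pairwise parallel-series correlations", {
  tr <- minimum_jerk(c(0, 0), c(20, 0), 2, fs_out = 100)
  base <- mk_trial(tr$p, fs = 100)
  expect_equal(orbit_correlation(list(base, base, base)), 1)
  # positive affine transformation preserves r = 1
  aff <- mk_trial(cbind(0.5 * tr$p[, 1] + 1, tr$p[, 2]), fs = 100)
  expect_equal(orbit_correlation(list(base, aff)), 1, tolerance = 1e-12)
  # time-mirrored trial: matches a direct Pearson computation
  mir <- mk_trial(tr$p[nrow(tr$p):1, ], fs = 100)
  r_direct <- cor(tr$p[, 1], rev(tr$p[, 1]))
  expect_equal(orbit_correlation(list(base, mir)), r_direct,
               tolerance = 1e-9)
  # zero-variance series are excluded with a warning
  flat <- mk_trial(cbind(rep(0, 10), rep(0, 10)))
  expect_warning(r <- orbit_correlation(list(base, base, flat)), "excluded")
  expect_equal(r, 1)
  expect_error(suppressWarnings(orbit_correlation(list(flat, flat))),
               "all trial pairs excluded")
})

test_that("jerk cost matches the minimum-jerk closed form and scales", {
  trial <- minjerk_trial_fixture()
  dc <- decompose(trial)
  expect_equal(jerk_cost(dc), 4500, tolerance = 0.01)   # 360 A^2 / T^5
  # constant-velocity motion has (near) zero jerk cost
  t <- seq(0, 2, by = 1e-3)
  ramp <- mk_trial(cbind(10 * t, 0), fs = 1000)
  expect_lt(jerk_cost(decompose(ramp)), 1e-9)
  # doubling the amplitude quadruples the cost
  tr2 <- minimum_jerk(c(0, 0), c(40, 0), 2, fs_out = 1000, limit = 45)
  dc2 <- decompose(trial_trajectory(tr2$t, tr2$p, c(0, 0), c(40, 0)))
  expect_equal(jerk_cost(dc2) / jerk_cost(dc), 4, tolerance = 1e-6)
  expect_error(jerk_cost(decompose(mk_trial(cbind(1:5, 0)))), "7 samples")
})

test_that("jerk cost converges to the closed form with order >= 1", {
  errs <- vapply(c(50, 100, 200, 400), function(fs) {
    tr <- minimum_jerk(c(0, 0), c(20, 0), 2, fs_out = fs)
    dc <- decompose(trial_trajectory(tr$t, tr$p, c(0, 0), c(20, 0)))
    abs(jerk_cost(dc) - 4500)
  }, 1)
  order_obs <- log2(errs[-4] / errs[-1])
  expect_true(all(order_obs >= 1))
})

test_that("normalized mean velocity distinguishes velocity profiles", {
  t <- seq(0, 2, by = 1e-3)
  ramp <- mk_trial(cbind(10 * t, 0), fs = 1000)
  expect_equal(normalized_mean_velocity(decompose(ramp)), 1,
               tolerance = 1e-9)
  trial <- minjerk_trial_fixture()
  expect_equal(normalized_mean_velocity(decompose(trial)), 8 / 15,
               tolerance = 0.005)
  # triangular velocity profile -> mean/peak = 1/2
  n <- 2001
  tt <- seq(0, 2, length.out = n)
  v <- ifelse(tt <= 1, tt, 2 - tt)
  pos <- cumsum(c(0, (v[-1] + v[-n]) / 2 * diff(tt)))
  tri <- trial_trajectory(tt, cbind(pos, 0), c(0, 0), c(pos[n], 0))
  expect_equal(normalized_mean_velocity(decompose(tri)), 0.5,
               tolerance = 0.01)
  flat <- mk_trial(cbind(rep(0, 10), rep(0, 10)))
  expect_error(normalized_mean_velocity(decompose(flat)), "zero peak")
})

test_that("reaching time matches closed-form threshold crossings", {
  trial <- minjerk_trial_fixture()
  # oracle: onset when v(tau) = 0.05 * v_peak; arrival when the position
  # enters the 2-degree radius of the endpoint, from the quintic closed form
  vprof <- function(tau) 30 * tau^2 - 60 * tau^3 + 30 * tau^4  # * A/T
  tau_on <- uniroot(function(x) vprof(x) - 0.05 * 1.875,
                    c(1e-6, 0.5))$root
  sprof <- function(tau) 6 * tau^5 - 15 * tau^4 + 10 * tau^3
  tau_arr <- uniroot(function(x) 20 * (1 - sprof(x)) - 2, c(0.5, 1))$root
  expected <- 2 * (tau_arr - tau_on)
  expect_equal(reaching_time(trial), expected, tolerance = 0.01)
  # time covariance: stretching the time axis doubles the duration
  tr <- minimum_jerk(c(0, 0), c(20, 0), 4, fs_out = 500)
  slow <- trial_trajectory(tr$t, tr$p, c(0, 0), c(20, 0))
  expect_equal(reaching_time(slow), 2 * expected, tolerance = 0.02)
  # zero movement: onset error
  flat <- mk_trial(matrix(0, 100, 2))
  expect_error(reaching_time(flat), "onset")
})

test_that("all indices are invariant under rigid frame transformations", {
  set.seed(21)
  sk <- subject_skill()
  trials <- lapply(1:3, function(i) generate_trial(sk, c(0, 0), c(20, 0), i))
  transform_trial <- function(tr, th, shift) {
    R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
    trial_trajectory(tr$t, sweep(tr$p %*% t(R), 2, shift, `+`),
                     drop(tr$start %*% t(R)) + shift,
                     drop(tr$target %*% t(R)) + shift)
  }
  th <- 0.77; shift <- c(-4, 9)
  trials2 <- lapply(trials, transform_trial, th = th, shift = shift)
  for (i in 1:3) {
    expect_equal(endpoint_error(trials2[[i]]), endpoint_error(trials[[i]]),
                 tolerance = 1e-9)
    d1 <- decompose(trials[[i]]); d2 <- decompose(trials2[[i]])
    expect_equal(max_lateral_deviation(d2), max_lateral_deviation(d1),
                 tolerance = 1e-9)
    expect_equal(jerk_cost(d2), jerk_cost(d1), tolerance = 1e-9)
    expect_equal(normalized_mean_velocity(d2),
                 normalized_mean_velocity(d1), tolerance = 1e-9)
    expect_equal(reaching_time(trials2[[i]]), reaching_time(trials[[i]]),
                 tolerance = 1e-9)
  }
  expect_equal(endpoint_sd(trials2), endpoint_sd(trials), tolerance = 1e-9)
  expect_equal(orbit_correlation(trials2), orbit_correlation(trials),
               tolerance = 1e-9)
})

test_that("metrics respond monotonically to the generator's skill dials", {
  # endpoint noise drives e and s; tremor (inverse smoothness) drives jc
  noise_levels <- c(0.5, 1, 2, 3, 4)
  e_means <- s_vals <- numeric(length(noise_levels))
  for (k in seq_along(noise_levels)) {
    sk <- subject_skill(endpoint_bias = c(0, 0),
                        endpoint_noise_sd = noise_levels[k],
                        curvature = 2, tremor_amplitude = 0, duration = 2)
    trials <- lapply(1:12, function(i) {
      generate_trial(sk, c(0, 0), c(20, 0), seed = 1000 * k + i)
    })
    e_means[k] <- mean(vapply(trials, endpoint_error, 1))
    s_vals[k] <- endpoint_sd(trials)
  }
  expect_gt(cor(e_means, noise_levels, method = "spearman"), 0.9)
  expect_gt(cor(s_vals, noise_levels, method = "spearman"), 0.9)
  tremor_levels <- c(0, 0.2, 0.5, 1, 2)
  jc_means <- vapply(seq_along(tremor_levels), function(k) {
    sk <- subject_skill(endpoint_bias = c(0, 0), endpoint_noise_sd = 0,
                        curvature = 2, tremor_amplitude = tremor_levels[k],
                        duration = 2)
    mean(vapply(1:6, function(i) {
      jerk_cost(decompose(generate_trial(sk, c(0, 0), c(20, 0),
                                         seed = 500 * k + i)))
    }, 1))
  }, 1)
  expect_gt(cor(jc_means, tremor_levels, method = "spearman"), 0.9)
})

test_that("a metric report aggregates per-trial and set-level indices", {
  sk <- subject_skill()
  trials <- lapply(1:3, function(i) generate_trial(sk, c(0, 0), c(0, 20), i))
  rep <- metric_report(trials)
  expect_equal(nrow(rep$per_trial), 3)
  expect_true(all(c("e", "e_perp_max", "jc", "v_norm", "reaching_time")
                  %in% names(rep$per_trial)))
  expect_true(rep$set$s >= 0)
  expect_true(rep$set$r_orbit >= -1 && rep$set$r_orbit <= 1)
  expect_output(print(rep), "endpoint spread")
})
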