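test_that("input expansion enumerates the quadratic basis", {
  expect_equal(ncol(expand_input(matrix(runif(4), 1, 4))), 15)  # 1 + 4*7/2
  expect_equal(as.numeric(expand_input(rep(0, 4))),
               c(1, rep(0, 14)))
  a <- 0.3
  expect_equal(as.numeric(expand_input(a)), c(1, a, a^2))
  # L = 2 enumeration: (1, x1, x2, x1^2, x1 x2, x2^2)
  expect_equal(as.numeric(expand_input(c(2, 3))), c(1, 2, 3, 4, 6, 9))
})

test_that("posteriors are normalized and symmetric weights give 1/C", {
  ncfg <- network_config(n_classes = 2, n_states = 2, n_components = 2,
                         seq_len = 8, input_dim = 2)
  dims <- emghybrid:::.rllgmn_dims(ncfg)
  set.seed(4)
  # identical weights across classes -> exact symmetry
  w_cls <- matrix(rnorm(8 * dims$H, sd = 0.5), 8, dims$H)
  w <- rbind(w_cls, w_cls)
  net <- structure(list(weights = w, config = ncfg, dims = dims),
                   class = "rllgmn")
  x <- matrix(rnorm(16), 8, 2)
  post <- predict(net, x, type = "sequence")[[1]]
  expect_equal(post, matrix(0.5, 8, 2), tolerance = 1e-12)
  # normalization for arbitrary weights
  w2 <- matrix(rnorm(16 * dims$H, sd = 1), 16, dims$H)
  net2 <- structure(list(weights = w2, config = ncfg, dims = dims),
                    class = "rllgmn")
  post2 <- predict(net2, x, type = "sequence")[[1]]
  expect_true(all(abs(rowSums(post2) - 1) < 1e-9))
  expect_true(all(post2 >= 0 & post2 <= 1))
})

test_that("forward pass equals the direct GMM-HMM forward oracle", {
  set.seed(11)
  hmm <- random_gmm_hmm(C = 2, K = 2, M = 2, L = 2)
  ncfg <- network_config(n_classes = 2, n_states = 2, n_components = 2,
                         seq_len = 10, input_dim = 2)
  net <- rllgmn_from_hmm(hmm, ncfg)
  for (r in 1:20) {
    xseq <- matrix(rnorm(20), 10, 2)
    expect_equal(predict(net, xseq, type = "posterior")[1, ],
                 hmm_forward_posterior(hmm, xseq), tolerance = 1e-6)
  }
})

test_that("scaling every unit activation at a step leaves posteriors unchanged", {
  # adding a constant to all bias weights multiplies every a(c,k',k,m) by
  # a positive constant at each step; normalization must cancel it
  set.seed(8)
  ncfg <- network_config(2, 2, 2, 6, 2)
  dims <- emghybrid:::.rllgmn_dims(ncfg)
  w <- matrix(rnorm(dims$U * dims$H, sd = 0.5), dims$U, dims$H)
  w_shift <- w
  w_shift[, 1] <- w_shift[, 1] + 37
  x <- matrix(rnorm(12), 6, 2)
  n1 <- structure(list(weights = w, config = ncfg, dims = dims),
                  class = "rllgmn")
  n2 <- structure(list(weights = w_shift, config = ncfg, dims = dims),
                  class = "rllgmn")
  expect_equal(predict(n1, x, type = "sequence")[[1]],
               predict(n2, x, type = "sequence")[[1]], tolerance = 1e-9)
})

test_that("analytic gradient matches central finite differences", {
  set.seed(3)
  ncfg <- network_config(2, 2, 2, 5, 2)
  dims <- emghybrid:::.rllgmn_dims(ncfg)
  xl <- lapply(1:5, function(t) expand_input(matrix(rnorm(12), 6, 2)))
  y <- rep(1:2, 3)
  w <- matrix(rnorm(dims$U * dims$H, sd = 0.3), dims$U, dims$H)
  g <- emghybrid:::.rllgmn_nll_grad(xl, y, w, dims)$grad
  eps <- 1e-6
  for (probe in list(c(1, 1), c(5, 3), c(16, 6), c(9, 2))) {
    wp <- w; wp[probe[1], probe[2]] <- wp[probe[1], probe[2]] + eps
    wm <- w; wm[probe[1], probe[2]] <- wm[probe[1], probe[2]] - eps
    num <- (emghybrid:::.rllgmn_nll_grad(xl, y, wp, dims, grad = FALSE)$nll -
              emghybrid:::.rllgmn_nll_grad(xl, y, wm, dims, grad = FALSE)$nll) /
      (2 * eps)
    expect_equal(g[probe[1], probe[2]], num, tolerance = 1e-5)
  }
})

test_that("training separates well-separated classes and is deterministic", {
  fx <- small_model_fixture()
  # nearest-centroid brute-force oracle confirms separability first
  set.seed(123)
  test1 <- fx$mk(1, 50); test2 <- fx$mk(2, 50)
  cents <- rbind(colMeans(fx$mk(1, 200)), colMeans(fx$mk(2, 200)))
  nc <- function(x) apply(x, 1, function(r) {
    which.min(colSums((t(cents) - r)^2))
  })
  expect_true(mean(nc(test1) == 1) == 1 && mean(nc(test2) == 2) == 1)
  expect_equal(fx$model$train_accuracy, 1.0)
  # determinism: same data and seed -> bitwise-identical weights
  set.seed(99)
  train <- list(fx$mk(1), fx$mk(2))
  m1 <- rllgmn(train, 1:2, fx$ncfg, seed = 7, stride = 5, maxit = 15)
  m2 <- rllgmn(train, 1:2, fx$ncfg, seed = 7, stride = 5, maxit = 15)
  expect_identical(m1$weights, m2$weights)
})

test_that("single-class training degenerates to certainty and zero loss", {
  ncfg <- network_config(n_classes = 1, n_states = 2, n_components = 2,
                         seq_len = 5, input_dim = 2)
  x <- matrix(runif(40, 0.2, 0.8), 20, 2)
  m <- rllgmn(list(x), 1, ncfg, seed = 1, stride = 3, maxit = 5)
  expect_equal(m$final_nll, 0, tolerance = 1e-9)
  expect_equal(unname(predict(m, x[1:5, ], type = "posterior")[1, 1]), 1)
})

test_that("classification takes the final-sample argmax with low-index ties", {
  expect_equal(classify_posterior(c(0.1, 0.7, 0.1, 0.1)), 2)
  expect_equal(classify_posterior(c(0.5, 0.5)), 1)
  # sequence: only the final sample matters
  post <- rbind(c(0.9, 0.1), c(0.2, 0.8))
  expect_equal(classify_posterior(post), 2)
  expect_error(classify_posterior(matrix(numeric(0), 0, 2)), "empty")
})

test_that("decision events fire once per sustained activation", {
  fx <- small_model_fixture()
  mkfeat <- function(gate, cls) {
    n <- length(gate)
    x <- fx$mk(cls, n)
    structure(list(t = seq_len(n) / 1000, x = x, activation = gate * 1,
                   gate = gate, sub_threshold = !gate),
              class = "feature_sequence")
  }
  # gate never true -> no events
  ev0 <- estimate_motion(mkfeat(rep(FALSE, 200), 1), fx$model)
  expect_equal(nrow(ev0), 0)
  # one sustained activation -> exactly one event, correct class
  g1 <- c(rep(FALSE, 50), rep(TRUE, 100), rep(FALSE, 50))
  ev1 <- estimate_motion(mkfeat(g1, 2), fx$model)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$class, 2)
  expect_equal(ev1$index, 51)
  # two separated activations -> two events
  g2 <- c(rep(FALSE, 30), rep(TRUE, 60), rep(FALSE, 40), rep(TRUE, 60),
          rep(FALSE, 10))
  ev2 <- estimate_motion(mkfeat(g2, 1), fx$model)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$class, c(1, 1))
  # gate opening before a full window exists defers with a warning
  g3 <- c(rep(TRUE, 30), rep(FALSE, 170))
  expect_warning(ev3 <- estimate_motion(mkfeat(g3, 1), fx$model),
                 "deferring")
  expect_equal(nrow(ev3), 1)  # fired once the window filled, gate still on
  expect_equal(ev3$index, 10)
})

test_that("weights survive a JSON round trip", {
  fx <- small_model_fixture()
  path <- tempfile(fileext = ".json")
  write_rllgmn(fx$model, path)
  back <- read_rllgmn(path)
  expect_equal(back$weights, fx$model$weights, tolerance = 1e-12)
  x <- fx$mk(2, 10)
  expect_equal(predict(back, x, type = "posterior"),
               predict(fx$model, x, type = "posterior"), tolerance = 1e-12)
})
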