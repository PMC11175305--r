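#' Quadratic input expansion
#'
#' Maps an `L`-dimensional coordination vector onto the log-linear basis
#' `X = [1, x_1..x_L, x_i * x_j for i <= j]` of length
#' `H = 1 + L(L+3)/2`. On this basis the log of a Gaussian-mixture HMM's
#' per-unit contribution (transition probability x mixture weight x Gaussian
#' density) is an exact linear function, which is what makes the
#' log-linearized network able to represent the model family.
#'
#' Monomial order: the pairs `(i, j)`, `i <= j`, are enumerated as
#' `(1,1), (1,2), ..., (1,L), (2,2), ..., (L,L)`.
#'
#' @param x Numeric vector of length `L`, or a matrix with `L` columns
#'   (one row per sample).
#' @return Expanded numeric matrix with `H` columns (a vector input returns
#'   a 1-row matrix).
#' @export
expand_input <- function(x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  L <- ncol(x)
  idx <- which(upper.tri(diag(L), diag = TRUE), arr.ind = TRUE)
  # enumerate (i, j) with i <= j, row-major: (1,1),(1,2),...,(1,L),(2,2),...
  ord <- order(idx[, "row"], idx[, "col"])
  idx <- idx[ord, , drop = FALSE]
  quad <- x[, idx[, "row"], drop = FALSE] * x[, idx[, "col"], drop = FALSE]
  cbind(1, x, quad, deparse.level = 0)
}

# unit bookkeeping: units are (c, k_prev, k, m) with m fastest, then k,
# then k_prev, then c. B groups over m; state order is (k fast, c slow).
.rllgmn_dims <- function(cfg) {
  C <- cfg$n_classes; K <- cfg$n_states; M <- cfg$n_components
  units <- expand.grid(m = seq_len(M), k = seq_len(K), kp = seq_len(K),
                       c = seq_len(C))
  groups <- expand.grid(k = seq_len(K), kp = seq_len(K), c = seq_len(C))
  states <- expand.grid(k = seq_len(K), c = seq_len(C))
  U <- nrow(units); G <- nrow(groups); S <- nrow(states)
  # unit -> (c,kp,k) group index
  unit_group <- (units$c - 1L) * K * K + (units$kp - 1L) * K + units$k
  # group -> previous-state (c,kp) and current-state (c,k) indices
  group_prev <- (groups$c - 1L) * K + groups$kp
  group_cur <- (groups$c - 1L) * K + groups$k
  # state -> class
  state_class <- states$c
  agg_units <- outer(unit_group, seq_len(G), `==`) * 1  # U x G indicator
  m_cur <- outer(group_cur, seq_len(S), `==`) * 1       # G x S indicator
  m_prev <- outer(group_prev, seq_len(S), `==`) * 1     # G x S indicator
  m_class <- outer(state_class, seq_len(C), `==`) * 1   # S x C indicator
  list(C = C, K = K, M = M, H = cfg$expanded_dim, U = U, G = G, S = S,
       units = units, unit_group = unit_group, group_prev = group_prev,
       group_cur = group_cur, state_class = state_class,
       agg_units = agg_units, m_cur = m_cur, m_prev = m_prev,
       m_class = m_class)
}

# One forward pass over a batch of expanded sequences.
# xl: list of T matrices (N x H), one per time step; w: U x H weights.
# Log-domain safety: per time step the row max of the logits is subtracted
# before exponentiation; the per-step normalization of Q makes this shift
# exactly neutral, so overflow cannot occur for finite weights.
# Returns posteriors at each step and (optionally) the caches needed by
# backpropagation through time.
.rllgmn_forward <- function(xl, w, dims, keep_cache = FALSE) {
  TT <- length(xl)
  N <- nrow(xl[[1]])
  Q <- matrix(1 / dims$S, N, dims$S)
  post <- array(NA_real_, c(N, TT, dims$C))
  cache <- if (keep_cache) vector("list", TT) else NULL
  wt <- t(w)
  for (t in seq_len(TT)) {
    logits <- xl[[t]] %*% wt                              # N x U
    mx <- logits[cbind(seq_len(N), max.col(logits))]
    A <- exp(logits - mx)                                 # N x U, scaled
    B <- A %*% dims$agg_units                             # N x G
    S <- (Q[, dims$group_prev, drop = FALSE] * B) %*% dims$m_cur
    Z <- rowSums(S)
    if (any(!is.finite(Z)) || any(Z <= 0)) {
      stop("numerical degeneracy in forward recursion", call. = FALSE)
    }
    Qprev <- Q
    Q <- S / Z
    post[, t, ] <- Q %*% dims$m_class
    if (keep_cache) cache[[t]] <- list(A = A, B = B, Qprev = Qprev, Q = Q, Z = Z)
  }
  list(post = post, Q = Q, cache = cache)
}

# Negative log-likelihood and gradient for labelled windows.
# labels: integer class per sequence; the reference unit's gradient is
# masked by the caller.
.rllgmn_nll_grad <- function(xl, labels, w, dims, grad = TRUE) {
  TT <- length(xl)
  N <- nrow(xl[[1]])
  fw <- .rllgmn_forward(xl, w, dims, keep_cache = grad)
  o_final <- matrix(fw$post[, TT, ], N, dims$C)
  p_true <- o_final[cbind(seq_len(N), labels)]
  nll <- -sum(log(pmax(p_true, .Machine$double.xmin)))
  if (!grad) return(list(nll = nll, post = o_final))
  dW <- matrix(0, dims$U, dims$H)
  # dL/dQ at final step: posterior O_c sums the states of class c
  dQ <- -dims$m_class[, labels, drop = FALSE]             # S x N
  dQ <- t(dQ) / p_true                                    # N x S (recycled)
  for (t in rev(seq_len(TT))) {
    ch <- fw$cache[[t]]
    inner <- rowSums(dQ * ch$Q)
    dS <- (dQ - inner) / ch$Z
    dS_g <- dS[, dims$group_cur, drop = FALSE]            # N x G
    dB <- ch$Qprev[, dims$group_prev, drop = FALSE] * dS_g
    dQprev <- (ch$B * dS_g) %*% dims$m_prev
    dA <- ch$A * dB[, dims$unit_group, drop = FALSE]
    dW <- dW + crossprod(dA, xl[[t]])
    dQ <- dQprev
  }
  list(nll = nll, grad = dW, post = o_final)
}

# Slice a feature matrix (rows = samples) into decision windows of length
# seq_len with the given stride, returning an [N, T, H] expanded array.
.window_array <- function(x, seq_len, stride) {
  n <- nrow(x)
  if (n < seq_len) stop("fewer samples than seq_len", call. = FALSE)
  starts <- seq.int(1L, n - seq_len + 1L, by = stride)
  xe <- expand_input(x)
  H <- ncol(xe)
  xa <- array(NA_real_, c(length(starts), seq_len, H))
  for (i in seq_along(starts)) {
    xa[i, , ] <- xe[starts[i]:(starts[i] + seq_len - 1L), , drop = FALSE]
  }
  xa
}

#' Fit a recurrent log-linearized Gaussian-mixture network (R-LLGMN)
#'
#' Trains the recurrent probabilistic classifier on labelled coordination
#' feature sequences. The network embeds a `C`-class Gaussian-mixture hidden
#' Markov model (`K` states per class, `M` components per state) in a
#' log-linear form: each unit's activation is `exp(w' X(t))` on the quadratic
#' basis of [expand_input()], states are propagated by the recurrent
#' recursion and normalized at every step, and the class posterior is the
#' within-class sum of normalized states. Training minimizes the negative
#' log posterior of the true class at the final window sample, by full-batch
#' gradient descent with backtracking (Armijo) line search and analytic
#' gradients obtained by backpropagation through time.
#'
#' @param x Either a list of numeric matrices (one labelled recording per
#'   element, rows = samples, columns = `L` channels) or a single matrix
#'   with `labels` per recording; recordings are sliced into overlapping
#'   decision windows of `config$seq_len` samples.
#' @param labels Integer class label (1..C) per element of `x`.
#' @param config A [network_config()].
#' @param seed Integer seed for the weight initialization (zero-mean
#'   Gaussian, `sd = init_sd`).
#' @param stride Window stride (samples) when slicing recordings.
#' @param maxit Maximum gradient-descent iterations.
#' @param reltol Stop when the relative loss decrease falls below this.
#' @param loss_floor Stop when the mean negative log-likelihood per window
#'   falls below this (posteriors saturated).
#' @param init_sd Standard deviation of the Gaussian weight initialization.
#' @param optimizer `"gd"` (default: full-batch gradient descent with
#'   backtracking line search) or `"lbfgs"` (via [stats::optim()]).
#' @return An object of class `"rllgmn"`: list with `weights` (U x H
#'   matrix), `config`, `dims` bookkeeping, `loss` trace, `converged`,
#'   `train_accuracy`, `seed`, `stride`, `n_windows`.
#' @seealso [predict.rllgmn()], [rllgmn_from_hmm()], [estimate_motion()]
#' @export
rllgmn <- function(x, labels, config, seed = 1L, stride = 10L,
                   maxit = 2000L, reltol = 1e-8, loss_floor = 1e-4,
                   init_sd = 0.01, optimizer = c("gd", "lbfgs")) {
  optimizer <- match.arg(optimizer)
  stopifnot(inherits(config, "network_config"))
  if (is.matrix(x)) x <- list(x)
  labels <- as.integer(labels)
  if (length(labels) != length(x)) {
    stop("one label per recording is required", call. = FALSE)
  }
  if (!all(seq_len(config$n_classes) %in% labels)) {
    stop("every class must appear at least once in the training set",
         call. = FALSE)
  }
  dims <- .rllgmn_dims(config)
  win <- lapply(x, .window_array, seq_len = config$seq_len, stride = stride)
  n_per <- vapply(win, function(a) dim(a)[1], 1L)
  xa <- lapply(seq_len(config$seq_len), function(t) {
    do.call(rbind, lapply(win, function(a) {
      matrix(a[, t, ], dim(a)[1], dims$H)
    }))
  })
  y <- rep(labels, n_per)

  set.seed(as.integer(seed))
  w <- matrix(stats::rnorm(dims$U * dims$H, sd = init_sd), dims$U, dims$H)
  w[dims$U, ] <- 0  # reference unit pinned for identifiability
  free <- matrix(TRUE, dims$U, dims$H)
  free[dims$U, ] <- FALSE

  n_win <- length(y)
  loss_trace <- numeric(0)
  converged <- FALSE

  if (optimizer == "lbfgs") {
    fn <- function(theta) {
      w[free] <- theta
      .rllgmn_nll_grad(xa, y, w, dims, grad = FALSE)$nll
    }
    gr <- function(theta) {
      w[free] <- theta
      .rllgmn_nll_grad(xa, y, w, dims)$grad[free]
    }
    opt <- stats::optim(w[free], fn, gr, method = "L-BFGS-B",
                        control = list(maxit = maxit, factr = 1e4))
    w[free] <- opt$par
    loss_trace <- opt$value
    converged <- opt$convergence == 0
  } else {
    cur <- .rllgmn_nll_grad(xa, y, w, dims)
    if (!is.finite(cur$nll)) {
      stop("training failure: non-finite initial loss", call. = FALSE)
    }
    step <- 1 / n_win
    for (it in seq_len(maxit)) {
      g <- cur$grad
      g[!free] <- 0
      gnorm2 <- sum(g^2)
      if (gnorm2 == 0) { converged <- TRUE; break }
      # backtracking (Armijo) with step growth on acceptance
      accepted <- FALSE
      for (bt in 1:30) {
        w_new <- w - step * g
        nll_new <- .rllgmn_nll_grad(xa, y, w_new, dims, grad = FALSE)$nll
        if (is.finite(nll_new) &&
            nll_new <= cur$nll - 1e-4 * step * gnorm2) {
          accepted <- TRUE
          break
        }
        step <- step / 2
      }
      if (!accepted) { converged <- TRUE; break }  # no descent possible
      rel <- (cur$nll - nll_new) / max(abs(cur$nll), .Machine$double.eps)
      w <- w_new
      cur <- .rllgmn_nll_grad(xa, y, w, dims)
      loss_trace <- c(loss_trace, cur$nll)
      if (!is.finite(cur$nll)) {
        stop("training failure: non-finite loss at iteration ", it,
             call. = FALSE)
      }
      step <- step * 2
      if (rel < reltol || cur$nll / n_win < loss_floor) {
        converged <- TRUE
        break
      }
    }
  }

  final <- .rllgmn_nll_grad(xa, y, w, dims, grad = FALSE)
  pred <- max.col(final$post, ties.method = "first")
  structure(
    list(weights = w, config = config, dims = dims,
         loss = loss_trace, final_nll = final$nll,
         converged = converged,
         train_accuracy = mean(pred == y),
         n_windows = n_win, seed = as.integer(seed),
         stride = as.integer(stride), optimizer = optimizer),
    class = "rllgmn"
  )
}

#' @export
print.rllgmn <- function(x, ...) {
  cfg <- x$config
  cat("Recurrent log-linearized Gaussian mixture network (R-LLGMN)\n")
  cat(sprintf("  classes C = %d, states K = %d, components M = %d, window T = %d\n",
              cfg$n_classes, cfg$n_states, cfg$n_components, cfg$seq_len))
  cat(sprintf("  input dim L = %d (expanded H = %d), %d units, %d weights\n",
              cfg$input_dim, cfg$expanded_dim, x$dims$U,
              sum(x$weights != 0 | row(x$weights) < x$dims$U)))
  cat(sprintf("  trained on %d windows (stride %d), final NLL %.4g, training accuracy %.3f\n",
              x$n_windows, x$stride, x$final_nll, x$train_accuracy))
  cat(sprintf("  optimizer: %s, %sconverged\n", x$optimizer,
              if (x$converged) "" else "NOT "))
  invisible(x)
}

#' @export
summary.rllgmn <- function(object, ...) {
  print(object)
  if (length(object$loss) > 1) {
    cat(sprintf("  loss trace: %.4g -> %.4g over %d iterations\n",
                object$loss[1], object$loss[length(object$loss)],
                length(object$loss)))
  }
  invisible(object)
}

#' Forward pass: class posteriors for feature windows
#'
#' @param object A fitted [rllgmn()] model (or one built by
#'   [rllgmn_from_hmm()]).
#' @param newdata A numeric matrix (one window, rows = samples) or a list of
#'   such matrices.
#' @param type `"class"` for hard decisions (argmax of the final-sample
#'   posterior, ties broken by the lowest class index), `"posterior"` for
#'   the final-sample posterior vectors, or `"sequence"` for the full
#'   per-sample posterior array.
#' @param ... Unused.
#' @return Integer classes, a posterior matrix (windows x classes), or a
#'   list of posterior sequences, according to `type`.
#' @export
predict.rllgmn <- function(object, newdata,
                           type = c("class", "posterior", "sequence"), ...) {
  type <- match.arg(type)
  if (is.matrix(newdata)) newdata <- list(newdata)
  dims <- object$dims
  out_post <- matrix(NA_real_, length(newdata), dims$C)
  out_seq <- vector("list", length(newdata))
  lens <- vapply(newdata, nrow, 1L)
  for (len in unique(lens)) {
    sel <- which(lens == len)
    xe <- lapply(newdata[sel], expand_input)
    xl <- lapply(seq_len(len), function(t) {
      do.call(rbind, lapply(xe, function(e) e[t, , drop = FALSE]))
    })
    fw <- .rllgmn_forward(xl, object$weights, dims)
    for (ii in seq_along(sel)) {
      seq_post <- matrix(fw$post[ii, , ], len, dims$C)
      out_seq[[sel[ii]]] <- seq_post
      out_post[sel[ii], ] <- seq_post[len, ]
    }
  }
  switch(type,
         class = max.col(out_post, ties.method = "first"),
         posterior = out_post,
         sequence = out_seq)
}

#' Hard decision from a posterior sequence
#'
#' Argmax of the final-time class posterior; ties are broken by the lowest
#' class index.
#'
#' @param posterior Numeric matrix of per-sample posteriors (rows = time) or
#'   a single posterior vector.
#' @return Integer class id.
#' @export
classify_posterior <- function(posterior) {
  if (is.null(dim(posterior))) posterior <- matrix(posterior, nrow = 1)
  if (nrow(posterior) < 1) stop("empty posterior sequence", call. = FALSE)
  final <- posterior[nrow(posterior), ]
  which.max(final)  # which.max takes the first (lowest index) on ties
}

#' Build an R-LLGMN from explicit Gaussian-mixture HMM parameters
#'
#' Log-linearizes a known Gaussian-mixture hidden Markov model onto the
#' network's weight basis: each unit's weight vector encodes
#' `log(transition(k', k) * mix_weight(k, m)) + log N(x; mu, Sigma)` exactly,
#' because the Gaussian log-density is a quadratic polynomial in `x`.
#' Useful for constructing reference classifiers with known behaviour.
#'
#' @param hmm List with elements per class: `trans` (K x K transition
#'   matrix), `mix` (K x M mixture weights), `mu` (list of lists:
#'   `mu[[k]][[m]]` mean vector length L), `sigma` (same shape, L x L
#'   covariance).
#' @param config A [network_config()] whose dimensions match `hmm`.
#' @return An object of class `"rllgmn"` (untrained; `train_accuracy` NA).
#' @export
rllgmn_from_hmm <- function(hmm, config) {
  stopifnot(inherits(config, "network_config"))
  dims <- .rllgmn_dims(config)
  L <- config$input_dim
  idx <- which(upper.tri(diag(L), diag = TRUE), arr.ind = TRUE)
  ord <- order(idx[, "row"], idx[, "col"])
  idx <- idx[ord, , drop = FALSE]
  w <- matrix(0, dims$U, dims$H)
  for (u in seq_len(dims$U)) {
    cc <- dims$units$c[u]; kp <- dims$units$kp[u]
    kk <- dims$units$k[u]; mm <- dims$units$m[u]
    cls <- hmm[[cc]]
    mu <- cls$mu[[kk]][[mm]]
    sig <- cls$sigma[[kk]][[mm]]
    prec <- solve(sig)
    const <- log(cls$trans[kp, kk]) + log(cls$mix[kk, mm]) -
      (L / 2) * log(2 * pi) - 0.5 * determinant(sig)$modulus[1] -
      0.5 * drop(t(mu) %*% prec %*% mu)
    lin <- drop(prec %*% mu)
    quad <- numeric(nrow(idx))
    for (q in seq_len(nrow(idx))) {
      i <- idx[q, "row"]; j <- idx[q, "col"]
      quad[q] <- if (i == j) -0.5 * prec[i, i] else -prec[i, j]
    }
    w[u, ] <- c(const, lin, quad)
  }
  structure(
    list(weights = w, config = config, dims = dims, loss = numeric(0),
         final_nll = NA_real_, converged = NA, train_accuracy = NA_real_,
         n_windows = 0L, seed = NA_integer_, stride = NA_integer_,
         optimizer = "none"),
    class = "rllgmn"
  )
}

#' Motion-intent decision events from a gated feature sequence
#'
#' Scans a [emg_features()] sequence: each time the activation gate turns
#' on, the trailing `seq_len`-sample feature window is classified and a
#' single decision event is emitted; further events are suppressed until the
#' gate has dropped again. If the gate opens before `seq_len` samples exist,
#' the decision is deferred (with a warning) until enough history has
#' accumulated, provided the gate is still open.
#'
#' @param features A `"feature_sequence"` from [emg_features()].
#' @param model A fitted [rllgmn()].
#' @return A data frame with one row per decision event: `time`, `index`,
#'   `class`, and posterior columns `p1..pC`.
#' @export
estimate_motion <- function(features, model) {
  stopifnot(inherits(features, "feature_sequence"), inherits(model, "rllgmn"))
  seq_len_w <- model$config$seq_len
  g <- features$gate
  n <- length(g)
  events <- list()
  armed <- TRUE   # can fire on next gate-on period
  pending <- FALSE
  i <- 1L
  while (i <= n) {
    if (g[i] && armed) {
      if (i < seq_len_w) {
        if (!pending) {
          warning("gate opened before a full decision window exists; deferring",
                  call. = FALSE)
          pending <- TRUE
        }
        i <- i + 1L
        next
      }
      win <- features$x[(i - seq_len_w + 1L):i, , drop = FALSE]
      post <- predict(model, win, type = "posterior")
      cls <- which.max(post[1, ])
      events[[length(events) + 1L]] <-
        data.frame(time = features$t[i], index = i, class = cls,
                   t(post[1, ]))
      armed <- FALSE
      pending <- FALSE
    } else if (!g[i]) {
      armed <- TRUE
      pending <- FALSE
    }
    i <- i + 1L
  }
  if (length(events) == 0) {
    out <- data.frame(time = numeric(0), index = integer(0),
                      class = integer(0))
    for (cc in seq_len(model$config$n_classes)) out[[paste0("p", cc)]] <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, events)
  names(out) <- c("time", "index", "class",
                  paste0("p", seq_len(model$config$n_classes)))
  rownames(out) <- NULL
  out
}

#' Serialize an R-LLGMN to JSON
#'
#' @param model A `"rllgmn"` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rllgmn <- function(model, path) {
  cfg <- model$config
  obj <- list(
    architecture = list(n_classes = cfg$n_classes, n_states = cfg$n_states,
                        n_components = cfg$n_components,
                        seq_len = cfg$seq_len, input_dim = cfg$input_dim),
    weights = as.vector(model$weights),
    n_units = nrow(model$weights),
    expanded_dim = ncol(model$weights),
    train = list(final_nll = model$final_nll,
                 train_accuracy = model$train_accuracy,
                 seed = model$seed, stride = model$stride,
                 converged = model$converged, loss = model$loss)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an R-LLGMN from JSON
#'
#' @param path File written by [write_rllgmn()].
#' @return A `"rllgmn"` object.
#' @export
read_rllgmn <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  a <- obj$architecture
  cfg <- network_config(a$n_classes, a$n_states, a$n_components,
                        a$seq_len, a$input_dim)
  dims <- .rllgmn_dims(cfg)
  w <- matrix(obj$weights, obj$n_units, obj$expanded_dim)
  structure(
    list(weights = w, config = cfg, dims = dims,
         loss = obj$train$loss, final_nll = obj$train$final_nll,
         converged = obj$train$converged,
         train_accuracy = obj$train$train_accuracy,
         n_windows = NA_integer_, seed = obj$train$seed,
         stride = obj$train$stride, optimizer = "loaded"),
    class = "rllgmn"
  )
}
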