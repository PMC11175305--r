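# Independent Gaussian-mixture HMM forward-algorithm oracle.
# Written directly from the model densities (no shared code with the
# network's exp(w'X) path): used to validate the recurrent forward pass.

gauss_density <- function(x, mu, sigma) {
  L <- length(mu)
  d <- x - mu
  exp(-0.5 * drop(t(d) %*% solve(sigma) %*% d)) /
    sqrt((2 * pi)^L * det(sigma))
}

hmm_forward_posterior <- function(hmm, xseq) {
  C <- length(hmm)
  K <- nrow(hmm[[1]]$trans)
  M <- ncol(hmm[[1]]$mix)
  alpha <- matrix(1 / (C * K), C, K)  # uniform over (class, state)
  for (t in seq_len(nrow(xseq))) {
    x <- xseq[t, ]
    newa <- matrix(0, C, K)
    for (cc in seq_len(C)) {
      for (k in seq_len(K)) {
        b <- sum(vapply(seq_len(M), function(m) {
          hmm[[cc]]$mix[k, m] *
            gauss_density(x, hmm[[cc]]$mu[[k]][[m]],
                          hmm[[cc]]$sigma[[k]][[m]])
        }, 1))
        newa[cc, k] <- sum(alpha[cc, ] * hmm[[cc]]$trans[, k]) * b
      }
    }
    alpha <- newa / sum(newa)
  }
  rowSums(alpha)
}

random_gmm_hmm <- function(C = 2, K = 2, M = 2, L = 2, sep = 0) {
  # sep > 0 pushes class means apart for separable problems
  lapply(seq_len(C), function(cc) {
    trans <- matrix(stats::runif(K * K, 0.2, 1), K, K)
    trans <- trans / rowSums(trans)
    mix <- matrix(stats::runif(K * M, 0.2, 1), K, M)
    mix <- mix / rowSums(mix)
    center <- if (sep > 0) sep * c(cos(2 * pi * cc / C),
                                   sin(2 * pi * cc / C))[seq_len(L)] else
      numeric(L)
    mu <- lapply(seq_len(K), function(k) {
      lapply(seq_len(M), function(m) center + stats::runif(L, -1, 1))
    })
    sigma <- lapply(seq_len(K), function(k) {
      lapply(seq_len(M), function(m) {
        a <- matrix(stats::runif(L * L, -0.3, 0.3), L, L)
        diag(L) * stats::runif(1, 0.5, 1.5) + crossprod(a)
      })
    })
    list(trans = trans, mix = mix, mu = mu, sigma = sigma)
  })
}
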