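# Independent oracles used across tests. These deliberately use naive dense /
# scalar-loop computations, not the package's own code paths.

# scalar double-loop Bernoulli-logit log-likelihood
oracle_loglik <- function(y, eta) {
  ll <- 0
  for (i in seq_len(nrow(y))) {
    for (k in seq_len(ncol(y))) {
      if (is.na(y[i, k])) next
      p <- 1 / (1 + exp(-eta[i, k]))
      ll <- ll + y[i, k] * log(p) + (1 - y[i, k]) * log(1 - p)
    }
  }
  ll
}

# scalar double-loop linear predictor
oracle_linear_predictor <- function(alpha, beta, X, S, V, district) {
  n <- nrow(X); K <- length(alpha)
  eta <- matrix(0, n, K)
  for (i in seq_len(n)) {
    for (k in seq_len(K)) {
      eta[i, k] <- alpha[k] + sum(X[i, ] * beta[, k]) +
        S[district[i], k] + V[district[i], k]
    }
  }
  eta
}

# conditional of block j of a zero-mean Gaussian with precision Q %x% solve(Sigma),
# computed by dense precision-block conditioning
oracle_micar_conditional <- function(S, j, Q, Sigma) {
  K <- ncol(Sigma)
  J <- nrow(Q)
  Sinv <- solve(Sigma)
  P <- Q %x% Sinv # (area-major blocks of size K)
  idx <- (j - 1) * K + seq_len(K)
  Pjj <- P[idx, idx]
  Pjr <- P[idx, -idx, drop = FALSE]
  s_rest <- as.vector(t(S[-j, , drop = FALSE]))
  cov_j <- solve(Pjj)
  mean_j <- -cov_j %*% (Pjr %*% s_rest)
  list(mean = drop(mean_j), cov = cov_j)
}

# random symmetric graph without self-loops (may contain islands)
random_graph <- function(J, p_edge = 0.4) {
  A <- matrix(0L, J, J)
  for (a in seq_len(J - 1)) {
    for (b in (a + 1):J) {
      if (runif(1) < p_edge) A[a, b] <- A[b, a] <- 1L
    }
  }
  nbs <- lapply(seq_len(J), function(j) which(A[j, ] == 1L))
  suppressWarnings(adjacency_graph(nbs))
}

# rank by eigenvalue count
oracle_rank <- function(Q, tol = 1e-8) {
  ev <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  sum(ev > tol * max(abs(ev), 1))
}

# minimal valid participant data frame of n all-missing records
blank_records <- function(n) {
  as.data.frame(setNames(
    lapply(c("sbp", "dbp", "tc", "tg", "ldl", "hdl", "hba1c", "bmi"),
           function(x) rep(NA_real_, n)),
    c("sbp", "dbp", "tc", "tg", "ldl", "hdl", "hba1c", "bmi")))
}
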