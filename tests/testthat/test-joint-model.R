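# small random model instance for oracle comparisons
.random_instance <- function(n = 7, J = 4, K = 2, p = 3, miss = 0.15) {
  g <- lattice_graph(2, 2)
  if (J != 4) g <- lattice_graph(1, J)
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("x", 1:p)))
  district <- sample(seq_len(J), n, replace = TRUE)
  y <- matrix(rbinom(n * K, 1, 0.5), n, K)
  y[runif(n * K) < miss] <- NA
  covs <- as.data.frame(X)
  spec <- mcar_spec(y, district, g, covs,
                    stats::as.formula(paste("~", paste(colnames(X), collapse = "+"))))
  state <- mcar_init(spec)
  state$alpha <- rnorm(K)
  state$beta <- matrix(rnorm(p * K), p, K)
  state$S <- matrix(rnorm(J * K), J, K)
  state$V <- matrix(rnorm(J * K), J, K)
  list(spec = spec, state = state, g = g)
}

test_that("linear predictor matches closed forms and the scalar-loop oracle", {
  set.seed(31)
  inst <- .random_instance()
  st0 <- inst$state
  st0$alpha[] <- 0; st0$beta[] <- 0; st0$S[] <- 0; st0$V[] <- 0
  expect_equal(unique(as.vector(stats::plogis(linear_predictor(st0, inst$spec)))),
               0.5)
  st0$alpha[] <- log(3)
  expect_equal(as.vector(stats::plogis(linear_predictor(st0, inst$spec))),
               rep(0.75, inst$spec$n * inst$spec$K))

  eta <- linear_predictor(inst$state, inst$spec)
  eta_oracle <- oracle_linear_predictor(inst$state$alpha, inst$state$beta,
                                        inst$spec$X, inst$state$S,
                                        inst$state$V, inst$spec$district)
  expect_lt(max(abs(eta - eta_oracle)), 1e-12)
})

test_that("log-likelihood matches the brute-force cell sum and is stable at extremes", {
  set.seed(32)
  inst <- .random_instance(n = 5, K = 2)
  ll <- log_likelihood(inst$state, inst$spec)
  eta <- linear_predictor(inst$state, inst$spec)
  expect_lt(abs(ll - oracle_loglik(inst$spec$y, eta)), 1e-10)

  # all pi = 0.5 gives n_obs * log(0.5)
  st0 <- inst$state
  st0$alpha[] <- 0; st0$beta[] <- 0; st0$S[] <- 0; st0$V[] <- 0
  expect_equal(log_likelihood(st0, inst$spec),
               sum(inst$spec$obs) * log(0.5))

  # monotone in eta for a positive cell; finite at extreme eta
  g1 <- suppressWarnings(lattice_graph(1, 1))
  spec1 <- mcar_spec(matrix(1, 1, 1), 1L, g1)
  st <- mcar_init(spec1)
  lls <- sapply(c(-5, 0, 5, 20), function(a) {
    st$alpha[] <- a; log_likelihood(st, spec1)
  })
  expect_true(all(diff(lls) > 0))
  st$alpha[] <- 500 # no overflow at extreme linear predictors
  expect_true(is.finite(log_likelihood(st, spec1)))
  st$alpha[] <- -500
  expect_equal(log_likelihood(st, spec1), -500)
})

test_that("multivariate ICAR full conditional matches dense joint-Gaussian conditioning", {
  set.seed(33)
  g <- lattice_graph(2, 2)
  Q <- icar_structure(g)$Q
  for (K in c(1, 2, 3)) {
    A <- matrix(rnorm(K * K), K)
    Sigma <- crossprod(A) + diag(K)
    S <- matrix(rnorm(4 * K), 4, K)
    for (j in 1:4) {
      got <- micar_conditional(S, j, g, Sigma)
      want <- oracle_micar_conditional(S, j, Q, Sigma)
      expect_lt(max(abs(got$mean - want$mean)), 1e-10)
      expect_lt(max(abs(got$cov - want$cov)), 1e-10)
    }
  }
  # all-zero neighbours give a zero conditional mean; K=1 reduces to sigma^2/m
  S0 <- matrix(0, 4, 2)
  expect_equal(micar_conditional(S0, 1, g, diag(2))$mean, c(0, 0))
  uni <- micar_conditional(matrix(rnorm(4), 4, 1), 2, g, matrix(2.5, 1, 1))
  expect_equal(uni$cov[1, 1], 2.5 / g$n_neighbours[2])
  # islands are flagged with the effect pinned at zero
  gi <- suppressWarnings(adjacency_graph(list(2L, 1L, integer(0))))
  isl <- micar_conditional(matrix(rnorm(6), 3, 2), 3, gi, diag(2))
  expect_true(isl$island)
  expect_equal(isl$mean, c(0, 0))
})

test_that("Wishart precision update has the conjugate df and scale", {
  g <- lattice_graph(3, 3)
  ic <- icar_structure(g)
  K <- 2
  prior_scale <- diag(K)
  # null data: scale* equals the prior scale
  upd0 <- update_precision(matrix(0, 9, K), K, prior_scale, "structured",
                           icar = ic)
  expect_equal(upd0$scale, prior_scale)
  expect_equal(upd0$df, K + ic$rank)
  updv <- update_precision(matrix(0, 9, K), K, prior_scale, "unstructured")
  expect_equal(updv$df, K + 9)

  # structured cross-product is the edge-difference form S'QS
  set.seed(34)
  S <- matrix(rnorm(18), 9, K)
  upd <- update_precision(S, K, prior_scale, "structured", icar = ic)
  edge_cross <- matrix(0, K, K)
  for (j in 1:9) for (l in g$neighbours[[j]]) {
    if (l > j) {
      d <- S[j, ] - S[l, ]
      edge_cross <- edge_cross + tcrossprod(d)
    }
  }
  expect_equal(solve(upd$scale) - solve(prior_scale), edge_cross,
               tolerance = 1e-10)

  # K = 1 reduces to a Gamma draw on the scalar precision
  set.seed(35)
  u1 <- replicate(4000, update_precision(matrix(rnorm(9, sd = 0.5), 9, 1),
                                         1, diag(1), "unstructured")$precision[1, 1])
  expect_true(all(u1 > 0))
})

test_that("recentering zeroes column sums, shifts intercepts, and preserves the likelihood", {
  set.seed(36)
  inst <- .random_instance()
  st <- inst$state
  eta0 <- linear_predictor(st, inst$spec)
  ll0 <- log_likelihood(st, inst$spec)
  st2 <- recenter(st, inst$g)
  expect_lt(max(abs(colSums(st2$S))), 1e-10)
  expect_lt(max(abs(linear_predictor(st2, inst$spec) - eta0)), 1e-12)
  expect_equal(log_likelihood(st2, inst$spec), ll0, tolerance = 1e-12)
  # already centred: unchanged; constant column: folded into alpha
  st3 <- recenter(st2, inst$g)
  expect_equal(st3$S, st2$S, tolerance = 1e-12)
  stc <- st
  stc$S[] <- 0; stc$S[, 1] <- 3
  stc2 <- recenter(stc, inst$g)
  expect_equal(unname(stc2$S[, 1]), rep(0, 4))
  expect_equal(stc2$alpha[1], st$alpha[1] + 3)
})

test_that("the Gibbs sweep and full runs are deterministic under a fixed seed", {
  set.seed(37)
  inst <- .random_instance(n = 40)
  set.seed(101); s1 <- mcmc_step(inst$state, inst$spec)
  set.seed(101); s2 <- mcmc_step(inst$state, inst$spec)
  expect_identical(s1, s2)

  fit1 <- run_mcmc(inst$spec, chains = 2, iterations = 60, burnin = 20,
                   thin = 2, seed = 9)
  fit2 <- run_mcmc(inst$spec, chains = 2, iterations = 60, burnin = 20,
                   thin = 2, seed = 9)
  expect_identical(fit1$alpha, fit2$alpha)
  expect_identical(fit1$Sigma_s, fit2$Sigma_s)
  expect_error(run_mcmc(inst$spec, iterations = 10, burnin = 20), "burnin")
})

test_that("a district with no participants draws its unstructured effect from the prior", {
  set.seed(38)
  g <- lattice_graph(2, 3)
  n <- 300
  district <- sample(1:5, n, replace = TRUE) # district 6 never sampled
  y <- matrix(rbinom(n * 2, 1, 0.4), n, 2)
  spec <- mcar_spec(y, district, g)
  state <- mcar_init(spec)
  V6 <- matrix(NA_real_, 800, 2)
  Svs <- array(NA_real_, c(800, 2, 2))
  for (it in 1:800) {
    state <- mcmc_step(state, spec)
    V6[it, ] <- state$V[6, ]
    Svs[it, , ] <- state$Sigma_v
  }
  keep <- 101:800
  emp <- cov(V6[keep, ])
  avg_Sigma <- apply(Svs[keep, , ], c(2, 3), mean)
  # prior-only draw: empirical covariance tracks the sampled Sigma_v
  expect_lt(abs(emp[1, 1] - avg_Sigma[1, 1]), 0.5 * avg_Sigma[1, 1] + 0.05)
  expect_lt(abs(mean(V6[keep, 1])), 3 * sd(V6[keep, 1]) / sqrt(effective_size(V6[keep, 1])) + 0.05)
})

test_that("posterior summaries transform draws correctly", {
  set.seed(39)
  inst <- .random_instance(n = 30)
  fit <- run_mcmc(inst$spec, chains = 2, iterations = 40, burnin = 10,
                  thin = 1, seed = 2)
  # constant beta draws map to the exact OR
  fit$beta[, , ] <- log(2)
  tab <- posterior_or_table(fit)
  expect_true(all(abs(tab$or[!tab$reference] - 2) < 1e-12))
  fit$beta[, , ] <- 0
  tab0 <- posterior_or_table(fit)
  expect_true(all(tab0$or == 1 & tab0$ci_low == 1 & tab0$ci_high == 1))

  fit$S[, , ] <- 0; fit$V[, , ] <- 0
  so <- spatial_odds(fit)
  expect_true(all(so$odds == 1))
  expect_true(all(so$exceedance == 0)) # P(U > 0) with U identically 0

  # median of exp equals exp of median, draw-wise (monotone transform)
  u <- rnorm(501)
  expect_equal(median(exp(u)), exp(median(u)))
})

test_that("factor covariates get reference rows in the OR table", {
  set.seed(40)
  g <- lattice_graph(2, 2)
  n <- 120
  covs <- data.frame(grp = factor(sample(c("a", "b", "c"), n, TRUE),
                                  levels = c("a", "b", "c")))
  y <- matrix(rbinom(n, 1, 0.4), ncol = 1, dimnames = list(NULL, "hbp"))
  spec <- mcar_spec(y, sample(1:4, n, TRUE), g, covs, ~ grp)
  fit <- run_mcmc(spec, chains = 2, iterations = 60, burnin = 20, thin = 2,
                  seed = 4)
  tab <- posterior_or_table(fit)
  expect_equal(tab$level[tab$reference], "a")
  expect_setequal(tab$level, c("a", "b", "c"))
})
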