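#' @title Joint multivariate CAR convolution logistic model
#' @description
#' For participant `i` living in district `j(i)` and condition `k = 1..K`,
#' the binary outcome `Y_ik` is Bernoulli with
#' `logit(pi_ik) = alpha_k + x_i' beta_k + S_{j(i),k} + V_{j(i),k}`.
#' The district effect decomposes, convolution-style, into a spatially
#' structured part `S` with a multivariate intrinsic CAR prior (cross-disease
#' covariance `Sigma_s`, shared adjacency graph, sum-to-zero constraint per
#' disease) and an exchangeable part `V ~ MVN(0, Sigma_v)` per district.
#' Priors: flat (improper uniform) on the intercepts `alpha_k`, independent
#' `Normal(0, 10^3)` on the fixed effects, and Wishart(`K`, identity scale)
#' on both precision matrices `Sigma_s^{-1}` and `Sigma_v^{-1}`.
#'
#' Inference is by Gibbs sampling with Polya-Gamma augmentation: each
#' observed Bernoulli-logit cell receives a latent `omega_ik ~ PG(1, eta_ik)`
#' making every full conditional Gaussian (or Wishart), so the sweep is an
#' exact Gibbs sampler with no tuning. Missing outcome cells simply drop
#' their latent draw and likelihood term.
#' @name joint_spatial_model
NULL

#' Polya-Gamma random draws
#'
#' Exact draws from PG(1, z) by the alternating-series rejection sampler,
#' vectorised over `z`. `E[PG(1, z)] = tanh(z/2) / (2 z)` (`1/4` at `z = 0`).
#'
#' @param z numeric vector of tilting parameters.
#' @return numeric vector of PG(1, z) draws.
#' @export
rpolyagamma <- function(z) {
  rpg_devroye(as.numeric(z))
}

#' Prior settings for the joint model
#'
#' @param K number of conditions.
#' @param beta_var fixed-effect prior variance (default 1000).
#' @param df_s,df_v Wishart degrees of freedom for the structured /
#'   unstructured precision matrices (default `K`, the minimal proper value).
#' @param scale_s,scale_v Wishart scale matrices (default identity).
#' @return list of prior settings.
#' @export
mcar_prior <- function(K, beta_var = 1000, df_s = K, df_v = K,
                       scale_s = diag(K), scale_v = diag(K)) {
  list(beta_var = beta_var, df_s = df_s, df_v = df_v,
       scale_s = scale_s, scale_v = scale_v)
}

#' Specify a joint multivariate spatial logistic model
#'
#' @param y n x K binary outcome matrix (`{1, 0, NA}`); column names name
#'   the conditions.
#' @param district integer district index per participant, in `1..J`.
#' @param graph an [adjacency_graph] over the `J` districts.
#' @param covariates data frame of covariates (used with `formula`).
#' @param formula one-sided formula selecting/coding covariates, e.g.
#'   `~ sex + age_group`; the intercept is handled separately (flat prior)
#'   and removed from the design matrix.
#' @param prior output of [mcar_prior].
#' @param include_structured,include_unstructured switch either random-effect
#'   component off (its effects stay fixed at zero), giving the unstructured-
#'   only, ICAR-only or purely fixed-effects reductions of the model.
#' @return object of class `mcar_spec`.
#' @export
mcar_spec <- function(y, district, graph, covariates = NULL, formula = NULL,
                      prior = NULL, include_structured = TRUE,
                      include_unstructured = TRUE) {
  y <- as.matrix(y)
  storage.mode(y) <- "double"
  if (is.null(colnames(y))) colnames(y) <- paste0("disease", seq_len(ncol(y)))
  if (any(!(y %in% c(0, 1)) & !is.na(y))) stop("y must be in {0, 1, NA}")
  K <- ncol(y); n <- nrow(y)
  stopifnot(inherits(graph, "adjacency_graph"))
  district <- as.integer(district)
  if (length(district) != n) stop("district must align with rows of y")
  if (any(is.na(district)) || any(district < 1L) ||
      any(district > graph$n_areas))
    stop("district indices must lie in 1..J")

  if (!is.null(formula)) {
    if (is.null(covariates)) stop("formula given without covariates")
    mf <- stats::model.frame(formula, covariates, na.action = stats::na.fail)
    X <- stats::model.matrix(formula, mf)
    xlevels <- stats::.getXlevels(stats::terms(formula, data = covariates), mf)
    asgn <- attr(X, "assign")
    terms_lab <- attr(stats::terms(formula, data = covariates), "term.labels")
    keep <- which(colnames(X) != "(Intercept)")
    term_of <- terms_lab[asgn[keep]]
    X <- X[, keep, drop = FALSE]
  } else {
    X <- matrix(0, n, 0)
    xlevels <- list(); term_of <- character(0)
  }
  if (nrow(X) != n) stop("covariates must align with rows of y")
  if (is.null(prior)) prior <- mcar_prior(K)
  ic <- icar_structure(graph)
  structure(
    list(y = y, X = X, district = district, graph = graph, icar = ic,
         n = n, K = K, J = graph$n_areas, p = ncol(X),
         diseases = colnames(y), prior = prior,
         include_structured = include_structured,
         include_unstructured = include_unstructured,
         xlevels = xlevels, term_of = term_of,
         obs = !is.na(y)),
    class = "mcar_spec")
}

#' @export
print.mcar_spec <- function(x, ...) {
  cat(sprintf("mcar_spec: %d participants, %d districts, %d conditions, %d covariate columns\n",
              x$n, x$J, x$K, x$p))
  invisible(x)
}

#' Initial model state
#'
#' Empirical-logit intercepts, zero effects, identity-scaled covariances.
#' @param spec an [mcar_spec].
#' @return list with `alpha`, `beta`, `S`, `V`, `Sigma_s`, `Sigma_v`.
#' @export
mcar_init <- function(spec) {
  pbar <- pmin(pmax(colMeans(spec$y, na.rm = TRUE), 0.01), 0.99)
  list(alpha = stats::qlogis(pbar),
       beta = matrix(0, spec$p, spec$K,
                     dimnames = list(colnames(spec$X), spec$diseases)),
       S = matrix(0, spec$J, spec$K),
       V = matrix(0, spec$J, spec$K),
       Sigma_s = diag(spec$K) * 0.1,
       Sigma_v = diag(spec$K) * 0.1)
}

#' Linear predictor of the joint model
#'
#' `eta_ik = alpha_k + x_i' beta_k + S_{j(i),k} + V_{j(i),k}`.
#'
#' @param state model state (see [mcar_init]).
#' @param spec an [mcar_spec].
#' @return n x K matrix of linear predictors.
#' @export
linear_predictor <- function(state, spec) {
  if (length(state$alpha) != spec$K || nrow(state$beta) != spec$p)
    stop("state dimensions inconsistent with spec")
  eta <- matrix(state$alpha, spec$n, spec$K, byrow = TRUE)
  if (spec$p > 0) eta <- eta + spec$X %*% state$beta
  eta + state$S[spec$district, , drop = FALSE] +
    state$V[spec$district, , drop = FALSE]
}

.log1pexp <- function(x) {
  # numerically stable log(1 + exp(x))
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x <= 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

#' Bernoulli log-likelihood of the joint model
#'
#' Sum over observed cells of `y * eta - log(1 + exp(eta))`, computed stably
#' for extreme linear predictors; missing cells contribute zero.
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood.
#' @export
log_likelihood <- function(state, spec) {
  eta <- linear_predictor(state, spec)
  obs <- spec$obs
  sum(spec$y[obs] * eta[obs] - .log1pexp(eta[obs]))
}

#' Full conditional of one district's structured effects
#'
#' Under the intrinsic multivariate CAR prior, the K-vector `S_j` given all
#' other rows is Gaussian with mean the average of the neighbouring rows and
#' covariance `Sigma_s / m_j`. For an island (`m_j = 0`) the conditional is
#' undefined and the effect is fixed at zero.
#'
#' @param S J x K matrix of structured effects.
#' @param j district index.
#' @param graph an [adjacency_graph].
#' @param Sigma_s K x K cross-condition covariance.
#' @return list with `mean` (K-vector), `cov` (K x K) and `island` flag.
#' @export
micar_conditional <- function(S, j, graph, Sigma_s) {
  stopifnot(inherits(graph, "adjacency_graph"))
  m <- graph$n_neighbours[j]
  K <- ncol(S)
  if (m == 0L)
    return(list(mean = rep(0, K), cov = matrix(0, K, K), island = TRUE))
  nb <- graph$neighbours[[j]]
  list(mean = colMeans(S[nb, , drop = FALSE]), cov = Sigma_s / m,
       island = FALSE)
}

#' Conjugate Wishart update of a random-effect precision matrix
#'
#' Draws `Sigma^{-1}` from its Wishart full conditional. For the structured
#' (ICAR) effects the data cross-product is `S' Q S` (the edge-difference
#' form) and the degrees of freedom increase by `rank(Q) = J - c`; for the
#' unstructured effects it is `V' V` with increment `J`.
#'
#' @param effects J x K matrix of current effects.
#' @param prior_df prior Wishart degrees of freedom.
#' @param prior_scale prior Wishart scale matrix.
#' @param kind `"structured"` or `"unstructured"`.
#' @param icar an [icar_structure] (required for `kind = "structured"`).
#' @return list: `precision` (the draw), `df` and `scale` of the full
#'   conditional.
#' @export
update_precision <- function(effects, prior_df, prior_scale,
                             kind = c("structured", "unstructured"),
                             icar = NULL) {
  kind <- match.arg(kind)
  effects <- as.matrix(effects)
  J <- nrow(effects)
  if (kind == "structured") {
    if (is.null(icar)) stop("structured update needs the ICAR structure")
    cross <- crossprod(effects, icar$Q %*% effects)
    df <- prior_df + icar$rank
  } else {
    cross <- crossprod(effects)
    df <- prior_df + J
  }
  cross <- (cross + t(cross)) / 2
  scale <- tryCatch(solve(solve(prior_scale) + cross),
                    error = function(e)
                      stop("precision update scale is singular: ",
                           conditionMessage(e)))
  scale <- (scale + t(scale)) / 2
  ev <- eigen(scale, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0))
    stop(sprintf("non-SPD scale in %s precision update (min eigenvalue %g)",
                 kind, min(ev)))
  W <- stats::rWishart(1, df, scale)[, , 1]
  list(precision = (W + t(W)) / 2, df = df, scale = scale)
}

#' Recenter structured effects and fold the means into the intercepts
#'
#' Enforces the sum-to-zero identification constraint: each condition's
#' column of `S` is centred over the non-island districts and the removed
#' mean is added to that condition's intercept, leaving the linear predictor
#' unchanged.
#'
#' @param state model state.
#' @param graph an [adjacency_graph].
#' @return recentred state.
#' @export
recenter <- function(state, graph) {
  J <- nrow(state$S)
  active <- setdiff(seq_len(J), graph$islands)
  mu <- colMeans(state$S[active, , drop = FALSE])
  state$S[active, ] <- sweep(state$S[active, , drop = FALSE], 2, mu)
  state$alpha <- state$alpha + mu
  state
}

# draw from N(P^{-1} b, P^{-1}) given precision P and linear term b
.rmvnorm_prec <- function(b, P) {
  U <- tryCatch(chol(P), error = function(e)
    stop("Gaussian full-conditional precision not positive definite: ",
         conditionMessage(e)))
  mu <- backsolve(U, backsolve(U, b, transpose = TRUE))
  drop(mu + backsolve(U, stats::rnorm(length(b))))
}

#' One full Gibbs sweep
#'
#' Sweep order: (1) Polya-Gamma latents for every observed cell; (2) per
#' condition, a joint Gaussian block update of (intercept, fixed effects);
#' (3) single-site systematic-scan update of each district's structured
#' K-vector `S_j`, combining the multivariate ICAR conditional with the
#' Gaussianised likelihood of that district's participants; (4) the same for
#' the unstructured `V_j` with its MVN(0, Sigma_v) prior; (5) recentering;
#' (6) Wishart updates of both precision matrices. The likelihood invariance
#' of recentering is asserted every sweep.
#'
#' @param state model state.
#' @param spec an [mcar_spec].
#' @param check assert recentering invariance (default TRUE).
#' @return updated state.
#' @export
mcmc_step <- function(state, spec, check = TRUE) {
  n <- spec$n; K <- spec$K; J <- spec$J; p <- spec$p
  obs <- spec$obs
  dist <- spec$district
  eta <- linear_predictor(state, spec)
  omega <- matrix(0, n, K)
  omega[obs] <- rpolyagamma(eta[obs])
  kappa <- ifelse(obs, spec$y - 0.5, 0)

  # (2) block update of (alpha_k, beta_k)
  U_area <- state$S[dist, , drop = FALSE] + state$V[dist, , drop = FALSE]
  D <- cbind(`(Intercept)` = 1, spec$X)
  B0 <- diag(c(0, rep(1 / spec$prior$beta_var, p)), p + 1)
  for (k in seq_len(K)) {
    rows <- obs[, k]
    w <- omega[rows, k]
    Dk <- D[rows, , drop = FALSE]
    r <- kappa[rows, k] - w * U_area[rows, k]
    P <- crossprod(Dk * sqrt(w)) + B0
    bb <- drop(crossprod(Dk, r))
    th <- .rmvnorm_prec(bb, P)
    state$alpha[k] <- th[1]
    if (p > 0) state$beta[, k] <- th[-1]
  }

  # per-area likelihood summaries given the new fixed effects
  fixed <- matrix(state$alpha, n, K, byrow = TRUE)
  if (p > 0) fixed <- fixed + spec$X %*% state$beta
  Wj <- rowsum(omega, dist)                    # sum of omegas per area
  Rj <- rowsum(kappa - omega * fixed, dist)    # kappa - omega*(alpha+Xb)
  present <- as.integer(rownames(Wj))
  Wfull <- matrix(0, J, K); Rfull <- matrix(0, J, K)
  Wfull[present, ] <- Wj; Rfull[present, ] <- Rj

  # (3) structured effects, systematic single-site scan
  if (spec$include_structured) {
    Sig_s_inv <- chol2inv(chol(state$Sigma_s))
    for (j in seq_len(J)) {
      m <- spec$graph$n_neighbours[j]
      if (m == 0L) { state$S[j, ] <- 0; next }
      nbmean <- colMeans(state$S[spec$graph$neighbours[[j]], , drop = FALSE])
      P <- m * Sig_s_inv
      bb <- drop(P %*% nbmean) + Rfull[j, ] - Wfull[j, ] * state$V[j, ]
      diag(P) <- diag(P) + Wfull[j, ]
      state$S[j, ] <- .rmvnorm_prec(bb, P)
    }
  }

  # (4) unstructured effects
  if (spec$include_unstructured) {
    Sig_v_inv <- chol2inv(chol(state$Sigma_v))
    for (j in seq_len(J)) {
      P <- Sig_v_inv
      bb <- Rfull[j, ] - Wfull[j, ] * state$S[j, ]
      diag(P) <- diag(P) + Wfull[j, ]
      state$V[j, ] <- .rmvnorm_prec(bb, P)
    }
  }

  # (5) recenter; the linear predictor must be unchanged
  if (spec$include_structured) {
    if (check) eta_before <- linear_predictor(state, spec)
    state <- recenter(state, spec$graph)
    if (check) {
      if (max(abs(linear_predictor(state, spec) - eta_before)) > 1e-10)
        stop("recentering changed the linear predictor")
    }
  }

  # (6) precision matrices
  if (spec$include_structured) {
    upd <- update_precision(state$S, spec$prior$df_s, spec$prior$scale_s,
                            "structured", icar = spec$icar)
    state$Sigma_s <- chol2inv(chol(upd$precision))
  }
  if (spec$include_unstructured) {
    upd <- update_precision(state$V, spec$prior$df_v, spec$prior$scale_v,
                            "unstructured")
    state$Sigma_v <- chol2inv(chol(upd$precision))
  }
  state
}

#' Run the MCMC sampler
#'
#' Runs `chains` independent chains (differing only by RNG stream) of the
#' Gibbs sweep, discards `burnin` iterations, retains every `thin`-th draw,
#' and computes split potential-scale-reduction and effective sample size for
#' the monitored scalar parameters (intercepts, fixed effects, and the
#' unique elements of both covariance matrices).
#'
#' @param spec an [mcar_spec].
#' @param chains number of chains (default 2).
#' @param iterations total sweeps per chain (default 10000).
#' @param burnin discarded initial sweeps (default 5000).
#' @param thin retention stride (default 5).
#' @param seed integer seed; chain `c` uses `seed + (c-1) * 100003`.
#' @param verbose print progress.
#' @return object of class `mcar_samples`: draw arrays `alpha` (D x K),
#'   `beta` (D x p x K), `S`, `V` (D x J x K), `Sigma_s`, `Sigma_v`
#'   (D x K x K), `chain` id per draw, diagnostics (`rhat`, `ess`,
#'   `converged`) and run metadata.
#' @export
run_mcmc <- function(spec, chains = 2, iterations = 10000, burnin = 5000,
                     thin = 5, seed = 1, verbose = FALSE) {
  stopifnot(inherits(spec, "mcar_spec"))
  if (burnin >= iterations) stop("burnin must be smaller than iterations")
  if (thin < 1) stop("thin must be >= 1")
  kept_idx <- seq(burnin + thin, iterations, by = thin)
  D <- length(kept_idx)
  K <- spec$K; J <- spec$J; p <- spec$p

  res <- list(
    alpha = array(NA_real_, c(D * chains, K),
                  dimnames = list(NULL, spec$diseases)),
    beta = array(NA_real_, c(D * chains, p, K),
                 dimnames = list(NULL, colnames(spec$X), spec$diseases)),
    S = array(NA_real_, c(D * chains, J, K)),
    V = array(NA_real_, c(D * chains, J, K)),
    Sigma_s = array(NA_real_, c(D * chains, K, K)),
    Sigma_v = array(NA_real_, c(D * chains, K, K)),
    chain = rep(seq_len(chains), each = D))

  for (ch in seq_len(chains)) {
    set.seed(seed + (ch - 1L) * 100003L)
    state <- mcar_init(spec)
    kept <- 0L
    for (it in seq_len(iterations)) {
      state <- mcmc_step(state, spec)
      if (!all(is.finite(state$alpha)) || !all(is.finite(state$S)))
        stop(sprintf("divergent state at chain %d iteration %d", ch, it))
      if (it > burnin && (it - burnin) %% thin == 0L) {
        kept <- kept + 1L
        row <- (ch - 1L) * D + kept
        res$alpha[row, ] <- state$alpha
        if (p > 0) res$beta[row, , ] <- state$beta
        res$S[row, , ] <- state$S
        res$V[row, , ] <- state$V
        res$Sigma_s[row, , ] <- state$Sigma_s
        res$Sigma_v[row, , ] <- state$Sigma_v
      }
      if (verbose && it %% 1000 == 0)
        message(sprintf("chain %d: %d / %d", ch, it, iterations))
    }
  }

  res$meta <- list(K = K, J = J, p = p, diseases = spec$diseases,
                   codes = spec$graph$codes, xlevels = spec$xlevels,
                   term_of = spec$term_of, coef_names = colnames(spec$X),
                   include_structured = spec$include_structured,
                   include_unstructured = spec$include_unstructured)
  res$config <- list(chains = chains, iterations = iterations,
                     burnin = burnin, thin = thin, seed = seed,
                     draws_per_chain = D)
  class(res) <- "mcar_samples"

  if (chains >= 2) {
    mon <- .monitored_draws(res)
    res$rhat <- vapply(mon, function(m)
      gelman_rubin(matrix(m, ncol = chains)), numeric(1))
    res$ess <- vapply(mon, function(m)
      effective_size(matrix(m, ncol = chains)), numeric(1))
    res$converged <- all(res$rhat < 1.1, na.rm = TRUE)
  }
  res
}

# monitored scalar traces: alpha, beta, unique Sigma elements
.monitored_draws <- function(samples) {
  K <- samples$meta$K; p <- samples$meta$p
  out <- list()
  for (k in seq_len(K)) {
    out[[paste0("alpha[", samples$meta$diseases[k], "]")]] <-
      samples$alpha[, k]
    for (q in seq_len(p))
      out[[paste0("beta[", samples$meta$coef_names[q], ",",
                  samples$meta$diseases[k], "]")]] <- samples$beta[, q, k]
  }
  for (a in seq_len(K)) for (b in a:K) {
    if (samples$meta$include_structured)
      out[[paste0("Sigma_s[", a, ",", b, "]")]] <- samples$Sigma_s[, a, b]
    if (samples$meta$include_unstructured)
      out[[paste0("Sigma_v[", a, ",", b, "]")]] <- samples$Sigma_v[, a, b]
  }
  out
}

#' @export
print.mcar_samples <- function(x, ...) {
  cat(sprintf("mcar_samples: %d draws (%d chain(s) x %d), %d conditions, %d districts\n",
              nrow(x$alpha), x$config$chains, x$config$draws_per_chain,
              x$meta$K, x$meta$J))
  if (!is.null(x$rhat))
    cat(sprintf("max split R-hat %.3f (%s)\n", max(x$rhat, na.rm = TRUE),
                if (isTRUE(x$converged)) "converged" else "NOT converged"))
  invisible(x)
}

#' Posterior odds-ratio table
#'
#' Posterior median and equal-tailed 95% credible interval of `exp(beta)` for
#' every covariate column and condition, with reference levels of factor
#' covariates reported as 1.00.
#'
#' @param samples an `mcar_samples` object.
#' @param conf_level credible level (default 0.95).
#' @return data frame: `disease`, `term`, `level`, `or`, `ci_low`, `ci_high`,
#'   `reference`.
#' @export
posterior_or_table <- function(samples, conf_level = 0.95) {
  stopifnot(inherits(samples, "mcar_samples"))
  meta <- samples$meta
  if (meta$p == 0) stop("model has no sampled covariate effects")
  a <- (1 - conf_level) / 2
  rows <- list()
  for (k in seq_len(meta$K)) {
    for (term in unique(meta$term_of)) {
      ref <- meta$xlevels[[term]]
      if (!is.null(ref)) {
        rows[[length(rows) + 1L]] <- data.frame(
          disease = meta$diseases[k], term = term, level = ref[1],
          or = 1, ci_low = 1, ci_high = 1, reference = TRUE)
      }
      for (q in which(meta$term_of == term)) {
        dr <- exp(samples$beta[, q, k])
        lvl <- sub(paste0("^", term), "", meta$coef_names[q])
        if (!nzchar(lvl)) lvl <- meta$coef_names[q]
        rows[[length(rows) + 1L]] <- data.frame(
          disease = meta$diseases[k], term = term, level = lvl,
          or = stats::median(dr),
          ci_low = stats::quantile(dr, a, names = FALSE),
          ci_high = stats::quantile(dr, 1 - a, names = FALSE),
          reference = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Posterior spatial odds per district and condition
#'
#' Summaries of `exp(U_jk) = exp(S_jk + V_jk)`, the multiplicative excess
#' odds of condition `k` attributable to residing in district `j` after
#' covariate adjustment, plus the exceedance probability `P(exp(U) > 1)`.
#'
#' @param samples an `mcar_samples` object.
#' @param conf_level credible level (default 0.95).
#' @return data frame: `district`, `code`, `disease`, `odds`, `ci_low`,
#'   `ci_high`, `exceedance`.
#' @export
spatial_odds <- function(samples, conf_level = 0.95) {
  stopifnot(inherits(samples, "mcar_samples"))
  meta <- samples$meta
  a <- (1 - conf_level) / 2
  rows <- list()
  for (k in seq_len(meta$K)) {
    U <- samples$S[, , k] + samples$V[, , k]
    for (j in seq_len(meta$J)) {
      u <- U[, j]
      rows[[length(rows) + 1L]] <- data.frame(
        district = j, code = meta$codes[j], disease = meta$diseases[k],
        odds = exp(stats::median(u)),
        ci_low = exp(stats::quantile(u, a, names = FALSE)),
        ci_high = exp(stats::quantile(u, 1 - a, names = FALSE)),
        exceedance = mean(u > 0))
    }
  }
  do.call(rbind, rows)
}
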