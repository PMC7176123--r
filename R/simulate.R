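#' @title Synthetic population generator
#' @description
#' Generates a survey-like population from the joint spatial model itself, so
#' every pipeline stage can be validated against known ground truth. The
#' generator is the exact dual of the fitting model: the same linear
#' predictor, the same convolution decomposition of district effects, and an
#' intrinsic multivariate CAR simulated spectrally on the sum-to-zero
#' subspace (the only construction consistent with the improper fitting
#' prior). Defaults emulate the structure of a national examination survey:
#' 52 districts, per-district sample sizes lognormal with median 277 and mean
#' 346 truncated to [22, 1625], four conditions with marginal prevalences
#' 0.286 (hypertension), 0.054 (IHD), 0.018 (stroke) and 0.531
#' (dyslipidaemia), and covariate category frequencies matching the survey's
#' socio-demographic table.
#' @name synthetic_data
NULL

.default_covariate_freqs <- function() {
  list(
    sex = c(female = 0.583, male = 0.417),
    age_group = c("15-24" = 0.177, "25-34" = 0.150, "35-44" = 0.149,
                  "45-54" = 0.196, "55-64" = 0.171, "65+" = 0.157),
    education = c(no_school = 0.103, primary = 0.236, secondary = 0.357,
                  matric = 0.205, higher = 0.099),
    race = c(african = 0.796, white = 0.065, coloured = 0.110,
             indian_asian = 0.029),
    locality = c(urban_formal = 0.550, urban_informal = 0.085,
                 rural_tribal = 0.286, rural_formal = 0.079),
    smoking = c(never = 0.775, ex_smoker = 0.189, current = 0.036),
    alcohol = c(never = 0.756, current = 0.244),
    wealth_quintile = c(Q1 = 0.210, Q2 = 0.191, Q3 = 0.205, Q4 = 0.206,
                        Q5 = 0.188),
    diabetes = c(no = 0.85, yes = 0.15),
    bmi_class = c(normal = 0.357, underweight = 0.051, overweight = 0.592))
}

# default true log-odds effects, qualitatively emulating the fitted gradients:
# strong age gradient for hypertension, diabetes raising all conditions,
# adiposity raising hypertension and dyslipidaemia
.default_true_beta <- function(diseases, coef_names) {
  full <- list(
    hbp = c(sexmale = -0.2, "age_group25-34" = 0.55, "age_group35-44" = 1.35,
            "age_group45-54" = 2.2, "age_group55-64" = 2.8,
            "age_group65+" = 3.3, diabetesyes = 1.0,
            bmi_classunderweight = -0.35, bmi_classoverweight = 0.55),
    ihd = c(sexmale = -0.35, "age_group25-34" = 0.8, "age_group35-44" = 1.2,
            "age_group45-54" = 1.25, "age_group55-64" = 1.45,
            "age_group65+" = 1.6, diabetesyes = 0.6,
            bmi_classunderweight = 0.25, bmi_classoverweight = 0.1),
    stroke = c(sexmale = -0.1, "age_group25-34" = 0.75, "age_group35-44" = 1.5,
               "age_group45-54" = 1.55, "age_group55-64" = 2.0,
               "age_group65+" = 2.4, diabetesyes = 0.3,
               bmi_classunderweight = 0.1, bmi_classoverweight = 0.1),
    dyslip = c(sexmale = -0.2, "age_group25-34" = 0.15, "age_group35-44" = 0.3,
               "age_group45-54" = 0.5, "age_group55-64" = 0.4,
               "age_group65+" = 0.3, diabetesyes = 0.55,
               bmi_classunderweight = -0.45, bmi_classoverweight = 0.65))
  beta <- matrix(0, length(coef_names), length(diseases),
                 dimnames = list(coef_names, diseases))
  for (d in diseases) {
    if (!d %in% names(full)) next
    b <- full[[d]]
    common <- intersect(names(b), coef_names)
    beta[common, d] <- b[common]
  }
  beta
}

.exchangeable_cov <- function(K, variance, correlation) {
  S <- matrix(variance * correlation, K, K)
  diag(S) <- variance
  S
}

#' Generator configuration
#'
#' All study conditions of the emulated survey live here: geography, district
#' sample-size law, condition set with target marginal prevalences, true
#' fixed effects, and the two random-effect covariances. The lognormal
#' sample-size law is calibrated from the reported median (277, fixing the
#' log-mean) and mean (346, fixing the log-sd), truncated to the reported
#' range [22, 1625].
#'
#' @param graph an [adjacency_graph]; default a 4 x 13 rook lattice standing
#'   in for the 52-district map.
#' @param diseases subset of `c("hbp", "ihd", "stroke", "dyslip")` (or any
#'   names, with `prevalence`/`beta` supplied).
#' @param prevalence named target marginal prevalences.
#' @param beta true fixed-effect matrix (coefficient x disease); default a
#'   realistic age/diabetes/BMI effect pattern, including the defaults'
#'   formula coding.
#' @param formula covariate formula shared by generator and model.
#' @param Sigma_s,Sigma_v cross-condition covariances of the structured /
#'   unstructured district effects; defaults are exchangeable with positive
#'   correlation (variance 0.09, correlation 0.4 structured; 0.04 and 0.3
#'   unstructured).
#' @param size_meanlog,size_sdlog,size_range district sample-size law.
#' @param covariate_freqs named list of category frequencies.
#' @param sampi optional district deprivation table from
#'   [make_district_sampi]; when given, `sampi_quintile` becomes available
#'   as a district-level covariate in `formula`.
#' @param biomarker_rate probability a participant consents to biomarker
#'   measurement (drives the second, differential weight column).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(graph = NULL,
                             diseases = c("hbp", "ihd", "stroke", "dyslip"),
                             prevalence = c(hbp = 0.286, ihd = 0.054,
                                            stroke = 0.018, dyslip = 0.531),
                             beta = NULL,
                             formula = ~ sex + age_group + diabetes + bmi_class,
                             Sigma_s = NULL, Sigma_v = NULL,
                             size_meanlog = log(277),
                             size_sdlog = sqrt(2 * log(346 / 277)),
                             size_range = c(22, 1625),
                             covariate_freqs = .default_covariate_freqs(),
                             sampi = NULL,
                             biomarker_rate = 0.66) {
  if (is.null(graph)) graph <- lattice_graph(4, 13)
  K <- length(diseases)
  prevalence <- prevalence[diseases]
  if (any(is.na(prevalence)))
    stop("a target prevalence is needed for every disease")
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("target prevalences must lie strictly in (0, 1)")
  if (is.null(Sigma_s)) Sigma_s <- .exchangeable_cov(K, 0.09, 0.4)
  if (is.null(Sigma_v)) Sigma_v <- .exchangeable_cov(K, 0.04, 0.3)
  # coefficient names implied by the formula under the default frequencies
  n0 <- max(lengths(covariate_freqs), if (!is.null(sampi)) 5L)
  protodata <- as.data.frame(lapply(covariate_freqs, function(f)
    factor(rep_len(names(f), n0), levels = names(f))))
  if (!is.null(sampi)) {
    stopifnot(is.data.frame(sampi), nrow(sampi) == graph$n_areas)
    protodata$sampi_quintile <- factor(rep_len(paste0("SAMPI", 1:5), n0),
                                       levels = paste0("SAMPI", 1:5))
  }
  coef_names <- colnames(stats::model.matrix(formula, protodata))
  coef_names <- setdiff(coef_names, "(Intercept)")
  if (is.null(beta)) beta <- .default_true_beta(diseases, coef_names)
  if (!identical(rownames(beta), coef_names) ||
      !identical(colnames(beta), diseases))
    stop("beta must be a coefficient x disease matrix matching the formula")
  structure(
    list(graph = graph, J = graph$n_areas, K = K, diseases = diseases,
         prevalence = prevalence, beta = beta, formula = formula,
         Sigma_s = Sigma_s, Sigma_v = Sigma_v,
         size_meanlog = size_meanlog, size_sdlog = size_sdlog,
         size_range = size_range, covariate_freqs = covariate_freqs,
         sampi = sampi, biomarker_rate = biomarker_rate),
    class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("generator_config: %d districts, %d conditions (%s)\n",
              x$J, x$K, paste(x$diseases, collapse = ", ")))
  invisible(x)
}

#' Simulate intrinsic multivariate CAR effects
#'
#' Spectral draw on the identified subspace: with `Q = E L E'` the
#' eigendecomposition of the ICAR structure matrix, coefficients on each
#' eigenvector with eigenvalue `lambda > 0` are drawn MVN(0, `Sigma_s /
#' lambda`); null-space directions (one per connected component) are omitted,
#' so each column of the result sums to zero within every component and
#' island rows are exactly zero.
#'
#' @param graph an [adjacency_graph].
#' @param Sigma_s K x K SPD cross-condition covariance.
#' @return J x K matrix of structured effects.
#' @export
sample_micar_effects <- function(graph, Sigma_s) {
  Sigma_s <- as.matrix(Sigma_s)
  K <- ncol(Sigma_s)
  R <- tryCatch(chol(Sigma_s), error = function(e)
    stop("Sigma_s must be symmetric positive definite"))
  ic <- icar_structure(graph)
  eg <- eigen(ic$Q, symmetric = TRUE)
  pos <- which(eg$values > 1e-9 * max(eg$values))
  J <- graph$n_areas
  S <- matrix(0, J, K)
  for (m in pos) {
    z <- drop(crossprod(R, stats::rnorm(K))) / sqrt(eg$values[m])
    S <- S + tcrossprod(eg$vectors[, m], z)
  }
  S
}

.sample_district_sizes <- function(J, cfg) {
  sizes <- integer(J)
  for (j in seq_len(J)) {
    repeat {
      s <- round(stats::rlnorm(1, cfg$size_meanlog, cfg$size_sdlog))
      if (s >= cfg$size_range[1] && s <= cfg$size_range[2]) break
    }
    sizes[j] <- s
  }
  sizes
}

# back-fill raw fields so derive_outcomes() round-trips the generated Y
# exactly: one sufficient positive field per positive outcome, all-negative
# observed fields otherwise. A round-trip device, not a physiologic simulator.
.backfill_records <- function(Y, covs, self_sens = c(hbp = 0.45, dyslip = 0.066)) {
  n <- nrow(covs)
  rec <- covs
  gety <- function(d) if (d %in% colnames(Y)) Y[, d] else rep(0L, n)
  hbp <- gety("hbp"); ihd <- gety("ihd")
  stroke <- gety("stroke"); dys <- gety("dyslip")
  rec$sbp <- ifelse(hbp == 1, 150, 120)
  rec$dbp <- rep(70, n)
  rec$self_hbp <- as.integer(hbp == 1 &
                               stats::runif(n) < self_sens[["hbp"]])
  rec$hbp_medication <- rep(0L, n)
  rec$self_ihd <- as.integer(ihd)
  rec$self_stroke <- as.integer(stroke)
  rec$tc <- ifelse(dys == 1, 6.5, 5.0)
  rec$tg <- rep(1.0, n); rec$ldl <- rep(3.0, n); rec$hdl <- rep(1.5, n)
  rec$lipid_drugs <- rep(0L, n)
  rec$dyslip_diagnosis <- as.integer(dys == 1 &
                                       stats::runif(n) < self_sens[["dyslip"]])
  if (!is.null(covs$diabetes)) {
    diab <- as.integer(covs$diabetes == "yes")
    rec$hba1c <- ifelse(diab == 1, 7.0, 5.5)
    rec$diabetes_history <- rep(0L, n)
    rec$diabetes_treatment <- rep(0L, n)
  }
  if (!is.null(covs$bmi_class)) {
    rec$bmi <- c(normal = 22, underweight = 17,
                 overweight = 28)[as.character(covs$bmi_class)]
  }
  rec
}

#' Generate a synthetic survey population with known ground truth
#'
#' District sizes are drawn from the configured law; covariates from the
#' configured category frequencies; district effects `S` (multivariate ICAR)
#' and `V` (MVN) from their priors; intercepts are calibrated by root-finding
#' on the realised population so each condition's expected marginal
#' prevalence equals its target; outcomes are Bernoulli through the model's
#' own linear predictor. Raw clinical fields are back-filled so
#' [derive_outcomes] reproduces the generated outcome matrix exactly, and two
#' weight columns (interview, biomarker) realise the differential-weighting
#' workflow.
#'
#' @param config a [generator_config].
#' @param seed integer seed (full determinism given the seed).
#' @return list: `records` (participant data frame), `outcomes` (n x K 0/1
#'   matrix), `truth` (alpha, beta, S, V, Sigma_s, Sigma_v, district sizes,
#'   seed, config).
#' @export
generate_population <- function(config, seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  J <- config$J; K <- config$K
  sizes <- .sample_district_sizes(J, config)
  n <- sum(sizes)
  district <- rep(seq_len(J), sizes)

  covs <- as.data.frame(lapply(config$covariate_freqs, function(f) {
    factor(sample(names(f), n, replace = TRUE, prob = f / sum(f)),
           levels = names(f))
  }))
  if (!is.null(config$sampi))
    covs$sampi_quintile <- config$sampi$quintile[district]

  S <- sample_micar_effects(config$graph, config$Sigma_s)
  Rv <- chol(config$Sigma_v)
  V <- matrix(stats::rnorm(J * K), J, K) %*% Rv

  X <- stats::model.matrix(config$formula, covs)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  fixed <- X %*% config$beta
  U <- S[district, , drop = FALSE] + V[district, , drop = FALSE]

  alpha <- numeric(K)
  for (k in seq_len(K)) {
    off <- fixed[, k] + U[, k]
    alpha[k] <- stats::uniroot(function(a)
      mean(stats::plogis(a + off)) - config$prevalence[k],
      interval = c(-25, 25), tol = 1e-10)$root
  }
  eta <- sweep(fixed + U, 2, alpha, "+")
  Y <- matrix(stats::rbinom(n * K, 1L, stats::plogis(eta)), n, K,
              dimnames = list(NULL, config$diseases))

  records <- .backfill_records(Y, covs)
  records$district <- district
  w <- exp(stats::rnorm(n, 0, 0.3))
  records$weight <- w / mean(w)
  consent <- stats::runif(n) < config$biomarker_rate
  records$biomarker_consent <- as.integer(consent)
  records$biomarker_weight <- ifelse(consent,
                                     records$weight / config$biomarker_rate,
                                     NA_real_)

  list(records = records, outcomes = Y,
       truth = list(alpha = stats::setNames(alpha, config$diseases),
                    beta = config$beta, S = S, V = V,
                    Sigma_s = config$Sigma_s, Sigma_v = config$Sigma_v,
                    sizes = sizes, seed = seed, config = config))
}

#' Synthetic district deprivation scores
#'
#' Draws per-district SAMPI scores in a configurable range (default
#' 0.008-0.1, the span between the least and most deprived districts of the
#' 2011 census-based index) either independently or with spatial
#' autocorrelation (rank-mapping an intrinsic CAR draw onto the range), and
#' assigns rank quintiles.
#'
#' @param graph an [adjacency_graph].
#' @param range score range, default `c(0.008, 0.1)`.
#' @param spatial if TRUE, scores follow the rank pattern of an ICAR draw.
#' @param seed integer seed, or NULL to use the current RNG state.
#' @return data frame: `district`, `code`, `sampi`, `quintile`.
#' @export
make_district_sampi <- function(graph, range = c(0.008, 0.1),
                                spatial = FALSE, seed = NULL) {
  stopifnot(inherits(graph, "adjacency_graph"))
  if (!is.null(seed)) set.seed(seed)
  J <- graph$n_areas
  if (spatial) {
    u <- drop(sample_micar_effects(graph, matrix(1, 1, 1)))
    scores <- range[1] + (rank(u, ties.method = "first") - 1) / (J - 1) *
      diff(range)
  } else {
    scores <- stats::runif(J, range[1], range[2])
  }
  data.frame(district = seq_len(J), code = graph$codes, sampi = scores,
             quintile = sampi_quintiles(scores))
}
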