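#' Design-weighted prevalence with a linearised logit-Wald interval
#'
#' Estimates `p = sum(w*y) / sum(w)` with a Taylor-linearised (ratio
#' estimator) variance and a 95% confidence interval built on the logit scale
#' so it respects `[0, 1]`. Missing outcomes are excluded pairwise with their
#' weights (complete-case; no imputation). With equal weights the point
#' estimate is exactly the sample proportion, and every estimate is invariant
#' to rescaling all weights by a positive constant.
#'
#' At a degenerate estimate (`p` of exactly 0 or 1) the logit interval is
#' undefined; a one-sided exact-style bound based on the effective sample
#' size `n_eff = (sum w)^2 / sum(w^2)` is substituted and the estimate is
#' flagged `degenerate`.
#'
#' @param y binary outcome vector (`{1, 0, NA}`).
#' @param weights positive survey weights, aligned with `y`.
#' @param psu optional primary-sampling-unit labels; when given, the variance
#'   is linearised over PSU totals instead of individual observations.
#' @param conf_level confidence level (default 0.95).
#' @return one-row data frame: `p_hat`, `ci_low`, `ci_high`, `n` (observed
#'   count), `n_eff`, `degenerate`.
#' @export
weighted_prevalence <- function(y, weights, psu = NULL, conf_level = 0.95) {
  stopifnot(length(y) == length(weights))
  if (!is.null(psu)) stopifnot(length(psu) == length(y))
  keep <- !is.na(y)
  y <- as.numeric(y[keep]); w <- as.numeric(weights[keep])
  if (!is.null(psu)) psu <- psu[keep]
  if (length(y) == 0L || sum(w) <= 0)
    stop("no observed outcomes with positive weight")
  if (any(!is.finite(w)) || any(w <= 0))
    stop("survey weights must be finite and > 0")
  n <- length(y)
  W <- sum(w)
  p <- sum(w * y) / W
  n_eff <- W^2 / sum(w^2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)

  if (p <= 0 || p >= 1) {
    alpha <- (1 - conf_level) / 2
    if (p >= 1) {
      ci <- c(alpha^(1 / n_eff), 1)
    } else {
      ci <- c(0, 1 - alpha^(1 / n_eff))
    }
    return(data.frame(p_hat = p, ci_low = ci[1], ci_high = ci[2],
                      n = n, n_eff = n_eff, degenerate = TRUE))
  }

  # Taylor linearisation of the ratio: residuals z_i = w_i * (y_i - p) / W
  if (is.null(psu)) {
    vp <- n / (n - 1) * sum((w * (y - p))^2) / W^2
  } else {
    zc <- tapply(w * (y - p), psu, sum)
    m <- length(zc)
    if (m < 2L) stop("PSU variance needs at least two PSUs")
    vp <- m / (m - 1) * sum((zc - mean(zc))^2) / W^2
  }
  L <- stats::qlogis(p)
  se_L <- sqrt(vp) / (p * (1 - p))
  ci <- stats::plogis(c(L - z * se_L, L + z * se_L))
  data.frame(p_hat = p, ci_low = ci[1], ci_high = ci[2],
             n = n, n_eff = n_eff, degenerate = FALSE)
}

#' Stratified weighted prevalence table
#'
#' One [weighted_prevalence] row per stratum level, plus each level's weighted
#' share of the sample (the "Total" column of a stratified prevalence table).
#' Levels with no observed outcome are kept but marked unavailable.
#'
#' @param y binary outcome vector.
#' @param weights positive survey weights.
#' @param strata factor (or coercible) of stratum labels aligned with `y`.
#' @param psu optional PSU labels.
#' @return data frame with columns `level`, `p_hat`, `ci_low`, `ci_high`,
#'   `n`, `weighted_share`, `available`.
#' @export
stratified_prevalence <- function(y, weights, strata, psu = NULL) {
  stopifnot(length(y) == length(strata))
  strata <- as.factor(strata)
  W <- sum(weights)
  rows <- lapply(levels(strata), function(lv) {
    sel <- strata == lv
    share <- sum(weights[sel]) / W
    if (!any(sel & !is.na(y))) {
      return(data.frame(level = lv, p_hat = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, n = 0L,
                        weighted_share = share, available = FALSE))
    }
    est <- weighted_prevalence(y[sel], weights[sel],
                               psu = if (is.null(psu)) NULL else psu[sel])
    data.frame(level = lv, p_hat = est$p_hat, ci_low = est$ci_low,
               ci_high = est$ci_high, n = est$n,
               weighted_share = share, available = TRUE)
  })
  do.call(rbind, rows)
}

#' Sensitivity and specificity of self-report against a measured gold standard
#'
#' 2x2 validity statistics on pairwise-complete pairs. A statistic whose
#' defining margin is empty (e.g. no measured positives for sensitivity) is
#' returned as `NA` and flagged, never silently zero.
#'
#' @param self_report,measured binary vectors (`{1, 0, NA}`).
#' @return object of class `validity_stats`: list with `tp`, `fp`, `fn`,
#'   `tn`, `sensitivity`, `specificity`, `undefined` (character vector).
#' @export
sensitivity_specificity <- function(self_report, measured) {
  stopifnot(length(self_report) == length(measured))
  keep <- !is.na(self_report) & !is.na(measured)
  s <- self_report[keep]; g <- measured[keep]
  tp <- sum(s == 1 & g == 1); fp <- sum(s == 1 & g == 0)
  fn <- sum(s == 0 & g == 1); tn <- sum(s == 0 & g == 0)
  undef <- character(0)
  sens <- if (tp + fn > 0) tp / (tp + fn) else { undef <- c(undef, "sensitivity"); NA_real_ }
  spec <- if (tn + fp > 0) tn / (tn + fp) else { undef <- c(undef, "specificity"); NA_real_ }
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 sensitivity = sens, specificity = spec, undefined = undef),
            class = "validity_stats")
}

#' @export
print.validity_stats <- function(x, ...) {
  cat(sprintf("sensitivity %.3f, specificity %.3f (tp %d fp %d fn %d tn %d)\n",
              x$sensitivity, x$specificity, x$tp, x$fp, x$fn, x$tn))
  if (length(x$undefined))
    cat("undefined:", paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}

#' Per-district weighted prevalence and cross-district summary
#'
#' Weighted prevalence per district plus the mean/median/min/max of the
#' district estimates, exposing the per-district sample sizes that drive the
#' instability of small-district rates. Districts with no sampled (observed)
#' participants are marked unavailable, excluded from the summary, and
#' reported with a warning.
#'
#' @param y binary outcome vector.
#' @param weights positive survey weights.
#' @param district integer district index per participant, in `1..J`.
#' @param graph an [adjacency_graph] supplying `J` and district codes; if
#'   `NULL`, `J = max(district)` and codes are the indices.
#' @return data frame (one row per district: `district`, `code`, `p_hat`,
#'   `ci_low`, `ci_high`, `n`, `available`) with attribute `summary` =
#'   list(mean, median, min, max, n_districts).
#' @export
district_prevalence <- function(y, weights, district, graph = NULL) {
  district <- as.integer(district)
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "adjacency_graph"))
    J <- graph$n_areas
    codes <- graph$codes
  } else {
    J <- max(district)
    codes <- as.character(seq_len(J))
  }
  if (any(district < 1L | district > J))
    stop("district indices must lie in 1..J")
  rows <- lapply(seq_len(J), function(j) {
    sel <- district == j & !is.na(y)
    if (!any(sel)) {
      return(data.frame(district = j, code = codes[j], p_hat = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_, n = 0L,
                        available = FALSE))
    }
    est <- weighted_prevalence(y[district == j], weights[district == j])
    data.frame(district = j, code = codes[j], p_hat = est$p_hat,
               ci_low = est$ci_low, ci_high = est$ci_high, n = est$n,
               available = TRUE)
  })
  out <- do.call(rbind, rows)
  if (any(!out$available))
    warning(sprintf("%d district(s) with no sampled participants excluded from summary",
                    sum(!out$available)))
  p <- out$p_hat[out$available]
  attr(out, "summary") <- list(mean = mean(p), median = stats::median(p),
                               min = min(p), max = max(p),
                               n_districts = length(p))
  out
}
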