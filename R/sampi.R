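#' @title South African Multidimensional Poverty Index (SAMPI)
#' @description
#' The SAMPI follows the Alkire-Foster construction of the global MPI: each
#' household carries binary deprivation indicators grouped into four
#' dimensions (education, health, living standards, economic activity) with
#' indicator weights summing to one. A household is multidimensionally poor
#' when its weighted deprivation share reaches the poverty cutoff `k`. The
#' index is the product of the headcount ratio `H` (share of poor households)
#' and the intensity `A` (mean weighted deprivation share among the poor):
#' `SAMPI = H * A`, ranging 0 (least poor) to 1 (most poor).
#'
#' The cutoff defaults to `k = 1/3`, the global-MPI convention, and indicator
#' weights default to nested equal weighting (equal across the four
#' dimensions, equal within each); both are configurable.
#' @name sampi
NULL

#' Nested equal indicator weights
#'
#' @param dimensions named list mapping dimension names to character vectors
#'   of indicator names.
#' @return named numeric vector of indicator weights summing to 1: each
#'   dimension gets equal weight, split equally among its indicators.
#' @export
sampi_weights <- function(dimensions = list(
    education = c("years_schooling", "school_attendance"),
    health = c("nutrition", "child_mortality"),
    living_standards = c("cooking_fuel", "sanitation", "water",
                         "electricity", "floor", "assets"),
    economic_activity = "unemployment")) {
  nd <- length(dimensions)
  w <- unlist(lapply(dimensions, function(ind)
    stats::setNames(rep(1 / (nd * length(ind)), length(ind)), ind)))
  names(w) <- unlist(dimensions)
  w
}

.deprivation_share <- function(flags, weights) {
  flags <- as.matrix(flags)
  if (is.null(colnames(flags)) || is.null(names(weights))) {
    if (ncol(flags) != length(weights))
      stop("indicator weights must align with deprivation columns")
  } else {
    if (!setequal(colnames(flags), names(weights)))
      stop("indicator weights must name every deprivation column")
    weights <- weights[colnames(flags)]
  }
  if (any(weights <= 0)) stop("indicator weights must be positive")
  if (abs(sum(weights) - 1) > 1e-8) stop("indicator weights must sum to 1")
  if (any(!(flags %in% c(0, 1)))) stop("deprivation flags must be binary")
  drop(flags %*% weights)
}

#' Multidimensional poverty headcount ratio
#'
#' @param flags households x indicators matrix (or data frame) of binary
#'   deprivation flags.
#' @param weights indicator weights summing to 1 (default [sampi_weights] when
#'   column names match, otherwise equal weights).
#' @param poverty_cutoff `k` in `(0, 1]`; a household is poor when its
#'   weighted deprivation share is `>= k`.
#' @return headcount ratio `H` in `[0, 1]`.
#' @export
compute_headcount <- function(flags, weights = NULL, poverty_cutoff = 1 / 3) {
  if (NROW(flags) == 0L) stop("no households")
  if (poverty_cutoff <= 0 || poverty_cutoff > 1)
    stop("poverty cutoff must lie in (0, 1]")
  if (is.null(weights)) weights <- rep(1 / NCOL(flags), NCOL(flags))
  share <- .deprivation_share(flags, weights)
  mean(share >= poverty_cutoff)
}

#' Average intensity of poverty among the poor
#'
#' @inheritParams compute_headcount
#' @return intensity `A` in `[0, 1]`, or `NA` (flagged by a warning) when no
#'   household is poor.
#' @export
compute_intensity <- function(flags, weights = NULL, poverty_cutoff = 1 / 3) {
  if (NROW(flags) == 0L) stop("no households")
  if (is.null(weights)) weights <- rep(1 / NCOL(flags), NCOL(flags))
  share <- .deprivation_share(flags, weights)
  poor <- share >= poverty_cutoff
  if (!any(poor)) {
    warning("no poor household: intensity undefined (index is 0 via H = 0)")
    return(NA_real_)
  }
  mean(share[poor])
}

#' SAMPI score: headcount times intensity
#'
#' @param H headcount ratio in `[0, 1]`.
#' @param A intensity in `[0, 1]`.
#' @return `H * A`.
#' @examples
#' compute_sampi(0.20, 0.44) # 0.088, i.e. 0.09 at 2 decimals
#' @export
compute_sampi <- function(H, A) {
  if (any(H < 0 | H > 1, na.rm = TRUE) || any(A < 0 | A > 1, na.rm = TRUE))
    stop("H and A must lie in [0, 1]")
  H * A
}

#' Per-district SAMPI from household deprivation profiles
#'
#' @param flags households x indicators binary matrix.
#' @param district district index per household.
#' @param weights indicator weights (default equal).
#' @param poverty_cutoff Alkire-Foster cutoff, default 1/3.
#' @return data frame: `district`, `H`, `A`, `sampi` (A is `NA` and sampi 0
#'   where a district has no poor household).
#' @export
district_sampi <- function(flags, district, weights = NULL,
                           poverty_cutoff = 1 / 3) {
  flags <- as.matrix(flags)
  stopifnot(nrow(flags) == length(district))
  rows <- lapply(sort(unique(as.integer(district))), function(j) {
    f <- flags[district == j, , drop = FALSE]
    H <- compute_headcount(f, weights, poverty_cutoff)
    A <- if (H > 0) compute_intensity(f, weights, poverty_cutoff) else NA_real_
    data.frame(district = j, H = H, A = A,
               sampi = if (H > 0) compute_sampi(H, A) else 0)
  })
  do.call(rbind, rows)
}

#' Rank-based SAMPI quintile categories
#'
#' Districts are ranked by score (ascending; ties broken by stable input
#' order) and assigned quintile `ceiling(5 * rank / n)`: SAMPI1 is the
#' least-deprived fifth, SAMPI5 the most deprived. For `n = 52` this rule
#' yields partition sizes (10, 10, 11, 10, 11).
#'
#' @param scores numeric vector of district SAMPI scores (length >= 5).
#' @return factor with levels `SAMPI1`..`SAMPI5`, aligned with `scores`.
#' @export
sampi_quintiles <- function(scores) {
  n <- length(scores)
  if (n < 5L) stop("quintile assignment needs at least 5 districts")
  r <- rank(scores, ties.method = "first")
  q <- ceiling(5 * r / n)
  factor(paste0("SAMPI", q), levels = paste0("SAMPI", 1:5))
}
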