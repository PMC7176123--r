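#' @title Clinical outcome derivation
#' @description
#' The four cardiovascular outcomes are composites of clinical measurements
#' and self-reports, each an OR-rule over its evidence fields:
#' \itemize{
#'   \item hypertension: SBP >= 140 mmHg, or DBP >= 90 mmHg, or self-reported
#'     history of high blood pressure, or antihypertensive medication;
#'   \item ischaemic heart disease: self-reported history of heart attack,
#'     angina or chest pain (pass-through);
#'   \item stroke: self-reported history of stroke (pass-through);
#'   \item dyslipidaemia: lipid-lowering drugs, or diagnosis, or
#'     TC >= 6.22 mmol/L, or TG >= 1.69, or LDL >= 4.14, or HDL < 1.04 (men) /
#'     HDL < 1.29 (women).
#' }
#' Diabetes (a model covariate) is HbA1c >= 6.5% or a diabetes history or
#' current treatment; BMI is classed underweight (< 18.5), normal
#' ([18.5, 25)) or overweight (>= 25).
#'
#' Missingness rule (the only monotone completion of an OR-rule): the outcome
#' is 1 on any positive evidence even if other fields are missing; 0 only
#' when at least one field is observed and every observed field is negative;
#' missing when no contributing field is observed.
#' @name outcome_derivation
NULL

# OR-rule over tri-state {1, 0, NA} evidence columns
.or_rule <- function(...) {
  ev <- cbind(...)
  pos <- rowSums(ev == 1L, na.rm = TRUE) > 0L
  obs <- rowSums(!is.na(ev)) > 0L
  ifelse(pos, 1L, ifelse(obs, 0L, NA_integer_))
}

.as_flag <- function(x) {
  if (is.null(x)) return(NA_integer_)
  if (is.logical(x)) return(as.integer(x))
  x <- as.integer(x)
  if (any(!is.na(x) & !(x %in% c(0L, 1L))))
    stop("flags must be coded {1, 0, NA}")
  x
}

#' Derive hypertension status
#'
#' @param sbp,dbp systolic / diastolic blood pressure, mmHg (NA = missing).
#' @param self_hbp,hbp_medication tri-state flags `{1, 0, NA}`.
#' @return integer vector in `{1, 0, NA}`.
#' @export
derive_hypertension <- function(sbp = NULL, dbp = NULL, self_hbp = NULL,
                                hbp_medication = NULL) {
  n <- max(length(sbp), length(dbp), length(self_hbp),
           length(hbp_medication), 1L)
  num <- function(x) if (is.null(x)) rep(NA_real_, n) else rep_len(x, n)
  flg <- function(x) rep_len(.as_flag(x), n)
  .or_rule(as.integer(num(sbp) >= 140),
           as.integer(num(dbp) >= 90),
           flg(self_hbp), flg(hbp_medication))
}

#' Derive dyslipidaemia status
#'
#' The HDL cut-off is sex-specific (< 1.04 mmol/L for men, < 1.29 for women).
#' A record with an observed HDL but missing sex cannot use its HDL evidence;
#' such records are reported in the `"flagged"` attribute of the result.
#'
#' @param tc,tg,ldl,hdl lipid panel, mmol/L (NA = missing).
#' @param sex `"male"`/`"female"` (or a factor); required only when HDL
#'   evidence is present.
#' @param lipid_drugs,dyslip_diagnosis tri-state flags.
#' @return integer vector in `{1, 0, NA}`, with attribute `flagged` giving
#'   indices of records whose HDL evidence was unusable for missing sex.
#' @export
derive_dyslipidaemia <- function(tc = NULL, tg = NULL, ldl = NULL, hdl = NULL,
                                 sex = NULL, lipid_drugs = NULL,
                                 dyslip_diagnosis = NULL) {
  n <- max(length(tc), length(tg), length(ldl), length(hdl), length(sex),
           length(lipid_drugs), length(dyslip_diagnosis), 1L)
  num <- function(x) if (is.null(x)) rep(NA_real_, n) else rep_len(x, n)
  flg <- function(x) rep_len(.as_flag(x), n)
  tc <- num(tc); tg <- num(tg); ldl <- num(ldl); hdl <- num(hdl)
  sex <- if (is.null(sex)) rep(NA_character_, n) else
    rep_len(tolower(as.character(sex)), n)
  bad_sex <- !is.na(sex) & !(sex %in% c("male", "female"))
  if (any(bad_sex)) stop("sex must be 'male' or 'female' (or NA)")
  hdl_cut <- ifelse(sex == "male", 1.04,
                    ifelse(sex == "female", 1.29, NA_real_))
  hdl_ev <- as.integer(hdl < hdl_cut)
  flagged <- which(!is.na(hdl) & is.na(sex))
  hdl_ev[flagged] <- NA_integer_
  out <- .or_rule(flg(lipid_drugs), flg(dyslip_diagnosis),
                  as.integer(tc >= 6.22), as.integer(tg >= 1.69),
                  as.integer(ldl >= 4.14), hdl_ev)
  attr(out, "flagged") <- flagged
  out
}

#' Derive diabetes status
#'
#' @param hba1c glycated haemoglobin, percent (NA = missing).
#' @param diabetes_history,diabetes_treatment tri-state flags.
#' @return integer vector in `{1, 0, NA}`.
#' @export
derive_diabetes <- function(hba1c = NULL, diabetes_history = NULL,
                            diabetes_treatment = NULL) {
  n <- max(length(hba1c), length(diabetes_history),
           length(diabetes_treatment), 1L)
  num <- function(x) if (is.null(x)) rep(NA_real_, n) else rep_len(x, n)
  flg <- function(x) rep_len(.as_flag(x), n)
  .or_rule(as.integer(num(hba1c) >= 6.5),
           flg(diabetes_history), flg(diabetes_treatment))
}

#' Classify body-mass index
#'
#' Underweight `< 18.5`, normal `[18.5, 25)`, overweight/obese `>= 25`.
#'
#' @param bmi numeric vector, kg/m^2.
#' @return factor with levels underweight, normal, overweight (NA preserved).
#' @export
classify_bmi <- function(bmi) {
  lev <- c("underweight", "normal", "overweight")
  cls <- ifelse(is.na(bmi), NA_character_,
                ifelse(bmi < 18.5, "underweight",
                       ifelse(bmi < 25.0, "normal", "overweight")))
  factor(cls, levels = lev)
}

.participant_fields <- c(
  "sbp", "dbp", "self_hbp", "hbp_medication", "self_ihd", "self_stroke",
  "lipid_drugs", "dyslip_diagnosis", "tc", "tg", "ldl", "hdl", "sex",
  "hba1c", "diabetes_history", "diabetes_treatment", "bmi")

#' Derive all outcomes for a set of participant records
#'
#' Vectorised application of the outcome rules to a participant data frame.
#' Expected columns (all optional; absent columns count as all-missing):
#' `sbp`, `dbp`, `self_hbp`, `hbp_medication`, `self_ihd`, `self_stroke`,
#' `lipid_drugs`, `dyslip_diagnosis`, `tc`, `tg`, `ldl`, `hdl`, `sex`,
#' `hba1c`, `diabetes_history`, `diabetes_treatment`, `bmi`. Flags are coded
#' `{1, 0, NA}`.
#'
#' @param records data frame of participant records.
#' @return data frame with columns `hbp`, `ihd`, `stroke`, `dyslip`,
#'   `diabetes` (each `{1, 0, NA}`) and `bmi_class`; attribute `report` holds
#'   per-outcome missingness counts and the indices of records flagged during
#'   dyslipidaemia derivation.
#' @export
derive_outcomes <- function(records) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  col <- function(name) if (name %in% names(records)) records[[name]] else NULL
  dys <- derive_dyslipidaemia(col("tc"), col("tg"), col("ldl"), col("hdl"),
                              col("sex"), col("lipid_drugs"),
                              col("dyslip_diagnosis"))
  pass <- function(x) if (is.null(x)) rep(NA_integer_, n) else
    rep_len(.as_flag(x), n)
  out <- data.frame(
    hbp = derive_hypertension(col("sbp"), col("dbp"), col("self_hbp"),
                              col("hbp_medication")),
    ihd = pass(col("self_ihd")),
    stroke = pass(col("self_stroke")),
    dyslip = as.integer(dys),
    diabetes = derive_diabetes(col("hba1c"), col("diabetes_history"),
                               col("diabetes_treatment")),
    bmi_class = classify_bmi(if (is.null(col("bmi"))) rep(NA_real_, n)
                             else col("bmi")))
  attr(out, "report") <- list(
    n = n,
    n_missing = vapply(out[c("hbp", "ihd", "stroke", "dyslip", "diabetes")],
                       function(x) sum(is.na(x)), integer(1)),
    flagged_dyslipidaemia = attr(dys, "flagged"))
  out
}

#' Read participant records from CSV
#'
#' Reads the documented column dictionary (see [derive_outcomes]) plus
#' `district`, `weight` (and optionally `biomarker_weight`, covariate
#' columns), validating physiologic sanity ranges at load.
#'
#' @param path CSV file path.
#' @param sanity named list of `c(min, max)` ranges; defaults cover SBP
#'   (60-300), DBP (30-200), BMI (10-80), HbA1c (2-20), lipids (0-30).
#' @return data frame of validated records.
#' @export
read_participants <- function(path,
                              sanity = list(sbp = c(60, 300),
                                            dbp = c(30, 200),
                                            bmi = c(10, 80),
                                            hba1c = c(2, 20),
                                            tc = c(0, 30), tg = c(0, 30),
                                            ldl = c(0, 30), hdl = c(0, 30))) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (v in names(sanity)) {
    if (!v %in% names(df)) next
    x <- df[[v]]
    bad <- which(!is.na(x) & (x < sanity[[v]][1] | x > sanity[[v]][2]))
    if (length(bad))
      stop(sprintf("%s out of sanity range [%g, %g] at row(s) %s",
                   v, sanity[[v]][1], sanity[[v]][2],
                   paste(utils::head(bad, 5), collapse = ", ")))
  }
  if ("weight" %in% names(df)) {
    w <- df$weight
    if (any(!is.na(w) & w <= 0) || any(!is.finite(w[!is.na(w)])))
      stop("survey weights must be finite and > 0")
  }
  df
}
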