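test_that("hypertension rule combines measurements, self-report and medication", {
  expect_equal(derive_hypertension(sbp = 145, dbp = 80, self_hbp = 0,
                                   hbp_medication = 0), 1L)
  expect_equal(derive_hypertension(sbp = 139, dbp = 89, self_hbp = 0,
                                   hbp_medication = 0), 0L)
  expect_equal(derive_hypertension(sbp = 120, dbp = 70, self_hbp = 1), 1L)
  expect_equal(derive_hypertension(sbp = NA, dbp = NA, self_hbp = NA,
                                   hbp_medication = NA), NA_integer_)
  # positive evidence wins even with everything else missing
  expect_equal(derive_hypertension(hbp_medication = 1), 1L)
  # one observed negative with the rest missing is a 0, not missing
  expect_equal(derive_hypertension(dbp = 70), 0L)
})

test_that("dyslipidaemia rule is the printed OR-list with sex-specific HDL", {
  expect_equal(as.integer(derive_dyslipidaemia(
    tc = 6.3, tg = 1.0, ldl = 3.0, hdl = 1.5, sex = "male",
    lipid_drugs = 0, dyslip_diagnosis = 0)), 1L)
  expect_equal(as.integer(derive_dyslipidaemia(
    tc = 5.0, hdl = 1.10, sex = c("male", "female"),
    lipid_drugs = 0, dyslip_diagnosis = 0)), c(0L, 1L))
  expect_equal(as.integer(derive_dyslipidaemia(
    tc = 5.0, tg = 1.0, ldl = 3.0, hdl = 1.5, sex = "female",
    lipid_drugs = 0, dyslip_diagnosis = 0)), 0L)
})

test_that("observed HDL with missing sex flags the record instead of guessing", {
  out <- derive_dyslipidaemia(hdl = c(0.9, 0.9), sex = c(NA, "male"),
                              tc = c(NA, NA))
  expect_equal(attr(out, "flagged"), 1L)
  expect_equal(as.integer(out), c(NA_integer_, 1L))
})

test_that("diabetes rule uses HbA1c threshold, history and treatment", {
  expect_equal(derive_diabetes(hba1c = 6.5, diabetes_history = 0), 1L)
  expect_equal(derive_diabetes(hba1c = 6.4, diabetes_history = 0,
                               diabetes_treatment = 0), 0L)
  expect_equal(derive_diabetes(hba1c = NA, diabetes_history = 1), 1L)
})

test_that("BMI classes follow the half-open intervals", {
  expect_equal(as.character(classify_bmi(c(18.5, 25.0, 18.4, 24.99, NA))),
               c("normal", "overweight", "underweight", "normal", NA))
})

test_that("every printed cut-off is inclusive/exclusive on the documented side", {
  eps <- 1e-9
  # (value, below-result, at-result) for each >= cut-off
  expect_equal(derive_hypertension(sbp = c(140 - eps, 140, 140 + eps)),
               c(0L, 1L, 1L))
  expect_equal(derive_hypertension(dbp = c(90 - eps, 90, 90 + eps)),
               c(0L, 1L, 1L))
  for (case in list(list(f = function(v) derive_dyslipidaemia(tc = v), cut = 6.22),
                    list(f = function(v) derive_dyslipidaemia(tg = v), cut = 1.69),
                    list(f = function(v) derive_dyslipidaemia(ldl = v), cut = 4.14))) {
    v <- c(case$cut - eps, case$cut, case$cut + eps)
    expect_equal(as.integer(case$f(v)), c(0L, 1L, 1L))
  }
  # HDL is a strict < rule
  expect_equal(as.integer(derive_dyslipidaemia(
    hdl = c(1.04 - eps, 1.04), sex = "male")), c(1L, 0L))
  expect_equal(as.integer(derive_dyslipidaemia(
    hdl = c(1.29 - eps, 1.29), sex = "female")), c(1L, 0L))
  expect_equal(derive_diabetes(hba1c = c(6.5 - eps, 6.5, 6.5 + eps)),
               c(0L, 1L, 1L))
  expect_equal(as.character(classify_bmi(c(18.5 - eps, 18.5, 25 - 1e-9, 25))),
               c("underweight", "normal", "normal", "overweight"))
})

test_that("derive_outcomes composes the rules, passes through self-reports and reports missingness", {
  rec <- blank_records(4)
  rec$sbp <- c(145, 139, 120, NA)
  rec$dbp <- c(80, 89, 70, NA)
  rec$self_hbp <- c(0, 0, 1, NA)
  rec$hbp_medication <- c(0, 0, NA, NA)
  rec$self_stroke <- c(1, 0, NA, NA)
  rec$self_ihd <- c(0, 1, NA, NA)
  out <- derive_outcomes(rec)
  expect_equal(out$hbp, c(1L, 0L, 1L, NA))
  expect_equal(out$stroke, c(1L, 0L, NA, NA))
  expect_equal(out$ihd, c(0L, 1L, NA, NA))
  # all-missing record: everything missing
  expect_true(all(is.na(out[4, c("hbp", "ihd", "stroke", "dyslip", "diabetes")])))
  rep_ <- attr(out, "report")
  expect_equal(unname(rep_$n_missing["stroke"]), 2L)
  expect_equal(rep_$n, 4L)
})

test_that("derivation is deterministic and monotone in positive evidence", {
  set.seed(5)
  n <- 200
  rec <- blank_records(n)
  rec$sbp <- ifelse(runif(n) < 0.3, NA, runif(n, 90, 200))
  rec$dbp <- ifelse(runif(n) < 0.3, NA, runif(n, 50, 120))
  rec$self_hbp <- sample(c(0L, 1L, NA), n, replace = TRUE)
  rec$hbp_medication <- sample(c(0L, 1L, NA), n, replace = TRUE)
  rec$tc <- ifelse(runif(n) < 0.3, NA, runif(n, 3, 8))
  rec$hdl <- ifelse(runif(n) < 0.3, NA, runif(n, 0.7, 2))
  rec$sex <- sample(c("male", "female"), n, replace = TRUE)
  rec$hba1c <- ifelse(runif(n) < 0.3, NA, runif(n, 4, 9))

  out1 <- derive_outcomes(rec)
  out2 <- derive_outcomes(rec)
  expect_identical(out1, out2)

  # flipping any single positive-evidence field never turns a 1 into a 0
  flips <- list(
    list(col = "self_hbp", val = 1L, outcome = "hbp"),
    list(col = "sbp", val = 180, outcome = "hbp"),
    list(col = "tc", val = 7, outcome = "dyslip"),
    list(col = "hba1c", val = 8, outcome = "diabetes"))
  for (fl in flips) {
    rec2 <- rec
    rec2[[fl$col]] <- fl$val
    out_fl <- derive_outcomes(rec2)
    was1 <- !is.na(out1[[fl$outcome]]) & out1[[fl$outcome]] == 1L
    expect_true(all(out_fl[[fl$outcome]][was1] == 1L))
    expect_true(all(out_fl[[fl$outcome]] == 1L)) # the field alone suffices
  }
})

test_that("participant reader enforces sanity ranges and positive weights", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sbp = c(120, 400), weight = c(1, 1)), f,
                   row.names = FALSE)
  expect_error(read_participants(f), "sanity range")
  f2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sbp = c(120, 130), weight = c(1, -1)), f2,
                   row.names = FALSE)
  expect_error(read_participants(f2), "weights")
  f3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(sbp = c(120, 130), weight = c(1, 2)), f3,
                   row.names = FALSE)
  expect_silent(df <- read_participants(f3))
  expect_equal(nrow(df), 2L)
})
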