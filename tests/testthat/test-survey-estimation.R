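test_that("weighted prevalence reduces to the sample proportion under equal weights", {
  est <- weighted_prevalence(c(1, 0, 1, 0), rep(2, 4))
  expect_identical(est$p_hat, 0.5)
  expect_false(est$degenerate)
  est2 <- weighted_prevalence(c(1, 0), c(3, 1))
  expect_identical(est2$p_hat, 0.75)
  set.seed(2)
  y <- rbinom(100, 1, 0.4)
  expect_equal(weighted_prevalence(y, rep(1, 100))$p_hat, mean(y))
})

test_that("estimates are invariant to rescaling weights and exclude missing pairwise", {
  set.seed(3)
  y <- c(rbinom(50, 1, 0.3), NA, NA)
  w <- runif(52, 0.5, 3)
  a <- weighted_prevalence(y, w)
  b <- weighted_prevalence(y, 7.3 * w)
  expect_equal(a, b, tolerance = 1e-12)
  cc <- weighted_prevalence(y[1:50], w[1:50])
  expect_equal(a$p_hat, cc$p_hat)
  expect_equal(a$n, 50L)
})

test_that("degenerate all-positive samples get a one-sided bound and a flag", {
  est <- weighted_prevalence(rep(1, 20), runif(20, 0.5, 2))
  expect_identical(est$p_hat, 1)
  expect_identical(est$ci_high, 1)
  expect_lt(est$ci_low, 1)
  expect_true(est$degenerate)
  expect_error(weighted_prevalence(c(NA, NA), c(1, 1)), "no observed")
})

test_that("confidence intervals respect [0,1] and PSU grouping changes the variance", {
  set.seed(4)
  y <- rbinom(400, 1, 0.05)
  w <- runif(400, 0.5, 2)
  est <- weighted_prevalence(y, w)
  expect_true(est$ci_low >= 0 && est$ci_high <= 1)
  expect_true(est$ci_low <= est$p_hat && est$p_hat <= est$ci_high)
  psu <- rep(1:20, each = 20)
  est_psu <- weighted_prevalence(y, w, psu = psu)
  expect_equal(est_psu$p_hat, est$p_hat)
  expect_false(isTRUE(all.equal(est_psu$ci_low, est$ci_low)))
})

test_that("stratified prevalence returns per-level rates and weighted shares", {
  y <- c(rep(c(1, 0, 0, 0, 0), 20), rep(c(1, 1, 1, 0, 0), 20))
  strata <- rep(c("a", "b"), each = 100)
  tab <- stratified_prevalence(y, rep(1, 200), strata)
  expect_equal(tab$p_hat, c(0.2, 0.6))
  expect_equal(tab$weighted_share, c(0.5, 0.5))
  # single stratum reduces to weighted_prevalence
  one <- stratified_prevalence(y, rep(1, 200), rep("all", 200))
  expect_equal(one$p_hat, weighted_prevalence(y, rep(1, 200))$p_hat)
  # level without observed outcomes is kept but unavailable
  y2 <- c(1, 0, NA, NA)
  tab2 <- stratified_prevalence(y2, rep(1, 4), c("u", "u", "v", "v"))
  expect_false(tab2$available[tab2$level == "v"])
  expect_true(is.na(tab2$p_hat[tab2$level == "v"]))
})

test_that("sensitivity/specificity come from the 2x2 counts with degenerate margins flagged", {
  s <- c(1, 1, 0, 0, 1, 0, 0, 0)
  g <- c(1, 1, 1, 1, 0, 0, 0, 0)
  vs <- sensitivity_specificity(s, g)
  expect_equal(vs$sensitivity, 0.5)
  expect_equal(vs$specificity, 0.75)
  expect_equal(c(vs$tp, vs$fp, vs$fn, vs$tn), c(2, 1, 2, 3))

  perfect <- sensitivity_specificity(c(1, 0, 1), c(1, 0, 1))
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$specificity, 1)

  none <- sensitivity_specificity(c(1, 0), c(0, 0))
  expect_true(is.na(none$sensitivity))
  expect_equal(none$specificity, 0.5)
  expect_equal(none$undefined, "sensitivity")
})

test_that("district prevalence summarises available districts and warns on empty ones", {
  g <- adjacency_graph(list(2L, c(1L, 3L), 2L))
  y <- c(rep(c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0), 2),  # district 1: 0.1
         rep(c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0), 2),  # district 2: 0.3
         rep(c(1, 1, 1, 1, 1, 0, 0, 0, 0, 0), 2))  # district 3: 0.5
  d <- rep(1:3, each = 20)
  dp <- district_prevalence(y, rep(1, 60), d, g)
  expect_equal(dp$p_hat, c(0.1, 0.3, 0.5))
  s <- attr(dp, "summary")
  expect_equal(s$median, 0.3)
  expect_equal(c(s$min, s$max), c(0.1, 0.5))

  expect_warning(dp2 <- district_prevalence(y[1:40], rep(1, 40), d[1:40], g),
                 "no sampled participants")
  expect_false(dp2$available[3])
  expect_equal(attr(dp2, "summary")$n_districts, 2L)
  expect_error(district_prevalence(y, rep(1, 60), rep(9, 60), g), "1..J")
})

test_that("district rates recover generator ground truth within binomial error", {
  g <- lattice_graph(3, 3)
  cfg <- generator_config(graph = g, diseases = "hbp",
                          prevalence = c(hbp = 0.286),
                          formula = ~ sex,
                          size_meanlog = log(400), size_sdlog = 0.1,
                          size_range = c(200, 900))
  pop <- generate_population(cfg, seed = 11)
  truth_p <- with(pop$truth, {
    eta <- alpha["hbp"] + as.numeric(stats::model.matrix(~ sex, pop$records)[, -1,
      drop = FALSE] %*% beta[, "hbp"]) +
      (S + V)[pop$records$district, 1]
    tapply(stats::plogis(eta), pop$records$district, mean)
  })
  dp <- district_prevalence(pop$outcomes[, "hbp"], rep(1, nrow(pop$records)),
                            pop$records$district, g)
  n_j <- tabulate(pop$records$district, 9)
  # each observed rate within 4 binomial SDs of its district's true mean risk
  expect_true(all(abs(dp$p_hat - truth_p) <
                    4 * sqrt(truth_p * (1 - truth_p) / n_j)))
})
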