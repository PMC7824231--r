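test_that("one-sample proportion test reproduces published comparisons", {
  # analytical-sample vs cohort margins, rounded to the printed precision
  expect_equal(round(one_sample_prop_test(116, 201, 748 / 1456)$p_value, 2),
               0.07)
  expect_equal(round(one_sample_prop_test(39, 200, 362 / 1442)$p_value, 2),
               0.07)
  expect_equal(round(one_sample_prop_test(25, 200, 158 / 1438)$p_value, 2),
               0.49)
  # null value: observed equals expected
  r <- one_sample_prop_test(50, 200, 0.25)
  expect_equal(r$z, 0)
  expect_equal(r$p_value, 1)
  expect_error(one_sample_prop_test(5, 10, 1), "strictly")
})

test_that("proportion test agrees with prop.test without correction", {
  set.seed(9)
  for (i in 1:25) {
    n <- sample(20:500, 1)
    x <- sample(0:n, 1)
    p0 <- runif(1, 0.05, 0.95)
    ours <- one_sample_prop_test(x, n, p0)
    ref <- prop.test(x, n, p = p0, correct = FALSE)
    expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
    expect_equal(ours$z^2, unname(ref$statistic), tolerance = 1e-10)
  }
})

test_that("goodness-of-fit chi-square reproduces published comparisons", {
  expect_equal(round(gof_chisq(c(80, 60, 48),
                               c(491, 394, 267) / 1152)$p_value, 2), 0.69)
  expect_equal(round(gof_chisq(c(66, 29, 37, 69),
                               c(442, 285, 225, 504) / 1456)$p_value, 2),
               0.23)
  # exactly proportional observed counts
  r <- gof_chisq(c(25, 50, 25), c(0.25, 0.5, 0.25))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  expect_equal(r$df, 2)
  expect_error(gof_chisq(c(1, 2), c(0.6, 0.5)), "sum to 1")
})

test_that("chi-square with two categories equals the squared z statistic", {
  set.seed(10)
  for (i in 1:20) {
    n <- sample(30:400, 1)
    x <- sample(1:(n - 1), 1)
    p0 <- runif(1, 0.1, 0.9)
    z <- one_sample_prop_test(x, n, p0)$z
    chi <- gof_chisq(c(x, n - x), c(p0, 1 - p0))
    expect_equal(chi$statistic, z^2, tolerance = 1e-10)
    expect_equal(chi$df, 1)
  }
})

test_that("one-sample t-test from summary statistics", {
  r <- one_sample_t(10, 2, 16, 9)
  expect_equal(r$t, 2)
  expect_equal(r$df, 15)
  expect_equal(r$p_value, 2 * pt(-2, 15), tolerance = 1e-12)
  r2 <- one_sample_t(15.3, 14.1, 201, 14.4)
  expect_equal(round(r2$t, 2), 0.9)
  r0 <- one_sample_t(5, 1, 30, 5)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_value, 1)
  expect_error(one_sample_t(5, 0, 30, 5), "positive")
})

test_that("representativeness wrapper runs the bundled worked example", {
  margins <- read_cohort_margins(system.file("extdata", "cohort_margins.csv",
                                             package = "methdelta"))
  out <- representativeness_tests(margins)
  p_of <- function(v) out$p_value[out$variable == v]
  expect_equal(round(p_of("male"), 2), 0.07)
  expect_equal(round(p_of("maternal_smoking"), 2), 0.07)
  expect_equal(round(p_of("maternal_asthma"), 2), 0.49)
  expect_equal(round(p_of("birth_order"), 2), 0.69)
  expect_equal(round(p_of("season_age10"), 2), 0.23)
  expect_identical(out$test[out$variable == "birthweight"], "t_one_sample")
})

test_that("gene-location enrichment counts multi-label probes in each group", {
  ann <- data.frame(
    cpg_id = sprintf("cg%02d", 1:12),
    location = c("TSS200", "TSS1500", "Body", "Body;TSS1500", "1stExon",
                 "5'UTR", "", "TSS200;Body", "Body", "3'UTR", "TSS1500",
                 "Body")
  )
  lists <- list(EBF = sprintf("cg%02d", 1:4),
                EFF = sprintf("cg%02d", 5:8),
                Mixed = sprintf("cg%02d", 9:12))
  res <- location_enrichment(lists, ann)
  # cg04 is Body AND TSS1500: counted in both groups
  expect_equal(unname(res$tss$table["in_group", "EBF"]), 3)
  expect_equal(unname(res$body$table["in_group", "EBF"]), 2)
  expect_equal(colSums(res$tss$table), c(EBF = 4, EFF = 4, Mixed = 4))
  expect_error(location_enrichment(lists["EBF"], ann), "at least two")
  expect_error(
    location_enrichment(list(A = "cg01", B = "cg99"), ann), "unannotated")
  bad <- data.frame(cpg_id = "cg01", location = "Promoter")
  expect_error(location_enrichment(list(A = "cg01", B = "cg01"), bad),
               "unknown location")
})

test_that("location chi-square matches a hand Pearson computation", {
  # counts per mode: in-group/not (13,14 | 17,31 | 0,12)
  counts <- matrix(c(13, 14, 17, 31, 0, 12), nrow = 2,
                   dimnames = list(c("in_group", "not_in_group"),
                                   c("EBF", "EFF", "Mixed")))
  ref <- suppressWarnings(chisq.test(counts, correct = FALSE))
  expect_equal(round(unname(ref$statistic), 2), 8.57)
  # the same table via the package op
  ann <- data.frame(
    cpg_id = sprintf("cg%03d", 1:87),
    location = c(rep("TSS200", 13), rep("Body", 14),
                 rep("TSS200", 17), rep("Body", 31),
                 rep("", 0), rep("Body", 12))
  )
  lists <- list(EBF = sprintf("cg%03d", 1:27),
                EFF = sprintf("cg%03d", 28:75),
                Mixed = sprintf("cg%03d", 76:87))
  res <- location_enrichment(lists, ann)
  expect_equal(res$tss$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(res$tss$df, 2)
})

test_that("stability classifier calls identical matrices stable", {
  set.seed(20)
  m10 <- named_matrix(rnorm(20 * 30), 20, 30)
  calls <- stability_classify(m10, m10 + 0)   # m18 equals m10 exactly
  expect_true(all(calls$call == "stable"))
  expect_true(all(abs(calls$estimate) < 1e-10))
  expect_error(stability_classify(m10[, 1:2], m10[, 1:2]), "3 paired")
})

test_that("stability classifier detects a real age shift", {
  set.seed(21)
  m10 <- named_matrix(rnorm(10 * 60), 10, 60)
  m18 <- m10 + 1.0 + named_matrix(rnorm(10 * 60, 0, 0.2), 10, 60)
  calls <- stability_classify(m10, m18)
  expect_true(all(calls$call == "dynamic"))
  expect_true(all(calls$estimate > 0.8))
})

test_that("closed-form REML agrees with the numerical mixed-model fit", {
  # subject-level intercepts keep the variance component away from the
  # zero boundary, where the two routes coincide exactly
  set.seed(22)
  subj_eff <- named_matrix(rep(rnorm(40, 0, 1), each = 3), 3, 40)
  m10 <- subj_eff + named_matrix(rnorm(3 * 40, 0, 0.4), 3, 40)
  m18 <- subj_eff + named_matrix(rnorm(3 * 40, 0.1, 0.4), 3, 40)
  exact <- stability_classify(m10, m18, method = "exact")
  lmerfit <- stability_classify(m10, m18, method = "lmer")
  expect_equal(exact$p_value, lmerfit$p_value, tolerance = 1e-6)
  expect_equal(exact$estimate, lmerfit$estimate, tolerance = 1e-8)
  # and both equal the paired t-test
  for (i in 1:3) {
    ref <- t.test(m18[i, ], m10[i, ], paired = TRUE)
    expect_equal(exact$p_value[i], ref$p.value, tolerance = 1e-10)
  }
})

test_that("per-feeding-group outcome regressions", {
  modes <- rep(c("EBF", "EFF", "Mixed"), each = 5)
  delta <- rep(seq(-1, 1, length.out = 5), 3)
  # exact linear relation within each group -> slope 2, intercept 1
  out <- outcome_by_feeding_regression(delta, 2 * delta + 1, modes)
  expect_equal(out$slope, rep(2, 3), tolerance = 1e-12)
  expect_equal(out$intercept, rep(1, 3), tolerance = 1e-12)
  # constant outcome -> slope 0
  out0 <- outcome_by_feeding_regression(delta, rep(3, 15), modes)
  expect_true(all(abs(out0$slope) < 1e-12))
  # hand 4-point least squares
  x <- c(0, 1, 2, 3); y <- c(1, 3, 2, 5)
  hand_slope <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  out4 <- outcome_by_feeding_regression(x, y, rep("EBF", 4))
  expect_equal(out4$slope, hand_slope, tolerance = 1e-12)
  # small group skipped with warning
  expect_warning(
    outcome_by_feeding_regression(c(delta, 0.5), c(2 * delta + 1, 9),
                                  c(modes, "Other")),
    "skipped")
})
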