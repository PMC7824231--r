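test_that("beta_from_intensities follows M/(c+M+U)", {
  expect_equal(beta_from_intensities(100, 100, c = 0), 0.5)
  expect_equal(beta_from_intensities(300, 100, c = 0), 0.75)
  expect_equal(beta_from_intensities(0, 50, c = 100), 0)
  expect_equal(beta_from_intensities(100, 100), 100 / 300)  # default c = 100
  expect_error(beta_from_intensities(0, 0, c = 0), "positive")
  expect_error(beta_from_intensities(-1, 10), "non-negative")
})

test_that("beta/M transform is the logit2 with a clipping guard", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)
  expect_equal(beta_to_m(0.2), -2)
  expect_true(is.finite(beta_to_m(1)))  # clipped, not infinite
  expect_error(beta_to_m(1.2), "lie in")
  # round trip at 1e-12 over the working range
  b <- seq(0.01, 0.99, by = 0.01)
  expect_equal(m_to_beta(beta_to_m(b)), b, tolerance = 1e-12)
  # strictly increasing
  expect_true(all(diff(beta_to_m(b)) > 0))
})

test_that("detection filter applies the >= 95% rule inclusively", {
  n_samp <- 100
  detp <- named_matrix(rep(1, 3 * n_samp), 3, n_samp)
  detp[1, 1:96] <- 1e-18   # 96 passing -> retained
  detp[2, 1:94] <- 1e-18   # 94 passing -> excluded
  detp[3, 1:95] <- 1e-18   # boundary: exactly 95 -> retained
  kept <- detection_filter(detp)
  expect_setequal(kept, rownames(detp)[c(1, 3)])
  # alignment check against a mismatched methylation matrix
  meth <- named_matrix(runif(3 * 99, 0.2, 0.8), 3, 99)
  expect_error(detection_filter(detp, meth = meth), "aligned")
})

test_that("SNP and autosome probe filter", {
  ann <- data.frame(
    cpg_id = c("cg1", "cg2", "cg3", "cg4", "cg5"),
    chr = c("7", "7", "X", "chr3", "12"),
    snp_distance = c(5, 5, 5, 50, NA),
    maf = c(0.08, 0.05, 0.20, 0.5, NA)
  )
  kept <- snp_probe_filter(ann)
  # cg1: SNP within 10 bp with MAF > 7% -> out; cg3: chr X -> out
  expect_setequal(kept, c("cg2", "cg4", "cg5"))
  expect_error(snp_probe_filter(ann, cpg_ids = c("cg1", "cg99")), "missing")
  expect_warning(
    kept2 <- snp_probe_filter(ann, cpg_ids = c("cg2", "cg99"),
                              missing = "keep"),
    "unannotated")
  expect_setequal(kept2, c("cg2", "cg99"))
})

test_that("timepoint intersection keeps shared CpGs and subjects", {
  m1 <- meth_matrix(matrix(runif(6, 0.3, 0.7), 3, 2,
                           dimnames = list(c("a", "b", "c"), c("s1", "s2"))),
                    "beta")
  m2 <- meth_matrix(matrix(runif(6, 0.3, 0.7), 3, 2,
                           dimnames = list(c("b", "c", "d"), c("s2", "s3"))),
                    "beta")
  out <- intersect_timepoints(m1, m2)
  expect_identical(rownames(out$birth), c("b", "c"))
  expect_identical(colnames(out$age10), "s2")
  m3 <- meth_matrix(matrix(runif(4, 0.3, 0.7), 2, 2,
                           dimnames = list(c("x", "y"), c("s1", "s2"))),
                    "beta")
  expect_error(intersect_timepoints(m1, m3), "no CpGs shared")
})

test_that("residualization is exact OLS per CpG", {
  # hand OLS: 4 samples, binary covariate -> group-mean centering
  X <- cbind(1, c(0, 0, 1, 1))
  rownames(X) <- sprintf("S%03d", 1:4)
  m <- meth_matrix(named_matrix(c(1, 2, 3, 4), 1, 4), "M")
  r <- residualize(m, X)
  expect_equal(unname(unclass(r)[1, ]), c(-0.5, 0.5, -0.5, 0.5),
               tolerance = 1e-12)

  # constant covariates -> centered M values (via the sheet interface)
  sheet <- tiny_sheet(8)
  sheet$season_birth <- "winter"   # constant season would be collinear
  X2 <- timepoint_design(sheet, "birth")
  # constant cell columns + constant season make the design rank deficient
  expect_error(residualize(meth_matrix(named_matrix(rnorm(16), 2, 8), "M"),
                           X2), "rank deficient")

  sheet <- tiny_sheet(16, seed = 1, jitter_cells = TRUE)
  X3 <- timepoint_design(sheet, "birth")
  mm <- named_matrix(rnorm(5 * 16), 5, 16)
  r3 <- residualize(meth_matrix(mm, "M"), X3)
  # residuals orthogonal to every design column and mean zero
  dots <- crossprod(X3, t(unclass(r3)))
  expect_lt(max(abs(dots)), 1e-8 * max(abs(mm)) * nrow(X3))
  # perfect linear dependence on CD4T -> zero residuals
  m_lin <- named_matrix(rep(0, 16), 1, 16)
  m_lin[1, ] <- 2 + 3 * sheet$CD4T_birth
  r_lin <- residualize(meth_matrix(m_lin, "M"), X3)
  expect_lt(max(abs(unclass(r_lin))), 1e-10)
})

test_that("residualization is idempotent", {
  sheet <- tiny_sheet(12, seed = 2, jitter_cells = TRUE)
  X <- timepoint_design(sheet, "age10")
  m <- meth_matrix(named_matrix(rnorm(6 * 12), 6, 12), "M")
  r1 <- residualize(m, X)
  r2 <- residualize(meth_matrix(unclass(r1), "M"), X)
  expect_equal(unclass(r1), unclass(r2), tolerance = 1e-8)
})

test_that("delta residuals subtract birth from age 10", {
  r0 <- meth_matrix(named_matrix(c(0.5, 1), 1, 2), "residual")
  r10 <- meth_matrix(named_matrix(c(2, 0.25), 1, 2), "residual")
  d <- delta_residuals(r10, r0)
  expect_equal(unname(unclass(d)[1, ]), c(1.5, -0.75))
  # identical inputs -> exact zeros
  expect_true(all(delta_residuals(r10, r10) == 0))
  # sign: decline in residual methylation gives a negative delta
  expect_lt(unclass(d)[1, 2], 0)
  # misaligned ids -> error
  r_bad <- meth_matrix(matrix(c(2, 0.25), 1, 2,
                              dimnames = list("other", c("S001", "S002"))),
                       "residual")
  expect_error(delta_residuals(r_bad, r0), "aligned")
})

test_that("zero-noise pipeline yields zero delta at non-effect CpGs", {
  # with no noise and no subject-level baseline deviation, every M value is
  # exactly linear in the cell/season design, so both residual matrices --
  # and hence the delta -- vanish at CpGs without injected effects
  cfg <- sim_config(n_subjects = 24, n_cpgs = 40, n_effect_cpgs_per_mode = 5,
                    effect_size_m = 0.8, global_shift_eff = 0, noise_sd_m = 0,
                    baseline_subject_sd = 0, seed = 9)
  coh <- simulate_cohort(cfg)
  pp <- preprocess_pipeline(coh$birth, coh$age10, coh$sheet)
  affected <- unlist(coh$truth$effect_cpg_ids)
  clean <- setdiff(rownames(pp$delta), affected)
  expect_lt(max(abs(unclass(pp$delta)[clean, ])), 1e-8)
})

test_that("subjects with missing covariates are dropped (complete-case)", {
  coh <- simulate_cohort(sim_config(n_subjects = 20, n_cpgs = 30,
                                    n_effect_cpgs_per_mode = 2, seed = 15))
  sheet <- coh$sheet
  sheet$season_age10[3] <- NA
  sheet$CD4T_birth[7] <- NA
  expect_message(
    pp <- preprocess_pipeline(coh$birth, coh$age10, sheet),
    "dropping 2 subject")
  expect_identical(ncol(pp$delta), 18L)
  expect_false(any(as.character(sheet$subject_id[c(3, 7)]) %in%
                     colnames(pp$delta)))
})

test_that("probe filtering and timepoint intersection commute", {
  set.seed(4)
  m1 <- meth_matrix(named_matrix(runif(40, 0.2, 0.8), 10, 4), "beta")
  m2v <- named_matrix(runif(40, 0.2, 0.8), 10, 4)
  rownames(m2v) <- c(rownames(m1)[3:10], "cgX1", "cgX2")
  m2 <- meth_matrix(m2v, "beta")
  ann <- data.frame(cpg_id = union(rownames(m1), rownames(m2)),
                    chr = rep(c("1", "X"), length.out = 12),
                    snp_distance = NA, maf = NA)
  filter_then_intersect <- intersect_timepoints(
    meth_matrix(unclass(m1)[intersect(rownames(m1), snp_probe_filter(ann)), , drop = FALSE], "beta"),
    meth_matrix(unclass(m2)[intersect(rownames(m2), snp_probe_filter(ann)), , drop = FALSE], "beta"))
  both <- intersect_timepoints(m1, m2)
  keep <- intersect(rownames(both$birth), snp_probe_filter(ann))
  expect_setequal(rownames(filter_then_intersect$birth), keep)
})
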