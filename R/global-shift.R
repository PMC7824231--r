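#' Per-subject mean delta-residual
#'
#' The first epigenome-wide shift outcome: each subject's mean
#' delta-residual across all CpGs.
#'
#' @param delta Delta-residual matrix (CpG x subject).
#' @return Named numeric vector, one mean per subject.
#' @export
per_subject_mean_delta <- function(delta) {
  colMeans(unclass(delta))
}

#' Per-subject quartile percentages of delta-residuals
#'
#' The second epigenome-wide shift outcome. For each subject, Q1 and Q3 of
#' that subject's delta-residuals are computed (25th/75th percentiles,
#' linear interpolation between order statistics). The population medians
#' of these per-subject Q1s and Q3s define the cutoffs; each subject's
#' `pct_below` is the percentage of their CpGs strictly below the median
#' Q1 (pronounced methylation decreases) and `pct_above` the percentage
#' strictly above the median Q3 (pronounced increases).
#'
#' @param delta Delta-residual matrix (CpG x subject); needs at least 2
#'   subjects and 4 CpGs.
#' @return Data frame with `subject_id`, `pct_below`, `pct_above` plus
#'   attributes `q1_median` and `q3_median`.
#' @export
quartile_percentages <- function(delta) {
  M <- unclass(delta)
  if (ncol(M) < 2 || nrow(M) < 4) {
    stop("need at least 2 subjects and 4 CpGs", call. = FALSE)
  }
  q1 <- apply(M, 2, quantile, probs = 0.25, type = 7, names = FALSE)
  q3 <- apply(M, 2, quantile, probs = 0.75, type = 7, names = FALSE)
  m1 <- median(q1)
  m3 <- median(q3)
  if (m1 == m3) {
    warning("degenerate delta distribution: median Q1 equals median Q3")
  }
  out <- data.frame(
    subject_id = colnames(M),
    pct_below = 100 * colMeans(M < m1),
    pct_above = 100 * colMeans(M > m3),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  structure(out, q1_median = m1, q3_median = m3)
}

#' Regress a per-subject global statistic on feeding modes
#'
#' OLS of a per-subject outcome (mean delta-residual or a quartile
#' percentage) on EFF and Mixed dummies (EBF as reference) plus the full
#' confounder design.
#'
#' @param per_subject_stat Named numeric vector (names = subject ids) or a
#'   vector aligned with the sheet.
#' @param sheet Sample sheet with feeding mode and confounders.
#' @param outcome_label Label recorded in the output rows.
#' @return Data frame with one row per non-reference feeding mode:
#'   `outcome`, `mode`, `coefficient`, `se`, `p_value`.
#' @export
regress_global <- function(per_subject_stat, sheet,
                           outcome_label = "statistic") {
  sheet <- validate_sample_sheet(sheet)
  if (!is.null(names(per_subject_stat))) {
    idx <- match(names(per_subject_stat), sheet$subject_id)
    if (anyNA(idx)) stop("sheet does not cover all subjects", call. = FALSE)
    sheet <- sheet[idx, ]
  } else if (length(per_subject_stat) != nrow(sheet)) {
    stop("statistic length does not match the sheet", call. = FALSE)
  }
  modes <- as.character(sheet$feeding_mode)
  X <- cbind(confounder_design(sheet),
             EFF = as.numeric(modes == "EFF"),
             Mixed = as.numeric(modes == "Mixed"))
  check_full_rank(X)
  y <- matrix(as.numeric(per_subject_stat), ncol = 1)
  rows <- lapply(c("EFF", "Mixed"), function(mode) {
    fit <- ols_matrix(X, y, which = match(mode, colnames(X)))
    data.frame(outcome = outcome_label, mode = mode,
               coefficient = unname(fit$coef), se = unname(fit$se),
               p_value = unname(fit$p), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Normality diagnostics for regression outcomes
#'
#' Shapiro-Wilk test per outcome plus Mardia-style multivariate skewness
#' and kurtosis when several outcomes are supplied. Report-only: the
#' pipeline never gates on these diagnostics.
#'
#' @param x Numeric vector or matrix/data frame of outcome columns
#'   (n >= 8 rows).
#' @return List with `shapiro` (data frame: outcome, W, p, degenerate) and,
#'   for multivariate input, `mardia` (skewness/kurtosis statistics with
#'   p-values).
#' @export
check_normality <- function(x) {
  X <- as.matrix(x)
  if (nrow(X) < 8) stop("need at least 8 observations", call. = FALSE)
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  shap <- do.call(rbind, lapply(colnames(X), function(cn) {
    v <- X[, cn]
    if (sd(v) == 0) {
      return(data.frame(outcome = cn, W = NA_real_, p = NA_real_,
                        degenerate = TRUE))
    }
    # shapiro.test caps n at 5000
    if (length(v) > 5000) v <- v[seq_len(5000)]
    st <- shapiro.test(v)
    data.frame(outcome = cn, W = unname(st$statistic),
               p = st$p.value, degenerate = FALSE)
  }))
  out <- list(shapiro = shap)
  if (ncol(X) > 1 && !any(shap$degenerate)) {
    out$mardia <- mardia_test(X)
  }
  out
}

# Mardia's multivariate skewness b1p and kurtosis b2p with their
# asymptotic chi-square / normal reference distributions.
mardia_test <- function(X) {
  n <- nrow(X); d <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / n
  Sinv <- solve(S)
  G <- Xc %*% Sinv %*% t(Xc)
  b1 <- sum(G^3) / n^2
  b2 <- mean(diag(G)^2)
  skew_stat <- n * b1 / 6
  skew_df <- d * (d + 1) * (d + 2) / 6
  kurt_stat <- (b2 - d * (d + 2)) / sqrt(8 * d * (d + 2) / n)
  data.frame(
    measure = c("skewness", "kurtosis"),
    statistic = c(skew_stat, kurt_stat),
    p = c(stats::pchisq(skew_stat, skew_df, lower.tail = FALSE),
          2 * pnorm(-abs(kurt_stat)))
  )
}

#' Full global methylation-shift analysis
#'
#' Computes the three per-subject outcomes (mean delta-residual,
#' percentage below the population-median Q1, percentage above the
#' population-median Q3), regresses each on the feeding modes with
#' confounder adjustment, and attaches normality diagnostics.
#'
#' @param delta Delta-residual matrix (CpG x subject).
#' @param sheet Sample sheet.
#' @return List with `results` (regression rows for the three outcomes),
#'   `per_subject` (data frame of the intermediates) and `normality`.
#' @export
global_shift_analysis <- function(delta, sheet) {
  means <- per_subject_mean_delta(delta)
  qp <- quartile_percentages(delta)
  per_subject <- data.frame(subject_id = qp$subject_id,
                            mean_delta = unname(means[qp$subject_id]),
                            pct_below = qp$pct_below,
                            pct_above = qp$pct_above)
  res <- rbind(
    regress_global(means, sheet, "mean_delta"),
    regress_global(setNames(qp$pct_below, qp$subject_id), sheet, "pct_below_q1"),
    regress_global(setNames(qp$pct_above, qp$subject_id), sheet, "pct_above_q3")
  )
  norm <- check_normality(per_subject[, c("mean_delta", "pct_below",
                                          "pct_above")])
  list(results = res, per_subject = per_subject, normality = norm)
}
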