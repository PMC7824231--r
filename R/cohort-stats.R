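#' One-sample proportion test
#'
#' Normal-approximation z-test of a sample proportion against a population
#' proportion. By default no continuity correction is applied (the variant
#' whose p-values match the published representativeness comparisons); the
#' corrected variant is available via `correct = TRUE`.
#'
#' @param x Successes in the sample.
#' @param n Sample size.
#' @param p0 Population proportion in `(0, 1)`.
#' @param correct Apply a continuity correction (default `FALSE`).
#' @return List with `z` and two-sided `p_value`.
#' @examples
#' one_sample_prop_test(116, 201, 748 / 1456)  # p ~ 0.07
#' @export
one_sample_prop_test <- function(x, n, p0, correct = FALSE) {
  stopifnot(n > 0, x >= 0, x <= n)
  if (p0 <= 0 || p0 >= 1) stop("p0 must lie strictly in (0, 1)",
                               call. = FALSE)
  diff <- x / n - p0
  if (correct) {
    diff <- sign(diff) * max(0, abs(diff) - 1 / (2 * n))
  }
  z <- diff / sqrt(p0 * (1 - p0) / n)
  list(z = z, p_value = 2 * pnorm(-abs(z)))
}

#' Goodness-of-fit chi-square against population proportions
#'
#' Pearson chi-square comparing observed multinomial counts against
#' expected counts from population proportions (df = k - 1), via
#' [stats::chisq.test()].
#'
#' @param observed Integer count vector (k categories).
#' @param population_props Population proportions summing to 1.
#' @return List with `statistic`, `df` and `p_value`.
#' @examples
#' gof_chisq(c(80, 60, 48), c(491, 394, 267) / 1152)  # p ~ 0.69
#' @export
gof_chisq <- function(observed, population_props) {
  if (abs(sum(population_props) - 1) > 1e-9) {
    stop("population proportions must sum to 1", call. = FALSE)
  }
  if (sum(observed) <= 0) stop("observed total must be positive",
                               call. = FALSE)
  if (any(population_props <= 0)) {
    stop("all expected counts must be positive", call. = FALSE)
  }
  ct <- stats::chisq.test(observed, p = population_props)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}

#' One-sample t-test from summary statistics
#'
#' @param sample_mean,sample_sd Sample mean and standard deviation.
#' @param n Sample size (>= 2).
#' @param mu0 Population mean under the null.
#' @return List with `t`, `df` and two-sided `p_value`.
#' @export
one_sample_t <- function(sample_mean, sample_sd, n, mu0) {
  stopifnot(n >= 2)
  if (sample_sd <= 0) stop("sample SD must be positive", call. = FALSE)
  t <- (sample_mean - mu0) / (sample_sd / sqrt(n))
  list(t = t, df = n - 1, p_value = 2 * pt(-abs(t), n - 1))
}

#' Representativeness tests of an analytical sample against its cohort
#'
#' Runs the appropriate test for each row group of a long-format margins
#' table: binary variables get a one-sample proportion test, multi-category
#' variables a goodness-of-fit chi-square against the cohort proportions,
#' continuous variables a one-sample t-test of the sample mean against the
#' cohort mean.
#'
#' @param margins Data frame with columns `variable`, `type`
#'   (`"proportion"`, `"multinomial"`, `"continuous"`), `category`,
#'   `sample_x`, `sample_n`, `pop_x`, `pop_n` (counts for categorical
#'   rows) and `sample_mean`, `sample_sd`, `pop_mean` (continuous rows).
#' @return Data frame with one row per variable: `variable`, `test`,
#'   `statistic`, `p_value`.
#' @export
representativeness_tests <- function(margins) {
  needed <- c("variable", "type")
  stopifnot(all(needed %in% names(margins)))
  groups <- split(margins, factor(margins$variable,
                                  levels = unique(margins$variable)))
  rows <- lapply(groups, function(g) {
    type <- g$type[1]
    if (type == "proportion") {
      r <- one_sample_prop_test(g$sample_x[1], g$sample_n[1],
                                g$pop_x[1] / g$pop_n[1])
      data.frame(variable = g$variable[1], test = "prop_z",
                 statistic = r$z, p_value = r$p_value)
    } else if (type == "multinomial") {
      r <- gof_chisq(g$sample_x, g$pop_x / sum(g$pop_x))
      data.frame(variable = g$variable[1], test = "chisq_gof",
                 statistic = r$statistic, p_value = r$p_value)
    } else if (type == "continuous") {
      r <- one_sample_t(g$sample_mean[1], g$sample_sd[1], g$sample_n[1],
                        g$pop_mean[1])
      data.frame(variable = g$variable[1], test = "t_one_sample",
                 statistic = r$t, p_value = r$p_value)
    } else {
      stop("unknown margins type: ", type, call. = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Gene-location groups; multi-valued labels (semicolon-separated) count in
# every group they mention. The body group includes first exons.
TSS_LABELS <- c("TSS200", "TSS1500")
BODY_LABELS <- c("Body", "1stExon")
KNOWN_LOCATIONS <- c(TSS_LABELS, BODY_LABELS, "5'UTR", "3'UTR", "")

#' Gene-location distribution of screened CpGs across feeding modes
#'
#' Builds 2-by-k contingency tables (TSS membership vs not; gene-body
#' membership vs not, body including first exon) for the CpG lists of each
#' feeding mode and tests each table with a Pearson chi-square. CpGs with
#' multiple location labels count in every group they mention.
#'
#' @param cpg_lists Named list (>= 2 feeding modes) of CpG id vectors.
#' @param annotation Data frame with `cpg_id` and `location`
#'   (semicolon-separated labels from TSS200, TSS1500, 5'UTR, 1stExon,
#'   Body, 3'UTR; empty for intergenic probes).
#' @return List with elements `tss` and `body`, each holding `table`,
#'   `statistic`, `df`, `p_value`.
#' @export
location_enrichment <- function(cpg_lists, annotation) {
  if (length(cpg_lists) < 2) {
    stop("need CpG lists for at least two feeding modes", call. = FALSE)
  }
  stopifnot(all(c("cpg_id", "location") %in% names(annotation)))
  get_labels <- function(ids) {
    idx <- match(ids, annotation$cpg_id)
    if (anyNA(idx)) stop("unannotated CpG(s): ",
                         paste(head(ids[is.na(idx)], 3), collapse = ", "),
                         call. = FALSE)
    loc <- as.character(annotation$location[idx])
    loc[is.na(loc)] <- ""
    labs <- strsplit(loc, ";\\s*")
    bad <- setdiff(unlist(labs), KNOWN_LOCATIONS)
    if (length(bad)) stop("unknown location label(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    labs
  }
  one_group <- function(group_labels) {
    counts <- vapply(cpg_lists, function(ids) {
      labs <- get_labels(ids)
      inside <- vapply(labs, function(l) any(l %in% group_labels), logical(1))
      c(sum(inside), sum(!inside))
    }, numeric(2))
    rownames(counts) <- c("in_group", "not_in_group")
    ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    list(table = counts, statistic = unname(ct$statistic),
         df = unname(ct$parameter), p_value = ct$p.value)
  }
  list(tss = one_group(TSS_LABELS), body = one_group(BODY_LABELS))
}

#' Temporal-stability classification of CpGs between ages 10 and 18
#'
#' For each CpG, fits a linear mixed model of the M-values on an age
#' indicator with a subject-level random intercept (REML via
#' \pkg{lmerTest}). A CpG is called `dynamic` when the age-effect p-value
#' is below `threshold` (default 0.1, deliberately liberal and with no
#' multiplicity adjustment so that instability is not missed), otherwise
#' `stable`.
#'
#' Because the function restricts both matrices to their shared subjects,
#' the design is always balanced and complete, and the REML solution for
#' the age effect then has a closed form: the age-effect t-test of the
#' random-intercept model coincides exactly with the paired t-test on the
#' per-subject differences. The default `method = "exact"` computes that
#' closed form, vectorized over CpGs; `method = "lmer"` fits the mixed
#' model numerically via \pkg{lmerTest} and exists mainly as a
#' cross-check (the two differ only when the REML variance component is
#' truncated at zero, where the numerical fit falls back to a pooled-df
#' test).
#'
#' @param m10,m18 M-scale (or residual) matrices at ages 10 and 18, CpG x
#'   subject; subjects are intersected.
#' @param cpg_ids CpGs to classify (default: all shared CpGs).
#' @param threshold Age-effect p-value below which a CpG is called dynamic.
#' @param method `"exact"` (closed-form REML, default) or `"lmer"`.
#' @return Data frame with `cpg_id`, `estimate` (age-18 minus age-10
#'   effect), `p_value` and `call`.
#' @export
stability_classify <- function(m10, m18, cpg_ids = NULL, threshold = 0.1,
                               method = c("exact", "lmer")) {
  method <- match.arg(method)
  subjects <- intersect(colnames(m10), colnames(m18))
  if (length(subjects) < 3) stop("need at least 3 paired subjects",
                                 call. = FALSE)
  cpgs <- intersect(rownames(m10), rownames(m18))
  if (!is.null(cpg_ids)) cpgs <- intersect(cpgs, cpg_ids)
  if (length(cpgs) == 0) stop("no CpGs to classify", call. = FALSE)
  A <- unclass(m10)[cpgs, subjects, drop = FALSE]
  B <- unclass(m18)[cpgs, subjects, drop = FALSE]
  ns <- length(subjects)

  if (method == "exact") {
    D <- B - A
    est <- rowMeans(D)
    sd_d <- sqrt(pmax(rowSums((D - est)^2), 0) / (ns - 1))
    se <- sd_d / sqrt(ns)
    tval <- est / se
    pv <- 2 * pt(-abs(tval), ns - 1)
    pv[!is.finite(pv)] <- 1        # zero-variance differences: no evidence
    out <- data.frame(cpg_id = cpgs, estimate = unname(est),
                      p_value = unname(pv), stringsAsFactors = FALSE)
  } else {
    subj <- factor(rep(subjects, 2))
    age <- rep(c(0, 1), each = ns)
    ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                              check.conv.singular = "ignore")
    rows <- lapply(seq_along(cpgs), function(i) {
      y <- c(A[i, ], B[i, ])
      fit <- suppressMessages(suppressWarnings(
        lmerTest::lmer(y ~ age + (1 | subj), REML = TRUE, control = ctrl)))
      cf <- coef(summary(fit))
      data.frame(cpg_id = cpgs[i], estimate = cf["age", "Estimate"],
                 p_value = cf["age", "Pr(>|t|)"], stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$p_value[is.nan(out$p_value)] <- 1
  }
  out$call <- ifelse(out$p_value < threshold, "dynamic", "stable")
  rownames(out) <- NULL
  out
}

#' Per-feeding-group regression of a health outcome on one CpG's delta
#'
#' Fits a separate OLS line of a continuous health outcome (e.g. lung
#' function, log IgE, log BMI) on the delta-residual of one CpG within
#' each feeding group, producing plot-ready slopes and intercepts.
#'
#' @param delta_cpg Per-subject delta-residuals at one CpG.
#' @param outcome Continuous outcome, aligned with `delta_cpg`.
#' @param modes Feeding-mode labels, aligned with `delta_cpg`.
#' @return Data frame with `mode`, `intercept`, `slope`, `n`; groups with
#'   fewer than 3 subjects are skipped with a warning.
#' @export
outcome_by_feeding_regression <- function(delta_cpg, outcome, modes) {
  stopifnot(length(delta_cpg) == length(outcome),
            length(outcome) == length(modes))
  rows <- lapply(unique(as.character(modes)), function(mode) {
    sel <- modes == mode & !is.na(outcome) & !is.na(delta_cpg)
    if (sum(sel) < 3) {
      warning(sprintf("feeding group %s has < 3 subjects; skipped", mode))
      return(NULL)
    }
    fit <- lm(outcome[sel] ~ delta_cpg[sel])
    data.frame(mode = mode, intercept = unname(coef(fit)[1]),
               slope = unname(coef(fit)[2]), n = sum(sel),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no feeding group had at least 3 subjects",
                         call. = FALSE)
  out
}
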