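#' Confounder-adjusted regression for one CpG
#'
#' Ordinary least squares of a CpG's delta-residuals on the feeding
#' indicator plus the full confounder design (see [confounder_design()]).
#' The coefficient is the change in birth-to-10y methylation (M-units)
#' associated with the feeding mode; a negative coefficient indicates a
#' methylation decrease relative to unexposed subjects.
#'
#' @param delta_row Numeric vector of delta-residuals, one per subject.
#' @param feeding Binary indicator for the feeding mode.
#' @param confounders Design matrix with intercept (subjects x covariates)
#'   aligned with `delta_row`.
#' @return List with `coefficient`, `se`, `p_value` and `df`.
#' @export
fit_adjusted <- function(delta_row, feeding, confounders) {
  f <- as.numeric(factor(feeding)) - 1
  X <- cbind(confounders, feeding = f)
  check_full_rank(X)
  fit <- ols_matrix(X, matrix(delta_row, ncol = 1), which = ncol(X))
  list(coefficient = unname(fit$coef), se = unname(fit$se),
       p_value = unname(fit$p), df = fit$df)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values via [stats::p.adjust()] with
#' `method = "BH"`.
#'
#' @param raw_p Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values (empty input gives an empty vector).
#' @export
bh_fdr <- function(raw_p) {
  if (length(raw_p) == 0) return(numeric(0))
  if (any(raw_p <= 0 | raw_p > 1, na.rm = TRUE)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p.adjust(raw_p, method = "BH")
}

#' Adjusted EWAS over a screened CpG set
#'
#' Fits [fit_adjusted()] for every screened CpG of one feeding mode and
#' applies FDR adjustment within the mode (each feeding mode's EWAS is
#' treated as a separate family).
#'
#' @param delta Delta-residual matrix (CpG x subject).
#' @param sheet Sample sheet (confounders + feeding mode).
#' @param cpg_ids CpGs to test (e.g. `result$cpg_id[result$selected]` from
#'   [tt_screen()]).
#' @param mode Feeding mode (`"EBF"`, `"EFF"` or `"Mixed"`) contrasted
#'   against all other subjects.
#' @param annotation Optional probe annotation joined onto the output by
#'   `cpg_id`.
#' @return Data frame with columns `cpg_id`, `mode`, `coefficient`, `se`,
#'   `p_raw`, `p_fdr` and `direction` (sign of the coefficient).
#' @export
run_ewas <- function(delta, sheet, cpg_ids, mode, annotation = NULL) {
  stopifnot(mode %in% FEEDING_MODES)
  sheet <- validate_sample_sheet(sheet)
  idx <- match(colnames(delta), sheet$subject_id)
  if (anyNA(idx)) stop("sheet does not cover all subjects", call. = FALSE)
  sheet <- sheet[idx, ]
  feeding <- as.integer(as.character(sheet$feeding_mode) == mode)
  design <- confounder_design(sheet)

  cpg_ids <- intersect(cpg_ids, rownames(delta))
  if (length(cpg_ids) == 0) {
    out <- data.frame(cpg_id = character(0), mode = character(0),
                      coefficient = numeric(0), se = numeric(0),
                      p_raw = numeric(0), p_fdr = numeric(0),
                      direction = integer(0))
    return(out)
  }
  X <- cbind(design, feeding = feeding)
  check_full_rank(X)
  Y <- t(unclass(delta)[cpg_ids, , drop = FALSE])
  fit <- ols_matrix(X, Y, which = ncol(X))
  out <- data.frame(cpg_id = cpg_ids, mode = mode,
                    coefficient = unname(fit$coef), se = unname(fit$se),
                    p_raw = unname(fit$p),
                    p_fdr = bh_fdr(unname(fit$p)),
                    direction = sign(unname(fit$coef)),
                    stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    out <- merge(out, annotation, by = "cpg_id", all.x = TRUE, sort = FALSE)
  }
  out[order(out$cpg_id), , drop = FALSE]
}

#' Direction summary and plot data for EWAS results
#'
#' Counts positive, negative and exactly-zero coefficients per feeding
#' mode and prepares volcano-plot data (coefficient vs -log10 raw p).
#'
#' @param rows EWAS result rows from [run_ewas()] (one or several modes
#'   row-bound).
#' @return List with `counts` (mode, n_positive, n_negative, n_zero) and
#'   `volcano` (cpg_id, mode, coefficient, neg_log10_p, direction).
#' @export
direction_summary <- function(rows) {
  if (nrow(rows) == 0) stop("no EWAS rows to summarize", call. = FALSE)
  counts <- do.call(rbind, lapply(split(rows, rows$mode), function(d) {
    data.frame(mode = d$mode[1],
               n_positive = sum(d$coefficient > 0),
               n_negative = sum(d$coefficient < 0),
               n_zero = sum(d$coefficient == 0))
  }))
  rownames(counts) <- NULL
  volcano <- data.frame(cpg_id = rows$cpg_id, mode = rows$mode,
                        coefficient = rows$coefficient,
                        neg_log10_p = -log10(rows$p_raw),
                        direction = sign(rows$coefficient))
  list(counts = counts, volcano = volcano)
}

#' Volcano plot of adjusted EWAS results
#'
#' @param rows EWAS rows from [run_ewas()].
#' @param alpha Raw p-value line to draw (default 0.05).
#' @return A ggplot object.
#' @export
plot_volcano <- function(rows, alpha = 0.05) {
  v <- direction_summary(rows)$volcano
  v$sign <- factor(ifelse(v$coefficient >= 0, "positive", "negative"),
                   levels = c("negative", "positive"))
  ggplot2::ggplot(v, ggplot2::aes(x = .data$coefficient,
                                  y = .data$neg_log10_p,
                                  colour = .data$sign)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(negative = "#2166AC",
                                            positive = "#B2182B")) +
    ggplot2::facet_wrap(~mode) +
    ggplot2::labs(x = "coefficient (Δ M-value)",
                  y = "-log10(raw p)", colour = "direction") +
    ggplot2::theme_minimal()
}

#' Bar plot of coefficient directions per feeding mode
#'
#' @param rows EWAS rows from [run_ewas()].
#' @return A ggplot object.
#' @export
plot_direction_bars <- function(rows) {
  v <- direction_summary(rows)$volcano
  v$sign <- factor(ifelse(v$coefficient >= 0, "positive", "negative"),
                   levels = c("negative", "positive"))
  ggplot2::ggplot(v, ggplot2::aes(x = .data$mode, fill = .data$sign)) +
    ggplot2::geom_bar(position = "dodge") +
    ggplot2::scale_fill_manual(values = c(negative = "#2166AC",
                                          positive = "#B2182B")) +
    ggplot2::labs(x = "feeding mode", y = "number of CpGs",
                  fill = "coefficient sign") +
    ggplot2::theme_minimal()
}
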