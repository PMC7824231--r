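#' Beta value from methylated/unmethylated intensities
#'
#' beta = M / (c + M + U), where `c` is a small constant guarding against a
#' zero denominator. Illumina convention uses c = 100; the constant is
#' exposed because array-processing pipelines differ.
#'
#' @param methylated,unmethylated Non-negative intensity vectors/matrices.
#' @param c Non-negative offset constant (default 100).
#' @return Beta values in `[0, 1)`.
#' @examples
#' beta_from_intensities(300, 100, c = 0)  # 0.75
#' @export
beta_from_intensities <- function(methylated, unmethylated, c = 100) {
  if (any(methylated < 0, na.rm = TRUE) || any(unmethylated < 0, na.rm = TRUE) ||
      c < 0) {
    stop("intensities and `c` must be non-negative", call. = FALSE)
  }
  denom <- c + methylated + unmethylated
  if (any(denom == 0, na.rm = TRUE)) {
    stop("c + methylated + unmethylated must be positive", call. = FALSE)
  }
  methylated / denom
}

#' Beta/M-value transformation
#'
#' M = log2(beta / (1 - beta)). Beta values are clipped to
#' `[clip, 1 - clip]` before the logit so that boundary values stay finite.
#'
#' @param beta Beta values in `(0, 1)` (values exactly 0 or 1 are clipped).
#' @param clip Clipping bound (default `1e-6`).
#' @return M-values.
#' @examples
#' beta_to_m(0.8)    # 2
#' m_to_beta(-2)     # 0.2
#' @export
beta_to_m <- function(beta, clip = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    stop("beta values must lie in [0, 1]", call. = FALSE)
  }
  b <- pmin(pmax(beta, clip), 1 - clip)
  log2(b / (1 - b))
}

#' @param m M-values.
#' @rdname beta_to_m
#' @export
m_to_beta <- function(m) {
  1 / (1 + 2^(-m))
}

#' Detection p-value probe filter
#'
#' A CpG is retained when the fraction of samples in which its detection
#' p-value falls below `threshold` is at least `min_frac` (inclusive
#' boundary: exactly 95% of samples passing keeps the probe).
#'
#' @param detection_p CpG-by-sample matrix of detection p-values with CpG
#'   row names.
#' @param threshold Detection p-value cutoff (default `1e-16`).
#' @param min_frac Minimum fraction of passing samples (default 0.95).
#' @param meth Optional methylation matrix to check row/column alignment
#'   against.
#' @return Character vector of retained CpG identifiers.
#' @export
detection_filter <- function(detection_p, threshold = 1e-16,
                             min_frac = 0.95, meth = NULL) {
  if (!is.matrix(detection_p) || is.null(rownames(detection_p))) {
    stop("`detection_p` must be a matrix with CpG row names", call. = FALSE)
  }
  if (!is.null(meth)) {
    if (!identical(dim(detection_p), dim(meth)) ||
        !identical(rownames(detection_p), rownames(meth)) ||
        !identical(colnames(detection_p), colnames(meth))) {
      stop("detection matrix is not aligned with the methylation matrix",
           call. = FALSE)
    }
  }
  frac_pass <- rowMeans(detection_p < threshold)
  rownames(detection_p)[frac_pass >= min_frac]
}

#' SNP-proximity and autosome probe filter
#'
#' Excludes probes with a SNP within `max_distance` base pairs whose minor
#' allele frequency exceeds `maf_cutoff`, and probes not on autosomes
#' (chromosomes 1-22).
#'
#' @param annotation Data frame with columns `cpg_id`, `chr`,
#'   `snp_distance` (bp; `NA` or `Inf` when no SNP nearby) and `maf`.
#' @param cpg_ids CpGs to filter; defaults to all annotated CpGs.
#' @param max_distance SNP distance cutoff in bp (default 10).
#' @param maf_cutoff Minor-allele-frequency cutoff (default 0.07; probes
#'   with MAF strictly greater are excluded).
#' @param missing Policy for queried CpGs absent from the annotation:
#'   `"error"` (default) or `"keep"` (retain with a warning).
#' @return Character vector of retained CpG identifiers.
#' @export
snp_probe_filter <- function(annotation, cpg_ids = NULL, max_distance = 10,
                             maf_cutoff = 0.07,
                             missing = c("error", "keep")) {
  missing <- match.arg(missing)
  stopifnot(all(c("cpg_id", "chr", "snp_distance", "maf") %in% names(annotation)))
  if (is.null(cpg_ids)) cpg_ids <- as.character(annotation$cpg_id)
  idx <- match(cpg_ids, annotation$cpg_id)
  if (anyNA(idx)) {
    absent <- cpg_ids[is.na(idx)]
    if (missing == "error") {
      stop(sprintf("%d CpG(s) missing from annotation (e.g. %s)",
                   length(absent), absent[1]), call. = FALSE)
    }
    warning(sprintf("%d unannotated CpG(s) retained", length(absent)))
  }
  ann <- annotation[idx[!is.na(idx)], ]
  chr <- sub("^chr", "", as.character(ann$chr))
  autosomal <- chr %in% as.character(1:22)
  dist <- ann$snp_distance
  dist[is.na(dist)] <- Inf
  maf <- ann$maf
  maf[is.na(maf)] <- 0
  snp_hit <- dist <= max_distance & maf > maf_cutoff
  keep_ann <- as.character(ann$cpg_id)[autosomal & !snp_hit]
  c(keep_ann, cpg_ids[is.na(idx)])
}

#' Restrict two timepoints to shared CpGs and subjects
#'
#' The longitudinal analysis is restricted to paired data: CpGs and
#' subjects present at both birth and age 10. Output matrices share an
#' identical ordered CpG set and subject set (order of appearance in the
#' birth matrix).
#'
#' @param birth,age10 [meth_matrix()] objects.
#' @return List with elements `birth`, `age10` (aligned matrices) and
#'   `subjects` (shared subject ids).
#' @export
intersect_timepoints <- function(birth, age10) {
  cpgs <- intersect(rownames(birth), rownames(age10))
  subjects <- intersect(colnames(birth), colnames(age10))
  if (length(cpgs) == 0) stop("no CpGs shared between timepoints", call. = FALSE)
  if (length(subjects) == 0) stop("no subjects shared between timepoints",
                                  call. = FALSE)
  sc <- meth_scale(birth)
  list(
    birth = meth_matrix(as_plain_matrix(birth)[cpgs, subjects, drop = FALSE], sc),
    age10 = meth_matrix(as_plain_matrix(age10)[cpgs, subjects, drop = FALSE], sc),
    subjects = subjects
  )
}

# Error if the design has linearly dependent columns, naming them.
check_full_rank <- function(X) {
  q <- qr(X)
  if (q$rank < ncol(X)) {
    dropped <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("design is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  q
}

#' Residualize M-values on cell-type proportions and season
#'
#' For one timepoint, regresses each CpG's M-values on the cell-type /
#' season design and returns the residuals. Because the design is common
#' to all CpGs, the fit is a single closed-form orthogonal projection
#' (shared QR decomposition), which is exact ordinary least squares for
#' every CpG.
#'
#' @param m_matrix [meth_matrix()] on the M scale (CpG x sample).
#' @param design Either a design matrix (samples x covariates, with
#'   intercept, rownames = sample ids) or a sample sheet, in which case
#'   `timepoint` selects the covariates via [timepoint_design()].
#' @param timepoint Used when `design` is a sample sheet.
#' @return [meth_matrix()] of residuals (scale `"residual"`), same
#'   dimnames as the input.
#' @export
residualize <- function(m_matrix, design, timepoint = c("birth", "age10")) {
  if (is.data.frame(design)) {
    design <- timepoint_design(design, match.arg(timepoint))
  }
  if (!identical(meth_scale(m_matrix), "M")) {
    stop("`m_matrix` must be on the M scale (use beta_to_m())", call. = FALSE)
  }
  samples <- colnames(m_matrix)
  if (is.null(rownames(design)) || !all(samples %in% rownames(design))) {
    stop("design rows do not cover all samples in the matrix", call. = FALSE)
  }
  X <- design[samples, , drop = FALSE]
  q <- check_full_rank(X)
  resid_t <- qr.resid(q, t(as_plain_matrix(m_matrix)))
  out <- t(resid_t)
  dimnames(out) <- dimnames(m_matrix)
  meth_matrix(out, "residual")
}

#' Delta-residuals: age-10 residual minus birth residual
#'
#' The pipeline outcome: per-CpG, per-subject change in residualized
#' methylation from birth to age 10. A negative value means methylation
#' declined (relative to the covariate-explained level) over childhood.
#'
#' @param resid_age10,resid_birth Residual-scale [meth_matrix()] objects
#'   with identical dimnames (use [intersect_timepoints()] first).
#' @return A `delta_matrix`: numeric CpG-by-subject matrix of
#'   delta-residuals.
#' @export
delta_residuals <- function(resid_age10, resid_birth) {
  if (!identical(dimnames(resid_age10), dimnames(resid_birth))) {
    stop("residual matrices are not aligned; run intersect_timepoints()",
         call. = FALSE)
  }
  if (!identical(meth_scale(resid_age10), "residual") ||
      !identical(meth_scale(resid_birth), "residual")) {
    stop("inputs must be residual-scale matrices from residualize()",
         call. = FALSE)
  }
  out <- as_plain_matrix(resid_age10) - as_plain_matrix(resid_birth)
  structure(out, class = c("delta_matrix", class(out)))
}

#' @export
print.delta_matrix <- function(x, ...) {
  cat(sprintf("<delta_matrix> %d CpGs x %d subjects\n", nrow(x), ncol(x)))
  invisible(x)
}

#' Full preprocessing pipeline from paired beta matrices
#'
#' Convenience wrapper: optional probe QC, beta-to-M transformation,
#' pairing of timepoints, per-timepoint residualization and
#' delta-residual construction.
#'
#' @param beta_birth,beta_age10 Beta-scale [meth_matrix()] objects.
#' @param sheet Sample sheet covering all subjects.
#' @param detection_p_birth,detection_p_age10 Optional detection p-value
#'   matrices for [detection_filter()].
#' @param annotation Optional probe annotation for [snp_probe_filter()].
#' @param clip Beta clipping bound for [beta_to_m()].
#' @return List with `delta` (delta_matrix), `resid_birth`, `resid_age10`,
#'   `subjects` and `cpgs`.
#' @export
preprocess_pipeline <- function(beta_birth, beta_age10, sheet,
                                detection_p_birth = NULL,
                                detection_p_age10 = NULL,
                                annotation = NULL, clip = 1e-6) {
  sheet <- validate_sample_sheet(sheet, require_confounders = FALSE)
  keep <- function(mat, detp) {
    ids <- rownames(mat)
    if (!is.null(detp)) ids <- intersect(ids, detection_filter(detp))
    if (!is.null(annotation)) {
      ids <- intersect(ids, snp_probe_filter(annotation, cpg_ids = ids))
    }
    meth_matrix(as_plain_matrix(mat)[ids, , drop = FALSE], "beta")
  }
  b0 <- keep(beta_birth, detection_p_birth)
  b10 <- keep(beta_age10, detection_p_age10)
  paired <- intersect_timepoints(b0, b10)
  m0 <- meth_matrix(beta_to_m(as_plain_matrix(paired$birth), clip = clip), "M")
  m10 <- meth_matrix(beta_to_m(as_plain_matrix(paired$age10), clip = clip), "M")
  sheet_sub <- sheet[match(paired$subjects, sheet$subject_id), ]
  if (anyNA(sheet_sub$subject_id)) {
    stop("sample sheet does not cover all paired subjects", call. = FALSE)
  }
  # complete-case: subjects missing any residualization covariate are
  # dropped from the analytical sample
  covar_cols <- c(paste0(CELL_TYPES, "_birth"), paste0(CELL_TYPES, "_age10"),
                  "season_birth", "season_age10")
  complete <- complete.cases(sheet_sub[, covar_cols])
  if (!all(complete)) {
    message(sprintf("dropping %d subject(s) with missing covariates",
                    sum(!complete)))
    sheet_sub <- sheet_sub[complete, ]
    keep_ids <- as.character(sheet_sub$subject_id)
    m0 <- meth_matrix(as_plain_matrix(m0)[, keep_ids, drop = FALSE], "M")
    m10 <- meth_matrix(as_plain_matrix(m10)[, keep_ids, drop = FALSE], "M")
    paired$subjects <- keep_ids
  }
  r0 <- residualize(m0, sheet_sub, "birth")
  r10 <- residualize(m10, sheet_sub, "age10")
  list(delta = delta_residuals(r10, r0),
       resid_birth = r0, resid_age10 = r10,
       subjects = paired$subjects, cpgs = rownames(paired$birth))
}
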