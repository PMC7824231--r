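#' Configuration for training/testing CpG screening
#'
#' @param n_iterations Number of random train/test splits (default 100).
#' @param train_fraction Fraction of subjects in the training half
#'   (default 2/3).
#' @param alpha_train,alpha_test Significance thresholds that the feeding
#'   coefficient must reach in the training and testing halves
#'   (default 0.05 each).
#' @param retain_fraction A CpG is selected when it is significant in both
#'   halves in at least this fraction of iterations (default 0.5).
#' @param n_sv Number of surrogate variables: `"auto"` (permutation-based
#'   choice, see [estimate_surrogate_variables()]) or a fixed count
#'   (0 disables them).
#' @param robust Use Huber robust regression (default `TRUE`); `FALSE`
#'   gives plain OLS, used by the exact oracle tests.
#' @param seed Integer RNG seed governing the splits.
#' @return A `screening_config` list.
#' @export
screening_config <- function(n_iterations = 100L, train_fraction = 2 / 3,
                             alpha_train = 0.05, alpha_test = 0.05,
                             retain_fraction = 0.5, n_sv = "auto",
                             robust = TRUE, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1,
            alpha_train > 0, alpha_train < 1,
            alpha_test > 0, alpha_test < 1,
            retain_fraction > 0, retain_fraction <= 1,
            n_iterations >= 1)
  structure(list(n_iterations = as.integer(n_iterations),
                 train_fraction = train_fraction,
                 alpha_train = alpha_train, alpha_test = alpha_test,
                 retain_fraction = retain_fraction,
                 n_sv = n_sv, robust = isTRUE(robust),
                 seed = as.integer(seed)),
            class = "screening_config")
}

#' Estimate surrogate variables from a delta-residual matrix
#'
#' Captures unmodelled systematic variation: the primary (feeding) fit is
#' removed from every CpG, and the leading right singular vectors of the
#' resulting CpG-by-subject residual matrix are returned. The number of
#' components is chosen by a permutation scheme in the style of
#' Buja and Eyuboglu: each row of the residual matrix is permuted
#' independently (`n_perm` times, default 20) and a component is kept while
#' its singular value exceeds the 95th percentile of the permuted singular
#' values at the same rank; the count is the length of the leading run.
#'
#' @param delta Delta-residual matrix (CpG x subject).
#' @param primary Feeding indicator (two levels, non-constant), one entry
#'   per subject.
#' @param n_sv `"auto"` (permutation choice) or a fixed non-negative count.
#' @param n_perm Number of row permutations (default 20).
#' @param quantile_cut Permutation percentile a singular value must exceed
#'   (default 0.95).
#' @param max_k Maximum number of components considered (default 10).
#' @return Subjects-by-k matrix of orthonormal surrogate variables
#'   (0 columns allowed).
#' @export
estimate_surrogate_variables <- function(delta, primary, n_sv = "auto",
                                         n_perm = 20L, quantile_cut = 0.95,
                                         max_k = 10L) {
  Y <- unclass(delta)
  n <- ncol(Y)
  if (n < 10) stop("at least 10 subjects are required", call. = FALSE)
  prim <- as.numeric(factor(primary))
  if (length(unique(prim)) < 2) {
    stop("primary variable is constant", call. = FALSE)
  }
  X <- cbind(1, prim)
  qX <- qr(X)
  R <- t(qr.resid(qX, t(Y)))             # CpG x subject residuals

  sing_vals <- function(M, k) {
    ev <- eigen(crossprod(M), symmetric = TRUE, only.values = TRUE)$values
    sqrt(pmax(ev[seq_len(k)], 0))
  }
  max_k <- min(max_k, n - ncol(X), nrow(Y))

  if (identical(n_sv, "auto")) {
    d_obs <- sing_vals(R, max_k)
    perm_d <- matrix(NA_real_, n_perm, max_k)
    for (b in seq_len(n_perm)) {
      # permute the raw data within rows, then residualize exactly as the
      # observed matrix was, so both spectra carry the same projection
      Yp <- t(apply(Y, 1, sample))
      Rp <- t(qr.resid(qX, t(Yp)))
      perm_d[b, ] <- sing_vals(Rp, max_k)
    }
    cut <- apply(perm_d, 2, quantile, probs = quantile_cut, type = 7)
    exceed <- d_obs > cut
    k <- if (exceed[1]) {
      runs <- rle(exceed)
      runs$lengths[1]
    } else 0L
  } else {
    k <- as.integer(n_sv)
    if (k < 0) stop("n_sv must be non-negative", call. = FALSE)
    k <- min(k, max_k)
  }

  if (k == 0L) {
    sv <- matrix(numeric(0), nrow = n, ncol = 0)
  } else {
    dec <- eigen(crossprod(R), symmetric = TRUE)
    sv <- dec$vectors[, seq_len(k), drop = FALSE]
  }
  rownames(sv) <- colnames(Y)
  colnames(sv) <- if (k > 0) paste0("SV", seq_len(k)) else character(0)
  sv
}

#' Training/testing screening of feeding-associated CpGs
#'
#' For each of `n_iterations` random splits of the subjects, the
#' delta-residual of every CpG is regressed on the feeding indicator (plus
#' surrogate variables) separately in the training and testing halves, by
#' Huber robust regression (or OLS when `robust = FALSE`). A CpG is
#' counted for an iteration when the feeding coefficient is significant in
#' both halves, and selected overall when counted in at least
#' `retain_fraction` of iterations. CpGs with zero variance in a half are
#' counted as non-significant for that iteration.
#'
#' @param delta Delta-residual matrix (CpG x subject).
#' @param feeding Binary indicator (logical, 0/1, or two-level factor) for
#'   one feeding mode, one entry per subject; both levels need at least
#'   5 subjects.
#' @param svs Surrogate-variable matrix (subjects x k) or `NULL` to
#'   estimate per `config$n_sv`. Estimated once on the full data and
#'   reused across splits.
#' @param config A [screening_config()].
#' @return A `tt_screening` data frame with columns `cpg_id`, `frequency`
#'   and `selected`, carrying the surrogate variables and config as
#'   attributes.
#' @export
tt_screen <- function(delta, feeding, svs = NULL,
                      config = screening_config()) {
  Y_full <- t(unclass(delta))                  # subjects x CpGs
  n <- nrow(Y_full)
  m <- ncol(Y_full)
  f <- as.numeric(factor(feeding)) - 1
  if (length(f) != n) stop("feeding length does not match subjects",
                           call. = FALSE)
  tab <- table(f)
  if (length(tab) < 2) stop("feeding indicator has a single level",
                            call. = FALSE)
  if (min(tab) < 5) stop("each feeding level needs at least 5 subjects",
                         call. = FALSE)

  if (is.null(svs)) {
    svs <- if (identical(config$n_sv, "auto") ||
               (is.numeric(config$n_sv) && config$n_sv > 0)) {
      estimate_surrogate_variables(delta, f, n_sv = config$n_sv)
    } else {
      matrix(numeric(0), nrow = n, ncol = 0)
    }
  }
  degen_full <- matrixStats_colVars(Y_full) < 1e-24
  if (any(degen_full)) {
    warning(sprintf("%d CpG(s) have (near-)zero variance and are counted as non-significant",
                    sum(degen_full)))
  }

  X <- cbind(`(Intercept)` = 1, feeding = f, svs)
  p <- ncol(X)
  n_train <- round(config$train_fraction * n)
  if (n_train <= p || (n - n_train) <= p) {
    stop("train/test split smaller than the number of model parameters",
         call. = FALSE)
  }

  fit_half <- function(idx) {
    Xh <- X[idx, , drop = FALSE]
    Yh <- Y_full[idx, , drop = FALSE]
    if (length(unique(Xh[, 2])) < 2) {
      return(list(p = rep(NA_real_, m), single_level = TRUE))
    }
    degenerate <- matrixStats_colVars(Yh) < 1e-24
    fit <- if (config$robust) huber_matrix(Xh, Yh, which = 2L)
           else ols_matrix(Xh, Yh, which = 2L)
    pv <- fit$p
    pv[degenerate | !is.finite(pv)] <- NA_real_
    list(p = pv, single_level = FALSE)
  }

  set.seed(config$seed)
  counts <- integer(m)
  n_single_level <- 0L
  for (it in seq_len(config$n_iterations)) {
    train <- sample.int(n, n_train)
    f_train <- fit_half(train)
    f_test <- fit_half(setdiff(seq_len(n), train))
    hit <- !is.na(f_train$p) & !is.na(f_test$p) &
      f_train$p < config$alpha_train & f_test$p < config$alpha_test
    if (f_train$single_level || f_test$single_level) {
      n_single_level <- n_single_level + 1L
    }
    counts <- counts + hit
  }
  if (n_single_level > 0) {
    warning(sprintf("%d iteration(s) had a half with a single feeding level",
                    n_single_level))
  }
  frequency <- counts / config$n_iterations
  out <- data.frame(cpg_id = colnames(Y_full),
                    frequency = frequency,
                    selected = frequency >= config$retain_fraction,
                    stringsAsFactors = FALSE)
  structure(out, svs = svs, config = config,
            class = c("tt_screening", "data.frame"))
}

# Column variances without a matrixStats dependency.
matrixStats_colVars <- function(M) {
  n <- nrow(M)
  if (n < 2) return(rep(0, ncol(M)))
  mu <- colMeans(M)
  (colSums(M^2) - n * mu^2) / (n - 1)
}

#' Screen all three feeding modes
#'
#' Runs one training/testing screen per feeding mode, each contrasting
#' that mode against all other subjects.
#'
#' @param delta Delta-residual matrix (CpG x subject).
#' @param sheet Sample sheet with `feeding_mode` covering every subject
#'   (column order of `delta`).
#' @param config A [screening_config()].
#' @return Named list of [tt_screen()] results (`EBF`, `EFF`, `Mixed`).
#' @export
screen_all_modes <- function(delta, sheet, config = screening_config()) {
  sheet <- validate_sample_sheet(sheet)
  idx <- match(colnames(delta), sheet$subject_id)
  if (anyNA(idx)) stop("sheet does not cover all subjects in delta",
                       call. = FALSE)
  modes <- as.character(sheet$feeding_mode)[idx]
  if (anyNA(modes)) stop("feeding mode missing for some subjects",
                         call. = FALSE)
  out <- lapply(FEEDING_MODES, function(mode) {
    tt_screen(delta, feeding = as.integer(modes == mode), config = config)
  })
  names(out) <- FEEDING_MODES
  out
}

#' Write a screening result as TSV
#'
#' @param result A [tt_screen()] result.
#' @param path Output path.
#' @export
write_screening_result <- function(result, path) {
  data.table::fwrite(as.data.frame(result), path, sep = "\t")
  invisible(path)
}
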