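#' Construct a methylation matrix
#'
#' A methylation matrix is a numeric CpG-by-sample matrix with CpG
#' identifiers as row names and sample (subject) identifiers as column
#' names, carrying a `scale` attribute that records whether the values are
#' beta values (bounded in (0,1)), M-values (logit2 of beta), or residuals
#' from the per-timepoint covariate regression.
#'
#' @param values Numeric matrix, CpGs in rows, samples in columns. Row and
#'   column names are required and must be unique.
#' @param scale One of `"beta"`, `"M"`, `"residual"`.
#' @return A `meth_matrix` object (a numeric matrix with a `scale`
#'   attribute).
#' @examples
#' m <- matrix(c(0.2, 0.8, 0.5, 0.6), 2, 2,
#'             dimnames = list(c("cg01", "cg02"), c("s1", "s2")))
#' meth_matrix(m, "beta")
#' @export
meth_matrix <- function(values, scale = c("beta", "M", "residual")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have CpG row names and sample column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate CpG identifiers in row names", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate sample identifiers in column names", call. = FALSE)
  }
  if (scale == "beta") {
    rng <- range(values, na.rm = TRUE)
    if (rng[1] <= 0 || rng[2] >= 1) {
      stop("beta-scale values must lie strictly in (0, 1)", call. = FALSE)
    }
  }
  structure(values, scale = scale, class = c("meth_matrix", class(values)))
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("<meth_matrix> %d CpGs x %d samples, scale = %s\n",
              nrow(x), ncol(x), attr(x, "scale")))
  cat(sprintf("  CpGs: %s ...\n", paste(head(rownames(x), 3), collapse = ", ")))
  cat(sprintf("  samples: %s ...\n", paste(head(colnames(x), 3), collapse = ", ")))
  invisible(x)
}

meth_scale <- function(x) {
  s <- attr(x, "scale")
  if (is.null(s)) NA_character_ else s
}

# Strip class/attr, keep dimnames.
as_plain_matrix <- function(x) {
  y <- unclass(x)
  attr(y, "scale") <- NULL
  y
}

#' Read / write methylation matrices as TSV
#'
#' Tab-separated text with CpG identifiers in the first column (`cpg_id`)
#' and one column per sample.
#'
#' @param path File path.
#' @param scale Scale label to attach on read (see [meth_matrix()]).
#' @return `read_meth_matrix()` returns a [meth_matrix()];
#'   `write_meth_matrix()` invisibly returns `path`.
#' @export
read_meth_matrix <- function(path, scale = c("beta", "M", "residual")) {
  scale <- match.arg(scale)
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = TRUE)
  ids <- as.character(dt[[1]])
  m <- as.matrix(dt[, -1, with = FALSE])
  rownames(m) <- ids
  meth_matrix(m, scale)
}

#' @param x A [meth_matrix()] (or plain matrix with dimnames).
#' @rdname read_meth_matrix
#' @export
write_meth_matrix <- function(x, path) {
  dt <- data.table::data.table(cpg_id = rownames(x),
                               as_plain_matrix(x))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
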