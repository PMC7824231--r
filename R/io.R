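#' Read a cohort margins table
#'
#' Long-format CSV consumed by [representativeness_tests()]: one row per
#' category (or one row per continuous variable) with sample and
#' population counts or summary statistics. The package ships a worked
#' example under `system.file("extdata", "cohort_margins.csv",
#' package = "methdelta")` with the published margins of a British birth
#' cohort and its methylation substudy.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_cohort_margins <- function(path) {
  data.table::fread(path, data.table = FALSE, na.strings = c("", "NA"))
}

#' Read a probe annotation table
#'
#' CSV with columns `cpg_id`, `chr`, and optionally `gene`, `location`
#' (semicolon-separated gene-location labels), `island_relation`,
#' `snp_distance`, `maf`.
#'
#' @param path CSV path.
#' @return Data frame.
#' @export
read_probe_annotation <- function(path) {
  ann <- data.table::fread(path, data.table = FALSE, na.strings = c("", "NA"))
  if (!"cpg_id" %in% names(ann)) {
    stop("annotation must have a cpg_id column", call. = FALSE)
  }
  ann
}

#' Read / write a delta-residual matrix as TSV
#'
#' @param path File path.
#' @return A `delta_matrix`.
#' @export
read_delta_matrix <- function(path) {
  m <- read_meth_matrix(path, scale = "residual")
  out <- as_plain_matrix(m)
  structure(out, class = c("delta_matrix", class(out)))
}

#' @param delta A `delta_matrix`.
#' @rdname read_delta_matrix
#' @export
write_delta_matrix <- function(delta, path) {
  dt <- data.table::data.table(cpg_id = rownames(delta), unclass(delta))
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
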