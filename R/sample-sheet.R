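#' Validate a sample sheet
#'
#' The sample sheet holds one row per subject with the covariates the
#' pipeline needs: estimated leukocyte proportions at each timepoint
#' (columns `<cell>_birth` and `<cell>_age10` for CD8T, CD4T, NK, Bcell,
#' Mono, Gran), season of blood collection at each timepoint
#' (`season_birth`, `season_age10`; winter/spring/summer/fall with winter
#' as reference), subject-level confounders (`sex`, `maternal_smoking`,
#' `maternal_age`, `birthweight`, `birth_order`, `ses`, `caesarean`,
#' `maternal_asthma`), infant feeding durations (`bf_weeks`,
#' `formula_week`, `solids_week`) and the derived `feeding_mode`.
#'
#' @param sheet A data frame with a `subject_id` column and the columns
#'   described above.
#' @param require_confounders If `TRUE` (default) the full confounder set is
#'   required; set to `FALSE` when only cell/season columns are needed
#'   (e.g. residualization on externally supplied data).
#' @return `sheet`, invisibly, with `season_*`, `birth_order`, `ses` and
#'   `feeding_mode` coerced to factors with their reference level first.
#' @export
validate_sample_sheet <- function(sheet, require_confounders = TRUE) {
  stopifnot(is.data.frame(sheet))
  cell_cols <- c(paste0(CELL_TYPES, "_birth"), paste0(CELL_TYPES, "_age10"))
  needed <- c("subject_id", cell_cols, "season_birth", "season_age10")
  if (require_confounders) {
    needed <- c(needed, "sex", "maternal_smoking", "maternal_age",
                "birthweight", "birth_order", "ses", "caesarean",
                "feeding_mode")
  }
  missing <- setdiff(needed, names(sheet))
  if (length(missing)) {
    stop("sample sheet is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sheet$subject_id)) {
    stop("duplicate subject_id in sample sheet", call. = FALSE)
  }
  for (tp in c("birth", "age10")) {
    props <- as.matrix(sheet[, paste0(CELL_TYPES, "_", tp)])
    if (any(props < 0 | props > 1, na.rm = TRUE)) {
      stop("cell proportions must lie in [0, 1]", call. = FALSE)
    }
    sums <- rowSums(props)
    bad <- which(abs(sums - 1) > 1e-6 & !is.na(sums))
    if (length(bad)) {
      stop(sprintf("cell proportions at %s do not sum to 1 for %d subject(s)",
                   tp, length(bad)), call. = FALSE)
    }
    sea <- as.character(sheet[[paste0("season_", tp)]])
    if (!all(sea[!is.na(sea)] %in% SEASON_LEVELS)) {
      stop("season levels must be one of: ",
           paste(SEASON_LEVELS, collapse = ", "), call. = FALSE)
    }
    sheet[[paste0("season_", tp)]] <- factor(sea, levels = SEASON_LEVELS)
  }
  if ("birth_order" %in% names(sheet)) {
    sheet$birth_order <- factor(as.character(sheet$birth_order),
                                levels = c("1", "2", "3+"))
  }
  if ("ses" %in% names(sheet)) {
    sheet$ses <- factor(as.character(sheet$ses),
                        levels = c("high", "medium", "low"))
  }
  if ("feeding_mode" %in% names(sheet)) {
    sheet$feeding_mode <- factor(as.character(sheet$feeding_mode),
                                 levels = FEEDING_MODES)
  }
  invisible(sheet)
}

#' Per-timepoint cell-type and season design
#'
#' Builds the design matrix used to residualize M-values at one timepoint:
#' an intercept, five cell-type proportions (granulocytes dropped to avoid
#' simplex collinearity), and three season dummies against the winter
#' reference.
#'
#' @param sheet A validated sample sheet (see [validate_sample_sheet()]).
#' @param timepoint `"birth"` or `"age10"`.
#' @return Numeric design matrix with one row per subject, rownames =
#'   `subject_id`.
#' @export
timepoint_design <- function(sheet, timepoint = c("birth", "age10")) {
  timepoint <- match.arg(timepoint)
  sheet <- validate_sample_sheet(sheet, require_confounders = FALSE)
  cells <- setdiff(CELL_TYPES, "Gran")
  d <- data.frame(sheet[, paste0(cells, "_", timepoint)],
                  season = sheet[[paste0("season_", timepoint)]])
  names(d)[seq_along(cells)] <- cells
  X <- model.matrix(~ ., data = d)
  rownames(X) <- as.character(sheet$subject_id)
  X
}

#' Full confounder design for adjusted regressions
#'
#' The adjusted per-CpG and global-shift models include the full confounder
#' list: infant sex, cell compositions and season of blood collection at
#' both timepoints, maternal age at delivery, maternal smoking during
#' pregnancy, mode of delivery (caesarean), birthweight, birth order and
#' family socioeconomic status. Reference levels: winter season, birth
#' order 1, high SES.
#'
#' @inheritParams timepoint_design
#' @return Numeric design matrix (with intercept), rownames = `subject_id`.
#' @export
confounder_design <- function(sheet) {
  sheet <- validate_sample_sheet(sheet)
  cells <- setdiff(CELL_TYPES, "Gran")
  d <- data.frame(
    sheet[, paste0(cells, "_birth")],
    sheet[, paste0(cells, "_age10")],
    season_birth = sheet$season_birth,
    season_age10 = sheet$season_age10,
    sex = as.numeric(sheet$sex %in% c("male", "M", "1", 1, TRUE)),
    maternal_age = sheet$maternal_age,
    maternal_smoking = as.numeric(sheet$maternal_smoking %in% c("yes", 1, TRUE)),
    caesarean = as.numeric(sheet$caesarean %in% c("yes", 1, TRUE)),
    birthweight = sheet$birthweight,
    birth_order = sheet$birth_order,
    ses = sheet$ses
  )
  X <- model.matrix(~ ., data = d)
  rownames(X) <- as.character(sheet$subject_id)
  X
}

#' Read / write sample sheets as CSV
#'
#' @param path File path.
#' @param require_confounders Passed to [validate_sample_sheet()].
#' @return A validated sample sheet data frame.
#' @export
read_sample_sheet <- function(path, require_confounders = TRUE) {
  dt <- data.table::fread(path, data.table = FALSE)
  validate_sample_sheet(dt, require_confounders = require_confounders)
}

#' @param sheet Sample sheet data frame.
#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  data.table::fwrite(sheet, path)
  invisible(path)
}
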