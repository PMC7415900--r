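#' Read and validate a cohort table
#'
#' The cohort CSV indexes one image set per (animal, eye, week): columns
#' `animal_id, eye, group, week, svp_path, dcp_path, choroid_path,
#' structural_path, bscan_stack_path` and optionally `roi_path`. Keys must be
#' unique; RCS follow-up visits occur every three weeks from week 3 to 18.
#'
#' @param path CSV file path.
#' @return A tibble, validated.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(sprintf("Cohort table not found: '%s'.", path))
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_cohort(tbl)
}

#' @rdname read_cohort
#' @param tbl A cohort data frame to validate.
#' @export
validate_cohort <- function(tbl) {
  tbl <- tibble::as_tibble(tbl)
  need <- c("animal_id", "eye", "group", "week")
  miss <- setdiff(need, names(tbl))
  if (length(miss)) abort(paste0("Cohort table lacks columns: ", paste(miss, collapse = ", ")))
  if (!all(tbl$eye %in% c("OD", "OS"))) abort("`eye` must be OD or OS.")
  if (!all(tbl$group %in% c("RCS", "control"))) abort("`group` must be RCS or control.")
  key <- paste(tbl$animal_id, tbl$eye, tbl$week)
  if (anyDuplicated(key)) {
    abort(paste0("Duplicate (animal_id, eye, week) keys: ",
                 paste(unique(key[duplicated(key)]), collapse = "; ")))
  }
  bad <- tbl$group == "RCS" & !tbl$week %in% seq(3, 18, by = 3)
  if (any(bad)) {
    abort(paste0("RCS follow-up weeks must be in {3, 6, 9, 12, 15, 18}; offending weeks: ",
                 paste(unique(tbl$week[bad]), collapse = ", ")))
  }
  tbl
}

#' Write a tidy table to CSV
#'
#' @param rows A data frame.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  readr::write_csv(tibble::as_tibble(rows), path, progress = FALSE)
  invisible(path)
}
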