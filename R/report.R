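#' Validation findings: critical errors and warnings
#'
#' Every loading, validation and cleaning step in the pipeline reports its
#' findings as rows of a *validation report*, a tibble with one finding per
#' row. Findings come in two severities:
#'
#' * `"error"` — critical: the finding would lead to a wrong implementation
#'   calculation (for example an unparseable date, a missing mandatory sheet,
#'   or a gap in regimen coverage). The pipeline refuses to write the
#'   implementation workbook while any error is outstanding.
#' * `"warning"` — an inconsistency the investigator should review (for
#'   example a declared monitor with no raw data). Warnings never block
#'   output.
#'
#' @param severity `"error"` or `"warning"`.
#' @param code Short machine-readable finding code, e.g. `"ON_OFF_PAIR"`.
#' @param sheet Sheet or file the finding refers to (`NA` when global).
#' @param row Workbook/file row number (`NA` when not row-specific). Row 1 is
#'   the header, so the first data row is row 2.
#' @param message Human-readable description.
#' @return A tibble with columns `severity`, `code`, `sheet`, `row`,
#'   `message`.
#' @examples
#' report_entry("warning", "NO_RAW_DATA", "EMInfo", 3,
#'              "no raw events for declared monitor")
#' @export
report_entry <- function(severity, code, sheet = NA_character_, row = NA_integer_,
                         message = "") {
  stopifnot(severity %in% c("error", "warning"))
  tibble::tibble(
    severity = severity,
    code = as.character(code),
    sheet = as.character(sheet),
    row = as.integer(row),
    message = as.character(message)
  )
}

#' @rdname report_entry
#' @export
empty_report <- function() {
  tibble::tibble(
    severity = character(), code = character(), sheet = character(),
    row = integer(), message = character()
  )
}

#' @param ... Validation report tibbles (or `NULL`s, which are dropped).
#' @rdname report_entry
#' @export
bind_reports <- function(...) {
  parts <- purrr::compact(rlang::list2(...))
  if (length(parts) == 0) return(empty_report())
  dplyr::bind_rows(parts)
}

#' @param report A validation report tibble.
#' @rdname report_entry
#' @export
report_errors <- function(report) dplyr::filter(report, .data$severity == "error")

#' @rdname report_entry
#' @export
report_warnings <- function(report) dplyr::filter(report, .data$severity == "warning")

#' @rdname report_entry
#' @export
has_errors <- function(report) nrow(report_errors(report)) > 0
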