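# Cell-level coercion shared by the workbook loader and the in-memory
# constructor. Workbook sheets are read with every cell typed individually
# (list columns), so a date column may legitimately contain native date
# cells, Excel serial numbers, or ISO text; in-memory data frames arrive as
# atomic vectors. Each parser returns the value plus a status so callers can
# distinguish "missing" from "malformed".

cell_at <- function(col, i) {
  if (is.list(col)) col[[i]] else col[i]
}

is_blank_cell <- function(v) {
  is.null(v) || length(v) == 0 || all(is.na(v)) ||
    (is.character(v) && !nzchar(trimws(v)))
}

# Dates: native Date/POSIXct cells, Excel serial numbers, or strict ISO 8601
# text. Ambiguous text like "03/04/2021" is deliberately rejected rather
# than guessed.
parse_cell_date <- function(v) {
  if (is_blank_cell(v)) return(list(value = as.Date(NA), status = "missing"))
  if (inherits(v, "Date")) return(list(value = as.Date(v), status = "ok"))
  if (inherits(v, "POSIXt")) {
    return(list(value = as.Date(format(v, "%Y-%m-%d")), status = "ok"))
  }
  if (is.numeric(v)) {
    if (abs(v - round(v)) < 1e-6 && v > 0) {
      return(list(value = as.Date(round(v), origin = "1899-12-30"), status = "ok"))
    }
    return(list(value = as.Date(NA), status = "bad"))
  }
  if (is.character(v)) {
    s <- trimws(v)
    if (grepl("^\\d{4}-\\d{2}-\\d{2}$", s)) {
      d <- suppressWarnings(as.Date(s, format = "%Y-%m-%d"))
      if (!is.na(d) && format(d, "%Y-%m-%d") == s) {
        return(list(value = d, status = "ok"))
      }
    }
    return(list(value = as.Date(NA), status = "bad"))
  }
  list(value = as.Date(NA), status = "bad")
}

parse_cell_chr <- function(v) {
  if (is_blank_cell(v)) return(list(value = NA_character_, status = "missing"))
  if (is.numeric(v) && abs(v - round(v)) < 1e-9) {
    return(list(value = format(round(v), scientific = FALSE), status = "ok"))
  }
  list(value = trimws(as.character(v)), status = "ok")
}

parse_cell_int <- function(v) {
  if (is_blank_cell(v)) return(list(value = NA_integer_, status = "missing"))
  if (is.numeric(v)) {
    if (abs(v - round(v)) < 1e-6) return(list(value = as.integer(round(v)), status = "ok"))
    return(list(value = NA_integer_, status = "bad"))
  }
  if (is.character(v)) {
    s <- trimws(v)
    if (grepl("^[+-]?\\d+$", s)) return(list(value = as.integer(s), status = "ok"))
    return(list(value = NA_integer_, status = "bad"))
  }
  list(value = NA_integer_, status = "bad")
}

# Collapse a readxl list column (or atomic vector) to the tightest common
# atomic type; used for covariable columns carried verbatim.
simplify_cell_col <- function(col) {
  if (!is.list(col)) return(col)
  vals <- lapply(col, function(v) if (is_blank_cell(v)) NA else v)
  non_na <- vals[!vapply(vals, function(v) all(is.na(v)), logical(1))]
  if (length(non_na) == 0) return(rep(NA, length(vals)))
  if (all(vapply(non_na, inherits, logical(1), what = "Date")) ||
      all(vapply(non_na, inherits, logical(1), what = "POSIXt"))) {
    return(as.Date(vapply(vals, function(v) {
      if (all(is.na(v))) NA_character_ else format(v, "%Y-%m-%d")
    }, character(1))))
  }
  if (all(vapply(non_na, is.numeric, logical(1)))) {
    return(vapply(vals, function(v) if (all(is.na(v))) NA_real_ else as.numeric(v), numeric(1)))
  }
  if (all(vapply(non_na, is.logical, logical(1)))) {
    return(vapply(vals, function(v) if (all(is.na(v))) NA else as.logical(v), logical(1)))
  }
  vapply(vals, function(v) {
    if (all(is.na(v))) NA_character_ else as.character(v)
  }, character(1))
}
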