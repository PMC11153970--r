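#' Write data frames to a minimal XLSX workbook
#'
#' Self-contained SpreadsheetML writer used for the Auxiliary Data and
#' implementation workbooks. One sheet per data frame; the first worksheet
#' row holds the column names. Numeric and logical cells are written as
#' native values, character cells as inline strings, `Date` columns as ISO
#' 8601 text (`"2021-05-02"`), and `NA` as a genuinely empty cell. The
#' archive uses stored (uncompressed) zip entries, so identical input always
#' produces a byte-identical file.
#'
#' @param sheets Named list of data frames; names become sheet names
#'   (case-sensitive, written verbatim).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @examples
#' path <- tempfile(fileext = ".xlsx")
#' write_xlsx_sheets(list(EMInfo = data.frame(PatientCode = "A")), path)
#' readxl::excel_sheets(path)
#' @export
write_xlsx_sheets <- function(sheets, path) {
  stopifnot(is.list(sheets), !is.null(names(sheets)), all(nzchar(names(sheets))))
  n <- length(sheets)
  entries <- list(
    "[Content_Types].xml" = charToRaw(xlsx_content_types(n)),
    "_rels/.rels" = charToRaw(xlsx_root_rels()),
    "xl/workbook.xml" = charToRaw(xlsx_workbook(names(sheets))),
    "xl/_rels/workbook.xml.rels" = charToRaw(xlsx_workbook_rels(n)),
    "xl/styles.xml" = charToRaw(xlsx_styles())
  )
  for (i in seq_len(n)) {
    entries[[sprintf("xl/worksheets/sheet%d.xml", i)]] <-
      charToRaw(xlsx_sheet_xml(as.data.frame(sheets[[i]])))
  }
  zip_store(entries, path)
  invisible(path)
}

#' Read every sheet of a workbook as text columns
#'
#' Thin wrapper around [readxl::read_excel()] returning all sheets with cells
#' kept as typed lists (so date cells, numbers and strings are distinguished
#' without guessing a column type from its first values).
#'
#' @param path Workbook path.
#' @return Named list of tibbles with list columns.
#' @keywords internal
read_xlsx_cells <- function(path) {
  sheets <- readxl::excel_sheets(path)
  out <- lapply(sheets, function(s) {
    suppressMessages(readxl::read_excel(path, sheet = s, col_types = "list"))
  })
  names(out) <- sheets
  out
}

# -- SpreadsheetML parts ------------------------------------------------------

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

xlsx_col_letter <- function(j) {
  vapply(j, function(n) {
    s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    s
  }, character(1))
}

xlsx_cell <- function(ref, v) {
  if (is.null(v) || length(v) == 0 || is.na(v)) return("")
  if (inherits(v, "Date")) v <- format(v, "%Y-%m-%d")
  if (inherits(v, "POSIXt")) v <- format(v, "%Y-%m-%d %H:%M:%S")
  if (is.logical(v)) return(sprintf('<c r="%s" t="b"><v>%d</v></c>', ref, as.integer(v)))
  if (is.numeric(v)) return(sprintf('<c r="%s"><v>%.15g</v></c>', ref, v))
  sprintf('<c r="%s" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
          ref, xml_escape(as.character(v)))
}

xlsx_sheet_xml <- function(df) {
  letters_ <- xlsx_col_letter(seq_len(max(ncol(df), 1L)))
  row_xml <- function(vals, rownum) {
    cells <- vapply(seq_along(vals), function(j) {
      xlsx_cell(paste0(letters_[j], rownum), vals[[j]])
    }, character(1))
    sprintf('<row r="%d">%s</row>', rownum, paste0(cells, collapse = ""))
  }
  rows <- row_xml(as.list(names(df)), 1L)
  if (nrow(df) > 0) {
    body <- vapply(seq_len(nrow(df)), function(i) {
      row_xml(lapply(df, function(col) col[i]), i + 1L)
    }, character(1))
    rows <- c(rows, body)
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste0(rows, collapse = ""), '</sheetData></worksheet>')
}

xlsx_content_types <- function(n) {
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    paste0(sprintf('<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
                   seq_len(n)), collapse = ""),
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    '</Types>')
}

xlsx_root_rels <- function() {
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>')
}

xlsx_workbook <- function(sheet_names) {
  n <- length(sheet_names)
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>',
    paste0(sprintf('<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
                   xml_escape(sheet_names), seq_len(n), seq_len(n)), collapse = ""),
    '</sheets></workbook>')
}

xlsx_workbook_rels <- function(n) {
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    paste0(sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
                   seq_len(n), seq_len(n)), collapse = ""),
    sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>', n + 1L),
    '</Relationships>')
}

xlsx_styles <- function() {
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="1"><font><sz val="11"/><name val="Calibri"/></font></fonts>',
    '<fills count="1"><fill><patternFill patternType="none"/></fill></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf numFmtId="0" fontId="0" fillId="0" borderId="0"/></cellStyleXfs>',
    '<cellXfs count="1"><xf numFmtId="0" fontId="0" fillId="0" borderId="0" xfId="0"/></cellXfs>',
    '</styleSheet>')
}

# -- stored-entry zip archive -------------------------------------------------

# CRC-32 (IEEE 802.3), table-driven; operates on R's 32-bit integers, whose
# bit pattern matches the unsigned value when written little-endian.
.crc32_table <- local({
  tab <- integer(256)
  for (i in 0:255) {
    cc <- i
    for (k in 1:8) {
      cc <- if (bitwAnd(cc, 1L) == 1L) {
        bitwXor(-306674912L, bitwShiftR(cc, 1L)) # 0xEDB88320
      } else {
        bitwShiftR(cc, 1L)
      }
    }
    tab[i + 1] <- cc
  }
  tab
})

crc32 <- function(x) {
  cc <- -1L
  for (b in as.integer(x)) {
    cc <- bitwXor(bitwShiftR(cc, 8L), .crc32_table[bitwAnd(bitwXor(cc, b), 255L) + 1L])
  }
  bitwXor(cc, -1L)
}

zip_u16 <- function(x) writeBin(as.integer(x), raw(), size = 2, endian = "little")
zip_u32 <- function(x) writeBin(as.integer(x), raw(), size = 4, endian = "little")

zip_store <- function(entries, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  dos_date <- bitwOr(bitwOr(bitwShiftL(44L, 9L), bitwShiftL(1L, 5L)), 1L) # fixed: 2024-01-01
  centrals <- vector("list", length(entries))
  off <- 0L
  for (i in seq_along(entries)) {
    nm <- names(entries)[i]
    data <- entries[[i]]
    name_raw <- charToRaw(nm)
    crc <- crc32(data)
    n <- length(data)
    writeBin(c(zip_u32(67324752L), zip_u16(20L), zip_u16(0L), zip_u16(0L),
               zip_u16(0L), zip_u16(dos_date), zip_u32(crc), zip_u32(n), zip_u32(n),
               zip_u16(length(name_raw)), zip_u16(0L), name_raw, data), con)
    centrals[[i]] <- c(zip_u32(33639248L), zip_u16(20L), zip_u16(20L), zip_u16(0L),
                       zip_u16(0L), zip_u16(0L), zip_u16(dos_date), zip_u32(crc),
                       zip_u32(n), zip_u32(n), zip_u16(length(name_raw)), zip_u16(0L),
                       zip_u16(0L), zip_u16(0L), zip_u16(0L), zip_u32(0L), zip_u32(off),
                       name_raw)
    off <- off + 30L + length(name_raw) + n
  }
  cd <- do.call(c, centrals)
  writeBin(cd, con)
  writeBin(c(zip_u32(101010256L), zip_u16(0L), zip_u16(0L),
             zip_u16(length(entries)), zip_u16(length(entries)),
             zip_u32(length(cd)), zip_u32(off), zip_u16(0L)), con)
  invisible(path)
}
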