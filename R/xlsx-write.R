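# Minimal Office Open XML spreadsheet writer. Emits plain (macro-free)
# workbooks with every cell as an inline string, which is all the sheet
# layout needs and what the text-typed reader expects back. Deterministic:
# fixed part order and fixed timestamps, so identical grids produce
# byte-identical files.

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  x
}

# 1-based column index -> A1-style letters
col_letter <- function(i) {
  out <- character(length(i))
  for (k in seq_along(i)) {
    n <- i[k]
    s <- ""
    while (n > 0) {
      r <- (n - 1) %% 26
      s <- paste0(LETTERS[r + 1], s)
      n <- (n - 1) %/% 26
    }
    out[k] <- s
  }
  out
}

sheet_xml <- function(grid) {
  # grid: character matrix (NA/"" cells skipped)
  rows <- character(0)
  if (length(grid) && nrow(grid)) {
    for (r in seq_len(nrow(grid))) {
      cells <- character(0)
      for (c in seq_len(ncol(grid))) {
        v <- grid[r, c]
        if (is.na(v) || !nzchar(v)) next
        cells <- c(cells, sprintf(
          '<c r="%s%d" t="inlineStr"><is><t xml:space="preserve">%s</t></is></c>',
          col_letter(c), r, xml_escape(v)))
      }
      if (length(cells)) {
        rows <- c(rows, sprintf('<row r="%d">%s</row>', r,
                                paste(cells, collapse = "")))
      }
    }
  }
  paste0('<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
         '<worksheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
         '<sheetData>', paste(rows, collapse = ""), '</sheetData></worksheet>')
}

#' Write grids of cells as a plain XLSX workbook
#'
#' Low-level writer used by [write_metadatasheet()] and the GEO exporter.
#' Every cell is written as text; no macros, styles or data-validation
#' artifacts are emitted. Output is byte-deterministic for identical input.
#'
#' @param grids Named list of character matrices, one per worksheet, in
#'   sheet order.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xlsx_grids <- function(grids, path) {
  stopifnot(is.list(grids), length(grids) >= 1L, !is.null(names(grids)),
            all(nzchar(names(grids))))
  tmp <- tempfile("xlsx_parts_")
  dir.create(file.path(tmp, "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "_rels"), recursive = TRUE)
  dir.create(file.path(tmp, "xl", "worksheets"), recursive = TRUE)
  on.exit(unlink(tmp, recursive = TRUE), add = TRUE)

  n <- length(grids)
  overrides <- paste(sprintf(
    '<Override PartName="/xl/worksheets/sheet%d.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.worksheet+xml"/>',
    seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Types xmlns="http://schemas.openxmlformats.org/package/2006/content-types">',
    '<Default Extension="rels" ContentType="application/vnd.openxmlformats-package.relationships+xml"/>',
    '<Default Extension="xml" ContentType="application/xml"/>',
    '<Override PartName="/xl/workbook.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.sheet.main+xml"/>',
    '<Override PartName="/xl/styles.xml" ContentType="application/vnd.openxmlformats-officedocument.spreadsheetml.styles+xml"/>',
    overrides, '</Types>'),
    file.path(tmp, "[Content_Types].xml"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    '<Relationship Id="rId1" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/officeDocument" Target="xl/workbook.xml"/>',
    '</Relationships>'),
    file.path(tmp, "_rels", ".rels"))

  sheets <- paste(sprintf(
    '<sheet name="%s" sheetId="%d" r:id="rId%d"/>',
    xml_escape(names(grids)), seq_len(n), seq_len(n)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<workbook xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main" ',
    'xmlns:r="http://schemas.openxmlformats.org/officeDocument/2006/relationships">',
    '<sheets>', sheets, '</sheets></workbook>'),
    file.path(tmp, "xl", "workbook.xml"))

  rels <- paste(c(sprintf(
    '<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/worksheet" Target="worksheets/sheet%d.xml"/>',
    seq_len(n), seq_len(n)),
    sprintf('<Relationship Id="rId%d" Type="http://schemas.openxmlformats.org/officeDocument/2006/relationships/styles" Target="styles.xml"/>',
            n + 1L)), collapse = "")
  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<Relationships xmlns="http://schemas.openxmlformats.org/package/2006/relationships">',
    rels, '</Relationships>'),
    file.path(tmp, "xl", "_rels", "workbook.xml.rels"))

  writeLines(paste0(
    '<?xml version="1.0" encoding="UTF-8" standalone="yes"?>\n',
    '<styleSheet xmlns="http://schemas.openxmlformats.org/spreadsheetml/2006/main">',
    '<fonts count="1"><font><sz val="11"/><name val="Calibri"/></font></fonts>',
    '<fills count="1"><fill><patternFill patternType="none"/></fill></fills>',
    '<borders count="1"><border/></borders>',
    '<cellStyleXfs count="1"><xf/></cellStyleXfs>',
    '<cellXfs count="1"><xf xfId="0"/></cellXfs>',
    '</styleSheet>'),
    file.path(tmp, "xl", "styles.xml"))

  for (i in seq_len(n)) {
    writeLines(sheet_xml(grids[[i]]),
               file.path(tmp, "xl", "worksheets", sprintf("sheet%d.xml", i)))
  }

  parts <- c("[Content_Types].xml", "_rels/.rels", "xl/workbook.xml",
             "xl/_rels/workbook.xml.rels", "xl/styles.xml",
             sprintf("xl/worksheets/sheet%d.xml", seq_len(n)))
  # pin mtimes so identical content zips to identical bytes
  epoch <- as.POSIXct("2020-01-01 00:00:00", tz = "UTC")
  for (p in parts) Sys.setFileTime(file.path(tmp, p), epoch)

  path <- normalizePath(path, mustWork = FALSE)
  zip::zip(path, files = parts, root = tmp, mode = "mirror",
           include_directories = FALSE)
  invisible(path)
}
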