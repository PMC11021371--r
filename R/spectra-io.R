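## Reading and writing delimited-text absorbance spectra.
##
## Format: a header row with a wavelength column (nm) and an absorbance
## column (AU); comma or tab delimited (autodetected); lines beginning
## with '#' are comments and may carry metadata as "key: value".

.wavelengthAliases <- c("wavelength_nm", "wavelength", "lambda", "lambda_nm",
                        "nm", "wl")
.absorbanceAliases <- c("absorbance", "abs", "a", "au", "od", "absorption")

.parseMetadataComment <- function(line) {
  body <- sub("^#+\\s*", "", line)
  if (!grepl(":", body, fixed = TRUE)) return(NULL)
  key <- trimws(sub(":.*$", "", body))
  val <- trimws(sub("^[^:]*:", "", body))
  if (!nzchar(key)) return(NULL)
  num <- suppressWarnings(as.numeric(val))
  if (!is.na(num)) val <- num
  else if (val %in% c("TRUE", "FALSE")) val <- as.logical(val)
  stats::setNames(list(val), key)
}

#' Read an absorbance spectrum from a delimited text file
#'
#' The file must contain a header row naming a wavelength column (nm) and
#' an absorbance column (AU); the delimiter (comma or tab) is autodetected.
#' Lines starting with `#` are comments; comments of the form `# key: value`
#' are collected into the spectrum's metadata. Rows are sorted by
#' wavelength and duplicate wavelengths are averaged.
#'
#' @param path path to the file.
#' @param dialect optional named character vector mapping roles to column
#'   names, e.g. `c(wavelength = "lambda", absorbance = "A")`. By default
#'   common aliases are recognised case-insensitively.
#' @param minRows minimum number of data rows required (default 8).
#' @return a [Spectrum-class].
#' @export
readSpectrum <- function(path, dialect = NULL, minRows = 8) {
  if (!file.exists(path))
    bsError("bs_io_error", sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  isComment <- grepl("^\\s*#", lines)
  isBlank <- grepl("^\\s*$", lines)
  metadata <- list()
  for (cl in lines[isComment]) {
    kv <- .parseMetadataComment(cl)
    if (!is.null(kv)) metadata[names(kv)] <- kv
  }
  dataIdx <- which(!isComment & !isBlank)
  if (length(dataIdx) < 2L)
    bsError("bs_insufficient_data", "no data rows found below the header")
  sep <- if (grepl("\t", lines[dataIdx[1]])) "\t" else ","
  tab <- tryCatch(
    utils::read.table(text = lines[dataIdx], sep = sep, header = TRUE,
                      check.names = FALSE, colClasses = "character",
                      strip.white = TRUE),
    error = function(e) bsError("bs_format_error",
                                sprintf("cannot parse table: %s", conditionMessage(e))))
  cols <- tolower(trimws(names(tab)))
  findCol <- function(role, aliases) {
    if (!is.null(dialect) && role %in% names(dialect)) {
      hit <- which(cols == tolower(dialect[[role]]))
    } else {
      hit <- which(cols %in% aliases)
    }
    if (!length(hit))
      bsError("bs_format_error", sprintf(
        "no %s column found; expected a header named one of: %s",
        role, paste(if (!is.null(dialect) && role %in% names(dialect))
          dialect[[role]] else aliases, collapse = ", ")))
    hit[1]
  }
  wCol <- findCol("wavelength", .wavelengthAliases)
  aCol <- findCol("absorbance", .absorbanceAliases)
  parseNum <- function(values, colName) {
    num <- suppressWarnings(as.numeric(values))
    bad <- which(is.na(num) & !is.na(values) & nzchar(values))
    if (length(bad)) {
      # +1 for the header row inside the data block
      fileLine <- dataIdx[bad[1] + 1L]
      bsError("bs_parse_error", sprintf(
        "non-numeric value '%s' in column '%s' at line %d",
        values[bad[1]], colName, fileLine))
    }
    num
  }
  w <- parseNum(tab[[wCol]], names(tab)[wCol])
  a <- parseNum(tab[[aCol]], names(tab)[aCol])
  keep <- !is.na(w) & !is.na(a)
  w <- w[keep]; a <- a[keep]
  if (length(w) < minRows)
    bsError("bs_insufficient_data", sprintf(
      "only %d data rows; at least %d required", length(w), minRows))
  label <- if (!is.null(metadata$label)) as.character(metadata$label)
           else basename(path)
  Spectrum(w, a, label = label, metadata = metadata)
}

#' Write a spectrum to a delimited text file
#'
#' Writes `# key: value` comment lines for scalar metadata followed by a
#' comma-separated table with header `wavelength_nm,absorbance`. Values are
#' written with 15 significant digits so a read/write round trip preserves
#' the data to better than 1e-9 relative.
#'
#' @param spec a [Spectrum-class].
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeSpectrum <- function(spec, path) {
  stopifnot(methods::is(spec, "Spectrum"))
  md <- spec@metadata
  lines <- character()
  if (nzchar(spec@label) && is.null(md$label)) md$label <- spec@label
  for (key in names(md)) {
    val <- md[[key]]
    if (length(val) == 1L && (is.numeric(val) || is.character(val) ||
                              is.logical(val))) {
      if (is.numeric(val)) val <- sprintf("%.15g", val)
      lines <- c(lines, sprintf("# %s: %s", key, val))
    }
  }
  lines <- c(lines, "wavelength_nm,absorbance",
             sprintf("%.15g,%.15g", spec@wavelength, spec@absorbance))
  writeLines(lines, path)
  invisible(path)
}
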