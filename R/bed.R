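#' @include AllClasses.R
NULL

#' Read RNA feature sites in BED3+ format
#'
#' Columns 1-3 must give the feature position: a transcript id and 0-based
#' half-open transcript coordinates. Any further columns (stoichiometry,
#' coverage, p-values, ...) are preserved verbatim as character data so
#' that downstream output reproduces them byte-identically. Lines starting
#' with `#` or `track` are captured as pass-through header lines; blank
#' lines are skipped. Gzip-compressed input is accepted.
#'
#' @param path path to a tab-separated BED3+ file.
#' @return data.frame with columns `transcript`, `start`, `end` (integer)
#'   and any extra input columns as character `X4`, `X5`, ... (or named
#'   from a commented header produced by [writeSiteTable()]). Attributes:
#'   `header` (pass-through lines) and `extraNames` (original extra-column
#'   labels, if any).
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("TX1\t10\t11\t0.86", f)
#' readSites(f)
#' @export
readSites <- function(path) {
  lines <- readTextLines(path)
  isHeader <- grepl("^#", lines) | grepl("^track( |$)", lines)
  header <- lines[isHeader]
  keep <- !isHeader & nzchar(trimws(lines))
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) {
    out <- data.frame(transcript = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE)
    attr(out, "header") <- header
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop(sprintf("BED line %d: expected at least 3 tab-separated columns",
                 lineNo[which(nf < 3L)[1L]]))
  ncol <- max(nf)
  fields <- lapply(fields, function(f) c(f, rep("", ncol - length(f))))
  mat <- do.call(rbind, fields)
  start <- suppressWarnings(as.integer(mat[, 2L]))
  end <- suppressWarnings(as.integer(mat[, 3L]))
  if (anyNA(start) || anyNA(end))
    stop(sprintf("BED line %d: non-integer coordinates",
                 lineNo[which(is.na(start) | is.na(end))[1L]]))
  if (any(start >= end))
    stop(sprintf("BED line %d: start must be < end",
                 lineNo[which(start >= end)[1L]]))
  out <- data.frame(transcript = mat[, 1L], start = start, end = end,
                    stringsAsFactors = FALSE)
  extraNames <- NULL
  if (ncol > 3L) {
    extra <- as.data.frame(mat[, 4:ncol, drop = FALSE],
                           stringsAsFactors = FALSE)
    names(extra) <- paste0("X", 4:ncol)
    # the last commented header line (the one adjacent to the data, as
    # writeSiteTable() emits it) names the columns when the count matches
    if (length(header) >= 1L) {
      hf <- strsplit(sub("^#", "", header[length(header)]),
                     "\t", fixed = TRUE)[[1L]]
      if (length(hf) == ncol) {
        extraNames <- hf[4:ncol]
        names(extra) <- make.names(extraNames, unique = TRUE)
      }
    }
    out <- cbind(out, extra)
  }
  attr(out, "header") <- header
  attr(out, "extraNames") <- extraNames
  out
}

#' Write a site table as tab-separated BED-like text
#'
#' Writes records exactly as tab-joined fields with no quoting or padding,
#' `NA` rendered literally, and a trailing newline — byte-stable across
#' runs. Pass-through header lines stored on the input (attribute
#' `header`) are emitted first; with `header = TRUE` an additional
#' `#`-prefixed line naming all columns is written.
#'
#' @param x data.frame of records; numeric columns are formatted with up
#'   to 6 significant digits (metacoordinates with 4 decimal places).
#' @param path output path, or `""` for standard output.
#' @param header emit a commented column-name line.
#' @return invisibly, the path.
#' @export
writeSiteTable <- function(x, path, header = FALSE) {
  con <- if (identical(path, "")) stdout() else file(path, "wt")
  if (!identical(path, "")) on.exit(close(con))
  passThrough <- attr(x, "header")
  if (length(passThrough)) writeLines(passThrough, con)
  if (isTRUE(header))
    writeLines(paste0("#", paste(names(x), collapse = "\t")), con)
  cols <- lapply(names(x), function(nm) formatBedColumn(x[[nm]], nm))
  if (nrow(x))
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

formatBedColumn <- function(v, name = "") {
  if (is.double(v)) {
    out <- if (identical(name, "transcript_metacoordinate"))
      sprintf("%.4f", v) else formatC(v, digits = 6, format = "g")
    out[is.na(v)] <- "NA"
    out
  } else {
    out <- as.character(v)
    out[is.na(out)] <- "NA"
    out
  }
}
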