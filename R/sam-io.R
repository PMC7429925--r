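# Byte-exact plain-SAM reading and writing.  The sorter routes records by
# byte offsets and line lengths, and its reproducibility contract is
# byte-identical output across worker counts, so SAM text is handled
# directly: lines are LF-terminated, offsets are 0-based, ranges half-open.

#' Read a plain SAM file, preserving bytes
#'
#' Splits the file into the @-prefixed header and the alignment body and
#' records the byte geometry of every body line.  The reference order is
#' taken from the header's `@SQ` lines (the `SN:` field), which defines the
#' chromosome index used as the leading sort key.  CR-LF line endings are
#' rejected as malformed: the byte arithmetic assumes LF.
#'
#' @param path Path to a SAM text file.
#' @return A list: `headerLines`, `headerLen` (bytes, including newlines),
#'   `bodyLines`, `lineLen` (bytes per body line, newline included),
#'   `sqNames` (reference names in @SQ order).
#' @export
readSamFile <- function(path) {
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  if (length(txt) == 0L || !nzchar(txt))
    return(list(headerLines = character(0), headerLen = 0,
                bodyLines = character(0), lineLen = numeric(0),
                sqNames = character(0)))
  if (grepl("\r", txt, fixed = TRUE, useBytes = TRUE))
    stop("readSamFile: CR found; only LF line endings are supported: ", path)
  lines <- strsplit(txt, "\n", fixed = TRUE, useBytes = TRUE)[[1]]
  if (length(txt) && nzchar(txt) && !endsWith(txt, "\n"))
    stop("readSamFile: file does not end with a newline: ", path)
  isHeader <- startsWith(lines, "@")
  # header is the leading run of @ lines only
  nHead <- if (all(isHeader)) length(lines) else which(!isHeader)[1L] - 1L
  headerLines <- lines[seq_len(nHead)]
  bodyLines <- if (nHead < length(lines)) lines[(nHead + 1L):length(lines)] else character(0)
  sq <- headerLines[startsWith(headerLines, "@SQ")]
  sqNames <- vapply(strsplit(sq, "\t", fixed = TRUE), function(f) {
    sn <- f[startsWith(f, "SN:")]
    if (length(sn) != 1L) stop("readSamFile: @SQ line without a single SN: field")
    substring(sn[1L], 4L)
  }, character(1))
  list(headerLines = headerLines,
       headerLen = sum(as.numeric(nchar(headerLines, type = "bytes")) + 1),
       bodyLines = bodyLines,
       lineLen = as.numeric(nchar(bodyLines, type = "bytes")) + 1,
       sqNames = sqNames)
}

#' Write SAM lines byte-exactly
#'
#' @param lines Character vector of complete SAM lines (no newlines).
#' @param path Output path; every line is terminated with a single LF.
#' @return `path`, invisibly.
#' @export
writeSamLines <- function(lines, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines))
    writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL,
              useBytes = TRUE)
  invisible(path)
}

samFields <- function(line) strsplit(line, "\t", fixed = TRUE, useBytes = TRUE)[[1]]
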