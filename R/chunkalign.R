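# Equal-nucleotide FASTQ chunking and deterministic parallel SAM emission.
#
# A chunk is a pair of byte offsets (half-open, record-aligned) into the
# FASTQ file — in paired mode two pairs, one per mate file, advanced in
# lock-step so mates never separate.  Chunks hold (as close as possible to)
# a fixed number of nucleotides, which is the granularity the underlying
# aligner processes at a time and what makes the output reproducible for
# any worker count.

#' Read a plain FASTQ file with byte geometry
#'
#' Parses 4-line records, validating the `@`/`+` markers and that the file
#' holds complete records, and returns per-record byte offsets so chunks
#' can be expressed as offsets into the original file.
#'
#' @param path FASTQ path (plain text, LF line endings).
#' @return A list: `name`, `seq`, `qual` (character vectors), `nt` (per-read
#'   nucleotide count), `recStart`/`recEnd` (0-based half-open byte range of
#'   each record).
#' @export
readFastqFile <- function(path) {
  txt <- readChar(path, file.size(path), useBytes = TRUE)
  if (length(txt) == 0L || !nzchar(txt))
    return(list(name = character(0), seq = character(0), qual = character(0),
                nt = integer(0), recStart = numeric(0), recEnd = numeric(0)))
  if (grepl("\r", txt, fixed = TRUE, useBytes = TRUE))
    stop("readFastqFile: CR found; only LF line endings are supported: ", path)
  lines <- strsplit(txt, "\n", fixed = TRUE, useBytes = TRUE)[[1]]
  n <- length(lines)
  if (n %% 4L != 0L)
    stop("readFastqFile: truncated record at read index ", n %/% 4L + 1L,
         " in ", path)
  idx <- seq(1L, n, by = 4L)
  if (!all(startsWith(lines[idx], "@")))
    stop("readFastqFile: record ", which(!startsWith(lines[idx], "@"))[1L],
         " does not start with '@' in ", path)
  if (!all(startsWith(lines[idx + 2L], "+")))
    stop("readFastqFile: record ", which(!startsWith(lines[idx + 2L], "+"))[1L],
         " lacks the '+' separator in ", path)
  lens <- nchar(lines, type = "bytes") + 1L
  # offsets as doubles: real FASTQ files overflow 32-bit byte counts
  recLen <- as.numeric(lens[idx] + lens[idx + 1L] + lens[idx + 2L] + lens[idx + 3L])
  recEnd <- cumsum(recLen)
  sq <- lines[idx + 1L]
  qual <- lines[idx + 3L]
  if (any(nchar(sq) != nchar(qual)))
    stop("readFastqFile: sequence/quality length mismatch at read ",
         which(nchar(sq) != nchar(qual))[1L], " in ", path)
  list(name = sub("^@", "", lines[idx]), seq = sq, qual = qual,
       nt = nchar(sq), recStart = recEnd - recLen, recEnd = recEnd)
}

#' Partition FASTQ input into chunks of (near-)equal nucleotide content
#'
#' Greedily packs consecutive records: a record (read pair, in paired mode)
#' is added to the current chunk unless that would push the chunk past
#' `ntBudget` — except that a chunk always holds at least one record, so a
#' single read longer than the budget still forms a chunk.  Every chunk but
#' possibly the last is therefore within one record length of the budget.
#' In paired mode nucleotides are counted over both mates and the two files
#' advance in lock-step, so mate `n` of each file always lands in the same
#' chunk.
#'
#' @param fastq1 Path to the (first) FASTQ file.
#' @param fastq2 Optional path to the mate file (paired mode).
#' @param ntBudget Target nucleotides per chunk; default 1e7.
#' @return A data.frame of chunk specs: `start`, `end` (byte offsets into
#'   `fastq1`, half-open, record-aligned), `start2`, `end2` (mate file, or
#'   `NA`), `read_count`, `nucleotide_count`.
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' generateFastq(fixtureSpec(seed = 1, nReads = 4, readLength = 10), fq)
#' computeChunks(fq, ntBudget = 20)  # 2 chunks of 2 reads
#' @export
computeChunks <- function(fastq1, fastq2 = NULL, ntBudget = 1e7) {
  if (ntBudget < 1) stop("computeChunks: ntBudget must be >= 1")
  r1 <- readFastqFile(fastq1)
  paired <- !is.null(fastq2)
  if (paired) {
    r2 <- readFastqFile(fastq2)
    if (length(r1$seq) != length(r2$seq))
      stop("computeChunks: paired files have unequal record counts (",
           length(r1$seq), " vs ", length(r2$seq), ")")
  }
  n <- length(r1$seq)
  if (n == 0L)
    return(data.frame(start = numeric(0), end = numeric(0),
                      start2 = numeric(0), end2 = numeric(0),
                      read_count = integer(0), nucleotide_count = numeric(0)))
  nt <- r1$nt + if (paired) r2$nt else 0L
  firsts <- integer(0)
  acc <- 0
  for (i in seq_len(n)) {
    if (acc == 0 || acc + nt[i] > ntBudget) {
      firsts <- c(firsts, i)
      acc <- 0
    }
    acc <- acc + nt[i]
  }
  lasts <- c(firsts[-1L] - 1L, n)
  data.frame(
    start = r1$recStart[firsts], end = r1$recEnd[lasts],
    start2 = if (paired) r2$recStart[firsts] else NA_real_,
    end2 = if (paired) r2$recEnd[lasts] else NA_real_,
    read_count = lasts - firsts + 1L,
    nucleotide_count = vapply(seq_along(firsts), function(k)
      sum(nt[firsts[k]:lasts[k]]), numeric(1)))
}

#' Build a shared reference handle
#'
#' Models the reference image loaded once into shared memory and read by
#' every aligner worker: an opaque handle holding the reference layout
#' (names and lengths) from which the SAM header is produced exactly once.
#'
#' @param chromLengths Named numeric vector: reference name -> length.
#' @return A list of class `referenceHandle`.
#' @export
makeReferenceHandle <- function(chromLengths) {
  if (is.null(names(chromLengths)) || any(!nzchar(names(chromLengths))))
    stop("makeReferenceHandle: chromLengths must be a named vector")
  structure(list(names = names(chromLengths),
                 lengths = as.numeric(chromLengths)),
            class = "referenceHandle")
}

referenceHeader <- function(ref) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", ref$names, as.integer(ref$lengths)))
}

# small deterministic string hash (polynomial, mod 2^31 - 1); keeps the mock
# aligner pure: same read -> same placement, no RNG state involved
.strHash <- function(s) {
  vapply(s, function(x) {
    h <- 0
    for (v in utf8ToInt(x)) h <- (h * 131 + v) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Mock aligner satisfying the aligner contract
#'
#' A pure stand-in for a real read aligner: it emits exactly one valid
#' minimal SAM line per read, with the reference and position derived
#' deterministically from a hash of the read name, so the same chunk always
#' yields the same lines.  Sufficient to exercise the chunking, emission and
#' downstream sorting machinery end to end; it performs no actual sequence
#' alignment.
#'
#' @param reads A list with `name`, `seq`, `qual` for the chunk's reads.
#' @param ref A reference handle from [makeReferenceHandle()].
#' @return Character vector of SAM alignment lines (one per read).
#' @export
mockAligner <- function(reads, ref) {
  n <- length(reads$name)
  if (n == 0L) return(character(0))
  h <- .strHash(reads$name)
  ci <- (h %% length(ref$names)) + 1L
  pos <- (floor(h / 7) %% pmax(ref$lengths[ci] - nchar(reads$seq) + 1, 1)) + 1
  sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
          reads$name, ref$names[ci], as.integer(pos),
          nchar(reads$seq), reads$seq, reads$qual)
}

#' Align chunks and emit one deterministic SAM file
#'
#' Runs the aligner on every chunk independently (each worker processes the
#' chunks assigned to it round-robin) and writes a single SAM file: the
#' header once, then the chunk outputs concatenated **in chunk order**,
#' whatever the worker count or completion order.  This is the
#' deterministic stand-in for a shared-file-pointer collective write: the
#' output bytes are defined by the chunk order alone.
#'
#' @param chunks Chunk table from [computeChunks()].
#' @param fastq1,fastq2 The FASTQ file(s) the chunk offsets refer to.
#' @param aligner A function `(reads, ref) -> SAM lines`; see [mockAligner()].
#' @param ref Reference handle ([makeReferenceHandle()]).
#' @param outPath Output SAM path.
#' @param workers Number of simulated workers; affects scheduling only,
#'   never the output bytes.
#' @return `outPath`, invisibly.
#' @export
alignChunks <- function(chunks, fastq1, fastq2 = NULL, aligner = mockAligner,
                        ref, outPath, workers = 1L) {
  paired <- !is.null(fastq2)
  r1 <- readFastqFile(fastq1)
  r2 <- if (paired) readFastqFile(fastq2) else NULL
  nChunks <- nrow(chunks)
  results <- vector("list", nChunks)
  # round-robin assignment; workers run independently, but emission below
  # is by chunk index, so scheduling cannot leak into the output
  for (w in seq_len(max(workers, 1L))) {
    mine <- seq_len(nChunks)[(seq_len(nChunks) - 1L) %% max(workers, 1L) == w - 1L]
    for (k in mine) {
      sel <- which(r1$recStart >= chunks$start[k] & r1$recEnd <= chunks$end[k])
      reads <- list(name = r1$name[sel], seq = r1$seq[sel], qual = r1$qual[sel])
      if (paired) {
        sel2 <- which(r2$recStart >= chunks$start2[k] & r2$recEnd <= chunks$end2[k])
        reads$name2 <- r2$name[sel2]
        reads$seq2 <- r2$seq[sel2]
        reads$qual2 <- r2$qual[sel2]
      }
      lines <- tryCatch(aligner(reads, ref), error = function(e)
        stop("alignChunks: aligner failed on chunk ", k, ": ",
             conditionMessage(e)))
      results[[k]] <- lines
    }
  }
  writeSamLines(c(referenceHeader(ref),
                  unlist(results, use.names = FALSE)), outPath)
  invisible(outPath)
}

#' Split a SAM file into one file per chromosome
#'
#' Writes, for every reference sequence in the header, a SAM file holding
#' the full original header plus the body lines mapped to that reference
#' (relative order preserved), and an `unmapped.sam` for RNAME `*`.  A body
#' line whose RNAME is neither `*` nor in the header is an error.
#'
#' @param samPath Input SAM path.
#' @param outDir Output directory (created if needed).
#' @return Named character vector of the files written.
#' @export
splitSamByChromosome <- function(samPath, outDir) {
  sam <- readSamFile(samPath)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  rname <- vapply(strsplit(sam$bodyLines, "\t", fixed = TRUE), `[[`,
                  character(1), 3L)
  unknown <- setdiff(unique(rname), c(sam$sqNames, "*"))
  if (length(unknown))
    stop("splitSamByChromosome: RNAME not in header: ",
         paste(unknown, collapse = ", "))
  outs <- character(0)
  for (chrom in sam$sqNames) {
    f <- file.path(outDir, paste0(chrom, ".sam"))
    writeSamLines(c(sam$headerLines, sam$bodyLines[rname == chrom]), f)
    outs[chrom] <- f
  }
  f <- file.path(outDir, "unmapped.sam")
  writeSamLines(c(sam$headerLines, sam$bodyLines[rname == "*"]), f)
  outs["*"] <- f
  outs
}
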