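# Distributed SAM coordinate sorting: block-partition the file across p
# simulated workers, parse five-value sort records (coordinate, origin
# rank/offset, destination rank/offset), run the parallel bitonic sort,
# route destinations back with a first all-to-all shuffle, move the line
# bytes with a second one, and write the sorted file in contiguous blocks,
# chromosome by chromosome.

# key columns of the within-chromosome total order: coordinate, then origin
# rank, then origin offset.  (r_i, o_i) lexicographic equals original file
# order for every block partition, which is what makes the output
# independent of the worker count.
SORT_KEY <- c("pos", "r_i", "o_i")

#' Split the body of a SAM file into near-equal byte ranges
#'
#' Excludes the header and cuts the alignment body into `p` contiguous,
#' line-aligned, half-open byte ranges of near-equal size: cut point `i` is
#' the first line start at or after `i/p` of the body bytes.  The ranges
#' are non-overlapping and cover every alignment line exactly once.
#'
#' @param sam A list as returned by [readSamFile()] (or a path to a SAM
#'   file, which is read first).
#' @param p Number of workers, `p >= 1`.
#' @return A data.frame with one row per worker: `start`, `end` (0-based
#'   byte offsets into the body, half-open), `firstLine`, `nLines`.
#' @export
splitSamIntoBlocks <- function(sam, p) {
  if (is.character(sam)) sam <- readSamFile(sam)
  p <- as.integer(p)
  if (p < 1L) stop("splitSamIntoBlocks: p must be >= 1")
  nLines <- length(sam$bodyLines)
  lineStarts <- cumsum(c(0, sam$lineLen))     # length nLines + 1
  total <- lineStarts[nLines + 1L]
  cutLine <- integer(p + 1L)                  # 0-based line index of each cut
  cutLine[1L] <- 0L
  cutLine[p + 1L] <- nLines
  for (i in seq_len(p - 1L)) {
    target <- i * total / p
    cutLine[i + 1L] <- sum(lineStarts[seq_len(nLines + 1L)] < target)
  }
  cutLine <- pmin(cutLine, nLines)
  data.frame(start = lineStarts[cutLine[seq_len(p)] + 1L],
             end = lineStarts[cutLine[-1L] + 1L],
             firstLine = cutLine[seq_len(p)] + 1L,
             nLines = diff(cutLine))
}

#' Parse one worker's block of SAM lines into sort records
#'
#' Builds the five-value routing record for every alignment line the worker
#' owns: the genomic coordinate (`chrom` = 0-based index of RNAME in @SQ
#' order, `pos` = 1-based POS), the origin rank `r_i`, the line's byte
#' offset `o_i` within this worker's buffer, and the line length in bytes
#' (newline included).  Destination rank `r_d` and offset `o_d` are filled
#' in only after the parallel sort completes.  Lines with RNAME `*` or an
#' RNAME absent from the header are diverted to an `unmapped` side table and
#' take no part in the coordinate sort.
#'
#' @param buffer Character vector: the worker's alignment lines.
#' @param rank Origin rank `r_i` (0-based).
#' @param sqNames Reference names in @SQ header order.
#' @return A list with `records` and `unmapped` data.frames (columns
#'   `chrom`, `pos`, `r_i`, `o_i`, `line_len`; unmapped rows have
#'   `chrom = NA`).
#' @export
parseBlock <- function(buffer, rank, sqNames) {
  n <- length(buffer)
  lens <- as.numeric(nchar(buffer, type = "bytes")) + 1
  offs <- cumsum(c(0, lens))[seq_len(n)]
  if (n == 0L) {
    empty <- data.frame(chrom = integer(0), pos = numeric(0),
                        r_i = integer(0), o_i = numeric(0),
                        line_len = numeric(0))
    return(list(records = empty, unmapped = empty))
  }
  fields <- strsplit(buffer, "\t", fixed = TRUE, useBytes = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1L]
    stop(sprintf("parseBlock: malformed SAM record at offset %d (rank %d): %d field(s), need >= 11",
                 as.integer(offs[bad]), rank, nf[bad]))
  }
  rname <- vapply(fields, `[[`, character(1), 3L)
  posStr <- vapply(fields, `[[`, character(1), 4L)
  if (!all(grepl("^[0-9]+$", posStr))) {
    bad <- which(!grepl("^[0-9]+$", posStr))[1L]
    stop(sprintf("parseBlock: non-integer POS at offset %d (rank %d)",
                 as.integer(offs[bad]), rank))
  }
  chrom <- match(rname, sqNames) - 1L        # NA for "*" and unknown RNAMEs
  rec <- data.frame(chrom = chrom, pos = as.numeric(posStr),
                    r_i = rank, o_i = offs, line_len = lens)
  mapped <- !is.na(chrom)
  list(records = rec[mapped, , drop = FALSE],
       unmapped = rec[!mapped, , drop = FALSE])
}

#' Assign destination ranks and offsets after the parallel sort
#'
#' Once the blocks are globally sorted (and sentinels stripped), the writer
#' of each record is simply the rank whose block holds it, and its offset in
#' the destination file is the running byte total: `baseOffset` plus the
#' exclusive prefix sum of `line_len` over the global sorted order.  Each
#' worker's assigned offsets therefore form one contiguous byte range, and
#' the ranges are adjacent in rank order — the property that lets every
#' writer emit a single contiguous block.
#'
#' @param blocks List of sorted record data.frames (output of
#'   [parallelBitonicSort()] after [stripSentinels()]).
#' @param baseOffset Byte offset where this batch begins in the destination
#'   file (header length plus previously written chromosomes).
#' @return The blocks, with `r_d` and `o_d` columns filled.
#' @export
assignDestinations <- function(blocks, baseOffset) {
  counts <- vapply(blocks, nrow, integer(1))
  allLens <- unlist(lapply(blocks, function(b) b$line_len), use.names = FALSE)
  if (length(allLens) == 0L) return(blocks)
  o_d <- baseOffset + cumsum(c(0, allLens))[seq_along(allLens)]
  splitIdx <- rep(seq_along(blocks), counts)
  odSplit <- split(o_d, factor(splitIdx, levels = seq_along(blocks)))
  for (r in seq_along(blocks)) {
    if (counts[r] == 0L) {
      blocks[[r]]$r_d <- integer(0)
      blocks[[r]]$o_d <- numeric(0)
    } else {
      blocks[[r]]$r_d <- r - 1L
      blocks[[r]]$o_d <- odSplit[[r]]
    }
  }
  blocks
}

emptySlot <- function(template) template[0L, , drop = FALSE]

#' First shuffle phase: return destinations to the origin workers
#'
#' After the sort, rank `r` holds records parsed by many origin ranks.  An
#' all-to-all exchange sends each record's routing row
#' `(o_i, r_d, o_d, line_len)` back to its origin `r_i`, so every worker
#' learns where each line it parsed must go.  The resulting routing table of
#' worker `w` has exactly one row per line `w` parsed (keyed by `o_i`).
#'
#' @param rt A [SimRuntime-class].
#' @param blocks Sorted blocks with destinations assigned
#'   ([assignDestinations()]).
#' @return List of per-origin routing tables (data.frames with columns
#'   `o_i`, `r_d`, `o_d`, `line_len`).
#' @export
shufflePhase1 <- function(rt, blocks) {
  p <- rt@p
  cols <- c("o_i", "r_d", "o_d", "line_len")
  template <- data.frame(o_i = numeric(0), r_d = integer(0),
                         o_d = numeric(0), line_len = numeric(0))
  outboxes <- lapply(seq_len(p), function(r) {
    b <- blocks[[r]]
    lapply(0:(p - 1L), function(dest) {
      rows <- b[b$r_i == dest, cols, drop = FALSE]
      if (nrow(rows) == 0L) emptySlot(template) else rows
    })
  })
  inboxes <- bruckAllToAll(rt, outboxes)
  lapply(seq_len(p), function(w) {
    tab <- do.call(rbind, inboxes[[w]])
    rownames(tab) <- NULL
    tab
  })
}

#' Second shuffle phase: move the line bytes to their writers
#'
#' Every origin worker copies, for each line it parsed, the line's bytes out
#' of its buffer and sends the pair `(o_d, line)` to the writer rank `r_d`
#' recorded in its routing table.  After the exchange each writer holds the
#' lines of exactly one contiguous byte range of the destination file; a
#' gap or overlap in that range aborts before anything is written.
#'
#' @param rt A [SimRuntime-class].
#' @param routingTables Per-origin tables from [shufflePhase1()].
#' @param buffers Per-origin worker buffers: each a list with `lines`
#'   (character) and `o_i` (byte offset of each line).
#' @return List of per-writer payload data.frames (columns `o_d`, `line`,
#'   `line_len`), ordered by `o_d` and verified contiguous.
#' @export
shufflePhase2 <- function(rt, routingTables, buffers) {
  p <- rt@p
  template <- data.frame(o_d = numeric(0), line = character(0),
                         line_len = numeric(0), stringsAsFactors = FALSE)
  outboxes <- lapply(seq_len(p), function(w) {
    tab <- routingTables[[w]]
    idx <- match(tab$o_i, buffers[[w]]$o_i)
    if (nrow(tab) > 0L && anyNA(idx))
      stop("shufflePhase2: routing table of rank ", w - 1L,
           " references an offset missing from its buffer")
    payload <- data.frame(o_d = tab$o_d,
                          line = buffers[[w]]$lines[idx],
                          line_len = tab$line_len,
                          stringsAsFactors = FALSE)
    lapply(0:(p - 1L), function(dest) {
      rows <- payload[tab$r_d == dest, , drop = FALSE]
      if (nrow(rows) == 0L) emptySlot(template) else rows
    })
  })
  inboxes <- bruckAllToAll(rt, outboxes)
  lapply(seq_len(p), function(w) {
    pay <- do.call(rbind, inboxes[[w]])
    rownames(pay) <- NULL
    pay <- pay[order(pay$o_d), , drop = FALSE]
    if (nrow(pay) > 1L) {
      expectNext <- pay$o_d[-nrow(pay)] + pay$line_len[-nrow(pay)]
      if (any(expectNext != pay$o_d[-1L]))
        stop("shufflePhase2: writer rank ", w - 1L,
             " received a non-contiguous byte range (gap or overlap)")
    }
    pay
  })
}

#' Validate writer coverage and write the sorted SAM file
#'
#' Checks that the writers' payloads tile the destination byte range
#' `[headerLen, headerLen + body bytes)` without gap or overlap — writers
#' are adjacent in rank order — and only then writes the header followed by
#' every line in destination-offset order, plus any tail lines (unmapped
#' records kept in origin order).
#'
#' @param headerLines Header lines, written verbatim.
#' @param writerPayloads List of per-writer payload data.frames
#'   ([shufflePhase2()] output, possibly concatenated over chromosomes).
#' @param outPath Output path.
#' @param tailLines Character vector appended after all sorted lines.
#' @return `outPath`, invisibly.
#' @export
writeSortedSam <- function(headerLines, writerPayloads, outPath,
                           tailLines = character(0)) {
  headerLen <- sum(nchar(headerLines, type = "bytes") + 1L)
  pay <- do.call(rbind, writerPayloads)
  lines <- character(0)
  if (!is.null(pay) && nrow(pay) > 0L) {
    pay <- pay[order(pay$o_d), , drop = FALSE]
    expected <- headerLen + cumsum(c(0, pay$line_len))[seq_len(nrow(pay))]
    if (any(pay$o_d != expected))
      stop("writeSortedSam: destination offsets do not tile the file; refusing to write")
    lines <- pay$line
  }
  writeSamLines(c(headerLines, lines, tailLines), outPath)
  invisible(outPath)
}

#' Coordinate-sort a SAM file on the simulated distributed runtime
#'
#' The full pipeline: the alignment body is split into `p` near-equal
#' line-aligned blocks, each worker parses its block into five-value sort
#' records, and each chromosome (in @SQ header order) is then sorted
#' successively — pad to uniform block size with sentinels, parallel bitonic
#' sort by `(coordinate, origin rank, origin offset)`, strip sentinels,
#' assign destination ranks/offsets, send the destinations back to the
#' origin workers with a first Bruck all-to-all, move the line bytes to the
#' writers with a second one — and written as adjacent contiguous blocks.
#' Unmapped records (RNAME `*` or not in the header) are appended after all
#' chromosomes in original file order, or dropped.
#'
#' The tie-break `(coordinate, origin rank, origin offset)` equals original
#' file order for every `p`, so the output is byte-identical for any
#' power-of-two worker count, and for `p = 1` the sort reduces to a
#' conventional stable coordinate sort.
#'
#' @param path Input SAM path.
#' @param p Number of workers; must be a power of two.
#' @param outPath Output SAM path.
#' @param unmapped `"keep-tail"` (default) appends unmapped records after
#'   the sorted chromosomes; `"drop"` discards them.
#' @param audit Record the worker-access log (see [runtimeReport()]).
#' @param report Optional path: write the runtime instrumentation as JSON.
#' @return Invisibly, the instrumentation report list.
#' @examples
#' spec <- fixtureSpec(seed = 7, nReads = 24, nChromosomes = 2)
#' sam <- tempfile(fileext = ".sam"); out <- tempfile(fileext = ".sam")
#' generateSam(spec, sam)
#' sortSamFile(sam, p = 4, out)
#' readSamFile(out)$bodyLines[1:2]
#' @export
sortSamFile <- function(path, p, outPath, unmapped = c("keep-tail", "drop"),
                        audit = FALSE, report = NULL) {
  unmapped <- match.arg(unmapped)
  p <- as.integer(p)
  if (!isPowerOfTwo(p))
    stop("sortSamFile: p must be a power of two, got ", p)
  sam <- readSamFile(path)
  rt <- simRuntime(p, audit = audit)
  ranges <- splitSamIntoBlocks(sam, p)

  parsed <- vector("list", p)
  buffers <- vector("list", p)
  for (r in seq_len(p)) {
    idx <- if (ranges$nLines[r] > 0L)
      ranges$firstLine[r] + seq_len(ranges$nLines[r]) - 1L else integer(0)
    buf <- sam$bodyLines[idx]
    parsed[[r]] <- parseBlock(buf, r - 1L, sam$sqNames)
    lens <- nchar(buf, type = "bytes") + 1L
    buffers[[r]] <- list(lines = buf, o_i = cumsum(c(0, lens))[seq_along(buf)])
  }

  currentOffset <- sam$headerLen
  writerPayloads <- list()
  for (ci in seq_along(sam$sqNames) - 1L) {
    chromBlocks <- lapply(parsed, function(pr)
      pr$records[pr$records$chrom == ci, , drop = FALSE])
    nChrom <- sum(vapply(chromBlocks, nrow, integer(1)))
    if (nChrom == 0L) next
    padded <- padToUniform(chromBlocks, keyCols = SORT_KEY)
    sorted <- parallelBitonicSort(rt, padded$blocks, keyCols = SORT_KEY)
    sorted <- stripSentinels(sorted)
    sorted <- assignDestinations(sorted, currentOffset)
    tables <- shufflePhase1(rt, sorted)
    expect <- vapply(chromBlocks, nrow, integer(1))
    got <- vapply(tables, nrow, integer(1))
    if (any(expect != got))
      stop("sortSamFile: shuffle phase 1 lost or duplicated routing rows")
    payloads <- shufflePhase2(rt, tables, buffers)
    writerPayloads <- c(writerPayloads, payloads)
    currentOffset <- currentOffset +
      sum(unlist(lapply(sorted, function(b) b$line_len)))
  }

  tailLines <- character(0)
  if (unmapped == "keep-tail") {
    tailLines <- unlist(lapply(seq_len(p), function(r) {
      um <- parsed[[r]]$unmapped
      um <- um[order(um$o_i), , drop = FALSE]
      buffers[[r]]$lines[match(um$o_i, buffers[[r]]$o_i)]
    }), use.names = FALSE)
    if (is.null(tailLines)) tailLines <- character(0)
  }

  writeSortedSam(sam$headerLines, writerPayloads, outPath, tailLines)
  rep <- runtimeReport(rt, file = report)
  invisible(rep)
}

#' Number of cores needed to sort a SAM file in memory
#'
#' The distributed sorter keeps the whole input resident, with a memory
#' footprint of about `multiplier` times the SAM size: around 2.5x for a
#' single-chromosome file and around 1.5x for a whole-genome file (where
#' chromosomes are sorted successively and the bound is driven by the file
#' plus the largest chromosome).  Since the bitonic network needs a
#' power-of-two worker count, the requirement is rounded up: the result is
#' the smallest power of two at or above
#' `ceiling(multiplier * samSizeGb / memPerCoreGb)`.
#'
#' @param samSizeGb SAM file size in GB.
#' @param memPerCoreGb Usable memory per core in GB.
#' @param multiplier Memory factor: 2.5 (default) for a single-chromosome
#'   file, 1.5 for a whole-genome file.
#' @return Integer core count (a power of two).
#' @examples
#' requiredCores(209, 4.5)        # 128 cores for a 209 GB chr1 SAM
#' requiredCores(110, 4.5)        # 64 cores for a 110 GB one
#' @export
requiredCores <- function(samSizeGb, memPerCoreGb, multiplier = 2.5) {
  if (any(c(samSizeGb, memPerCoreGb, multiplier) <= 0))
    stop("requiredCores: all arguments must be positive")
  needed <- ceiling(multiplier * samSizeGb / memPerCoreGb)
  as.integer(2^ceiling(log2(needed)))
}
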