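# Parallel sorting engine over the simulated runtime: per-worker merge sort,
# compare-split, and the block-level bitonic sort that replaces every
# comparator of the sorting network by a compare-split between two workers.
#
# A worker block is a data.frame of records; the sort key is a set of
# columns compared lexicographically (base::order, which is stable).  The
# logical column .sentinel marks padding records that compare greater than
# every real key and are stripped before any output is written.

blockOrder <- function(block, keyCols) {
  do.call(order, c(unname(as.list(block[keyCols])), list(method = "radix")))
}

#' Sort one worker block locally
#'
#' Stable sort of a block's records by the lexicographic key columns; this
#' is the per-processor merge sort that precedes the parallel bitonic phase.
#' Records with equal keys keep their input order.
#'
#' @param block A data.frame of records.
#' @param keyCols Character vector of key column names, compared in order.
#' @return The block, sorted.
#' @export
localSort <- function(block, keyCols = "key") {
  block[blockOrder(block, keyCols), , drop = FALSE]
}

blockIsSorted <- function(block, keyCols) {
  !is.unsorted(blockOrder(block, keyCols)) ||
    identical(blockOrder(block, keyCols), seq_len(nrow(block)))
}

#' Compare-split between two workers
#'
#' The block-level analogue of a compare-exchange: the two workers exchange
#' their full sorted blocks through the mailbox (two block messages), each
#' merges the `2m` records into one sorted list, and the worker designated
#' low keeps the lower `m` records while the other keeps the upper `m`.
#' With `increasing = TRUE` the lower rank keeps the low half.
#'
#' @param rt A [SimRuntime-class]; carries the mailbox and counters.
#' @param blockA,blockB Sorted blocks of equal size belonging to `rankA`
#'   and `rankB`.
#' @param rankA,rankB Ranks (0-based), `rankA < rankB`.
#' @param increasing Direction: `TRUE` sends small keys to `rankA`.
#' @param keyCols Key column names.
#' @return List with the two updated blocks, `a` and `b`.
#' @export
compareSplit <- function(rt, blockA, blockB, rankA, rankB,
                         increasing = TRUE, keyCols = "key") {
  m <- nrow(blockA)
  if (nrow(blockB) != m)
    stop("compareSplit: blocks must have equal size, got ",
         m, " and ", nrow(blockB))
  if (!blockIsSorted(blockA, keyCols) || !blockIsSorted(blockB, keyCols))
    stop("compareSplit: both blocks must be sorted")
  # full-block exchange through the mailbox: 2 messages
  mbSend(rt, rankA, rankB, blockA)
  mbSend(rt, rankB, rankA, blockB)
  fromA <- mbReceive(rt, rankA, rankB)
  fromB <- mbReceive(rt, rankB, rankA)
  merged <- rbind(fromA, fromB)
  merged <- merged[blockOrder(merged, keyCols), , drop = FALSE]
  lowHalf  <- merged[seq_len(m), , drop = FALSE]
  highHalf <- merged[m + seq_len(m), , drop = FALSE]
  if (increasing) list(a = lowHalf, b = highHalf)
  else            list(a = highHalf, b = lowHalf)
}

sentinelRow <- function(template, keyCols) {
  row <- lapply(template, function(col) {
    if (is.numeric(col)) NA_real_
    else if (is.character(col)) ""
    else if (is.logical(col)) NA
    else NA
  })
  row <- as.data.frame(row, stringsAsFactors = FALSE)
  if (nrow(row) == 0L) row <- row[NA_integer_, , drop = FALSE]
  for (kc in keyCols) row[[kc]] <- Inf   # compares greater than any real key
  row$.sentinel <- TRUE
  row
}

#' Pad worker blocks to a uniform size with sentinel records
#'
#' The bitonic machinery needs all `p` blocks to hold the same number of
#' records.  Blocks are padded with sentinel records whose key columns are
#' `+Inf`, so they sort after every real record and collect at the global
#' tail; the pad count is returned so sentinels can be stripped before any
#' output is written.
#'
#' @param blocks List of record data.frames (equal column layout).
#' @param keyCols Key column names set to `Inf` in sentinel rows.
#' @param m Target block size; defaults to the largest current block.
#' @return List with `blocks` (all of size `m`, each with a `.sentinel`
#'   column) and `padCount`.
#' @export
padToUniform <- function(blocks, keyCols = "key", m = NULL) {
  sizes <- vapply(blocks, nrow, integer(1))
  if (is.null(m)) m <- max(sizes, 0L)
  if (any(sizes > m)) stop("padToUniform: m smaller than an existing block")
  template <- blocks[[which.max(vapply(blocks, ncol, integer(1)))]]
  padCount <- 0L
  blocks <- lapply(blocks, function(b) {
    if (!".sentinel" %in% names(b))
      b$.sentinel <- rep(FALSE, nrow(b))
    need <- m - nrow(b)
    if (need > 0L) {
      pad <- sentinelRow(template, keyCols)
      pad <- pad[rep(1L, need), , drop = FALSE]
      b <- rbind(b, pad)
    }
    b
  })
  padCount <- as.integer(sum(pmax(m - sizes, 0L)))
  list(blocks = blocks, padCount = padCount)
}

#' Remove sentinel padding from worker blocks
#'
#' @param blocks List of blocks carrying a `.sentinel` column.
#' @return The blocks with sentinel rows dropped and the marker column kept
#'   (all `FALSE`).
#' @export
stripSentinels <- function(blocks) {
  lapply(blocks, function(b) {
    if (!".sentinel" %in% names(b)) return(b)
    b[!b$.sentinel, , drop = FALSE]
  })
}

#' Parallel bitonic sort of worker blocks
#'
#' Sorts `n = p * m` records distributed over `p = 2^q` message-isolated
#' workers: each worker first sorts its own block locally, then the blocks
#' traverse the bitonic sorting network for `p` inputs with every comparator
#' replaced by a [compareSplit()] between the two ranks it connects.  The
#' network has `q(q+1)/2` parallel stages, so that many compare-split steps
#' are performed (3 for `p = 4`); the runtime counts them.  Afterwards the
#' concatenation `blocks[[1]], ..., blocks[[p]]` is globally sorted.
#'
#' The runtime is synchronous-stepped: all compare-splits of a network stage
#' complete before the next stage begins, matching the staged semantics of
#' the comparator schedule.
#'
#' @param rt A [SimRuntime-class] with `p` equal to the number of blocks.
#' @param blocks List of `p` record data.frames of equal size.
#' @param keyCols Key column names.
#' @return The list of blocks, globally sorted across the concatenation.
#' @export
parallelBitonicSort <- function(rt, blocks, keyCols = "key") {
  p <- length(blocks)
  if (rt@p != p)
    stop("parallelBitonicSort: runtime has p = ", rt@p,
         " but ", p, " blocks were given")
  if (!isPowerOfTwo(p))
    stop("parallelBitonicSort: number of workers must be a power of two, got ", p)
  sizes <- vapply(blocks, nrow, integer(1))
  if (length(unique(sizes)) > 1L)
    stop("parallelBitonicSort: all blocks must have equal size")
  blocks <- lapply(blocks, localSort, keyCols = keyCols)
  if (p == 1L) return(blocks)
  net <- buildSortingNetwork(p)
  for (s in seq_along(net@stages)) {
    st <- net@stages[[s]]
    for (i in seq_len(nrow(st))) {
      ra <- st$a[i] - 1L            # network indices are 1-based, ranks 0-based
      rb <- st$b[i] - 1L
      res <- compareSplit(rt, blocks[[ra + 1L]], blocks[[rb + 1L]],
                          ra, rb, increasing = st$increasing[i],
                          keyCols = keyCols)
      blocks[[ra + 1L]] <- res$a
      blocks[[rb + 1L]] <- res$b
      auditRecord(rt, s, c(ra, rb))
    }
    rt@state$compareSplitSteps <- rt@state$compareSplitSteps + 1L
  }
  blocks
}
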