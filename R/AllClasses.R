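#' @import methods
NULL

#' Comparator network for the bitonic sort
#'
#' A fixed, data-independent schedule of two-input comparators, organised as
#' an ordered list of parallel stages.  Within a stage no input index appears
#' twice, so all comparators of a stage can fire simultaneously; the number
#' of stages is the parallel depth of the network.  For `n = 2^k` inputs the
#' bitonic construction yields `k(k+1)/2` stages of `n/2` comparators each.
#'
#' @slot n Integer, the number of inputs; must be a power of two.
#' @slot stages A list of data.frames, one per parallel stage, each with
#'   columns `a`, `b` (1-based input indices, `a < b`) and `increasing`
#'   (logical; `TRUE` routes the smaller value to the lower index).
#'
#' @seealso [buildSortingNetwork()], [applyNetwork()], [networkDump()]
#' @export
setClass("ComparatorNetwork",
  slots = c(n = "integer", stages = "list"))

setValidity("ComparatorNetwork", function(object) {
  n <- object@n
  if (length(n) != 1L || is.na(n) || n < 1L)
    return("n must be a single positive integer")
  if (!isPowerOfTwo(n))
    return("n must be a power of two")
  for (s in seq_along(object@stages)) {
    st <- object@stages[[s]]
    if (!is.data.frame(st) ||
        !all(c("a", "b", "increasing") %in% names(st)))
      return(sprintf("stage %d is not a data.frame with columns a, b, increasing", s))
    if (any(st$a >= st$b))
      return(sprintf("stage %d has a comparator with a >= b", s))
    if (any(st$a < 1L) || any(st$b > n))
      return(sprintf("stage %d has indices outside [1, n]", s))
    idx <- c(st$a, st$b)
    if (anyDuplicated(idx))
      return(sprintf("stage %d reuses an input index; stage comparators must be independent", s))
  }
  TRUE
})

#' @describeIn ComparatorNetwork Number of inputs of the network.
#' @param x,object A `ComparatorNetwork`.
#' @export
networkSize <- function(x) x@n

#' @describeIn ComparatorNetwork Parallel depth (number of stages).
#' @export
stageCount <- function(x) length(x@stages)

#' @describeIn ComparatorNetwork Total number of comparators over all stages.
#' @export
comparatorCount <- function(x) sum(vapply(x@stages, nrow, integer(1)))

setMethod("show", "ComparatorNetwork", function(object) {
  cat(sprintf("ComparatorNetwork on %d inputs\n", object@n))
  cat(sprintf("  %d parallel stages, %d comparators\n",
              stageCount(object), comparatorCount(object)))
})

#' Specification of a synthetic sequencing fixture
#'
#' Describes a deterministic synthetic FASTQ or SAM file: the random seed,
#' read geometry, the reference layout (@SQ lines), and the rates of unmapped
#' and coordinate-duplicated records used to stress tie-breaking.  The same
#' spec and seed always regenerate byte-identical files.
#'
#' @slot seed Integer random seed.
#' @slot nReads Number of reads (read pairs in paired mode).
#' @slot readLength Read length in nucleotides.
#' @slot nChromosomes Number of reference sequences in the header.
#' @slot chromosomeLengths Numeric vector of reference lengths (recycled to
#'   `nChromosomes` if scalar).
#' @slot paired Logical; emit two mate FASTQ files with matched names.
#' @slot fractionUnmapped Fraction of SAM records with RNAME `*`, in [0, 1].
#' @slot duplicateCoordinateRate Fraction of mapped records forced onto one
#'   shared coordinate, in [0, 1].
#'
#' @seealso [fixtureSpec()], [generateFastq()], [generateSam()]
#' @export
setClass("FixtureSpec",
  slots = c(seed = "integer", nReads = "integer", readLength = "integer",
            nChromosomes = "integer", chromosomeLengths = "numeric",
            paired = "logical", fractionUnmapped = "numeric",
            duplicateCoordinateRate = "numeric"))

setValidity("FixtureSpec", function(object) {
  if (object@nReads < 0L) return("nReads must be >= 0")
  if (object@readLength < 1L) return("readLength must be >= 1")
  if (object@nChromosomes < 0L) return("nChromosomes must be >= 0")
  if (object@nChromosomes > 0L &&
      length(object@chromosomeLengths) != object@nChromosomes)
    return("chromosomeLengths must have one entry per chromosome")
  if (any(object@chromosomeLengths < 1)) return("chromosome lengths must be >= 1")
  for (nm in c("fractionUnmapped", "duplicateCoordinateRate")) {
    v <- slot(object, nm)
    if (length(v) != 1L || is.na(v) || v < 0 || v > 1)
      return(sprintf("%s must be a single value in [0, 1]", nm))
  }
  TRUE
})

setMethod("show", "FixtureSpec", function(object) {
  cat(sprintf("FixtureSpec: %d %sreads x %d nt, %d chromosome(s), seed %d\n",
              object@nReads, if (object@paired) "paired " else "",
              object@readLength, object@nChromosomes, object@seed))
  if (object@fractionUnmapped > 0 || object@duplicateCoordinateRate > 0)
    cat(sprintf("  unmapped fraction %.2f, duplicate-coordinate rate %.2f\n",
                object@fractionUnmapped, object@duplicateCoordinateRate))
})

#' Simulated distributed runtime
#'
#' Models `p` message-isolated workers connected by a mailbox: every
#' cross-worker data movement goes through explicit send/receive calls whose
#' counts and byte volumes are instrumented, and per-(source, destination)
#' delivery order is preserved.  Mirrors the point-to-point contract of a
#' message-passing system so the parallel algorithms can be audited in a
#' single process.
#'
#' @slot p Integer number of workers (ranks 0..p-1).
#' @slot state Environment holding the mailbox queues, instrumentation
#'   counters and the access-audit log.
#'
#' @seealso [simRuntime()], [runtimeReport()]
#' @export
setClass("SimRuntime", slots = c(p = "integer", state = "environment"))

setValidity("SimRuntime", function(object) {
  if (object@p < 1L) return("p must be >= 1")
  TRUE
})

setMethod("show", "SimRuntime", function(object) {
  r <- runtimeReport(object)
  cat(sprintf("SimRuntime with %d worker(s)\n", object@p))
  cat(sprintf("  messages: %d (%.0f bytes), compare-split steps: %d, shuffle rounds: %d\n",
              r$messages, r$bytes, r$compareSplitSteps, r$bruckRounds))
})
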