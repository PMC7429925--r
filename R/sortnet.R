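# Sequential building blocks of the bitonic sort: bitonic sequences, the
# min/max split, the recursive bitonic merge, and the full comparator network.

isPowerOfTwo <- function(n) {
  n >= 1 && bitwAnd(as.integer(n), as.integer(n) - 1L) == 0L
}

#' Test whether a sequence is bitonic
#'
#' A sequence is bitonic when it first increases then decreases
#' (non-strictly), or when some cyclic shift of it does.  Every sorted,
#' constant, empty or single-element sequence is bitonic.
#'
#' The test counts cyclic sign changes of the successive differences after
#' dropping ties: a sequence is bitonic exactly when there are at most two
#' such changes around the cycle.
#'
#' @param x Numeric vector.
#' @return `TRUE` or `FALSE`.
#' @examples
#' isBitonic(c(1, 3, 5, 4, 2))  # TRUE: rises then falls
#' isBitonic(c(3, 1, 2))        # TRUE: cyclic shift of 1,2,3
#' isBitonic(c(1, 3, 2, 4))     # FALSE
#' @export
isBitonic <- function(x) {
  n <- length(x)
  if (n <= 2L) return(TRUE)
  d <- sign(diff(c(x, x[1L])))   # cyclic differences
  d <- d[d != 0]
  if (length(d) <= 1L) return(TRUE)
  changes <- sum(d != c(d[-1L], d[1L]))
  changes <= 2L
}

#' Bitonic split of a bitonic sequence
#'
#' Pairs element `i` with element `i + n/2` and takes elementwise minima and
#' maxima: `s1[i] = min(a[i], a[i + n/2])`, `s2[i] = max(a[i], a[i + n/2])`.
#' For a bitonic input both halves are again bitonic and every element of
#' `s1` is less than or equal to every element of `s2`, which is what lets
#' the merge recurse independently on the two halves.
#'
#' @param x Bitonic numeric vector of even length.
#' @return A list with components `s1` (low half) and `s2` (high half).
#' @examples
#' bitonicSplit(c(3, 5, 8, 9, 7, 4, 2, 1))
#' @export
bitonicSplit <- function(x) {
  n <- length(x)
  if (n %% 2L != 0L)
    stop("bitonicSplit: sequence length must be even, got ", n)
  if (!isBitonic(x))
    stop("bitonicSplit: input sequence is not bitonic")
  h <- n %/% 2L
  lo <- x[seq_len(h)]
  hi <- x[h + seq_len(h)]
  list(s1 = pmin(lo, hi), s2 = pmax(lo, hi))
}

#' Sort a bitonic sequence by recursive bitonic splits
#'
#' Recursively splits a bitonic sequence of length `n = 2^k` until the
#' pieces have size one, which sorts it in exactly `k` split levels.  The
#' number of levels actually performed is attached to the result as the
#' `"splitLevels"` attribute so the depth can be inspected.
#'
#' @param x Bitonic numeric vector; length must be a power of two.
#' @param decreasing Sort direction; `FALSE` (default) sorts increasing.
#' @return Sorted numeric vector with attribute `splitLevels = log2(n)`.
#' @examples
#' bitonicMerge(c(3, 5, 8, 9, 7, 4, 2, 1))
#' @export
bitonicMerge <- function(x, decreasing = FALSE) {
  n <- length(x)
  if (!isPowerOfTwo(max(n, 1L)))
    stop("bitonicMerge: length must be a power of two, got ", n)
  if (!isBitonic(x))
    stop("bitonicMerge: input sequence is not bitonic")
  rec <- function(v) {
    if (length(v) <= 1L) return(v)
    sp <- .splitNoCheck(v)
    c(rec(sp$s1), rec(sp$s2))
  }
  out <- rec(x)
  if (decreasing) out <- rev(out)
  attr(out, "splitLevels") <- if (n > 0L) as.integer(log2(n)) else 0L
  out
}

# split without the bitonicity re-check (the split theorem guarantees it
# for recursion); keeps the merge O(n log n) comparisons, not O(n^2)
.splitNoCheck <- function(x) {
  h <- length(x) %/% 2L
  lo <- x[seq_len(h)]
  hi <- x[h + seq_len(h)]
  list(s1 = pmin(lo, hi), s2 = pmax(lo, hi))
}

#' Build the full bitonic sorting network
#'
#' Constructs the comparator schedule that sorts any `n = 2^k` inputs:
#' merge phases of widths 2, 4, ..., n, where phase `j` runs blocks of
#' alternating increasing/decreasing bitonic merges (turning the input into
#' ever longer bitonic runs) and the final phase is a single increasing
#' merge of the whole sequence.  Phase `j` contributes `j` parallel stages
#' of `n/2` comparators, so the network has `k(k+1)/2` stages and
#' `n/2 * k(k+1)/2` comparators in total.
#'
#' The direction convention is: an *increasing* comparator routes the
#' smaller value to its lower input index.  Comparators swap only on strict
#' order violation, so ties keep their positions.
#'
#' @param n Number of inputs; must be a power of two, `n >= 2`.
#' @return A [ComparatorNetwork-class] object.
#' @examples
#' net <- buildSortingNetwork(8)
#' stageCount(net)       # 6 parallel stages
#' comparatorCount(net)  # 24 comparators
#' @export
buildSortingNetwork <- function(n) {
  n <- as.integer(n)
  if (!isPowerOfTwo(n) || n < 2L)
    stop("buildSortingNetwork: n must be a power of two >= 2, got ", n)
  k <- as.integer(log2(n))
  i0 <- 0:(n - 1L)                       # 0-based for the bit tests
  stages <- vector("list", k * (k + 1L) %/% 2L)
  s <- 0L
  for (j in seq_len(k)) {                # merge phase: block width 2^j
    for (lvl in (j - 1L):0L) {           # split distance 2^lvl within blocks
      d <- bitwShiftL(1L, lvl)
      a <- i0[bitwAnd(i0, d) == 0L]
      inc <- bitwAnd(a, bitwShiftL(1L, j)) == 0L  # block direction alternates
      s <- s + 1L
      stages[[s]] <- data.frame(a = a + 1L, b = a + d + 1L, increasing = inc)
    }
  }
  new("ComparatorNetwork", n = n, stages = stages)
}

#' Execute a comparator network
#'
#' Applies every compare-exchange of the network in stage order.  A
#' comparator swaps its two values only when they strictly violate the
#' requested direction.  If the network came from [buildSortingNetwork()],
#' the output is sorted for every input (0-1 principle).
#'
#' `x` may also be a matrix with `net@n` columns, in which case every row is
#' pushed through the network simultaneously; this is how the exhaustive
#' binary-input checks run in reasonable time.
#'
#' @param x Numeric vector of length `networkSize(net)`, or a matrix with
#'   that many columns (one input sequence per row).
#' @param net A [ComparatorNetwork-class].
#' @return Vector or matrix of the same shape, with comparators applied.
#' @examples
#' applyNetwork(c(5, 2), buildSortingNetwork(2))
#' @export
applyNetwork <- function(x, net) {
  stopifnot(is(net, "ComparatorNetwork"))
  vec <- is.null(dim(x))
  m <- if (vec) matrix(x, nrow = 1L) else x
  if (ncol(m) != net@n)
    stop("applyNetwork: input length ", ncol(m),
         " does not match network size ", net@n)
  for (st in net@stages) {
    va <- m[, st$a, drop = FALSE]
    vb <- m[, st$b, drop = FALSE]
    # violation: for increasing, a > b; for decreasing, a < b
    dirs <- matrix(st$increasing, nrow = nrow(m), ncol = nrow(st), byrow = TRUE)
    swap <- ifelse(dirs, va > vb, va < vb)
    lo <- ifelse(swap, vb, va)
    hi <- ifelse(swap, va, vb)
    m[, st$a] <- lo
    m[, st$b] <- hi
  }
  if (vec) as.vector(m) else m
}

#' Dump a comparator network as a plain-text schedule
#'
#' One line per stage in the form `stage s: (a,b,dir) ...` with `dir` either
#' `inc` or `dec`; useful for debugging and for documenting small networks.
#'
#' @param net A [ComparatorNetwork-class].
#' @param file Optional path; when given the schedule is written there.
#' @return Character vector of schedule lines, invisibly when `file` is set.
#' @export
networkDump <- function(net, file = NULL) {
  stopifnot(is(net, "ComparatorNetwork"))
  lines <- vapply(seq_along(net@stages), function(s) {
    st <- net@stages[[s]]
    steps <- sprintf("(%d,%d,%s)", st$a, st$b,
                     ifelse(st$increasing, "inc", "dec"))
    sprintf("stage %d: %s", s, paste(steps, collapse = " "))
  }, character(1))
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
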