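# All-to-all personalized exchange over the mailbox contract.
#
# An outbox is one worker's view of the exchange: a list with p slots where
# slot d holds the payload destined for rank d-1 (payloads are opaque; a
# zero-row data.frame or empty list is a valid empty payload).  The naive
# path delivers every payload directly; the Bruck path completes in
# ceil(log2 p) communication rounds by routing each payload along the binary
# decomposition of its relative destination distance.

checkOutboxes <- function(outboxes, p) {
  if (length(outboxes) != p)
    stop("all-to-all: expected ", p, " outboxes, got ", length(outboxes))
  slots <- lengths(outboxes)
  if (any(slots != p))
    stop("all-to-all: every worker must have exactly p = ", p,
         " destination slots (found ", paste(unique(slots), collapse = ", "), ")")
  invisible(TRUE)
}

#' Direct all-to-all personalized exchange
#'
#' Delivers `outboxes[[i]][[j]]` straight to `inboxes[[j]][[i]]` with one
#' mailbox message per ordered pair of distinct workers (`p(p-1)` messages);
#' self-destined payloads move locally.  This is the correctness reference
#' the Bruck path is tested against, and the fallback for worker counts that
#' are not powers of two.
#'
#' @param rt A [SimRuntime-class] with `p` workers.
#' @param outboxes List of `p` outboxes, each a list of `p` payload slots.
#' @return List of `p` inboxes: `inboxes[[j]][[i]]` is what rank `i-1` sent
#'   to rank `j-1`.
#' @export
naiveAllToAll <- function(rt, outboxes) {
  p <- rt@p
  checkOutboxes(outboxes, p)
  inboxes <- replicate(p, vector("list", p), simplify = FALSE)
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) {
        inboxes[[j]][[i]] <- outboxes[[i]][[j]]
      } else {
        mbSend(rt, i - 1L, j - 1L, outboxes[[i]][[j]])
        inboxes[[j]][[i]] <- mbReceive(rt, i - 1L, j - 1L)
      }
    }
  }
  inboxes
}

#' Bruck all-to-all personalized exchange
#'
#' Logarithmic-round all-to-all: after a local rotation that reindexes every
#' payload by its relative destination distance `d = (dest - src) mod p`,
#' round `r` (for `r = 0, ..., ceil(log2 p) - 1`) has every rank `i` bundle
#' the payloads whose remaining distance has bit `r` set into a single
#' message for rank `(i + 2^r) mod p`.  A payload at remaining distance `d`
#' therefore hops along the set bits of `d` and arrives after the last
#' round; a final local pass reassembles each inbox by origin rank.  All
#' traffic goes through the runtime mailbox and the round counter on the
#' runtime is incremented by exactly `ceil(log2 p)`.
#'
#' Results are identical to [naiveAllToAll()]: content and intra-slot order
#' of every payload are preserved.
#'
#' @inheritParams naiveAllToAll
#' @return List of `p` inboxes, as for [naiveAllToAll()].
#' @export
bruckAllToAll <- function(rt, outboxes) {
  p <- rt@p
  checkOutboxes(outboxes, p)
  if (p == 1L) return(list(list(outboxes[[1L]][[1L]])))
  if (!isPowerOfTwo(p))
    stop("bruckAllToAll: p must be a power of two (use naiveAllToAll otherwise)")
  q <- as.integer(ceiling(log2(p)))
  ranks <- 0:(p - 1L)

  # phase 1 — local rotation: unit for (origin i, dest (i + d) mod p) starts
  # in the slot indexed by its relative distance d
  buf <- lapply(ranks, function(i) {
    slots <- vector("list", p)          # slots[[d + 1]] = list of units
    for (d in 0:(p - 1L)) {
      j <- (i + d) %% p
      slots[[d + 1L]] <- list(list(origin = i, payload = outboxes[[i + 1L]][[j + 1L]]))
    }
    slots
  })

  # phase 2 — q exchange rounds along the binary decomposition of d
  for (r in 0:(q - 1L)) {
    hop <- bitwShiftL(1L, r)
    outgoing <- vector("list", p)
    for (i in seq_len(p)) {
      sendSlots <- which(bitwAnd(0:(p - 1L), hop) != 0L)   # d with bit r set
      bundle <- list()
      for (d1 in sendSlots) {
        units <- buf[[i]][[d1]]
        if (length(units)) {
          bundle[[length(bundle) + 1L]] <- list(d = d1 - 1L, units = units)
          buf[[i]][[d1]] <- list()
        }
      }
      outgoing[[i]] <- bundle
    }
    for (i in seq_len(p)) {
      dest <- (i - 1L + hop) %% p
      mbSend(rt, i - 1L, dest, outgoing[[i]])
    }
    for (i in seq_len(p)) {
      src <- (i - 1L - hop) %% p
      bundle <- mbReceive(rt, src, i - 1L)
      for (part in bundle) {
        d1 <- part$d - hop + 1L          # remaining distance shrinks by 2^r
        buf[[i]][[d1]] <- c(buf[[i]][[d1]], part$units)
      }
    }
    rt@state$bruckRounds <- rt@state$bruckRounds + 1L
  }

  # phase 3 — inverse rotation: everything sits at distance 0 of its
  # destination; reassemble inboxes keyed by origin rank
  inboxes <- replicate(p, vector("list", p), simplify = FALSE)
  for (j in seq_len(p)) {
    for (unit in buf[[j]][[1L]])
      inboxes[[j]][[unit$origin + 1L]] <- unit$payload
    leftovers <- sum(lengths(buf[[j]][-1L]))
    if (leftovers > 0L)
      stop("bruckAllToAll: ", leftovers, " payload(s) failed to reach rank ", j - 1L)
  }
  inboxes
}
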