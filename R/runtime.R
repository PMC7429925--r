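# Simulated distributed runtime: mailbox message contract + instrumentation.
#
# All cross-worker data movement in this package goes through mbSend/mbReceive
# on a SimRuntime, so message counts, byte volumes and communication rounds
# can be audited exactly as they would be on a real message-passing system.

#' Create a simulated distributed runtime
#'
#' @param p Number of workers (ranks `0..p-1`).
#' @param audit Keep a log of block accesses during the parallel sort so
#'   worker isolation can be verified.
#' @return A [SimRuntime-class] object.
#' @examples
#' rt <- simRuntime(4)
#' runtimeReport(rt)
#' @export
simRuntime <- function(p, audit = TRUE) {
  p <- as.integer(p)
  st <- new.env(parent = emptyenv())
  st$queues <- list()            # keyed "src->dest", FIFO lists
  st$messages <- 0L
  st$bytes <- 0
  st$compareSplitSteps <- 0L
  st$bruckRounds <- 0L
  st$audit <- audit
  st$accessLog <- list()         # (stage, ranks touched) during parallel sort
  new("SimRuntime", p = p, state = st)
}

payloadBytes <- function(payload) {
  if (is.data.frame(payload) && "line_len" %in% names(payload))
    return(sum(payload$line_len))
  as.numeric(utils::object.size(payload))
}

#' Send a message between two simulated workers
#'
#' Appends `payload` to the FIFO queue from `src` to `dest`; per-(src, dest)
#' delivery order is preserved and the runtime's message and byte counters
#' are incremented.
#'
#' @param rt A [SimRuntime-class].
#' @param src,dest Ranks in `0..p-1`.
#' @param payload Arbitrary R object (typically a block data.frame or a list
#'   of routing rows).
#' @return The runtime, invisibly.
#' @export
mbSend <- function(rt, src, dest, payload) {
  st <- rt@state
  if (src < 0L || src >= rt@p || dest < 0L || dest >= rt@p)
    stop("mbSend: rank out of range [0, p)")
  key <- paste0(src, "->", dest)
  st$queues[[key]] <- c(st$queues[[key]], list(payload))
  st$messages <- st$messages + 1L
  st$bytes <- st$bytes + payloadBytes(payload)
  invisible(rt)
}

#' Receive the oldest pending message between two workers
#'
#' @inheritParams mbSend
#' @return The payload; errors if the queue is empty.
#' @export
mbReceive <- function(rt, src, dest) {
  st <- rt@state
  key <- paste0(src, "->", dest)
  q <- st$queues[[key]]
  if (is.null(q) || length(q) == 0L)
    stop("mbReceive: no pending message from rank ", src, " to rank ", dest)
  st$queues[[key]] <- q[-1L]
  q[[1L]]
}

mbPendingCount <- function(rt) {
  sum(lengths(rt@state$queues))
}

auditRecord <- function(rt, stage, ranks) {
  st <- rt@state
  if (isTRUE(st$audit))
    st$accessLog[[length(st$accessLog) + 1L]] <- list(stage = stage,
                                                      ranks = sort(ranks))
  invisible(rt)
}

#' Instrumentation report for a runtime
#'
#' @param rt A [SimRuntime-class].
#' @param file Optional path; when given, the report is written there as JSON.
#' @return A list with `p`, `messages`, `bytes`, `compareSplitSteps`,
#'   `bruckRounds` and the access-audit log.
#' @export
runtimeReport <- function(rt, file = NULL) {
  st <- rt@state
  rep <- list(p = rt@p, messages = st$messages, bytes = st$bytes,
              compareSplitSteps = st$compareSplitSteps,
              bruckRounds = st$bruckRounds,
              accessLog = st$accessLog)
  if (!is.null(file))
    jsonlite::write_json(rep[-length(rep)], file, auto_unbox = TRUE)
  rep
}
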