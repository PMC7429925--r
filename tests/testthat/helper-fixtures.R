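# Shared helpers: random bitonic sequences, byte-exact file reads, and
# tagged outboxes for the all-to-all tests.

randomBitonic <- function(n) {
  # sorted values, rise to a random peak then fall, then a random cyclic
  # shift: covers every shape the definition allows, ties included
  vals <- sort(sample.int(n * 2L, n, replace = TRUE))
  peak <- sample.int(n, 1L)
  seqv <- c(vals[seq_len(peak)], rev(vals[-seq_len(peak)]))
  shift <- sample.int(n, 1L) - 1L
  if (shift > 0L) seqv <- c(seqv[-seq_len(shift)], seqv[seq_len(shift)])
  seqv
}

# independent bitonicity oracle: try every cyclic shift explicitly;
# a shift qualifies when it is nondecreasing up to its (first) maximum and
# nonincreasing afterwards
isBitonicExhaustive <- function(x) {
  n <- length(x)
  if (n <= 2L) return(TRUE)
  upDown <- function(v) {
    i <- which.max(v)
    !is.unsorted(v[seq_len(i)]) && !is.unsorted(rev(v[i:length(v)]))
  }
  for (s in 0:(n - 1L)) {
    v <- if (s == 0L) x else c(x[-seq_len(s)], x[seq_len(s)])
    if (upDown(v)) return(TRUE)
  }
  FALSE
}

fileBytes <- function(path) readChar(path, file.size(path), useBytes = TRUE)

taggedOutboxes <- function(p, payloadsPerSlot = 1L) {
  lapply(0:(p - 1L), function(i)
    lapply(0:(p - 1L), function(j)
      sprintf("%d->%d#%d", i, j, seq_len(payloadsPerSlot))))
}

keyBlocksFromVector <- function(keys, p) {
  # tag rows by their global input position so payload routing is checkable
  m <- length(keys) %/% p
  lapply(seq_len(p), function(r) {
    idx <- (r - 1L) * m + seq_len(m)
    data.frame(key = keys[idx], tag = sprintf("g%03d", idx))
  })
}

blockKeys <- function(blocks) {
  unlist(lapply(blocks, function(b) b$key), use.names = FALSE)
}
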