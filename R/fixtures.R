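# Synthetic FASTQ/SAM generation and the single-process sorting oracle.
# Everything is deterministic under the spec's seed, so every test input is
# rebuilt from code and no data files ship with the package.

#' Construct a fixture specification
#'
#' @param seed Integer random seed.
#' @param nReads Number of reads (pairs, in paired mode).
#' @param readLength Read length in nucleotides (default 50).
#' @param nChromosomes Number of reference sequences (default 1).
#' @param chromosomeLengths Reference lengths; scalar values are recycled
#'   (default 10000).
#' @param paired Emit mate files (default `FALSE`).
#' @param fractionUnmapped Fraction of SAM records with RNAME `*`.
#' @param duplicateCoordinateRate Fraction of mapped records forced onto a
#'   single shared coordinate (stresses tie-breaking).
#' @return A [FixtureSpec-class] object.
#' @examples
#' fixtureSpec(seed = 1, nReads = 100)
#' @export
fixtureSpec <- function(seed, nReads, readLength = 50L, nChromosomes = 1L,
                        chromosomeLengths = 10000, paired = FALSE,
                        fractionUnmapped = 0, duplicateCoordinateRate = 0) {
  if (length(chromosomeLengths) == 1L)
    chromosomeLengths <- rep(chromosomeLengths, nChromosomes)
  new("FixtureSpec", seed = as.integer(seed), nReads = as.integer(nReads),
      readLength = as.integer(readLength),
      nChromosomes = as.integer(nChromosomes),
      chromosomeLengths = as.numeric(chromosomeLengths),
      paired = paired, fractionUnmapped = as.numeric(fractionUnmapped),
      duplicateCoordinateRate = as.numeric(duplicateCoordinateRate))
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

randomSeq <- function(n, len) {
  if (n == 0L) return(character(0))
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

#' Generate a deterministic synthetic FASTQ file (or mate pair)
#'
#' @param spec A [FixtureSpec-class].
#' @param path Output path for the (first) FASTQ file.
#' @param path2 Output path for the mate file; required when
#'   `spec@paired` is `TRUE`.
#' @return Character vector of the file(s) written, invisibly.
#' @export
generateFastq <- function(spec, path, path2 = NULL) {
  stopifnot(is(spec, "FixtureSpec"))
  if (spec@paired && is.null(path2))
    stop("generateFastq: paired spec needs path2")
  withSeed(spec@seed, {
    n <- spec@nReads
    names <- sprintf("read_%06d", seq_len(n))
    writeFq <- function(p, mate) {
      seqs <- randomSeq(n, spec@readLength)
      quals <- vapply(seq_len(max(n, 0L)), function(i)
        paste(sample(strsplit("!\"#$%&'()*+,-./0123456789:;<=>?@ABCDEFGHI", "")[[1]],
                     spec@readLength, replace = TRUE), collapse = ""),
        character(1))
      lines <- if (n == 0L) character(0) else
        as.vector(rbind(paste0("@", names, "/", mate), seqs, "+", quals))
      con <- file(p, open = "wb")
      on.exit(close(con))
      if (length(lines))
        writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL,
                  useBytes = TRUE)
    }
    writeFq(path, 1L)
    if (spec@paired) writeFq(path2, 2L)
  })
  invisible(c(path, if (spec@paired) path2))
}

#' Generate a deterministic synthetic SAM file
#'
#' Emits an `@SQ` header line per chromosome and `nReads` shuffled-coordinate
#' alignment lines (valid 11-field records): a `fractionUnmapped` share gets
#' RNAME `*`/POS 0/flag 4, and a `duplicateCoordinateRate` share of the
#' mapped records is collapsed onto one shared coordinate to stress
#' tie-breaking in the sorter.
#'
#' @param spec A [FixtureSpec-class].
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
generateSam <- function(spec, path) {
  stopifnot(is(spec, "FixtureSpec"))
  if (spec@nChromosomes < 1L && spec@fractionUnmapped < 1 && spec@nReads > 0L)
    stop("generateSam: mapped reads need at least one chromosome")
  withSeed(spec@seed, {
    n <- spec@nReads
    chromNames <- if (spec@nChromosomes > 0L)
      paste0("chr", seq_len(spec@nChromosomes)) else character(0)
    header <- c("@HD\tVN:1.6\tSO:unsorted",
                sprintf("@SQ\tSN:%s\tLN:%d", chromNames,
                        as.integer(spec@chromosomeLengths)))
    lines <- character(0)
    if (n > 0L) {
      unmapped <- runif(n) < spec@fractionUnmapped
      ci <- if (spec@nChromosomes > 0L)
        sample.int(spec@nChromosomes, n, replace = TRUE) else rep(1L, n)
      pos <- floor(runif(n) * pmax(spec@chromosomeLengths[ci] -
                                     spec@readLength + 1, 1)) + 1
      if (spec@duplicateCoordinateRate > 0 && any(!unmapped)) {
        dup <- runif(n) < spec@duplicateCoordinateRate
        ci[dup] <- ci[which(!unmapped)[1L]]
        pos[dup] <- pos[which(!unmapped)[1L]]
      }
      seqs <- randomSeq(n, spec@readLength)
      qual <- strrep("I", spec@readLength)
      rname <- ifelse(unmapped, "*", chromNames[ci])
      lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t%s\t%s",
                       sprintf("read_%06d", seq_len(n)),
                       ifelse(unmapped, 4L, 0L), rname,
                       ifelse(unmapped, 0L, as.integer(pos)),
                       ifelse(unmapped, 0L, 60L),
                       ifelse(unmapped, "*",
                              paste0(spec@readLength, "M")),
                       seqs, qual)
    }
    writeSamLines(c(header, lines), path)
  })
  invisible(path)
}

#' Single-process reference coordinate sort
#'
#' The oracle the distributed sorter is tested against: read the whole SAM
#' file, stable-sort the body by (chromosome index in @SQ order, position)
#' — unmapped records compare greater than everything, so they end up at
#' the tail in original order — and write header plus body back verbatim.
#'
#' @param path Input SAM path.
#' @param outPath Output SAM path.
#' @return `outPath`, invisibly.
#' @export
oracleSortSam <- function(path, outPath) {
  sam <- readSamFile(path)
  fields <- strsplit(sam$bodyLines, "\t", fixed = TRUE, useBytes = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L))
    stop("oracleSortSam: malformed SAM record (", nf[nf < 11L][1L], " fields)")
  rname <- vapply(fields, `[[`, character(1), 3L)
  pos <- as.numeric(vapply(fields, `[[`, character(1), 4L))
  ci <- match(rname, sam$sqNames)
  ci[is.na(ci)] <- length(sam$sqNames) + 1L     # unmapped to the tail
  ord <- order(ci, ifelse(ci > length(sam$sqNames), 0, pos), method = "radix")
  writeSamLines(c(sam$headerLines, sam$bodyLines[ord]), outPath)
  invisible(outPath)
}

#' Self-test: oracle equivalence and worker-count independence
#'
#' Runs the distributed sorter against the single-process oracle on a few
#' small seeded fixtures and checks that outputs are byte-identical across
#' worker counts — the file-level restatement of the engine's
#' reproducibility contract.
#'
#' @param seeds Integer seeds, one fixture per seed.
#' @param pSet Worker counts to compare (powers of two).
#' @param quiet Suppress the progress message.
#' @return `TRUE` invisibly on success; stops on the first discrepancy.
#' @export
selfTest <- function(seeds = 1:5, pSet = c(1L, 2L, 4L), quiet = FALSE) {
  for (s in seeds) {
    spec <- fixtureSpec(seed = s, nReads = 40 + (s %% 4L) * 20L,
                        nChromosomes = 1L + (s %% 3L),
                        chromosomeLengths = 5000,
                        fractionUnmapped = 0.1,
                        duplicateCoordinateRate = 0.3)
    sam <- tempfile(fileext = ".sam")
    generateSam(spec, sam)
    oracle <- tempfile(fileext = ".sam")
    oracleSortSam(sam, oracle)
    ref <- readChar(oracle, file.size(oracle), useBytes = TRUE)
    for (p in pSet) {
      out <- tempfile(fileext = ".sam")
      sortSamFile(sam, p, out)
      got <- readChar(out, file.size(out), useBytes = TRUE)
      if (!identical(got, ref))
        stop("selfTest: seed ", s, ", p = ", p,
             ": sorted output differs from the oracle")
      unlink(out)
    }
    unlink(c(sam, oracle))
  }
  if (!quiet)
    message("selfTest: ", length(seeds), " fixture(s) x p in {",
            paste(pSet, collapse = ","), "}: oracle-identical output")
  invisible(TRUE)
}
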