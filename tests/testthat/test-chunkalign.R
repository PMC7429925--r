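# FASTQ chunking by nucleotide budget, deterministic SAM emission through
# the aligner contract, and per-chromosome splitting.

writeFastq <- function(path, names, seqs) {
  quals <- vapply(nchar(seqs), function(k) strrep("I", k), character(1))
  lines <- as.vector(rbind(paste0("@", names), seqs, "+", quals))
  con <- file(path, "wb")
  writeChar(paste0(paste(lines, collapse = "\n"), "\n"), con, eos = NULL)
  close(con)
  path
}

test_that("chunks pack records greedily up to the nucleotide budget", {
  fq <- tempfile(fileext = ".fastq")
  writeFastq(fq, sprintf("r%d", 1:4), rep(strrep("A", 10), 4))
  ch <- computeChunks(fq, ntBudget = 20)
  expect_identical(ch$read_count, c(2L, 2L))
  expect_identical(ch$nucleotide_count, c(20, 20))
  # budget equal to one read: one chunk per read
  ch1 <- computeChunks(fq, ntBudget = 10)
  expect_identical(ch1$read_count, rep(1L, 4))
  # a read longer than the budget still forms its own chunk
  writeFastq(fq, c("a", "b"), c(strrep("C", 30), strrep("G", 5)))
  chBig <- computeChunks(fq, ntBudget = 8)
  expect_identical(chBig$read_count, c(1L, 1L))
  expect_identical(chBig$nucleotide_count, c(30, 5))
  # empty FASTQ: empty chunk list
  con <- file(fq, "wb"); close(con)
  expect_identical(nrow(computeChunks(fq, ntBudget = 10)), 0L)
})

test_that("chunk byte ranges are record-aligned and covering", {
  fq <- tempfile(fileext = ".fastq")
  set.seed(53)
  lens <- sample(5:20, 9, replace = TRUE)
  writeFastq(fq, sprintf("read%02d", 1:9),
             vapply(lens, function(k)
               paste(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                     collapse = ""), character(1)))
  ch <- computeChunks(fq, ntBudget = 25)
  expect_identical(ch$start[1], 0)
  expect_identical(ch$start[-1L], ch$end[-nrow(ch)])       # adjacent
  expect_identical(ch$end[nrow(ch)], file.size(fq))        # covering
  txt <- fileBytes(fq)
  rebuilt <- paste(vapply(seq_len(nrow(ch)), function(k)
    substr(txt, ch$start[k] + 1, ch$end[k]), character(1)), collapse = "")
  expect_identical(rebuilt, txt)                            # byte-for-byte
  expect_identical(sum(ch$read_count), 9L)
  expect_identical(sum(ch$nucleotide_count), as.numeric(sum(lens)))
})

test_that("paired chunking advances both mates in lock-step", {
  fq1 <- tempfile(fileext = ".fastq")
  fq2 <- tempfile(fileext = ".fastq")
  spec <- fixtureSpec(seed = 5, nReads = 12, readLength = 10, paired = TRUE)
  generateFastq(spec, fq1, fq2)
  ch <- computeChunks(fq1, fq2, ntBudget = 60)   # 3 pairs x 20 nt per chunk
  expect_identical(ch$read_count, rep(3L, 4))
  expect_identical(ch$nucleotide_count, rep(60, 4))
  r1 <- readFastqFile(fq1)
  r2 <- readFastqFile(fq2)
  # mate n of both files lands in the same chunk index
  chunkOf <- function(recStart, starts, ends)
    vapply(recStart, function(s) which(s >= starts & s < ends), integer(1))
  expect_identical(chunkOf(r1$recStart, ch$start, ch$end),
                   chunkOf(r2$recStart, ch$start2, ch$end2))
  # unequal record counts are a pairing error
  writeFastq(fq2, "solo", "ACGT")
  expect_error(computeChunks(fq1, fq2, ntBudget = 60), "unequal")
})

test_that("FASTQ reader rejects malformed records", {
  bad <- tempfile(fileext = ".fastq")
  con <- file(bad, "wb")
  writeChar("@r1\nACGT\n+\nIIII\n@r2\nACGT\n", con, eos = NULL)
  close(con)
  expect_error(readFastqFile(bad), "truncated")
  con <- file(bad, "wb")
  writeChar("r1\nACGT\n+\nIIII\n", con, eos = NULL)
  close(con)
  expect_error(readFastqFile(bad), "does not start with '@'")
})

test_that("aligned SAM output is independent of the worker count", {
  fq <- tempfile(fileext = ".fastq")
  generateFastq(fixtureSpec(seed = 11, nReads = 40, readLength = 20), fq)
  ch <- computeChunks(fq, ntBudget = 100)
  ref <- makeReferenceHandle(c(chr1 = 5000, chr2 = 3000, chr3 = 1000))
  outs <- vapply(c(1L, 2L, 5L), function(w) {
    f <- tempfile(fileext = ".sam")
    alignChunks(ch, fq, ref = ref, outPath = f, workers = w)
    fileBytes(f)
  }, character(1))
  expect_identical(outs[2], outs[1])
  expect_identical(outs[3], outs[1])
  # conservation with the mock aligner: one body line per read, valid SAM
  f <- tempfile(fileext = ".sam")
  alignChunks(ch, fq, ref = ref, outPath = f)
  parsed <- readSamFile(f)
  expect_identical(length(parsed$bodyLines), 40L)
  expect_identical(parsed$sqNames, c("chr1", "chr2", "chr3"))
  expect_true(all(lengths(strsplit(parsed$bodyLines, "\t")) == 11L))
  # zero chunks: header-only SAM
  f0 <- tempfile(fileext = ".sam")
  alignChunks(ch[0, ], fq, ref = ref, outPath = f0)
  expect_identical(length(readSamFile(f0)$bodyLines), 0L)
  # aligner failure names the chunk
  boom <- function(reads, ref) stop("nope")
  expect_error(alignChunks(ch, fq, aligner = boom, ref = ref,
                           outPath = tempfile()), "chunk 1")
})

test_that("mock-aligned output feeds the distributed sorter end to end", {
  fq <- tempfile(fileext = ".fastq")
  generateFastq(fixtureSpec(seed = 23, nReads = 32, readLength = 15), fq)
  ch <- computeChunks(fq, ntBudget = 75)
  ref <- makeReferenceHandle(c(chrA = 2000, chrB = 900))
  sam <- tempfile(fileext = ".sam")
  alignChunks(ch, fq, ref = ref, outPath = sam)
  out <- tempfile(fileext = ".sam")
  orc <- tempfile(fileext = ".sam")
  sortSamFile(sam, 4, out)
  oracleSortSam(sam, orc)
  expect_identical(fileBytes(out), fileBytes(orc))
})

test_that("per-chromosome splitting partitions the body and keeps order", {
  spec <- fixtureSpec(seed = 31, nReads = 50, nChromosomes = 2L,
                      chromosomeLengths = 1000, fractionUnmapped = 0.2)
  sam <- tempfile(fileext = ".sam")
  generateSam(spec, sam)
  outDir <- tempfile()
  outs <- splitSamByChromosome(sam, outDir)
  expect_named(outs, c("chr1", "chr2", "*"))
  parts <- lapply(outs, readSamFile)
  counts <- vapply(parts, function(s) length(s$bodyLines), integer(1))
  expect_identical(sum(counts), 50L)
  full <- readSamFile(sam)
  for (nm in names(outs)) {
    rn <- vapply(strsplit(full$bodyLines, "\t"), `[[`, character(1), 3L)
    expect_identical(parts[[nm]]$bodyLines, full$bodyLines[rn == nm])
    expect_identical(parts[[nm]]$headerLines, full$headerLines)
  }
  # single-chromosome input: body passes through unchanged
  spec1 <- fixtureSpec(seed = 32, nReads = 10, nChromosomes = 1L)
  generateSam(spec1, sam)
  outs1 <- splitSamByChromosome(sam, tempfile())
  expect_identical(readSamFile(outs1[["chr1"]])$bodyLines,
                   readSamFile(sam)$bodyLines)
  # all-unmapped input: chromosome files are header-only
  specU <- fixtureSpec(seed = 33, nReads = 6, nChromosomes = 1L,
                      fractionUnmapped = 1)
  generateSam(specU, sam)
  outsU <- splitSamByChromosome(sam, tempfile())
  expect_identical(length(readSamFile(outsU[["chr1"]])$bodyLines), 0L)
  expect_identical(length(readSamFile(outsU[["*"]])$bodyLines), 6L)
  # unknown RNAME is an error
  writeSamLines(c("@SQ\tSN:chr1\tLN:10",
                  "r\t0\tchrX\t1\t60\t1M\t*\t0\t0\tA\tI"), sam)
  expect_error(splitSamByChromosome(sam, tempfile()), "chrX")
})
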