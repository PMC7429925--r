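# Distributed SAM coordinate sorting: block partitioning, record parsing,
# destination assignment, the two shuffle phases, the end-to-end driver and
# the core-sizing rule.

makeSam <- function(path, sqLines, bodyLines) {
  writeSamLines(c("@HD\tVN:1.6\tSO:unsorted", sqLines, bodyLines), path)
  path
}

samLine <- function(name, rname, pos, flag = 0L) {
  sprintf("%s\t%d\t%s\t%d\t60\t5M\t*\t0\t0\tACGTA\tIIIII", name, flag, rname, pos)
}

test_that("block partition is line-aligned, covering and near-equal", {
  tmp <- tempfile(fileext = ".sam")
  body <- samLine(sprintf("r%d", 1:8), "chr1", 1:8)    # equal line lengths
  makeSam(tmp, "@SQ\tSN:chr1\tLN:1000", body)
  sam <- readSamFile(tmp)
  bl <- splitSamIntoBlocks(sam, 2)
  expect_identical(bl$nLines, c(4L, 4L))
  # 7 equal-length lines, p = 2: boundary snaps to a newline -> sizes 4, 3
  makeSam(tmp, "@SQ\tSN:chr1\tLN:1000", body[1:7])
  bl7 <- splitSamIntoBlocks(readSamFile(tmp), 2)
  expect_identical(bl7$nLines, c(4L, 3L))
  expect_identical(bl7$start[2], bl7$end[1])
  # covering invariant: ranges reproduce the body exactly
  sam7 <- readSamFile(tmp)
  rebuilt <- unlist(lapply(seq_len(2), function(r)
    sam7$bodyLines[bl7$firstLine[r] + seq_len(bl7$nLines[r]) - 1L]))
  expect_identical(rebuilt, sam7$bodyLines)
  expect_identical(bl7$end[2], sum(sam7$lineLen))
  # empty body: p empty ranges, no error
  makeSam(tmp, "@SQ\tSN:chr1\tLN:1000", character(0))
  bl0 <- splitSamIntoBlocks(readSamFile(tmp), 4)
  expect_identical(bl0$nLines, rep(0L, 4))
  expect_true(all(bl0$start == 0) && all(bl0$end == 0))
})

test_that("parsing extracts the five-value record and diverts unmapped lines", {
  sqNames <- c("chr1", "chr2")
  buf <- c(samLine("r1", "chr2", 100),
           samLine("r2", "*", 0, flag = 4L),
           samLine("r3", "chr1", 7))
  pb <- parseBlock(buf, rank = 2L, sqNames)
  expect_identical(pb$records$chrom, c(1L, 0L))      # @SQ order, 0-based
  expect_identical(pb$records$pos, c(100, 7))
  expect_true(all(pb$records$r_i == 2L))
  expect_identical(nrow(pb$unmapped), 1L)
  # offsets equal cumulative byte lengths (independent byte-count pass)
  lens <- nchar(buf, type = "bytes") + 1
  expect_identical(c(pb$records$o_i[1], pb$unmapped$o_i, pb$records$o_i[2]),
                   cumsum(c(0, lens))[1:3])
  expect_identical(pb$records$line_len, lens[c(1L, 3L)])
  expect_error(parseBlock("r1\tonly\tthree", 0L, sqNames), "malformed")
  expect_error(parseBlock("a\t0\tchr1\tXYZ\t60\t5M\t*\t0\t0\tA\tI", 0L, sqNames),
               "non-integer POS")
})

test_that("destination offsets are the exclusive prefix sum after the header", {
  blocks <- list(
    data.frame(chrom = 0L, pos = c(1, 2), r_i = 0L, o_i = c(0, 10),
               line_len = c(10L, 10L)),
    data.frame(chrom = 0L, pos = c(3, 4), r_i = 1L, o_i = c(0, 10),
               line_len = c(10L, 10L)))
  out <- assignDestinations(blocks, baseOffset = 50)
  expect_identical(unlist(lapply(out, `[[`, "o_d"), use.names = FALSE),
                   c(50, 60, 70, 80))
  expect_identical(out[[1]]$r_d, c(0L, 0L))
  expect_identical(out[[2]]$r_d, c(1L, 1L))
  # single worker: o_d strictly increases by line_len
  one <- assignDestinations(list(data.frame(chrom = 0L, pos = 1:3, r_i = 0L,
                                            o_i = c(0, 12, 30),
                                            line_len = c(12L, 18L, 9L))), 100)
  expect_identical(diff(one[[1]]$o_d), c(12, 18))
  # conservation: last offset + last length == file size
  expect_identical(one[[1]]$o_d[3] + 9, 100 + 12 + 18 + 9)
})

test_that("shuffle phases route every record once and tile the writers", {
  spec <- fixtureSpec(seed = 101, nReads = 16, nChromosomes = 1L,
                      chromosomeLengths = 500)
  sam <- tempfile(fileext = ".sam")
  generateSam(spec, sam)
  s <- readSamFile(sam)
  p <- 4L
  rt <- simRuntime(p)
  ranges <- splitSamIntoBlocks(s, p)
  parsed <- lapply(seq_len(p), function(r) {
    idx <- ranges$firstLine[r] + seq_len(ranges$nLines[r]) - 1L
    parseBlock(s$bodyLines[idx], r - 1L, s$sqNames)
  })
  chromBlocks <- lapply(parsed, `[[`, "records")
  pad <- padToUniform(chromBlocks, keyCols = c("pos", "r_i", "o_i"))
  sorted <- stripSentinels(parallelBitonicSort(rt, pad$blocks,
                                               keyCols = c("pos", "r_i", "o_i")))
  sorted <- assignDestinations(sorted, s$headerLen)
  tables <- shufflePhase1(rt, sorted)
  # each origin's table has exactly its parsed-line count, keyed by o_i
  expect_identical(vapply(tables, nrow, integer(1)),
                   vapply(chromBlocks, nrow, integer(1)))
  for (r in seq_len(p))
    expect_setequal(tables[[r]]$o_i, chromBlocks[[r]]$o_i)
  # union of all tables covers all records exactly once
  expect_identical(sum(vapply(tables, nrow, integer(1))), 16L)
  buffers <- lapply(seq_len(p), function(r) {
    idx <- ranges$firstLine[r] + seq_len(ranges$nLines[r]) - 1L
    lines <- s$bodyLines[idx]
    lens <- nchar(lines, type = "bytes") + 1
    list(lines = lines, o_i = cumsum(c(0, lens))[seq_along(lines)])
  })
  payloads <- shufflePhase2(rt, tables, buffers)
  # writers tile [headerLen, fileSize) in rank order: offsets in o_d order
  # are the exclusive prefix sums of the line lengths
  allPay <- do.call(rbind, payloads)
  ord <- order(allPay$o_d)
  expect_identical(allPay$o_d[ord],
                   s$headerLen + cumsum(c(0, allPay$line_len[ord]))[seq_len(16)])
  expect_identical(sum(allPay$line_len), sum(s$lineLen))
  # each writer's own range is gap-free and writers are rank-adjacent
  ends <- vapply(payloads, function(pp) max(pp$o_d + pp$line_len), numeric(1))
  starts <- vapply(payloads, function(pp) min(pp$o_d), numeric(1))
  nonEmpty <- vapply(payloads, nrow, integer(1)) > 0L
  expect_identical(starts[nonEmpty][-1L],
                   ends[nonEmpty][-sum(nonEmpty)])
  # concatenating writer ranges in rank order equals the oracle body
  orc <- tempfile(fileext = ".sam")
  oracleSortSam(sam, orc)
  expect_identical(allPay$line[order(allPay$o_d)], readSamFile(orc)$bodyLines)
})

test_that("full driver equals the oracle and is worker-count independent", {
  for (s in 1:6) {
    spec <- fixtureSpec(seed = 200 + s, nReads = 30 + 8 * s,
                        nChromosomes = 1L + (s %% 3L),
                        chromosomeLengths = 3000,
                        fractionUnmapped = ifelse(s %% 2 == 0, 0.15, 0),
                        duplicateCoordinateRate = ifelse(s == 3, 1, 0.2))
    sam <- tempfile(fileext = ".sam")
    generateSam(spec, sam)
    orc <- tempfile(fileext = ".sam")
    oracleSortSam(sam, orc)
    ref <- fileBytes(orc)
    for (p in c(1L, 2L, 4L, 8L)) {
      out <- tempfile(fileext = ".sam")
      sortSamFile(sam, p, out)
      expect_identical(fileBytes(out), ref)
      unlink(out)
    }
    # permutation: output body is a reordering of the input body
    outSam <- readSamFile(orc)
    expect_identical(sort(outSam$bodyLines), sort(readSamFile(sam)$bodyLines))
    # sortedness of the mapped body in (chrom, pos)
    f <- strsplit(outSam$bodyLines, "\t", fixed = TRUE)
    ci <- match(vapply(f, `[[`, character(1), 3L), outSam$sqNames)
    pos <- as.numeric(vapply(f, `[[`, character(1), 4L))
    mapped <- !is.na(ci)
    expect_false(is.unsorted(ci[mapped] * 1e9 + pos[mapped]))
    unlink(c(sam, orc))
  }
})

test_that("driver handles degenerate inputs", {
  tmp <- tempfile(fileext = ".sam")
  out <- tempfile(fileext = ".sam")
  # chromosome present in header but without reads: no lines, no error
  makeSam(tmp, c("@SQ\tSN:chr1\tLN:100", "@SQ\tSN:chrEmpty\tLN:50"),
          samLine(c("r2", "r1"), "chr1", c(9, 3)))
  sortSamFile(tmp, 2, out)
  res <- readSamFile(out)
  expect_identical(length(res$bodyLines), 2L)
  expect_match(res$bodyLines[1], "^r1\t")
  # already-sorted input passes through unchanged
  sortSamFile(out, 4, tmp)
  expect_identical(fileBytes(tmp), fileBytes(out))
  # unmapped handling: keep-tail retains origin order, drop removes them
  makeSam(tmp, "@SQ\tSN:chr1\tLN:100",
          c(samLine("u1", "*", 0, 4L), samLine("m1", "chr1", 5),
            samLine("u2", "*", 0, 4L)))
  sortSamFile(tmp, 2, out)
  expect_match(readSamFile(out)$bodyLines[2], "^u1\t")
  expect_match(readSamFile(out)$bodyLines[3], "^u2\t")
  sortSamFile(tmp, 2, out, unmapped = "drop")
  expect_identical(length(readSamFile(out)$bodyLines), 1L)
  expect_error(sortSamFile(tmp, 3, out), "power of two")
})

test_that("core sizing rounds up to the next power of two", {
  expect_identical(requiredCores(209, 4.5, 2.5), 128L)
  expect_identical(requiredCores(110, 4.5, 2.5), 64L)
  expect_identical(requiredCores(1, 4.5, 2.5), 1L)
  # whole-genome factor
  expect_identical(requiredCores(300, 4.5, 1.5), 128L)
  expect_error(requiredCores(-1, 4.5), "positive")
  expect_error(requiredCores(10, 0), "positive")
})
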