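---
title: "Distributed bitonic sorting and chunked alignment for HTS data: methods"
author: "bitonica"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Distributed bitonic sorting and chunked alignment for HTS data: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bitonica)
```

## The problem

Aligning sequencing reads and coordinate-sorting the resulting alignments are
the two dominant pre-processing steps of every resequencing workflow, and on
whole-genome data both are bottlenecked by single-machine CPU, memory and I/O.
Distributed-memory implementations remove those bottlenecks by partitioning
the FASTQ/SAM byte streams over many processors that communicate only by
message passing, but their correctness arguments — that the output is
*byte-identical* to the single-process result, for *any* processor count —
are hard to audit inside a production MPI code base.

`bitonica` re-implements these engines on an explicit simulated runtime:
`p` workers that can read only their own block of records and exchange data
exclusively through an instrumented mailbox ([`simRuntime()`]). Every
algorithmic claim (schedule sizes, message counts, round counts,
reproducibility across `p`) then becomes an assertion that runs in an
ordinary R session at desk scale.

## The bitonic sorting network

A sequence is *bitonic* when it rises then falls (non-strictly), or is a
cyclic shift of such a sequence. The *bitonic split* of a bitonic sequence
of even length `n` pairs element `i` with element `i + n/2`:

$$ s_1 = \langle \min(a_0, a_{n/2}), \ldots, \min(a_{n/2-1}, a_{n-1}) \rangle,
   \quad
   s_2 = \langle \max(a_0, a_{n/2}), \ldots, \max(a_{n/2-1}, a_{n-1}) \rangle $$

Both halves are again bitonic and $\max(s_1) \le \min(s_2)$, so recursive
splitting sorts a bitonic sequence of length $n = 2^k$ in exactly $k$ split
levels (`bitonicMerge()` instruments this depth). Arbitrary inputs are first
turned into a bitonic sequence by merge phases of widths $2, 4, \ldots, n/2$
with alternating directions, followed by one full-width increasing merge;
`buildSortingNetwork()` materialises the whole schedule as staged comparator
lists rather than executing it recursively, so the parallel depth
($k(k+1)/2$ stages) and the comparator count ($n/2$ per stage) are plain
data that tests can inspect:

```{r network}
net <- buildSortingNetwork(8)
net
networkDump(net)[1:3]
```

Because a comparator network is data-independent, the 0–1 principle applies:
a network that sorts all $2^n$ binary inputs sorts everything. The test
suite checks this exhaustively up to $n = 16$ (65,536 inputs), pushing all
inputs through the network simultaneously as a matrix.

Two conventions are fixed throughout: an *increasing* comparator routes the
smaller value to its lower index, and a compare-exchange swaps only on a
strict order violation, so already-equal keys never move — duplicate
genomic coordinates are common and this keeps the machinery stable.

## The parallel engine

For `p = 2^q` workers holding `m` records each, every comparator of the
`p`-input network becomes a *compare-split* between two workers: both send
their full sorted block to the other (two mailbox messages), merge the `2m`
records, and keep the low or high half according to the comparator's
direction. Workers first sort locally (a stable merge sort via
`base::order`), then traverse the network stage by stage; the runtime is
synchronous-stepped, so all compare-splits of a stage finish before the next
begins — this matches the staged network semantics and makes every run
deterministic. Counters verify that `p = 4` performs exactly 3 compare-split
steps and that exactly $2 \cdot p/2 \cdot q(q+1)/2$ block messages are sent.

Real inputs rarely give every worker the same `m`, so blocks are padded with
*sentinel* records whose keys are $+\infty$ (`padToUniform()`); sentinels
collect at the global tail during the sort and are stripped before anything
is written. Padding (rather than truncation or redistribution) was chosen
because it leaves record ownership untouched and keeps the accounting
trivial: the real-record multiset is preserved by construction.

## All-to-all with the Bruck algorithm

After sorting, data must be reshuffled so each writer owns one contiguous
range of the output — an all-to-all personalized exchange. `bitonica`
implements the classic Bruck scheme: a local rotation reindexes payloads by
relative destination distance `d`, then round `r` bundles everything whose
remaining `d` has bit `r` set into a single message to rank `i + 2^r (mod
p)`, completing in exactly $\lceil \log_2 p \rceil$ rounds. In-flight
payloads are carried as origin-tagged units, which makes the textbook
framing and final reversal corrections unnecessary in R while preserving
the defining property, asserted against the direct-delivery oracle
`naiveAllToAll()`: `inbox[j][i] == outbox[i][j]`, contents and intra-slot
order intact. The naive path also covers worker counts that are not powers
of two.

## Distributed SAM coordinate sorting

The sorter's unit of routing is a five-value record per alignment line: the
genomic coordinate (chromosome index in `@SQ` header order plus 1-based
position), the origin rank `r_i`, the byte offset `o_i` of the line in the
origin worker's buffer, and — known only after the sort — the destination
writer rank `r_d` and destination byte offset `o_d`. The pipeline per
chromosome (chromosomes are processed successively, in header order):

1. **Partition**: the body is cut into `p` line-aligned, near-equal byte
   ranges; cut `i` is the first line start at or after `i/p` of the body.
2. **Parse**: each worker builds its records; RNAME `*` (or an RNAME absent
   from the header) is diverted to an unmapped side list.
3. **Sort**: pad, parallel bitonic sort by `(pos, r_i, o_i)`, strip.
4. **Assign**: `o_d` is the exclusive prefix sum of line lengths over the
   global sorted order (offset by header and previously written
   chromosomes); `r_d` is the rank holding the record, so each writer's
   offsets form one contiguous range, adjacent in rank order.
5. **Shuffle twice**: a first Bruck phase returns `(o_i, r_d, o_d,
   line_len)` to each record's origin; a second moves the actual line bytes
   to the writers. Writers verify their range is gap-free before anything
   is written.

The tie-break is the crux of reproducibility. `(r_i, o_i)` ordered
lexicographically equals original file position for *every* partition into
blocks, because blocks are contiguous in file order. The sort key
`(coordinate, r_i, o_i)` is therefore a total order whose restriction to
equal coordinates is input order — i.e. for `p = 1` the sort degenerates to
a conventional stable coordinate sort, and for any power-of-two `p` the
output file is byte-identical. The test suite asserts this at file level on
seeded fixtures for `p` in {1, 2, 4, 8}, including fixtures where every
record shares one coordinate.

Unmapped records are appended after all chromosomes in origin order (or
dropped on request); the format gives them no coordinate, and keeping them
at the tail preserves the permutation property without inventing an order
for them. Secondary/supplementary alignments are sorted by their own
coordinates like any other line.

### Memory-driven core sizing

The sorter keeps the input resident, so the worker count is chosen from
memory: sorting needs roughly 2.5 times the SAM size for a
single-chromosome file, and roughly 1.5 times for a whole-genome file
(chromosomes sorted successively; the bound follows the file plus its
largest chromosome). `requiredCores()` rounds the resulting core count up
to the next power of two, as the network requires:

```{r cores}
requiredCores(209, 4.5, 2.5)   # 209 GB single-chromosome SAM, 4.5 GB/core
requiredCores(110, 4.5, 2.5)
```

The multipliers are exposed as parameters because they summarise internal
structures of a resident sort rather than a law; callers with different
record overheads can recalibrate.

## Chunked alignment

The alignment side splits FASTQ input into chunks holding (as close as
possible to) a fixed number of nucleotides — nucleotides, not bytes or read
counts, because that is the granularity at which the underlying aligner
consumes work, and equal-nucleotide chunking is what makes the chunked
output reproduce the single-process run. A chunk is just two byte offsets
per file (record-aligned, half-open); in paired mode both mate files
advance in lock-step so mates never separate, and the greedy packer never
splits a record: a chunk may overshoot the budget by at most one record,
and a read longer than the whole budget forms its own chunk. The default
budget is 10,000,000 nucleotides; tests use small budgets so the geometry
is inspectable by hand.

Alignment itself sits behind a contract: a pure function from (chunk reads,
shared reference handle) to SAM lines, with the header derived once from
the reference. The package ships `mockAligner()`, which emits one
deterministic, valid SAM line per read with placement derived from a hash
of the read name — enough to drive the emission and sorting machinery end
to end; it performs no sequence alignment, and results about alignment
quality cannot be drawn from it. Chunk outputs are written in chunk order
regardless of worker count or completion order, which is the deterministic
stand-in for a shared-file-pointer collective write. A per-chromosome
splitter (`splitSamByChromosome()`) turns one SAM into one file per
reference plus an unmapped file, each carrying the full header.

## Synthetic fixtures, and what the tests do not show

All test inputs come from `generateFastq()`/`generateSam()` driven by a
seeded `fixtureSpec()`: uniform coordinates over a configurable reference
layout, a configurable unmapped fraction, and a duplicate-coordinate rate
that collapses records onto one position to stress tie-breaking. The
generators emulate the *structure* of HTS data (valid 4-line FASTQ, valid
11-field SAM, realistic header geometry) but not its content: no error
model, no quality distributions, no real genome. Passing tests therefore
establish the algorithmic contracts — sortedness, conservation, schedule
and message counts, byte-identical reproducibility — on files up to a few
hundred records and a handful of chromosomes; they say nothing about
wall-clock performance on parallel filesystems, which is a property of
hardware this package deliberately does not model.

Problem sizes used by the default test run: exhaustive 0–1 checks up to
`n = 16`; 1,000 random bitonic sequences for the split theorem; 200
randomized all-to-all cases over `p` in {2, 4, 8, 16}; 50 seeded SAM
fixtures (up to 512 reads, 4 chromosomes) sorted at `p` in {1, 2, 4, 8}.

## Numerical and degenerate-input choices

* Offsets are 0-based doubles (exact for file sizes far beyond 32-bit) and
  ranges half-open; lines are LF-terminated, and CR-LF input is rejected
  rather than silently re-terminated, since byte-identity is part of the
  contract.
* An empty body yields `p` empty ranges and a header-only output; a
  chromosome present in the header with no reads is skipped without error.
* A worker with no records for a chromosome participates via sentinel
  padding; `p = 1` short-circuits to the local sort.
* Equal keys never swap (non-strict comparators); `base::order`'s stable
  radix sort provides the local merge and the compare-split merge.
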