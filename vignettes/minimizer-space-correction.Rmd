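---
title: "Minimizer-space self-correction of noisy long reads"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizer-space self-correction of noisy long reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Oxford Nanopore long reads now reach per-base error rates of 1–2%, which is
accurate enough for metagenome assembly in *minimizer space* — where a read
is represented not by its bases but by a sparse, ordered list of selected
k-mers (universal minimizers). The catch is that a 1% base error rate
translates into a much higher minimizer error rate: with k = 15, roughly
`1 - 0.99^15 ≈ 14%` of a read's minimizers are corrupted, which breaks the
long minimizer chains that minimizer-space assemblers rely on.

`mscorrect` implements self-correction performed *entirely* in minimizer
space. No base-level alignment is ever computed; reads are compared,
aligned and corrected as minimizer lists, which is why the method is cheap
enough to run on very large read sets.

## The method

For each read (the *target*), the pipeline runs five steps:

1. **Sketching at two nested densities.** A k-mer is a universal minimizer
   when its canonical-strand hash `f(m)` falls below `d * H`, with `H` the
   hash-range bound. Two densities share one hash function: a sparse sketch
   (`dLow = 0.005`) for cheap all-vs-all comparison and a dense sketch
   (`dHigh = 0.025`) for accurate work. Because the selection predicate is a
   simple threshold, the low sketch is by construction a subsequence of the
   high sketch. The most abundant `1e-4` fraction of distinct minimizers
   (repeats) is blacklisted before any comparison.
2. **Recruitment.** An inverted index over the low-density sketches yields,
   for the target, every read sharing minimizers with it. Shared minimizers
   become *anchors*; banded dynamic-programming chaining finds the best
   colinear chain per candidate, which is expanded into a minimizer-space
   alignment (matches, mismatches, insertions, deletions of minimizers).
   Candidates are ranked by `score = matches - differences` and accepted
   greedily up to 20x cumulative coverage of the target.
3. **High-density filtering.** Recruited reads are re-aligned on the dense
   sketches, and the divergence of each alignment is estimated from the
   fraction of shared seeds: `divergence = 1 - (n/m)^(1/k)` with `n`
   matching seeds out of `m` query seeds in the aligned span. Alignments
   with divergence above 4%, span below 1000 bp, or an end overhang above
   2000 bp are discarded — the divergence cut rejects reads from other
   species, the span/overhang cuts mis-recruitment across repeats.
4. **Variation-graph pileup.** The surviving alignments are threaded
   through a DAG seeded with the target's own minimizer path. A supporter
   mismatch adds a node parallel to a target node, an insertion a bridging
   path between target nodes, a deletion a skip edge. Edge weights count
   supporting transitions — or, for FASTQ input, accumulate the sum of the
   source and destination minimizer qualities, where a minimizer's quality
   is the minimum Phred score over its k bases. The graph is, by
   construction, independent of the order supporters are added.
5. **Consensus.** Support scores are propagated in topological order,
   `S[v] = S[u] + w_e`, and the consensus is read off by backtracking from
   the highest-scoring node. The corrected minimizer list can then be
   turned back into bases by stitching, for each consecutive consensus
   pair, the spanning subsequence of the supporter with the strongest
   transition.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `k` | 15 | minimizer length (bases) |
| `dLow` | 0.005 | recruitment sketch density |
| `dHigh` | 0.025 | correction sketch density |
| `repetitiveFraction` | 1e-4 | fraction of distinct minimizers blacklisted |
| `coverageCap` | 20 | recruitment coverage cap (× target length) |
| `maxDivergence` | 0.04 | alignment divergence cut |
| `minSpanBases` | 1000 | minimum aligned target span (bp) |
| `maxOverhangBases` | 2000 | maximum unaligned end flank (bp) |
| `matchBonus`, `gapScale`, `gapCap`, `bandH` | 50, 0.05, 50, 50 | chaining score model |

The first eight are the method's published operating point. The chaining
constants are this package's own calibration of a skani-style scoring model
(reward each chained anchor, penalise diagonal drift linearly, cap the
penalty so long indels do not break chains, examine a bounded band of
predecessors); they are exposed through `ChainParams` and `RunConfig`.

## Design choices worth knowing about

* **Hash range.** Hashes are the top 53 bits of a 64-bit mixing function,
  so `H = 2^53 - 1` and every hash value is exact in an R double. The
  selection rule `f(m) < d * H` and hash uniformity are unaffected.
* **Divergence, not identity.** The shared-seed fraction `(n/m)^(1/k)` is
  an identity-like quantity (1 for identical sequences); the package works
  with its complement `1 - (n/m)^(1/k)` so that the 4% filter reads
  directly as a divergence threshold.
* **Consensus parent rule.** Each node's parent is the incoming edge
  maximizing the *cumulative* support `S[u] + w_e` — the standard DAG
  longest-path recurrence. A greedy rule that picks the locally
  heaviest incoming edge regardless of its source's score can return a
  sub-optimal path (a heavy edge hanging off an unsupported prefix); the
  cumulative rule provably extracts the most supported path, which is the
  method's stated goal, and is what the exhaustive-enumeration tests
  verify. Ties (in parents and in the final argmax) go to the earliest
  topological index; topological order itself is fixed as (target
  position, node class, insertion key), making results reproducible and
  independent of supporter order.
* **Equal-hash pairing.** When positional pairing between anchors lines up
  two hits with the *same* hash (possible when the banded chain skipped a
  true anchor), the pair is recorded as a match, not a mismatch — otherwise
  the graph would grow a spurious variant node parallel to an identical
  target node.
* **Target self-support.** The target's own path contributes one
  supporter's weight. This makes the zero-supporter case well defined (the
  consensus is the read itself) and lets reconstruction always fall back on
  the target's bases.
* **Opposite strands.** Strand-mixed overlaps are handled by reversing the
  query hit frame before chaining; all reported coordinates are on each
  read's forward strand. Canonical-strand hashing makes the hash multiset
  strand-invariant, so anchoring works across strands.
* **Cap semantics.** "Up to 20x" is enforced as a coverage cap on the
  cumulative aligned target span, not a flat read count; the candidate that
  first crosses the cap is still accepted. A flat count misbehaves when
  overlaps are short.
* **Homopolymer compression** is available (`hpc = TRUE`) but off by
  default: it is standard for PacBio HiFi sketching but not established
  for ONT-style data, which this package targets. When enabled, selection
  runs on the compressed sequence while offsets and qualities are reported
  in original coordinates.
* **Threads.** `correctReads()` accepts a `threads` argument for interface
  compatibility but runs serially: per-read correction is independent and
  deterministic, so outputs are byte-identical for any thread count.

## The simulator, and what passing tests mean

`simulateGenome()` / `simulateReads()` generate uniform-random genomes
(optionally several related species at a stated pairwise divergence),
draw reads uniformly with random strand, and corrupt them with i.i.d.
per-base substitutions, insertions and deletions; qualities are drawn
around a mean Phred score. The ground truth for every read is the
high-density sketch of its uncorrupted origin interval.

This emulates what the correction algorithm actually consumes — noisy
minimizer lists with known truth — and exercises every code path
(strand mixing, indels, repeats across species). It does *not* model
flow-cell-specific error spectra, basecaller artifacts, quality/error
correlation, or real genome repeat structure. Passing the simulation-based
tests therefore demonstrates algorithmic correctness and parameter
conformance, not field performance on real ONT data.

The validation suite runs at desk scale, chosen to keep the full test run
within minutes while leaving no estimate starved of data: density
calibration on 1 Mbp of random sequence; chaining verified against
exhaustive enumeration on 200 anchor sets of up to 15 anchors; consensus
verified against exhaustive path enumeration on 100 random DAGs of up to
12 nodes; order-independence on 50 pileup instances × 20 permutations; and
parameter recovery on a 100 kb genome at 30× coverage with 1% errors
(~300 reads of ~10 kb), where corrected sketches must beat uncorrected
ones at least 5-fold and the divergence estimator must recover simulated
substitution rates of 1–3% within ±0.5 points.

## Degenerate inputs and numerical notes

* Sequences shorter than `k` sketch to an empty hit list; empty reads and
  empty read sets flow through every stage without error.
* k-mers containing `N` are never selected.
* A read whose quality string length mismatches its sequence is rejected
  with a warning rather than silently mis-weighted.
* Divergence is undefined on an empty span (`m = 0`); callers never
  request it because expansion requires a non-empty chain.
* Blacklist ties at the cutoff abundance break by ascending hash value;
  recruitment ties by ascending read id; all consensus ties by earliest
  topological index. Every tie rule is deterministic.
* Insertion nodes have no target offset; consensus offsets are
  interpolated and then forced strictly increasing, so a corrected mRead
  is always a valid sketch.

## Known limitations

* The minimizer-space consensus cannot fix errors that corrupt *every*
  supporter at the same locus, and reads with fewer than two similar
  neighbours are returned uncorrected (flagged in the report).
* Base-space reconstruction spans first-to-last consensus minimizer;
  flanks outside the sketch are not reconstructed.
* The chaining constants are a calibration, not a published value; they
  are exposed for tuning.
* Assembly of the corrected reads (the downstream minimizer-space de
  Bruijn graph) is out of scope for this package.
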