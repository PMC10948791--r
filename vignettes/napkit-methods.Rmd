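---
title: "Methods and design of the napkit boundary caller"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the napkit boundary caller}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(napkit)
```

## The measurement model

napkit analyses libraries in which specific adapters are ligated directly
to the intact 5' and 3' termini of noncapped RNAs (napRNAs) before
reverse transcription. Because ligation requires an accessible terminus,
a read that still carries the 5' adapter testifies that its first insert
base is a genuine transcript 5' end, and likewise for the 3' adapter.
Between each adapter and the insert sits a randomized 6-nt barcode (N6).
This converts full-length transcript identification into a counting
problem at single-nucleotide resolution: coverage tells where RNA is,
and adapter-verified end counts tell where it starts and stops.

Everything downstream follows from three per-position, per-strand
signals on each chromosome:

* `cov` — read coverage depth;
* `start5` — number of adapter-verified 5' ends at the position;
* `end3` — number of adapter-verified 3' ends.

All coordinates are 0-based half-open (BED convention) internally; the
biological 5' end of `[start, end)` is `start` on `+` and `end - 1` on
`-`. 1-based coordinates appear only in serialized output where a format
demands them.

## Adapter and barcode removal

`trim_reads()` locates each adapter with an edge-anchored semi-global
alignment: a 5' adapter must align as a read prefix (possibly entering
the read mid-adapter), a 3' adapter as a read suffix. Two scoring
choices matter and are deliberate:

* **Indels cost 2, substitutions 1.** With unit-cost indels, a
  substitution at the adapter's terminal base is exactly re-explainable
  as a single deletion, which silently shifts the cut point — and hence
  the 6-nt barcode frame — by one. Short-read errors are
  substitution-dominated, so indels are admitted but disfavoured. With
  this weighting, 10^4 simulated reads carrying up to two substitutions
  per adapter trim back to their exact inserts, flags and barcodes in
  the test suite; with unit costs a handful per 10^4 are cut one base
  off.
* **Hits are ranked by error rate (errors / matched adapter bases),**
  then by matched length. Ranking by raw error count would let a chance
  10-nt perfect match at a read edge outrank the true full-length
  adapter carrying two sequencing errors.

The minimum adapter overlap defaults to 10 nt. A permissive cutadapt-
style overlap of 3 would flag roughly 1 in 64 adapterless reads per end
by chance, polluting the boundary signal the whole method rests on; at
10 nt the chance rate is about 10^-6 per read end. Error rate (default
0.1), minimum retained insert (15 nt), and barcode length (6) are
exposed in `trim_config()`; the `tgs` preset switches to long-read
settings (error rate 0.3, minimum insert 20, at least one adapter
required). When fewer than 6 nt remain between a matched adapter and
the insert, that end is treated as adapterless rather than inventing a
truncated barcode.

Barcodes are preserved in the output so that barcode-based
deduplication can be added later; counting currently uses raw reads.

## The boundary caller

`call_naprnas()` proceeds per sample:

1. **Contigs.** Maximal runs of positions with `cov >= cov_floor`
   (default 1) are assembled per strand; each contig is one candidate
   search unit.
2. **Boundaries.** The candidate 5' boundary `p5` is the contig position
   maximising `start5` (ties resolve to the most-5' position on the
   feature strand), the 3' boundary `p3` maximises `end3` (ties most-3').
   A contig whose best 5' boundary falls downstream of its best 3'
   boundary is degenerate and yields no candidate.
3. **Six statistics.**
   * `startReadNum = start5[p5]`, `endReadNum = end3[p3]`.
   * `startFC = startReadNum / max(1, sum(start5 over p5 ± 100 nt,
     excluding p5))`, and symmetrically `endFC`. The sum-with-self-
     exclusion reading was chosen because comparing a peak against a
     window that includes the peak itself can never reach a fold change
     of 2 for dominant peaks; the floor of 1 read avoids division by
     zero in clean windows.
   * `up20ntFC = mean cov over the candidate / max(0.05, mean cov over
     the 20 nt upstream of p5)`, and symmetrically `down20ntFC`
     downstream of `p3`. Means rather than sums make the statistic
     independent of candidate length; the floor 0.05 equals one read
     spread over the 20-nt flank; flanks are clipped at chromosome ends
     and the mean renormalized to the clipped width.
4. **Thresholds.** A candidate passes if `startReadNum >= 7`,
   `endReadNum >= 7`, both boundary fold changes `>= 2`, both flank fold
   changes `>= 2` and `length >= 100` nt — all boundary-inclusive, all
   configurable.
5. **Cross-sample merging.** Passing candidates from different samples
   whose 5' and 3' boundaries each agree within `end_tolerance`
   (default 5 nt; 0 for exact) are merged by single linkage. Each
   sample's support is `min(startReadNum, endReadNum)` — a lower bound
   on molecules verified at both ends; a merged call is kept when
   supported by at least 2 samples with summed support of at least 20.
   The representative interval comes from the sample with the highest
   support. The merging tolerance and the per-sample support definition
   are the two places where the procedure is under-determined by its
   published description; both are parameters, and the defaults are
   argued here rather than inherited.

The test suite fuzzes this machinery: on 1000 random signal tracks,
every emitted candidate re-satisfies all thresholds when its statistics
are recomputed by an independent position-by-position routine, and the
four fold changes agree with brute force to machine precision.

## Cap-site calling

The complementary caller for cap-enriched libraries treats each
position with at least `min_count` (default 10) 5'-end reads as a
candidate and tests, per replicate: `upFC = endCov / max(upCov, 1) >= 2`
and `downFC >= 2` against the single nucleotides up/downstream
(strand-aware); and a one-sided binomial p-value below 0.05 for
`endCov` successes out of all 5'-end counts within ±100 nt at success
probability 1/201. The binomial local-uniform null is the simplest
model consistent with the fold-change criteria; the window and
pseudocount are parameters. A site must pass in at least two replicates
at the identical position (cap sites are TSS-like single-nucleotide
features) and lie inside an annotated mRNA 5'UTR.
`compare_cap_overlap()` then reports how many napRNA 5' starts coincide
with cap sites — the specificity control separating noncapped calls
from capped transcription starts.

## Classification rules

Labels are independent flags; one transcript may carry several. All
rules are same-strand.

* **sliRNA** — both biological ends match a known intron's splice sites
  within `end_tolerance` (default 0; excised introns that persist as
  stable linear RNAs retain their exact splice boundaries).
* **snotron** — one end coincides with an intronic snoRNA's end while
  the other lies within 10 nt (boundary-inclusive) of the host intron's
  opposite splice site; both orientations are recognised and recorded.
  The snoRNA must be contained in the matched intron.
* **misRNA** — the call intersects a pre-miRNA cluster (single-linkage,
  gap strictly below 10 kb, at least two members — a spacer needs two
  flanking genes) and is not wholly contained in any single pre-miRNA.
  End-coincidence with mature-miRNA ends (tolerance 3 nt) is recorded
  as evidence and optionally enforced.
* **Pol III** — a terminator run of ≥ 4 U within the last 6 nt, an
  A-box (`TRGCNNARYNNG`, ≤ 2 mismatches) starting in the 5' half, and a
  B-box (`GTTCRANNC`, ≤ 1 mismatch) downstream of it.
* **C/D box** — a C box (`RUGAUGA`, ≤ 1 mismatch) starting within 12 nt
  of the 5' end, an exact D box (`CUGA`) ending within 12 nt of the 3'
  end, and a terminal stem of ≥ 4 consecutive pairs (G·U allowed)
  between the regions outside the boxes.
* **H/ACA box** — an ACA box followed by at most 3 nt, an H box
  (`ANANNA`, ≤ 1 mismatch) in the middle third, and two predicted
  hairpins: the segments 5' and 3' of the H box (the 3' one ending at
  the ACA box) must each fold to ≥ 4 base pairs under the pluggable
  folder. A run of ≥ 6 unpaired A inside the 5' hairpin is annotated as
  a poly(A) pocket.

The motif consensi are the canonical literature elements, not values
printed by any single study; they, the mismatch budgets and the offsets
are all configurable, and the defaults should be read as a transparent,
replaceable stand-in for unpublished pipeline internals. On random
200-mers the Pol III detector agrees exactly with an exhaustive
consensus scan; like any short-motif rule, the detectors have a
non-zero chance hit rate on long random sequences, which is visible in
the simulation tests and should be kept in mind for genome-scale use.

A packaged hand-constructed world (`fixture_world()`: 12 introns, 6
snoRNAs, 2 pre-miRNA cluster groups, 30 candidates) pins the interval
rules down, including the exactly-10-nt snotron case and the
exactly-10-kb cluster split.

## Structure and probing evidence

`fold_pairmax()` is a Nussinov-style base-pair maximization over
Watson-Crick plus G·U pairs with hairpin loops ≥ 3 nt, written to be
*exactly* testable: for every sequence up to length 14 the DP equals
exhaustive enumeration over all nested structures. Its energy is the
negative pair count — a deliberate, self-contained proxy rather than a
thermodynamic model; any external folder with the same contract
(sequence, optional constraint string → dot-bracket + energy) can be
plugged into every function that takes a `folder` argument. The
traceback is deterministic (the 5'-most base pairs with its smallest
admissible partner), so outputs are reproducible byte for byte.

`z_score()` standardises the native folding energy against
`n_shuffles` (default 100) composition-preserving shuffles: order 1
permutes bases; order 2 is an Euler-path (Altschul–Erickson) shuffle
that conserves every dinucleotide count exactly, which matters because
stacking, and hence apparent stability, is dinucleotide-driven.
Negative z means more stable than expected from composition alone. The
score is invariant to affine rescaling of the energy function, so the
pair-count proxy and a kcal/mol folder yield comparable z scales. When
all shuffle energies coincide the score is degenerate and reported as
0 with a flag rather than NaN.

Chemical-probing evidence follows the mutational-profiling convention:
`mutation_rates()` piles up per-read mutation events; raw reactivity is
treated minus untreated rate, clipped at zero; positions under 100×
depth in either channel are masked (distinct from zero — no data is not
low reactivity); normalization divides by the mean of the 90th–98th
percentile band after excluding the top 2% (so the band mean is exactly
1 by construction). `reactivity_constraints()` turns normalized
reactivity ≥ 0.7 into hard forced-unpaired positions for the built-in
folder — a simplification of pseudo-energy SHAPE-directed folding,
chosen because the pair-count folder has no free-energy scale to
perturb; the exported SHAPE two-column file feeds external folders that
do.

## The simulator: what it does and does not emulate

`simulate_world()` builds a single random chromosome (default 100 kb,
GC 0.5) and implants truth napRNAs whose geometry satisfies the
corresponding class rule *by construction*: sliRNAs coincide with an
implanted intron; snotrons run from an intronic snoRNA end to 4 nt
inside the opposite splice site; misRNAs span the 200-nt spacer of a
two-member pre-miRNA cluster with mature-flush ends; Pol III / C-D /
H-ACA sequences carry their boxes, terminators and stems written into
the genome. `simulate_library()` then emits, per sample, full-length
reads per truth transcript whose ends carry adapters independently
with probability 0.5 — the retention level reported for well-made
boundary-ligation libraries — plus uniform background reads (0.2
reads/kb, 50–200 nt). The default depth is 30 reads per transcript per
sample, i.e. ~15 verified ends per boundary: an adequately sequenced
library relative to the ≥ 7 verified-end threshold. Optional geometric
end jitter models imperfect processing and is off by default.

Deliberate non-goals: sequencing-error models, expression-level
realism, fragmentation of long transcripts (reads are full-length
inserts; mapping is outside the package, so the simulator emits exact
alignment records alongside FASTQ), spliced alignments, and chimeric
artefacts. Consequently, passing the end-to-end tests demonstrates that
the statistics, thresholds and classifiers are implemented correctly
and recover implanted truth under controlled noise — not that the
caller is robust to the full messiness of real libraries.

## Problem sizes and determinism

The shipped tests run the caller fuzz at 1000 random 1.5-kb tracks, the
end-to-end recovery at 50 implanted transcripts (100–600 nt, 10
verified reads per end, 2 samples, no background — recovering 50/50
with exact boundaries and no false positives), the trimmer round-trip
at 10^4 constructed reads, the folding oracle at 200 sequences ≤ 14 nt,
and shuffle conservation at 10^4 dinucleotide shuffles; these sizes
keep the whole suite in the low minutes on one core while leaving no
statistic untested against an independent recomputation. Every
stochastic function takes a seed (`withr::with_seed` restores the
global RNG state), the pipeline derives all stage seeds from the single
config seed, and reruns with identical configuration are byte-identical.

## Known limitations

* The pair-count folder ignores stacking energies, dangles and
  temperature; z-scores from it are rank-useful but not comparable to
  published kcal/mol MFEs unless an external folder is plugged in.
* Motif-based families (Pol III, C/D, H/ACA) are rule-based stand-ins
  with appreciable false-positive rates on kb-scale sequences; they are
  evidence annotations, not definitive family assignments.
* The cap caller's binomial null assumes local uniformity of 5'-end
  noise within ±100 nt; promoter-shaped backgrounds will inflate
  significance.
* Counting ignores the N6 barcodes (no deduplication), matching the
  raw-read convention; PCR-duplicated libraries will overstate support.
* Multi-transcript contigs emit a single best candidate; overlapping
  or nested transcripts on one strand are not deconvolved.
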