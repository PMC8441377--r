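---
title: "Quantifying dual-guide CRISPR deletions from pooled amplicon sequencing"
author: "ampliconDel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dual-guide CRISPR deletions from pooled amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliconDel)
```

## Scope and model

A dual-guide CRISPR experiment pairs one upstream (US) and one downstream
(DS) sgRNA so that simultaneous Cas9 cuts excise the intervening interval —
typically a putative regulatory element such as an open-chromatin region
carrying candidate causal variants. The readout analysed here is pooled
amplicon sequencing: PCR across the target region followed by short single-end
reads primed a fixed distance (by default 50 bp) upstream of each cut site.
A read spanning an excision aligns to the wild-type amplicon as two collinear
pieces separated by a reference gap — a *spliced read* in the assay's
vocabulary. The pipeline estimates, per sequencing library, the fraction of
mapped reads attributable to each sgRNA pair (its *editing efficiency*),
summarises replicates, and reports the deletion spectrum (unique breakpoint
pairs with counts and per-pair breakpoint dispersion).

Everything is amplicon-local and 0-based half-open: a cut site is an
inter-base coordinate, a deletion is the interval `[start, end)`, and a pair's
expected deletion size is `dsCut - usCut`. The size arithmetic connecting a
deletion to its expected gel band is exact: a wild-type product of $W$ bp with
a $d$-bp deletion migrates as a $W - d$ bp product (`predictedProductSize()`).

## Cut-site convention

Guides may be configured directly by cut-site coordinate, or by protospacer:
`cutSiteFromProtospacer()` requires a unique occurrence of the protospacer on
either strand with an adjacent NGG PAM and places a blunt cut 3 bp 5′ of the
PAM on the protospacer strand — standard SpCas9 geometry. The blunt-cut
convention is a modelling choice (Cas9 occasionally leaves staggered ends);
any systematic offset it hides is absorbed by the simulator's breakpoint
jitter and by the 60-bp assignment window. When both a coordinate and a
protospacer are given, the coordinate wins and the protospacer is kept as
annotation. Only the NGG PAM is supported; PAM variants are out of scope.

## The split aligner

Each read is aligned on both strands under a two-part model: the best of

1. a single ungapped local alignment, and
2. every chain of two collinear ungapped segments separated by one reference
   gap of arbitrary size (the junction),

scored match +1 / mismatch −1, with the junction itself free. The optimum is
found exactly by dynamic programming in $O(nm)$ per read (a forward Kadane
pass for best segment ending at each cell, a running row maximum as chain
source, a reverse pass for best segment starting at each cell), so its score
provably equals a brute-force maximization over all (deletion start, length)
placements — the property the test suite checks against an independent
enumeration oracle on randomized planted instances. Score ties are broken
towards the smaller junction (so an equal-scoring contiguous alignment beats
a split one), then the leftmost junction start, then the + strand.

Two deliberate restrictions keep the model identical to the enumeration
space. First, segments are substitution-only: within-segment indels are not
modelled, and a read with a genuine sequencing indel loses score gradually
rather than being realigned around it. Second, a handful of bases inserted at
a deletion junction (a common end-joining outcome) is absorbed into the
flanking segments as mismatches rather than reported separately; with the
default filters this costs at most a few percent identity and does not change
classification. Free-junction chaining means two chance micro-matches could
pair across a long gap, which is why classification (below) additionally
requires a minimum flank on both sides of a junction.

Reads are classified as:

* **spliced** — junction strictly larger than `minJunction` (default 2 bp,
  so 3 bp and up qualify), aligned fraction of the read strictly above
  `minAlignedRatio` (default 0.95), identity within segments at least
  `minIdentity` (default 0.95), and both segments at least `minFlank`
  (default 20 bp);
* **wt_mapped** — ratio and identity pass but no qualifying junction;
* **unmapped** — everything else.

The junction and ratio thresholds with their strict comparisons are the
assay's published extraction rule; the identity floor and the per-segment
flank minimum are safeguards this implementation adds (a genome-scale mapper
imposes both implicitly) — without them uniform-random reads occasionally
chain two short perfect matches across a free gap. All four are parameters of
`filterParams()`, as is the choice of whether the ratio filter measures
placed bases (default) or matching bases — the upstream tooling's definition
of "alignment ratio" is ambiguous between the two, so both are computed and
either can drive the filter.

## Pair assignment and efficiency

A spliced read's breakpoints `(start, end)` are compared with every pair's
cut sites. Candidates are pairs with *both* `|start - usCut|` and
`|end - dsCut|` within the assignment window (default 60 bp); requiring both
ends prevents a large deletion from being credited to a nested pair that
matches on one side only (a one-sided mode exists behind the `bothEnds`
flag). Among several candidates the smallest summed distance wins; an exact
tie is reported as `ambiguous` rather than split fractionally — conservative
and reproducible. Efficiency divides each pair's assigned count by total
mapped reads (wild-type + spliced), one shared denominator per library;
ambiguous and unassigned spliced reads stay in the spliced total but credit
no pair. 95% Wilson score intervals accompany the point estimates — the
upstream assay reports none, but they make simulation-based testing and
replicate comparison honest.

One subtlety: per-pair counts are *not* monotone in the window width.
Widening the window can admit a closer candidate that takes reads from the
pair they were previously assigned to under the nearest-pair rule. The total
assigned count is monotone non-decreasing and the unassigned pool monotone
non-increasing, and those are the invariants the tests assert. Similarly,
when cut sites of different guides lie within a window width of each other,
a jittered breakpoint can legitimately be nearest to the wrong guide; with
the default 5-bp jitter and 20-bp guide spacing of the demo design this
affects roughly 2% of reads, visible in the worked example as small counts
on neighbouring pairs.

Replicate aggregation is the arithmetic mean and sample standard deviation
of per-pair efficiencies across libraries; a pair absent from a library
counts as 0 there (with a warning), and a single library reports sd 0 with a
warning rather than NA, so downstream tables stay numeric.

## The simulator and what it does (not) emulate

`simulateLibrary()` draws each read's class from the configured mixture
(wild-type, one of the pairs, or unmappable garbage) multinomially, so class
counts fluctuate binomially around their expectations — matching how a real
library samples molecules. For a deletion read the excised interval is the
pair's inter-cut interval plus independent, symmetric, integer-rounded
Gaussian jitter (default sd 5 bp) per breakpoint, standing in for end
resection and processing; with probability `insertJunctionProb` (default
0.1) 1–5 random bases are inserted at the junction. Reads are windowed to
`readLength` (default 150 bp, single-end) starting `readAnchorOffset`
(default 50 bp) upstream of the pair's upstream cut site — wild-type reads
anchor at a randomly chosen pair's upstream cut, mimicking the pooled primer
design. Substitution errors are applied uniformly per base (default 0.003);
qualities are written as constant Q30. Garbage reads are i.i.d. uniform
ACGT. Everything is deterministic given the seed, which is embedded in every
read id.

Deliberately not modelled: quality-dependent or position-dependent error
profiles, PCR chimeras and primer carryover, microhomology-biased end
joining, paired-end reads, and coverage bias between pairs. Passing
recovery tests therefore show that the aligner, filters and assignment
arithmetic are correct under realistic noise — not that the pipeline is
robust to every artefact of a real MiSeq run; in particular, real breakpoint
distributions are more structured than Gaussian jitter.

## Expression statistics

The comparative-CT module is the pure Livak method: technical replicate rows
are averaged to one Cq per sample and gene, ΔCt subtracts the housekeeping
gene, ΔΔCt subtracts the mean ΔCt of the calibrator samples, and fold change
is $2^{-\Delta\Delta Ct}$ with amplification efficiency fixed at 2 (no
Pfaffl-style efficiency correction). Two normalisation schemes cover the two
ways such experiments are reported: one `global_calibrator` cell (e.g. the
control group under permissive growth) for all samples, or a
`condition_matched` calibrator per condition. The schemes are linked by an
exact identity — each condition-matched fold change equals the global fold
change divided by the geometric-mean control fold change of that condition —
which the tests verify to 1e-9, along with calibrator closure (mean fold
change of the calibrator cell is exactly 1).

`percentChange()` reports intensity differences on the percent scale with
decreases positive (matching how staining and band losses are described),
optionally dividing each replicate by a matched normaliser measure such as a
tubulin loading control; it is scale-invariant by construction.
`transductionEfficiency()` averages per-replicate marker/bright-field count
ratios rather than pooling counts, so replicates weigh equally.
`twoSampleT()` defaults to Welch's unequal-variance test (the safer choice
when only "t test" is specified), with the pooled-variance variant behind a
flag; constant identical inputs return t = 0, p = 1 rather than erroring.
No multiple-testing adjustment is applied by default, matching the pairwise
reporting style of such figure legends.

## Numerical and design choices

* **Ties and determinism.** All tie-breaks (junction size, junction
  position, strand, assignment distance) are fixed and documented; reruns of
  any seeded configuration are byte-identical, and the pipeline manifest
  records parameters and MD5 checksums of inputs and outputs so silent input
  changes are detectable.
* **Degenerate inputs.** Empty reads or references, libraries with zero
  mapped reads, missing housekeeping Cq values, zero control means and zero
  bright-field counts all raise immediate, specific errors rather than
  propagating NaN.
* **Validation problem sizes.** The test suite and acceptance script verify
  ground-truth recovery on 20 simulated libraries of 10,000 reads (pair
  fractions 0.1/0.3/0.6, jitter sd 5, error rate 0.003; each recovered
  fraction within 4 binomial sigma, mean absolute error < 0.01), aligner
  optimality against exhaustive enumeration on 200 randomized planted
  deletions (references 150–300 bp, reads 60–120 bp, deletions 3–150 bp),
  filter monotonicity on 1000 fuzzed alignments, and breakpoint-dispersion
  recovery on 2000-read libraries. These sizes give the statistical checks
  comfortable power while keeping a full validation run in the low minutes.

## Limitations

* One junction per read: multi-deletion alleles, inversions and duplications
  are outside the alignment model and will surface as reduced identity or
  unmapped reads.
* Amplicon-local only: no genome-wide mapping, no off-target accounting, and
  no allele-level phasing of variants inside the deleted interval.
* Efficiencies are read-level, not cell-level: PCR amplification bias
  between short deletion products and the long wild-type product is not
  corrected, so read fractions approximate molecular fractions only as far
  as the amplification is even — the usual caveat of pooled amplicon
  readouts.
* The simulator's noise model is intentionally simple (see above); use it to
  validate arithmetic, not to benchmark robustness to platform artefacts.
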