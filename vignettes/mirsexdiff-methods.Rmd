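---
title: "Quantifying miRNA sex differences in Four Core Genotypes designs: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying miRNA sex differences in Four Core Genotypes designs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Mature miRNAs are 18–24 nt sequences excised from longer hairpin
precursors. Quantifying them from small RNA-seq has three complications
that ordinary gene-level counting ignores:

* **Families.** Several genes can produce an *identical* mature
  sequence. A read cannot identify the gene, so `mirsexdiff` quantifies
  at the level of distinct mature sequences: identical matures are
  collapsed into one target named after the byte-order-first member
  gene, with all members recorded. Gene-level abundance for family
  members is simply not identifiable from sequencing and is not
  reported.
* **Precursors.** Reads can also arise from precursor regions outside
  the mature (loop, star, flanks). Including unmodified hairpin
  sequences in the reference would let every mature read hit twice —
  once on its mature target and once inside its hairpin. We therefore
  mask each precursor's own annotated matures to `N` before indexing,
  and define a precursor's count as reads mapping *exclusively* to
  precursor sequence. The mapper treats `N` as matching nothing, so a
  read overlapping two or more masked bases can never hit; overlapping
  exactly one costs the single allowed mismatch.
* **Nested pairs.** Occasionally two distinct mature sequences differ
  by exactly one terminal base. A read of the shorter length maps to
  both targets; a read of the longer maps only to the longer. Counting
  follows the subtraction rule: the shorter target receives the reads
  shared with the longer target (total on the long target minus reads
  unique to it), and the longer keeps its unique reads. Pair totals are
  conserved by construction, and a negative intermediate is treated as
  a hard accounting error. Containments with a length difference of two
  or more are only warned about — they are rare enough that the
  subtraction algebra has no agreed extension, and reads internal to
  both members become ambiguous instead.

The biological question sits on top of this machinery: in the Four Core
Genotypes (FCG) model, gonadal sex (testes vs. ovaries) and sex
chromosome complement (XX vs. XY) vary independently, so comparing
{XX-F, XY-F} against {XX-M, XY-M} isolates gonadal effects while
{XX-F, XX-M} against {XY-F, XY-M} isolates chromosomal ones, in each of
three physiological conditions (gonadally intact on chow diet,
gonadectomized on chow, gonadectomized on high-fat diet).

## Mapping

Reads are demultiplexed by exact barcode match (a one-mismatch barcode
is unassigned — with six-base indices, tolerating mismatches would
merge libraries at a rate comparable to the sequencing error rate),
adapter-clipped, filtered to 18–30 nt inclusive, and collapsed to
unique sequences with multiplicities.

The mapper implements the stated contract — every end-to-end placement
of the read inside a target at Hamming distance ≤ 1, no gaps — rather
than emulating any particular aligner's heuristics. It splits the read
into two halves; at most one mismatch means at least one half is exact,
so the read's first or last *k* bases (k = 9 = half the minimum read
length) occur verbatim in the target. Candidate placements come from an
exact k-mer index of all targets and are verified by full byte-wise
Hamming comparison with the `N`-never-matches rule. This is complete by
the pigeonhole argument; the test suite additionally checks exact
equivalence against a brute-force scan over every target and offset on
1000 random instances.

Adapter clipping truncates at the leftmost full adapter occurrence or at
a terminal exact match of an adapter prefix of ≥ 3 nt (the common
default minimum overlap). Untrimmed reads are kept and left to the
length filter, which removes full-length read-through; no quality
filtering is done beyond this, as base qualities carry no information
the 1-mismatch allowance does not already absorb at these read lengths.

## Counting rules

Per collapsed read, weighted by multiplicity:

1. if any 0-mismatch placement exists, 1-mismatch placements are
   dropped;
2. precursor placements are dropped when a mature placement remains;
3. one remaining target → counted there;
4. exactly the two members of a registered nested pair → counted toward
   the longer member and flagged shared (redistributed by the
   subtraction rule afterwards);
5. anything else is *ambiguous*: included in the per-library mapped
   total but assigned to no target. This is the conservative reading —
   fractional or random assignment would fabricate precision — and the
   ambiguous mass is reported so conservation
   (assigned + ambiguous + unmapped = filtered reads) is auditable in
   every library.

Reads counted via a 1-mismatch placement increment a separate mismatch
subcount (always ≤ the total), preserving the distinction between
perfect and rescued evidence in the output table.

CPM normalization divides by the per-library sum of *counted* miRNA
reads, not the raw read number: the denominator should measure the
miRNA sampling depth, and unmapped or ambiguous reads carry no miRNA
identity. The "highly expressed" set is CPM strictly greater than 100
in at least one library — strict, because the threshold is a floor on
evidence, and one library suffices because a miRNA expressed in only
one condition is still biologically real.

## Ratio statistics

Group ratios are computed on CPM (libraries differ in depth, so raw
counts are not comparable), as the log2 of the ratio of arithmetic
group means over the two libraries in each group. miRNAs with a zero
group mean get a 0.5-CPM pseudocount added to both means and are
flagged; the highly-expressed filter makes this rare, and adding to
both sides biases the ratio toward zero rather than inventing a
direction.

The sign-bias test is a two-sided exact binomial test of
positive-vs-negative ratio counts against 0.5, with exact zeros
excluded (they carry no directional evidence). Condition comparisons
use the two-sided unpaired Wilcoxon rank-sum test — exact for ≤ 20
untied observations per side, otherwise the normal approximation with
continuity correction and tie-corrected variance (midranks). Both
tests are reported two-sided; one-sided versions would presuppose the
direction under test. Histograms use half-open 0.5-wide bins spanning
[−4, 4] with extremes clamped into the terminal bins.

PCA treats libraries as observations and highly-expressed miRNAs as
features, transformed as log2(CPM + 1) and centered, without
unit-variance scaling: scaling would equalize the influence of miRNAs
whose variance is mostly counting noise with that of genuinely
regulated ones. The transform is configurable (`cpm`, `percent`)
because reasonable analysts differ here; component signs follow a
deterministic convention (largest-magnitude loading positive) so runs
are reproducible.

No per-miRNA differential testing is attempted: with one (pooled)
library per genotype × condition cell there is no within-group
replication, so only profile-level statements — sign bias,
distribution shifts, covariance structure — are supported. This is a
deliberate scope boundary, not an omission.

## The synthetic experiment

The generator exists so that every stage is testable against known
truth without any external download. It emulates, at roughly quarter
scale, a study of ~1800 targets:

* 300 mature gene records collapsing to 260 distinct sequences —
  20 families of 3 genes share one mature sequence; 7 nested pairs
  differ by one terminal base (3' extension); all other containments
  are rejected and re-drawn, so the planted registry is exactly the
  true one.
* Hairpins embed their matures between random flanks (18–28 nt; ~30%
  of hairpins carry both a -5p and a -3p arm). Precursor-exclusive
  reads are drawn from a fixed unmasked window at the start of the 3'
  flank, 1% of reads in total.
* Baseline expression is log-normal with σ = 2.5 on the log scale,
  shared across libraries. At 260 targets this reproduces the
  count-dominance of real adipose libraries: across realizations the
  top three miRNAs carry a median of nearly half the mature-mapped
  reads (with a wide spread, roughly a quarter to two-thirds), and
  about half the targets clear 100 CPM at the default depth. A smaller
  σ of 2.0 was tried first and leaves the top three around a quarter
  at the median, too egalitarian to exercise the abundance-dependent
  behaviour of the pooling correlation and the highly-expressed
  filter.
* Reads: insert + TruSeq small-RNA 3' adapter, truncated to 36 cycles,
  uniform substitution errors at 1% per base (applied to the whole
  read, adapter included: an adapter-region error defeats exact
  trimming and the read is lost at the length filter, just as with a
  real exact-overlap trimmer), flat qualities, library barcode. A 12%
  contaminant fraction (random 20–24-mers standing in for degradation
  fragments and other small RNA classes) brings the mapping rate to
  ~86%, inside the 80–90% band seen in practice. No indels are
  simulated, matching the ungapped mapper.
* Depth is 100,000 reads per library. Real small-RNA libraries run
  one to two orders of magnitude deeper; this scale keeps a full
  12-library experiment around a minute end-to-end while leaving
  median per-miRNA counts high enough (tens to hundreds) for the
  profile statistics to behave qualitatively like the deep-sequencing
  case. The consequence of scaling down is larger per-miRNA ratio
  noise, which the planted effect sizes must clear (below).

Planted effects are multiplicative in expression (hence additive in
log2 ratios): per condition, a log2 effect of a given size is applied
to a drawn fraction of miRNAs in the gonadally male libraries (sex
effect; negative = female-biased) and in the XY libraries (chromosome
effect); high-fat-diet libraries additionally get a ±1.5 log2 diet
effect with random per-miRNA sign on half the miRNAs, which creates the
dominant diet axis in PCA without biasing either sex contrast. The
default pattern is male bias when intact on chow (sex effect +1.0 on
60% of eligible miRNAs), slight female bias after gonadectomy (−0.4 on
60%), and combined male (+0.8) and XY (+0.8) biases under high-fat
diet.

Two details matter and are easy to get wrong:

* **CPM compensation.** Scaling a fraction *f* of miRNAs up in one
  group scales *every* miRNA's CPM down in that group by the changed
  total. If the affected set carries much of the expression weight,
  the unaffected majority acquires an opposite apparent bias and the
  planted direction inverts in the sign test. The generator therefore
  draws affected sets from miRNAs *outside the top decile* of baseline
  abundance: the dominant species stay sex-stable (which is also what
  stable overall tissue composition suggests biologically), the
  compensation term stays small, and the sign of the majority follows
  the planted direction.
* **Effect size vs. counting noise.** At this depth the log2-ratio
  noise for a 100-CPM miRNA is ± ~0.4. Effects of the magnitudes seen
  in deep real libraries (0.1–0.25 net median shifts) would be detectable only
  unreliably seed-to-seed, so the planted sizes are set a factor ~2
  larger; the recovered medians (≈ −0.4 / +0.12 / −0.3) accordingly
  overshoot a deep-sequencing study's while preserving every direction
  and ordering. This is a deliberate scaled-down calibration, stated
  here once; the recovery test requires all planted directions, the
  two hormone/diet distribution shifts and the diet-first PCA axis in
  ≥ 90% of 20 seeds.

What passing these tests shows — and what it does not: the pipeline's
bookkeeping is exact (at zero noise, every count equals truth through
collapsing, masking, priority assignment and nested subtraction), its
mapper is complete, and its statistics recover planted distributional
effects of realistic shape. It does not show that real libraries meet
the generator's assumptions (no indels, uniform errors, no ligation
bias, no within-group biological variance beyond the replicate
perturbation used in the pooling emulation), and recovered effect
sizes on real data would not be comparable to the planted ones.

## Numerical and degenerate-input choices

* Ties in the Wilcoxon test use midranks with tie-corrected variance;
  exact enumeration is only used when both sides are ≤ 20 and untied.
* `sample`-style length draws use explicit range vectors so degenerate
  configurations (e.g. fixed 22-nt matures) stay literal.
* A zero-count library is an error in CPM normalization (there is
  nothing to normalize), as is an empty highly-expressed set at the
  configured threshold; both fail loudly with the stage named rather
  than propagating NaNs.
* Collapsed-group naming uses byte order (C-locale radix sort) so
  reference builds are locale-independent.
* The pooled-library emulation draws each replicate's expression as the
  baseline perturbed by a log-normal factor (σ = 0.3) and the pooled
  library from the replicate mean at matched depth, so the
  individual-vs-pooled correlation approaches 1 for abundant miRNAs
  minus multinomial sampling noise — and degrades for rare ones, as
  observed.

## Limitations

* No gapped alignment, no >1 mismatch, no novel-miRNA discovery, no
  isomiR resolution beyond the 1-nt nested-pair rule.
* Gene-level quantification inside shared families is out of reach by
  design; member lists are reported instead.
* The whole-profile statistics assume miRNAs are exchangeable
  contributors to a distribution; correlated miRNA clusters (e.g. a
  polycistronic family responding as one unit) violate independence
  and make the binomial p-values anti-conservative. With pooled
  single libraries per cell this is unresolvable; treat the p-values
  as descriptive.
* The generator's contaminants are uniform random sequences; real
  unmapped fractions are structured (rRNA/tRNA fragments), which can
  collide with targets in ways random sequence does not. At the
  1-mismatch radius and these lengths the collision probability is
  negligible, but it is a simulation simplification.
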