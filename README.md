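# mirsexdiff

Small RNA-seq quantification and sex-difference profiling for Four Core
Genotypes (FCG) experiments.

Adipose tissue miRNA expression differs between the sexes, and the FCG
mouse model makes it possible to ask *why*: by decoupling gonadal sex
(testes vs. ovaries, via the *Sry* transgene) from the sex chromosome
complement (XX vs. XY), it separates hormonal from genetic contributions.
`mirsexdiff` implements the complete computational path for such a study:

1. **Reference preparation** — mature and hairpin miRBase-style FASTA
   files are collapsed so that each *distinct mature sequence* is one
   quantification target (several genes can produce an identical mature
   miRNA; reads cannot tell them apart), every precursor has its own
   mature sequences masked to `N` so that precursor counts mean
   "precursor-exclusive reads", and *nested pairs* — two matures
   differing by one terminal base — are registered for special counting.
2. **Read processing** — demultiplexing by exact barcode match, 3'
   adapter clipping, an 18–30 nt length filter, collapsing of identical
   reads, and ungapped mapping with at most one mismatch (pigeonhole
   seeding over the two read halves guarantees every ≤1-mismatch
   placement is found; a masked `N` base never matches).
3. **Counting** — priority rules: perfect matches beat 1-mismatch
   matches; mature hits beat precursor hits; reads hitting exactly a
   nested pair are resolved by the subtraction rule
   `count(short) = total(long) − unique(long)`; everything else
   ambiguous and excluded. Counts are normalized to counts per million
   (CPM) over mapped miRNA reads.
4. **Sex-difference statistics** over the *highly expressed* set
   (CPM > 100 in ≥ 1 library): per-condition female/male and XX/XY log2
   ratio profiles, where the female value of a miRNA is the mean of the
   XX-F and XY-F libraries' CPM (male, XX, XY analogous),

   `r_i = log2( mean(CPM_i, F libraries) / mean(CPM_i, M libraries) )`,

   the exact binomial *sign-bias test* of #positive vs. #negative ratios
   against 50:50, Wilcoxon rank-sum comparisons of ratio distributions
   between conditions (intact vs. gonadectomized, chow vs. high fat
   diet), 0.5-wide binned histograms on [−4, 4], and library-level PCA
   of log2(CPM+1).
5. **Synthetic data** — a seeded generator that emulates the full
   2 (gonadal sex) × 2 (chromosome complement) × 3 (intact-chow,
   GDX-chow, GDX-HFD) design with known ground truth: shared-sequence
   gene families, masked hairpins, 1-nt nested pairs, heavy-tailed
   baseline expression, multiplicative planted effects, adapter- and
   error-bearing reads, and a contaminant fraction producing realistic
   80–90% mapping rates.

## Worked example

```r
library(mirsexdiff)

cfg <- simulation_config(seed = 1)          # the default study conditions
exp <- generate_fcg_experiment(cfg, seed = 1)
q   <- quantify_experiment(exp)             # trim, filter, map, count, CPM
st  <- sex_difference_stats(q$abundance, exp$design)

mean(q$per_library$mapping_rate)            # 0.863
length(st$highly_expressed)                 # 258
st$medians[["F_vs_M.intact_chow"]]          # -0.417
st$sign_tests[["F_vs_M.intact_chow"]]$majority_group  # "M"
st$sign_tests[["F_vs_M.intact_chow"]]$p_value          # 4.76e-05
st$condition_tests[["F_vs_M.intact_chow vs F_vs_M.GDX_chow"]]  # 3.3e-14
100 * st$pca$variance_fraction[1]           # 49.6
```

Reading: 86.3% of reads map to the reference; 258 miRNAs exceed 100 CPM;
in gonadally intact chow-fed animals the female/male ratio distribution
has median −0.42 and is significantly male-biased (exact binomial
p = 4.8 × 10⁻⁵); gonadectomy shifts the distribution (Wilcoxon
p = 3.3 × 10⁻¹⁴) to a slight female bias; and diet dominates library
covariance (PC1 = 49.6%). These match the planted effect directions in
`exp$planted_directions`.

The same flow as a narrative analysis lives under `analysis/`
(`01_simulate_experiment.R` → `04_pca_and_pooling.R`); each script
prints what it found and writes compact tables under `results/`. The
file-based equivalent of `quantify_experiment()` is `run_pipeline()`
with a `pipeline_config()` (or a YAML file via
`load_pipeline_config()`), which also writes a provenance manifest.

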