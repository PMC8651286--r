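---
title: "Measuring immune cell type-specific cfDNA: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring immune cell type-specific cfDNA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Dying cells release nucleosome-sized fragments of cell-free DNA (cfDNA) into
plasma. Because DNA methylation marks cell identity stably, a CpG site that
is unmethylated only in one immune cell type acts as a barcode: the fraction
of plasma molecules that are fully unmethylated at that site measures the
contribution of that cell type to the cfDNA pool, and hence its turnover —
including death occurring in tissues that peripheral blood counts never see.

`immunecfdna` implements the complete desk-side half of such an assay:

1. **Marker discovery** (`find_candidate_cpgs`, `density_filter`,
   `select_top_k`) from a 450K-style methylation atlas (rows = CpGs,
   columns = tissues and sorted cell types).
2. **Panel representation** (`amplicon_panel`) of short (≤ 160 bp, the size
   of a cfDNA nucleosome fragment) bisulfite amplicons and their CpG
   structure.
3. **Read interpretation** (`tally_sample`): assignment of bisulfite
   amplicon reads to markers, CG/TG methylation calls, conversion QC, and
   the per-marker fraction of fully unmethylated molecules.
4. **Quantification** (`quantify_sample`): calibrated cell-type fractions
   and genome equivalents (GE) per ml of plasma.
5. **Spike-in calibration** (`fit_recovery`, `derive_coefficients`).
6. **Cohort statistics** (`intra_cv`, `inter_cv_balanced`,
   `fold_change_from_baseline`, `classify_responders`, `roc_auc`,
   `group_compare`, `cfdna_count_ratio`).
7. **Synthetic data** (`simulate_atlas`, `simulate_reads`,
   `simulate_cohort`) so that every stage is testable without any external
   download.

# Marker discovery

A CpG qualifies as a marker for a target cell type when

* its mean beta over the target columns is **< 0.3** (`beta_target_max`),
* **more than 90%** of the non-target columns have beta **> 0.8**
  (`beta_other_min`, `other_pass_fraction`; both inequalities strict), and
* its 150 bp window (centred on the candidate and including it) contains at
  least **6** atlas CpGs ("more than five"), so that a single amplicon can
  read a co-methylated block.

The top 10 CpGs per cell type are kept. The ranking statistic is not fixed
by the assay's description, so we made a documented choice: rank by
`margin` = (mean beta of non-target columns) − (target beta), descending,
with ties broken by the fraction of non-target columns above 0.8 and then
by genomic coordinate. This maximises beta separation and is deterministic.
Two further documented choices: the 90% criterion counts atlas *columns*
(not collapsed tissues), and the 150 bp window is anchored at the candidate
(the anchor is not defined by the assay description).

Missing betas are dropped from means and denominators; CpGs missing in more
than 20% of columns are excluded (`max_missing_fraction`, configurable).

# Read interpretation

Each amplicon's reference is bisulfite-converted in silico: non-CpG
cytosines become `T`, CpG cytosines become the wildcard `Y` (matches `C` or
`T`), so identity is methylation-agnostic. Reads are compared ungapped at
every sliding offset, in both orientations; amplicons are primer-defined so
indels are rare and gapped alignment is deliberately out of scope. Identity
is `matches / aligned reference length`; a read is assigned to the best
marker when identity ≥ **80%** and the best marker is unique (equal-best
matches are rejected as ambiguous).

Calls follow the bisulfite rule: `CG` read = methylated, `TG` =
unmethylated, any other dinucleotide = ambiguous, CpG outside the read =
absent. Filters, in order: mean Phred < 30 (`low_quality`; the quality
threshold is not published, 30 is a common amplicon default), identity
(`low_identity` / `ambiguous_assignment`), any expected CpG unreadable or
more than one ambiguous call (`missing_cpgs`), and bisulfite conversion —
measured as the fraction of covered non-CpG cytosines reading `T` — below
0.95 when defined (`poor_conversion`; threshold also a documented default).
Every read lands in exactly one category, which the tests assert as a
conservation law.

A molecule counts as **fully unmethylated** when every CpG reads `TG`
(`strict`), or with at most one deviating CpG for markers configured
`allow_one_exception` (optionally restricted to listed exempt CpGs) — some
markers are more sensitive under that rule. Ambiguous calls never count
toward the unmethylated class.

# Quantification

Per cell type, the 2–3 marker fractions are combined by unweighted mean
(read-weighted pooling available by configuration); the combiner is not
fixed by the assay description. The corrected fraction is `raw /
coefficient`, with the published neutrophil coefficient **0.69** as default
and 1.0 elsewhere (other coefficients are not published, so none are
guessed). Absolute levels use the genome-equivalent constant: a haploid
genome weighs ~3.3 pg, so 1 ng contains ~**303** genomes:

`GE/ml = corrected fraction × cfDNA (ng/ml) × 303`

The printed constant 303 (not 1000/3.3) is stored once (`ge_per_ng()`) and
used everywhere. Fractions of different cell types are independent assays;
no renormalisation across cell types is ever applied, and corrected
fractions above 1 are kept but flagged.

# Spike-in calibration and the attenuation model

Mixing leukocyte DNA into an immune-null background (e.g. HEK-293) at known
proportions gives expected fractions `leukocyte fraction × composition`.
Ordinary least squares of observed on expected yields a per-cell-type
slope; `derive_coefficients` uses the slope as the calibration divisor and
reports the intercept only as QC (subtracting it could produce negative
fractions, and the published calibration is a single divisor).

Why are slopes below 1? A molecule is only counted when *every* CpG reads
`TG`. With conversion failure rate $1-c$ and per-base error $e$, the
probability that one CpG of an unmethylated molecule reads `TG` is roughly
$c(1-e)^2$, so an $n$-CpG strict marker recovers only $\approx (c(1-e)^2)^n$
of its molecules (~0.89–0.93 for $c = 0.99$, $e = 0.003$, $n = 4$–8). This
is the same mechanism that makes the real assay's neutrophil slope 0.69
rather than 1, and it is exactly what the spike-in calibration corrects.
The acceptance tests compare fitted slopes against this closed-form truth,
and the end-to-end recovery test quantifies mixtures *after* applying
spike-in-derived coefficients — the method's own workflow — which makes the
estimator unbiased at the 3-binomial-SD tolerance.

# Cohort statistics

* **CV**: sample SD (n−1) over mean; undefined at mean 0.
* **Intra-individual CV**: per donor across timepoints, averaged over
  donors. **Inter-individual CV**: across donors per timepoint. To compare
  the two without a sample-size bias (6 timepoints vs 15 donors), the
  inter CV is computed on every six-donor subset — per timepoint, then
  averaged across timepoints, then averaged over all `C(15,6) = 5005`
  subsets. Enumeration is exact up to 10^6 subsets, with seeded sampling of
  10^5 subsets beyond that. Whether the original procedure averaged per
  timepoint or on time-averaged donor values is not stated; per-timepoint
  is the default with `time_averaged = TRUE` as the alternative.
* **Fold change from baseline**: value divided by the donor's D0 value;
  donors with zero/missing baseline are excluded, not pseudo-counted
  (pseudo-counts would distort low-signal analytes such as Tregs).
* **Responder classification**: HI titers are reciprocal dilutions with the
  conventional 1:40 positivity cut-off. Strains with baseline titer < 40
  are eligible; donors with no eligible strain are excluded; a responder
  seroconverts (post titer **strictly > 40**) on ≥ 1 eligible strain. A
  post titer of exactly 40 is therefore a non-response; the boundary is
  ambiguous in the source and documented here.
* **ROC**: empirical curve with rank-convention tie handling, so AUC equals
  the Mann-Whitney `U/(n1·n2)` identity (asserted by test).
* **Group tests**: two-tailed Mann-Whitney, Kruskal-Wallis, Pearson —
  delegated to R's standard routines, whose exact small-sample p-values the
  tests verify against full enumeration.
* **Outliers**: the proprietary ROUT procedure is out of scope; a
  transparent median ± 5·MAD flagger (`mad_outliers`) is provided and off
  by default.

# What the synthetic data emulates — and what it does not

`simulate_atlas` plants hypomethylated marker CpGs (beta < 0.15 in one cell
type, 0.9–1.0 elsewhere) inside dense clusters whose satellite CpGs
(beta 0.5 in the target) satisfy the density filter without themselves
qualifying, on a methylated background (0.85–1.0). `simulate_reads` draws
each molecule's source from the mixture, applies the default pattern (a
cell type is fully unmethylated at its own markers and methylated
elsewhere), then bisulfite conversion (99% default), inappropriate
conversion of methylated CpGs (0.2%), substitution errors (0.3%, with
quality downgrades at error sites; base quality Q37), and optional
reverse-complement orientation.

`simulate_cohort` embodies the turnover model: cfDNA release is
proportional to (cell number / lifespan). Blood counts have per-donor set
points (donor-level lognormal, sdlog 0.30) with small within-donor noise
(sdlog 0.08) — so counts show intra < inter individual variation — while
cfDNA carries large population-level lognormal noise (sdlog 0.80) with no
donor set point beyond the count link, so its intra- and inter-individual
CVs coincide. These dispersions were fixed once: sdlog 0.80 makes the
simulated healthy neutrophil range bracket the published 10–1064 GE/ml at
the published mean of 390. Scenario effects use published group means
(vaccination B-cell cfDNA rise at day 3, peak at day 7, return by day 28,
larger in responders, counts moving only from day 7; EoE eosinophil cfDNA
115 vs 34/36 GE/ml with unchanged counts; lymphoma B-cell cfDNA 264.4 vs
18.3 GE/ml with counts 0.079 vs 0.162 × 10^9/l).

Not emulated: fragmentomics, PCR duplicates and primer artifacts, index
hopping, gapped sequencing errors, age/sex structure, and within-donor
autocorrelation beyond the set-point model. A green test therefore
establishes correctness of the computational pipeline under the stated
statistical model, not the wet-lab performance of the assay.

# Numerical choices and degenerate inputs

* Identity ties across markers reject the read (ambiguous) rather than
  picking arbitrarily; offset ties keep the first (leftmost) offset and
  forward orientation, deterministically.
* Conversion rate is undefined (NA) for amplicons without non-CpG
  cytosines; such reads pass the conversion filter by default.
* Markers with zero retained reads have undefined fractions and are
  flagged; aggregation skips them and flags the cell type when all its
  markers are missing.
* `fit_recovery` refuses degenerate designs (all expected equal); r² is
  computed directly so perfect fits do not warn.
* The subset-enumeration cap (10^6) keeps the balanced CV exact for every
  design the method targets; sampling beyond the cap is seeded.
* All generators are pure functions of (parameters, seed); the orientation
  randomisation draws are made unconditionally so the simulated molecules
  are identical for any `frac_reverse` under the same seed.

# Known limitations

* Ungapped matching slightly underestimates identity for reads with true
  indels; such reads fall into `low_identity` rather than being rescued.
* Only the neutrophil calibration coefficient is published; other cell
  types default to 1.0, so their absolute GE/ml underestimate truth by the
  attenuation factor unless a spike-in calibration is run.
* The balanced inter-CV treats timepoints as exchangeable; secular trends
  within the sampling window would inflate it.
* The cohort simulator's effect sizes are group means, not full
  distributions; it is a test harness and a teaching tool, not a power
  calculator.
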