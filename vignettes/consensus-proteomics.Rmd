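---
title: "Consensus differential expression with left-censored multiple imputation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential expression with left-censored multiple imputation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proteoconsensus)
```

## The problem

Label-free proteomics of xenograft tumors yields a protein x sample
intensity matrix in which a zero means "not detected". Because
low-abundance proteins preferentially fall below the detection limit, these
zeros are missing-not-at-random (left-censored), and any test that treats
them as ordinary data — or ignores the information they carry — can be
badly miscalibrated. The design analyzed here is a 2 x 2 layout: tumors
treated with a non-targeting siRNA (si-NT) or a human-VDAC1-silencing
siRNA (si-hVDAC1), each for a short or a long period, nominally in
triplicate. Because the tumors grow in mice, the quantified proteome is a
mixture of human (tumor) and mouse (microenvironment) proteins; the two
species are analyzed separately after an annotation-based partition.

## The analysis model

After ingest (all-zero rows dropped), the organism/unique-peptide inclusion
filter and `log2` transformation (no pseudocount: zeros become explicit
missing values), the pipeline builds **six analysis datasets**:

* **Dataset 1** neglects missing values: each per-protein test uses only
  observed measurements.
* **Datasets 2–6** impute every missing cell of sample column $s$ with an
  independent draw from
  $\mathcal N(\mu_s - d\,\sigma_s,\ (w\,\sigma_s)^2)$, where $\mu_s$ and
  $\sigma_s$ are the observed mean and standard deviation of that column
  and the defaults are the Perseus left-censoring defaults $d = 1.8$,
  $w = 0.3$. Five independently seeded repetitions avoid relying on any
  one set of fabricated numbers.

On each dataset, each protein gets a one-way ANOVA over the four groups
with two planned contrasts (si-hVDAC1 vs. si-NT within each duration). The
contrast uses the pooled mean-square error across all groups contributing
at least two observations:

$$t = \frac{\bar y_A - \bar y_B}{\sqrt{\mathrm{MSE}\,(1/n_A + 1/n_B)}},
\qquad \mathrm{df} = N_{\mathrm{obs}} - g_{\mathrm{obs}},$$

two-sided p from Student's t. Pooling across all four groups (rather than
a Welch two-group test) is the standard reading of a planned contrast
inside a one-way ANOVA and buys residual degrees of freedom, which matters
once the long-term groups are reduced to duplicates. A `mse_scope` switch
is deliberately not offered: restricting the pool to the contrast pair is
expressible by subsetting the sample sheet.

The signed linear fold change is $2^\Delta$ for $\Delta \ge 0$ and
$-2^{-\Delta}$ otherwise, so $|FC| \ge 1$ and a 2-fold decrease reads
$-2$.

**Consensus rule.** A (protein, contrast) *passes* a dataset when
$p < 0.05$ and $|FC| > 1.5$ — both strict, matching the usual phrasing
"p-value < 0.05", "fold change higher than 1.5"; boundary values do not
pass. The protein is called differentially expressed when it passes
dataset 1, or passes more than 3 (i.e. at least 4) of the 5 imputed
datasets. An unevaluable dataset-1 result (a contrast group with fewer
than two observed values, or no residual df) counts as not passing rather
than propagating an error.

Three aggregation conventions the consensus needs but the rule itself does
not fix:

* **Sign coherence.** Imputed votes count toward the consensus only if at
  least 4 agree in sign; a protein whose passing datasets disagree on
  direction is not called (and logged). This prevents direction-incoherent
  "DE" calls that a pure count would admit.
* **Direction** is the sign of the median $\Delta$ across passing
  datasets.
* **Representative statistics** are medians across the imputed datasets
  (robust, and independent of which single imputation one inspects), with
  the dataset-1 values reported alongside whenever defined.

No multiple-testing correction is applied to the per-protein p-values —
the calling rule is deliberately defined on nominal p-values, with the
fold-change filter and the imputation vote supplying the guard against
noise. BH-FDR is applied only in gene-set enrichment.

## Quality control and sample exclusion

QC computes per-sample distribution summaries, a sample dendrogram
(Pearson dissimilarity, complete linkage) and PCA scores. PCA uses only
protein rows observed in every sample, centered per protein and unscaled,
so that QC never depends on the imputation whose inputs it gates.

Outlier flagging codifies what is usually a visual judgment: a sample is
flagged when its Euclidean distance from its group centroid in the
PC1–PC2 plane exceeds median + $k$·MAD of the within-group distances
pooled over groups of at least three samples. Two choices here were made
after explicit calibration on the design geometry (four triplicate groups,
12 pooled distances), and they matter:

* the **centroid is the componentwise median**. With a mean centroid, a
  single aberrant replicate drags the centroid toward itself: at shift
  $s$ it sits only $2s/3$ from the contaminated centroid while pushing its
  two groupmates to $s/3$, and the pooled threshold then always exceeds
  $2s/3$ — the rule can never flag the very sample it exists to catch,
  at any shift. The median centroid stays with the healthy pair and
  restores detection.
* the **default multiplier is $k = 5$**. The pooled MAD of 12 skewed
  distances underestimates their extreme tail; at $k = 3$ homogeneous
  data trip a flag in roughly a fifth of runs, while $k = 5$ keeps the
  family false-flag rate under 5% and still recovers a strongly shifted
  replicate pair essentially always (both measured on 3,000 geometry
  simulations).

Flags are advisory. Exclusion happens only through
`apply_exclusions()` — either by explicit sample ids or via
`auto_exclude = TRUE` in unattended runs — and each design group must
retain at least two samples, the minimum for the ANOVA contracts. Dropping
the degraded long-term replicate pair leaves duplicate long-term and
triplicate short-term samples, the configuration whose residual df
($10 - 4 = 6$) the tests pin down. No between-sample normalization is
applied by default; the intensity tables this pipeline targets arrive
already processed, and silently renormalizing them would change the very
quantity the fold changes report.

## The synthetic-data generator

`simulate_experiment()` emulates the statistical structure the analysis
assumes, not the mass spectrometer: per-protein baselines
$\mathcal N(25,\ 2.5^2)$ on the log2 scale, replicate noise sd 0.5 (a
typical label-free replicate spread), 1,845 human plus 400 mouse proteins,
a 10% DE fraction with |log2 effects| uniform in [1, 3] applied to the
si-hVDAC1 group of the affected duration(s), and Poisson(3) unique-peptide
counts so a realistic ~5% of proteins fail the inclusion filter.
Missingness is generated *mechanistically*: each cell is censored with
probability $\mathrm{logit}^{-1}(\kappa(m - x))$ (midpoint $m = 22$,
steepness $\kappa = 1$, giving roughly a fifth of cells missing,
concentrated in the low-intensity tail). The censoring model is
intentionally different from the down-shifted-normal family the imputation
assumes, so the imputation stage is validated against a mechanism it does
not presume. Replicate 1 of each long-term group receives a global
−3 log2 shift, emulating a degraded sample pair for the QC path to find;
the magnitude was chosen once as "clearly pathological but not absurd"
(an 8-fold global signal loss).

What the generator does **not** emulate — and what passing tests therefore
do not certify about real data: peptide-to-protein rollup and shared
peptides, between-sample normalization artifacts, correlated effects across
proteins (each protein is independent), heavy-tailed or
intensity-dependent replicate noise, and batch structure. Mouse proteins
are generated by the same model with an organism tag; peptide-level
homology between species is out of scope because the analysis operates on
a processed protein table that has already resolved it.

Gene-set fixtures (`simulate_gene_sets()`) plant enrichment by weighted
sampling: inside an enriched term, truly-DE genes carry a configurable
odds multiplier (default 8). The planted terms are recorded so recovery
can be scored.

## Numerical and interface choices

* Standard deviations use the $n-1$ denominator throughout, including the
  per-column $\sigma_s$ of the imputation.
* Imputed draws are not truncated at zero or at the observed minimum: the
  defining distribution is exactly the stated normal.
* Imputation moments are per sample column (the Perseus default); a
  whole-matrix scope is available as an option.
* Strict inequalities at every threshold (p, |FC|, q, term size); ties
  never pass.
* Zero pooled MSE with a nonzero contrast difference yields the boundary
  p = 0 with a logged message; with a zero difference, p = 1.
* Clustering sorts rows lexicographically by accession before
  agglomeration, making equal-height merges deterministic; zero-variance
  rows (no defined correlation) are excluded with a message.
* Enrichment tests one-sided over-representation against the
  quantified-protein background (the proteins surviving the ingest
  filter), not the genome: the DE list is drawn from what was quantified,
  and a genome background would manufacture enrichment from detectability
  alone. Terms are intersected with the background before testing.
* All randomness flows from explicit seeds. `run_pipeline()` derives the
  imputation base seed as `seed + 100`; the generator's censoring stage
  uses `seed + 1`. Identical configuration and seed give byte-identical
  output files, and every run writes a provenance sidecar with the
  configuration hash, derived seeds and package version.
* The per-organism unique-peptide rule is applied uniformly; whether the
  original mouse-protein analyses used the same inclusion rule as the
  human ones is not documented, so the filter takes the organism as a
  parameter and the analyst can diverge.

## Verification strategy and problem sizes

Every statistical operation is checked against an independent oracle:
the pooled contrast against `aov` + `emmeans` and a hand-computed
3/3/2/2 fixture; Fisher enrichment against exhaustive hypergeometric
enumeration on a 20-gene universe; BH against a from-the-definition
step-up implementation on 100 random vectors; complete linkage against a
naive $O(n^3)$ agglomeration on 12 rows; censoring against numerical
integration of the sigmoid-normal expectation on $10^5$ draws. Calibration
checks use 2,000-protein null simulations (type-I rate within three
binomial standard errors of 0.05; Kolmogorov–Smirnov uniformity below the
1% critical value), $10^4$ imputed cells for the moment laws, 500-protein
simulations across an effect grid for power monotonicity and consensus
recovery, and 20-seed batches for the QC flagging characteristics. These
sizes give Monte-Carlo standard errors well below the tolerances they are
tested against while keeping the full suite in the tens of seconds.

## Known limitations

* The consensus rule is a vote, not a pooled estimate; Rubin's rules are
  out of scope by design, and the reported representative FC/p are
  summary conventions, not inferentially pooled quantities.
* Dataset-1 results with duplicates-only groups rest on few degrees of
  freedom; the pooled MSE mitigates but does not remove this.
* No moderated-variance (empirical Bayes) shrinkage: the method is
  deliberately the classical ANOVA contrast the consensus rule was
  defined around.
* The QC flag threshold was calibrated for the 4 x 3 design geometry;
  markedly different designs may warrant re-examining `k_mad`.
* Enrichment treats gene sets as flat symbol lists (no ontology-graph
  propagation) and collapses proteins to unique gene symbols before
  testing.
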