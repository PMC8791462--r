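---
title: "Methods: screening endogenous retroviruses for shared T cell epitopes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening endogenous retroviruses for shared T cell epitopes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and rationale

Human endogenous retroviruses (HERVs) occupy a large fraction of the genome,
are epigenetically silenced in most normal tissue, and are aberrantly
re-expressed in many solid tumors. Because their proteins resemble viral
antigens, HERV-derived peptides presented on MHC class I are attractive
shared tumor antigens: the same epitope can recur across many proviral loci
and many patients. `hervscreen` implements a complete in-silico funnel from
a HERV count matrix to a ranked list of candidate 9-mer epitopes:

1. **Normalization** — counts per million (CPM), then `log2(CPM + 1)`.
2. **Differential expression** — a negative-binomial Wald test per cancer
   type, tumor versus matched peritumoral tissue.
3. **Cancer-associated HERVs (CAHs)** — overexpressed at least twofold in at
   least one cancer and never overexpressed in any peritumoral tissue.
4. **Cytotoxicity-associated HERVs (cyt-HERVs)** — CAHs associated by
   L1-penalized regression with a T cell *phenotype* signature (criterion A)
   and a cytolytic/IFN-γ *function* signature (criterion B), and not
   overexpressed by purified T or NK cells (criterion C): `A ∧ B ∧ ¬C`.
5. **Epitope screening** — six-frame translation, stop-to-stop ORFs of ≥ 10
   amino acids, homology filtering against retroviral Gag/Pol references,
   HLA-binding screening at a ≤ 0.5 percentile-rank cutoff, relocation of
   each strong binder across the HERV catalogue to count sharing, and exact
   self-match exclusion against the host proteome.
6. **Scoring** — the π value (log2 fold change × log10(1/p)) per HERV, its
   sum over all HERVs containing an epitope, expression-tercile survival
   stratification with a log-rank test, and correlation of expression with
   local methylation.

Every stage is driven by a seeded synthetic-data generator so the whole
pipeline is testable end to end without any external download.

## Differential expression model

Counts are modeled as negative binomial with `Var = μ + α μ²`. Library
effects are removed with median-of-ratios size factors (the geometric-mean
reference excludes features with a zero in any sample). The per-feature
dispersion is a pooled within-group method-of-moments estimate

```
α̂ = Σ_g (n_g − 1)(s²_g − m_g · mean(1/sf_g)) / Σ_g (n_g − 1) m_g² ,
```

floored at `1e-8`; the `mean(1/sf)` term corrects the Poisson part of the
variance of size-factor-scaled counts. The two-group log-link GLM is fit by
iteratively reweighted least squares, vectorized across features (linear
predictors are clamped to ±30 to avoid overflow; convergence tolerance
`1e-8`, at most 50 iterations). The group coefficient is tested with a Wald
z statistic, and p-values are Benjamini–Hochberg adjusted across features
with positive base mean; all-zero features are reported with `NA`
statistics and excluded from the BH denominator.

Reported fold changes are shrunk toward zero with an empirical-Bayes normal
prior: the prior variance is estimated as `mean(β̂²) − mean(se²)` (floored),
and the posterior mode under the normal approximation is
`β̂ · τ²/(τ² + se²)`. Shrinkage therefore never changes the sign of a
confident estimate and never increases magnitude; p-values always refer to
the unshrunken estimate. This is a deliberately transparent stand-in for
heavier GLM machinery: it reproduces the qualitative behavior (and, on
shared fixtures, correlates > 0.95 with an established NB Wald
implementation in the test suite) while remaining fast enough to power the
simulation studies below.

Under a pure null simulation the test holds its size (type-I error ≈ 0.05,
verified in the acceptance suite). When a sizeable minority of features is
truly differential in one direction, median-of-ratios normalization absorbs
most — but not all — of the compositional shift, leaving null fold changes
displaced by a few hundredths of a log2 unit. This mirrors the behavior of
standard count-based DE tools and is harmless for CAH annotation, which
thresholds at a full log2 unit.

## CAH annotation

The rule is exclusion-first: any HERV with shrunken `log2FC ≤ −1` (at the
default twofold threshold) and `padj < 0.05` in *any* cancer is removed;
the remaining HERVs with `log2FC ≥ +1` and `padj < 0.05` in at least one
cancer form the CAH set. The twofold criterion is described in the source
method without an explicit significance cutoff; we default to requiring
`padj < 0.05` alongside the fold change, and expose a pure fold-change mode
(`padj_threshold = NULL`) for the alternative reading. Both thresholds are
configurable. The operation is idempotent and independent of cancer-type
order.

## Immune association

**CYT score.** Geometric mean of two cytolytic effector genes per sample.
Both gene pairs in common use are supported — GZMB + PRF1 (the default) and
GZMA + PRF1 — because the literature defines the score both ways; the pair
is a parameter, and no claim is made about which is canonical.

**IFN-γ signature.** A single-sample rank-based enrichment score: genes are
ordered by decreasing expression (ties stably by input order), the in-set
cumulative distribution is weighted by `rank^0.25` (exponent configurable),
the out-of-set distribution is uniform, and the score is the sum of the
running difference. A set equal to the whole gene universe scores 0 by
convention.

**Penalized regression.** For each cancer type, each signature is regressed
on the tumor-sample `log2(CPM + 1)` matrix of the CAH set under an L1
penalty, `(1/2n)·deviance + λ‖β‖₁`. Predictors are *not* standardized
(log2-CPM units are already comparable). λ is chosen by 10-fold
cross-validation minimizing mean squared error (gaussian: CYT, IFN-γ) or
mean deviance (poisson: cell-type phenotype scores, applied to continuous
nonnegative values without rounding — mirroring the upstream choice, not
questioning it). Fold assignment is a seeded random permutation, and the
seed is recorded in the output. Fitting is delegated to coordinate descent
in `glmnet`; single-predictor designs are padded with a dummy column that
carries an infinite penalty factor. A HERV is *associated* when its
coefficient at the selected λ is strictly positive. Restricting the design
matrix to CAHs (rather than all HERVs) reflects that only CAHs are eligible
downstream; it also keeps cross-validation cheap.

**Criterion C.** Mean log2-CPM in sorted T cells (and, independently, NK
cells) is compared with the mean over the remaining sorted PBMC samples; a
HERV is flagged when either difference reaches `log2(2)`. The boundary is
inclusive, and the threshold defaults to the same twofold used for CAHs
(the source method states no explicit value). Final call:
`cyt = A ∧ B ∧ ¬C`, invariant to the order of cancers and signatures.

## Epitope screening

**ORFs.** All six frames are translated with the standard genetic code;
codons containing `N` become `X` and never terminate an ORF. ORFs are
stop-to-stop runs without a start-codon requirement, with an *inclusive*
minimum length of 10 amino acids ("more than 10" being read as ≥ 10;
configurable). Coordinates are 0-based half-open on the forward strand;
negative frames are defined on the reverse complement read 5'→3'.

**Homology filter.** Each ORF is aligned to every kept reference protein
(default: names matching `Gag|Pol`) by exact Smith–Waterman with BLOSUM62
and affine gaps (open 11, extend 1) — on inputs of this size the seeded
heuristics of database search tools are unnecessary, so the optimal
alignment is computed directly. E-values follow Karlin–Altschul,
`E = K·m·n·e^(−λS)` with the gapped BLOSUM62 constants λ = 0.267,
K = 0.041, with `n` the summed length of the kept references. An ORF is
retained when its best hit reaches ≥ 90% identity (computed over all
aligned columns, counting gap columns as mismatches) and E ≤ 0.05. No
minimum alignment coverage is enforced — the upstream method does not state
one — so a short, highly conserved core can carry a longer ORF; this is
flagged rather than silently guessed.

**Binding.** Prediction is pluggable. The `table` predictor consumes
externally computed percentile ranks (e.g. from a neural MHC-binding
predictor run outside this package). The built-in `anchor` predictor is a
deliberately crude HLA-A\*02:01 stub — strong iff position 2 ∈ {L, M} and
the C-terminal residue ∈ {V, L, I} — documented as non-physiological and
intended only to exercise the funnel in tests and simulations. Strong
binders are those with percentile rank ≤ 0.5 (inclusive).

**Relocation and sharing.** Each strong binder is searched as an exact
substring over the six-frame ORF translations (minimum length relaxed to
the peptide length) of every HERV in scope; the sharing count is the number
of *distinct* HERV ids containing it. Whether the upstream method matched
ORF-level translations or raw frames is not stated; ORF-level containment
is implemented and documented. Counts are monotone as the scope widens from
cyt-HERVs through CAHs to the full catalogue. Ties in the ranked list break
lexicographically by peptide.

**Proteome exclusion.** An exact-substring scan against the host proteome;
matching peptides are flagged and removed before any downstream use.

## Scoring and survival

The π value is `log2FC × log10(1/p)` with p floored at `1e-300`. By default
the BH-adjusted p feeds the score — the printed tables upstream report
adjusted values — with a raw-p mode available. The cumulative epitope score
sums π over all HERVs containing the peptide; it is exactly additive, and a
per-peritumoral-sample variant is supported by passing per-comparison π
vectors.

The HERV-set survival score is the arithmetic mean of the set's log2-CPM
rows per sample (the upstream normalization for this score is not stated;
log2-CPM is the default here). Samples are split at the empirical 1/3 and
2/3 quantiles, lower-inclusive, implemented as stable order-based blocks so
group sizes differ by at most one and boundary ties resolve by sample
order; constant scores collapse to a single group with a warning. Groups
are compared with the k-group log-rank (Mantel–Cox) test via the `survival`
package, returning the χ² statistic, df, p, and the fitted Kaplan–Meier
curves for plotting.

Methylation context takes the 10 probes nearest the HERV locus midpoint on
the same chromosome (an edge-distance alternative was considered and
rejected as more sensitive to locus length), averages their β values per
sample, and correlates the mean β with the HERV's log2-CPM across samples.
Spearman correlation is the default (the upstream method does not state
one; rank correlation is robust to the bounded, often skewed β scale), with
Pearson available. Labels (`demethylation` / `methylation`) require
BH-adjusted p < 0.05.

## The synthetic-data generator

`simulation_config()` fixes the study conditions; `simulate_bundle()`
produces every pipeline input with recoverable ground truth. Defaults, each
chosen once:

* 200 HERVs, 2 cancer types, 50 tumor + 50 matched peritumoral samples per
  cancer, and 32 sorted-PBMC samples (8 T, 8 NK, 16 other).
* Counts are NB with one shared dispersion α = 0.1 and `Var = μ + αμ²`;
  baselines are log-normal across HERVs and shared between each tumor and
  its matched peritumoral group (matching is implemented as shared
  baselines, not paired counts, since the differential test is group-wise).
  Expected HERV-mapped library size is 1e5 reads with mild (±15%) log-normal
  sample variation.
* 20 planted CAHs at log2 effect +2 in every cancer; 3 decoys
  overexpressed in peritumoral tissue (exercising the exclusion rule); 5 of
  the planted CAHs are cyt-HERVs; 2 further decoys are overexpressed only
  in sorted T/NK cells (exercising criterion C).
* Each immune signature is the mean log2-CPM of the planted cyt-HERVs plus
  Gaussian noise with SD equal to half the signal SD, where the signal SD is
  measured over the tumor samples — the samples the association analysis
  sees — so the noise level is defined relative to biological variation
  rather than to the tumor-versus-peritumoral separation. Function
  signatures stay on the linear scale (gaussian family); phenotype
  signatures are exponentiated, i.e. log-linear in the planted HERVs and
  nonnegative, matching the log-link Poisson family used to analyze them.
* Reference proteins are synthetic (random amino-acid sequences, labelled
  `_synthetic`) carrying planted 9-mers at well-separated positions. Each
  designated HERV receives a 60-aa protein window, reverse-translated with
  uniform synonymous codon choice (the identity filter operates on amino
  acids, so codon choice is immaterial) and embedded at a random strand and
  frame inside 2-kb random DNA. Planted epitopes come in four classes:
  *shared* (must survive the funnel; embedded in 7 and 3 HERVs), *weak
  binder* (anchor-negative; dies at binding), *self* (present in the
  synthetic proteome; dies at exclusion) and *non-homologous* (embedded via
  a non-retroviral protein; dies at homology).
* Survival times are exponential with hazard `h0 · HR^z`, where `z` is the
  standardized set score and HR = 0.5 per SD (high expression protective);
  censoring is uniform administrative. Standardizing makes the effect
  independent of set size and expression units; the default gives roughly a
  fourfold hazard spread between extreme terciles, a realistic effect for a
  cohort of 100.
* Methylation probes are placed around each locus midpoint; for cyt-HERVs
  the β values decrease with expression on the logit scale, otherwise they
  are independent noise.

The generator emulates the *statistical* structure the pipeline assumes —
NB counts, signature associations, embedded coding fragments, proximal
methylation, score-linked survival. It deliberately does **not** emulate
HERV family phylogeny, real batch structure, genuine MHC-binding
physico-chemistry, or cell-type deconvolution scores; passing tests
therefore demonstrate correctness of the pipeline's logic and statistics,
not biological performance on real tumors.

## Problem sizes and numerical choices

The test and acceptance suites run at desk scale by design: recovery
studies use the default 200-HERV, 232-sample configuration over 10 seeds;
calibration uses 1500 null NB features and 200 null log-rank replicates;
oracle equivalence uses 100 random 2-kb sequences and 50 random alignment
pairs. Unit tests use a reduced 60-HERV configuration. Other numerical
choices not already noted: the lasso convergence threshold is `1e-8` for
cross-validated fits and `1e-12` for fixed-λ fits (where closed-form
comparisons at `1e-6` are made); fixed λ values are evaluated on a path
containing them exactly, avoiding interpolation.

## Known limitations

* The NB Wald test uses moment dispersion estimates; with very few samples
  per group (< 5) it is less well calibrated than shrinkage-based
  dispersion estimators, and the plug-in path for externally computed
  differential tables is the recommended route there.
* The anchor binding stub is not a physiological predictor and must not be
  used for real candidate selection; supply an external rank table.
* E-values use fixed gapped BLOSUM62 Karlin–Altschul constants; they are
  not recomputed per scoring system.
* Cross-validated λ selection (`lambda.min`) is liberal by construction;
  among correlated eligible predictors the false-selection rate within the
  CAH set is appreciable even when the rate over the whole catalogue is
  low. Stability selection is out of scope.
* No Cox regression or multivariate survival adjustment is provided; the
  survival surface is the tercile log-rank comparison.
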