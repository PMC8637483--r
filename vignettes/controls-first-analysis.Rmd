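---
title: "Controls-first analysis of low-biomass amplicon tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Controls-first analysis of low-biomass amplicon tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contamscope)
```

## The problem

A single insect gut — the motivating case is an individual mosquito midgut —
carries very little microbial DNA. When such a specimen is extracted,
amplified and sequenced, a substantial share of its 16S reads originates not
from the gut community but from bacterial DNA in extraction and library
reagents (the "kitome") and from cross-contamination between wells. Extraction
negative controls (blank PBS tubes processed alongside the specimens) capture
this contaminant signal, but they also pick up cross-contaminants leaking
*from* the specimens, so simply deleting every ASV seen in a blank throws away
real biology.

contamscope implements a controls-first workflow around this tension:

1. classify and remove only *major* contaminants, using both prevalence
   across specimens and enrichment in the blanks;
2. keep the negative controls in every downstream table, ordination and test,
   so residual contamination stays visible rather than silently ignored;
3. screen for specimens whose composition is suspiciously close to their own
   blank — candidates for failed extractions or below-detection biomass.

## The major-contaminant classifier

For taxon $i$, let $\pi_i$ be the fraction of specimen samples with
$c_{ij} > 0$, and let $\bar a_i^{ctrl}$ and $\bar a_i^{spec}$ be its mean
abundance over negative controls and over specimens (zeros included in both
means; abundance is per-sample relative abundance by default, raw counts
optionally). Taxon $i$ is flagged iff

$$\pi_i \ge \tau \quad\text{and}\quad \bar a_i^{ctrl} > \bar a_i^{spec},$$

with $\tau = 0.8$ by default. The intuition: a reagent contaminant enters
every library at roughly constant mass, so it appears in nearly all specimens,
while its *relative* share is largest in the low-biomass blanks. A genuine
symbiont may be prevalent too, but its mean abundance is higher in specimens
than in blanks, so the second (strict) inequality protects it.

Choices a user can revisit:

* **Inclusive prevalence comparison** (`>=`). Verbal descriptions of such
  rules oscillate between "at least" and "more than"; we default to inclusive
  and expose `strict_prevalence` for the strict reading. At realistic
  specimen counts the two differ only when $\pi_i$ lands exactly on $\tau$.
* **Denominator = specimens only.** Contaminant prevalence is about true
  samples; `include_controls_in_prevalence = TRUE` switches to all libraries.
* **Ties lose.** A control mean exactly equal to the specimen mean does not
  flag; in particular a taxon absent from every control can never be flagged,
  because 0 is not strictly greater than any mean.

The reference *prevalence rule* (`classify_prevalence_rule()`) is the
presence/absence comparison popularised by negative-control filtering tools:
at the default threshold 0.5 a taxon is a contaminant iff its presence
fraction among controls strictly exceeds that among specimens. We implement
the rule exactly as stated, not the score-based statistic of the original
package — a deliberate simplification so the decision boundary is auditable.
Both classifiers always run in the pipeline and their flag sets are compared;
removal (`remove_contaminants()`) drops flagged taxa from *all* samples,
blanks included, and never drops a sample.

## Diversity with controls retained

* **Chao1** uses the bias-corrected estimator
  $\hat S = S_{obs} + F_1(F_1-1)/(2(F_2+1))$ with the classic asymptotic
  variance (Chao 1987). Note other toolchains use the later Chiu et al.
  variance; point estimates agree, standard errors differ by a few percent.
* **Shannon** is $-\sum p_i \ln p_i$, natural log (configurable base).
* **Bray-Curtis** is computed on per-sample proportions by default, since
  the raw-count form confounds dissimilarity with sequencing depth; a
  raw-count mode exists for datasets with deliberately equalized depths.
* **PCoA** is classical scaling: double-center $-d^2/2$, eigendecompose,
  scale eigenvectors by $\sqrt\lambda$. Bray-Curtis is semi-metric, so
  negative eigenvalues are expected; they are reported untouched (no
  Lingoes/Cailliez correction) and coordinates are returned only for
  positive axes, with variance explained relative to the positive spectrum.
* **Control proximity** (`control_proximity()`): each specimen's Bray-Curtis
  distance to its own replicate's blank (the mean over blanks if a replicate
  has several). Flagging is by caller-chosen `k` closest or a distance
  threshold — there is no principled universal cutoff, so the rule is
  explicit rather than hidden. The report gives mean ± SEM for the flagged
  set versus all specimens.

## Hypothesis tests

* **Wilcoxon rank sum** p-values are exact (full enumeration) when the
  pooled sample size is ≤ 12 with no ties, otherwise normal approximation
  with tie and continuity corrections. Alpha-diversity comparison families
  use Holm; differential-abundance contrasts use Benjamini-Hochberg,
  mirroring common practice for each family type.
* **PERMANOVA** uses the McArdle-Anderson trace formulation: with
  $G$ the Gower-centered $-d^2/2$ and $H_k$ the hat matrix of the $k$-th
  sequential model, $SS_k = \mathrm{tr}[(H_k - H_{k-1})G]$. Terms are
  sequential (Type-I) in caller order, interactions supported for two
  factors. P-values come from free permutation of sample labels with the
  add-one convention $p = (1 + \#\{F^\pi \ge F\})/(1 + B)$, $B = 999$ by
  default, seeded for bit-reproducibility. An explicit permutation matrix
  can be supplied, which turns the test into exact enumeration.
* **Two-way ANOVA** is the sequential-SS fit of `stats::aov`, with an
  explicit error when an empty design cell makes the interaction
  inestimable.
* **Differential abundance** (`nb_wald_diff_abundance()`) is a deliberately
  simplified negative-binomial Wald test: median-of-ratios size factors,
  per-genus method-of-moments dispersion on normalized counts (floored at
  1e-8, no shrinkage across genera), a two-group log-linear model fit by
  IRLS with log size factors as offset, $z = \hat\beta/\widehat{SE}$, BH
  across genera. Contrasts on any field other than `role` use specimen
  samples only: blanks share factor labels with real samples (a blank is
  "mock-treated" by construction), and letting them into a treatment level
  would attribute their contaminant load to that treatment. Blanks
  participate exactly when the contrast *is* blank-versus-specimen
  (`role`). Because there is no dispersion or fold-change shrinkage,
  estimates for low-count genera are noisier than shrinkage-based tools
  would give. When a genus is entirely absent from one group the likelihood
  has no interior maximum; we then add 0.5 to both normalized group means,
  use the delta-method standard error
  $\widehat{Var}(\log \hat m_g) \approx (1/m_g + \alpha)/n_g$, and flag the
  row as a boundary estimate — such fold changes are direction and
  magnitude indications, not precise estimates. A structural caveat worth
  knowing: median-of-ratios normalization absorbs any fold change shared by
  the majority of genera, so a "global" shift is unidentifiable from depth;
  effects are estimable only relative to a stable majority.
* **Survival** uses the Gehan-Breslow-Wilcoxon weighted log-rank test,
  weight = number at risk at each event time, which emphasizes early
  deaths; the statistic is chi-square with (groups − 1) df. (The common
  `survdiff(rho = 1)` is the Peto-Peto variant, a different weight, which
  is why this test is implemented directly.) Kaplan-Meier median survival
  per group is reported alongside.

## The synthetic study generator

`generate_study()` emulates the study design the pipeline targets:
3 replicates × 3 treatments (control, amoxicillin, amoxicillin/clavulanate)
× 2 timepoints (24 h, 72 h) × 5 specimens = 90 specimens, plus one blank per
replicate. The pieces:

* **Communities.** 60 community taxa assigned to a dozen genera (named after
  well-known mosquito-gut genera purely for readable reports). A global
  geometric-series profile is perturbed per replicate (Dirichlet,
  concentration 100) and per specimen (concentration 50).
* **Biomass-dependent contamination.** Specimen biomass $B_j$ is log-normal
  (meanlog $\log 4$, sdlog 0.8, units relative to the contaminant mass
  constant $c_0 = 1$); the library is a multinomial draw from
  $w_j \cdot \text{community}_j + (1 - w_j) \cdot \text{pool}$ with
  $w_j = B_j/(B_j + c_0)$. This one-parameter form encodes the low-biomass
  premise — the contaminant share rises as biomass falls — and makes the
  expected contaminant read fraction $1 - w_j$ available in closed form for
  validation. The functional form is the simulator's convention, not an
  estimate of any real dataset.
* **The contaminant pool.** 40 reagent taxa; 6 designated "majors" share
  99.2% of pool mass, so with the default biomass distribution each major
  is expected in essentially every specimen (satisfying both classifier
  criteria), while the 34 minors receive so few specimen reads
  (~1 expected) that they violate the 80% prevalence criterion — giving the
  classifier a planted positive set and a planted negative set.
* **Blanks.** Controls draw from
  $(1-\varepsilon)\cdot\text{pool} + \varepsilon \cdot \text{mean specimen
  composition of the replicate}$ with $\varepsilon = 0.02$, modelling
  specimen-to-blank cross-contamination only (blank-to-blank and
  specimen-to-specimen leakage are omitted for identifiability).
* **Planted effects.** A 2-unit log2 depletion of *Elizabethkingia* under
  both antibiotic treatments at 24 h, and a 1-unit log2 enrichment of
  *Asaia* in infected replicates. Depletions act multiplicatively on the
  genus proportion before renormalization, so the recoverable fold change
  is slightly smaller than $2^{-\delta}$ (renormalization lifts all
  proportions; with the default shares the expected estimate is about
  −1.9 rather than −2.0).
* **Read depth** is log-normal around 20,000 reads, floored at 100.

What the generator does *not* emulate: taxonomic misassignment, chimeras and
denoising artifacts, batch effects beyond the replicate level, overdispersion
beyond the Dirichlet-multinomial hierarchy, specimen-to-specimen
cross-contamination, and any compositional realism of actual mosquito guts.
Passing end-to-end tests on this generator therefore demonstrates that the
pipeline recovers *its own* ground truth under the stated noise model — not
that any particular real dataset is contamination-free.

`generate_survival()` draws exponential event times per group, rounds up to
whole days (daily monitoring), and censors administratively at the horizon
(default 30 days).

## Numerical conventions and degenerate inputs

* Zero-total samples are rejected wherever proportions are needed, with an
  explicit `drop_empty` escape hatch at normalization.
* All-zero count vectors give Chao1 = 0 with a warning; Shannon errors.
* Permutation p-values are never zero (add-one convention).
* Permutation streams, simulations and the pipeline all require explicit
  seeds; reruns of `run_pipeline()` with the same config are byte-identical.
* Rank aggregation groups taxa unannotated at the target rank under their
  deepest available label ("Unclassified" only when no rank is annotated),
  so per-sample totals are conserved exactly.
* PCoA treats eigenvalues below `1e-12` times the leading eigenvalue as
  numerically zero.
* The IRLS fit runs at most 50 iterations to a 1e-10 step tolerance; the
  trace-form PERMANOVA compares permuted statistics with a 1e-12 slack to
  make enumeration robust to roundoff.

## Problem sizes used in the validation suite

The test suite validates the classifier against a brute-force oracle on
1,000 random tables (≤ 20 taxa, ≤ 12 samples, 1–3 controls), checks
raw/relative flag concordance on 200 equal-depth tables, verifies PCoA on
100 random Euclidean configurations, calibrates PERMANOVA type-I error on
500 null datasets × 999 permutations (12 samples), the ANOVA interaction on
500 null replicates, NB Wald recovery on 200 genera × 40 samples with
calibration on 500 null genera, and the survival test's level on 500 null
simulations of 200 animals per group. The end-to-end check runs the full
default synthetic study (100 taxa × 93 samples). These sizes keep each
property statistically informative while the whole suite completes in well
under a minute.

## Limitations

* The major-contaminant rule is designed for designs with *few* blanks
  (the motivating study had three); with many blanks, score-based
  prevalence methods become competitive and should be compared.
* No DNA-concentration data are used (the frequency-based contaminant
  model family is out of scope by design).
* The differential-abundance stage trades the robustness of
  shrinkage-based tools for transparency; for borderline genera, confirm
  with an established implementation.
* PERMANOVA uses free permutations; restricted/stratified permutation
  schemes are not implemented.
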