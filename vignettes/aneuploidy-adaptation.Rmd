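---
title: "Models and methods for quantifying adaptation to aneuploidy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for quantifying adaptation to aneuploidy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aneuadapt)
```

This vignette explains the statistical machinery behind `aneuadapt`: the
models, the tunable parameters and their defaults, the numerical choices,
what the synthetic-data generator does and does not emulate, and the known
limitations.

## The scientific setting

Cell lines engineered to carry an extra chromosome (trisomy 3 copies,
tetrasomy 4) initially proliferate worse than their diploid parent and
recover over ~50 passages of in vitro evolution. The package quantifies
that adaptation at four levels: the genome (what is gained or lost), the
proteome (how much of the DNA dosage reaches protein level), proliferation
(growth-curve areas), and correspondence with aneuploid human tumors
(cohort-level association between aneuploidy burden and expression change).

## Copy number: segmentation and arm calls

Binned log2 copy-number ratios, already normalized to the unevolved
wild-type line, are partitioned per chromosome into constant-mean segments
by recursive binary segmentation. At each stage the candidate split
maximizes the two-sample pooled-variance t statistic over admissible
positions; it is accepted only if a within-segment permutation test
(`n_perm = 1000` by default) yields p below `alpha = 0.01`, and each side
must hold at least `min_width = 3` bins. Defaults follow common practice in
the change-point literature for noisy genomic ratios; an exhaustive-scan
oracle validates the split choice in the test suite.

Numerical care: when a candidate split leaves zero pooled variance
(noise-free piecewise-constant data), accumulated floating-point rounding
can make segment means differ at the 1e-15 level. The statistic treats
means as different only beyond `1e-8` of the data range, so exactly
constant segments are never split and noise-free steps are split with
"infinite" evidence at the true position.

An arm is called gained (lost) when segments whose mean exceeds
`log2_threshold = 0.2` (falls below −0.2) cover more than
`coverage_threshold = 0.75` of the arm length, strict inequality, with
gains and losses never pooling on one arm. The aneuploidy score (AS) is the
number of non-neutral autosomal arms. Samples whose genome-average ploidy
is 2.5 or above are treated as whole-genome doubled and excluded from
cohort analyses; the boundary is strict (< 2.5 retained) and configurable,
since a sample exactly at the cutoff is ambiguous.

The total-relative-DNA heuristic converts each segment's mean ratio $q_i$
into an approximate integer copy-number difference
$R_i = 2(2^{q_i} - 1)$, rounded half away from zero, and sums
$D = \sum_i \mathrm{round}(R_i)\,L_i$ over autosomal segments. The signed
form lets gains and losses cancel; because the quantity of interest for
comparing against proliferation is the total amount of *altered* DNA, the
default is the unsigned sum of $|\mathrm{round}(R_i)|\,L_i$, with the mode
flagged in the output. Rounding half away from zero (not banker's rounding)
keeps a heterozygous-level ratio of exactly ±log2(3/2) mapping to ±1 copy.

## Growth curves: residual-bootstrap AUC fold changes

Raw luminescence values are normalized by subtracting each replicate
trace's reading at the earliest timepoint. A continuous piecewise-linear
(linear-spline) model is fitted per cell line and experimental run; knots
default to every interior measured timepoint, which makes the fit the
maximum-flexibility piecewise-linear curve through the per-timepoint
replicate means — the natural choice when the assay measures a handful of
fixed timepoints in triplicate. The area under the curve is the trapezoid
sum, which is exact for a piecewise-linear function evaluated at its knots.

Uncertainty comes from a homoscedastic residual bootstrap: residuals are
pooled within one curve, resampled with replacement, added to the fitted
values, and the model is refitted. Because the least-squares AUC is a
linear functional of the observations ($\mathrm{AUC} = a^\top y$ with $a$
fixed by the design), each bootstrap refit reduces to adding $a^\top e^*$
to the fitted AUC, so the default 10,000 replicates are cheap and exact.
Each bootstrap AUC is divided by the reference line's bootstrap AUC within
the same run, ratios are averaged across runs, and the 2.5%/97.5% quantiles
of the run-averaged ratios form the empirical 95% CI. Bootstrap replicates
with a non-positive reference AUC leave the ratio undefined; they are
dropped with the count reported and a warning when more than 1% are lost.
Noise-free data collapses the CI to a point, which the tests assert.

## Proteomes: moderated tests, compensation, scaling

Preprocessing removes contaminant/reverse/site-only rows and any protein
with a missing (or non-positive) intensity, log2-transforms, scales each
sample by the median of its log-ratios to a per-protein reference (all
samples by default, or a designated reference-sample set), and removes
per-protein batch means by least squares with the biological design
preserved. The median-of-ratios scaling is robust to a minority of
genuinely shifted proteins — a gained arm moves a few percent of the
proteome — but not unbiased against it; see Limitations.

Differential abundance uses the empirical-Bayes moderated t: per protein,
the pooled two-group variance $s^2$ on $d$ degrees of freedom is shrunk
toward a prior $s_0^2$ with weight $d_0$,
$\tilde s^2 = (d_0 s_0^2 + d s^2)/(d_0 + d)$, where $(d_0, s_0^2)$ are
estimated across proteins by the method of moments on $\log s^2$ (closed
forms with a Newton inverse-trigamma solve; an infinite prior is capped at
$10^6$). Setting $d_0 = 0$ recovers the ordinary t statistic, and the full
fit matches `limma::eBayes` to 1e-6 in the test suite. Observation-level
precision weights are deliberately omitted (uniform weights): for
complete-case TMT matrices the mean–variance trend is weak, and the
moderated test is the component that matters downstream.

Arm-level dosage compensation is the difference between the average
genomic log2 ratio of an arm (bp-weighted over overlapping segments) and
the average log2 fold change of proteins encoded there, both relative to
the same parental line: 0 means protein scales fully with DNA;
log2(3/2) ≈ 0.585 on a trisomic arm means complete buffering. A planted
compensation factor c enters the generator as expected fold change
$(1-c)\log_2(\text{dosage ratio})$, so the estimate targets
$c\,\log_2(3/2)$.

Scaling classification in tumors follows a two-stage Welch scheme per
protein: a one-sided test of whether the mean delta difference between
arm-gained and non-gained tumors is *below* log2(3/2) (BH-FDR < 0.05 ⇒
`non_scaling`), then a two-sided test among the remainder for a
significant positive change (⇒ `scaling`), else `unclassified`. The 3/2
threshold is applied on the log2 scale as the expectation for a single-copy
gain in a diploid background. Tumors gaining *other* arms stay in the
"without gain" group — the contrast is defined only by the encoding arm.
Proteins with fewer than two tumors on either side are flagged and left
unclassified.

## AADEPT: aneuploidy-associated differential expression

Cohort preprocessing: genes must be valid (non-missing and positive, since
a log transform follows) in at least 60% of samples, tumor and normal
pooled; each sample is divided by the 75th percentile of its positive
values (upper-quartile normalization) and log2-transformed; matched normal
profiles are subtracted per patient; WGD patients are removed. The AADEPT
score of a gene is the Spearman rank correlation (average ranks for ties)
between its per-patient delta and the patient aneuploidy score, with
p-values from the asymptotic t approximation — exact enumeration is
immaterial at cohort sizes of hundreds — and BH FDR across genes. The
score is invariant under strictly monotone transforms of either variable,
which the tests assert. The pan-cancer cohort is analyzed pooled; no
per-cancer-type stratification is applied by default.

## Rank-based enrichment in N dimensions

For each dimension (a comparison's fold changes, or an AADEPT axis), values
are ranked with average ranks for ties and mapped linearly to [−1, 1]. A
set's enrichment score per dimension is mean(set) − mean(background). In
one dimension significance comes from a two-group ANOVA on the scaled
ranks; in N dimensions from a two-group MANOVA using Pillai's trace with
its F approximation — the conventional default and the robust choice among
the four classical statistics. With one dimension the MANOVA reduces
exactly to the ANOVA. A singular within-group covariance (duplicated or
collinear dimensions) is reported as an error naming the dimensions rather
than producing an unstable fit. Items missing any dimension are dropped
listwise per test with the count reported. FDR is adjusted per
signature-set collection.

Overrepresentation of a hit list against a set uses the hypergeometric
upper tail $P(X \ge q)$ with background size N, hit count k and set size m,
and reports the strength $s = \log_{10}(Nq/(km))$ — the log ratio of
observed to expected overlap — as missing when q = 0 (not −∞). FDR is
adjusted within each set category.

## The protein relevance score

Fold changes are first ranked across proteins within every comparison and
scaled to [−1, 1] — the same convention as the enrichment module — then
grouped: G1 (unevolved polysomic vs parental), G2 (evolved polysomic vs its
passage-0 counterpart), G3 (evolved wild-type control vs its passage 0).
The score is

$$S = \left|\sum G_1 + \sum G_2 - \text{penalty}\right|,$$

where the penalty is the G3 rank with the same sign as $\sum G_2$ and the
largest magnitude, or 0 when no G3 rank matches the sign (a zero sum
matches nothing). Reading "maximum" as largest magnitude rather than
largest signed value keeps the penalty symmetric: in both directions it
discounts the strongest control-evolution change in the same direction,
which is the point of the term — changes that also occur under mere
passaging should not count as aneuploidy adaptation. Only proteins
quantified in every comparison are scored.

Empirical p-values permute protein labels independently within each
comparison column, breaking a protein's cross-comparison dependence while
preserving every column's marginal rank distribution, and use the add-one
estimator $p = (1 + \#\{S^* \ge S\})/(1 + B)$ with $B = 100{,}000$ by
default, so p is never 0 and a zero score gets p = 1. Permutation (not
resampling with replacement) is the implemented null; a bootstrap variant
would mix marginals and is not exposed.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with truth
labels:

- **Genomes**: n autosomes of 100 Mb, centromere placed uniformly between
  30% and 70% of the chromosome, a fixed number of non-overlapping genes
  per arm. Tests standardize on 22 autosomes with 50 genes per arm (2200
  genes) where human-like proportions matter — notably, the fraction of
  the proteome on one chromosome (~4.5%) controls how much a gained arm
  perturbs sample-level normalization.
- **Cohorts**: each patient's arms are independently altered with a
  per-patient propensity drawn from U(0, 0.5), spreading the aneuploidy
  score over its range; planted genes receive delta = β·AS + N(0, σ), null
  genes N(0, σ). The headline conditions β = 0.2, σ = 1, n = 200 give
  clean planted-versus-null separation while keeping individual
  correlations realistic (ρ ≈ 0.5).
- **Cell-line proteomes**: log2 intensities with per-gene baselines
  N(25, 2), dosage effects (1−c)·log2(dosage ratio) for genes on altered
  arms, protein-specific batch effects centred on per-batch offsets
  (replicate r measured in batch r), and replicate noise (default sd 0.1,
  a typical TMT replicate spread). Planted adaptation genes shift ±1 log2
  unit versus wild type at passage 0 and continue in the same direction to
  ±2 by passage 50, absent from wild-type evolution. This is the
  aneuploidy-specific persistent pattern the relevance score is
  constructed to reward; a pattern that reverses sign between G1 and G2
  cancels in the score by design and would not be recoverable by any
  method based on it. Half the planted genes shift up and half down so
  both score directions are exercised.
- **Growth curves**: RLU(t) = baseline + amplitude·(e^{rate·t} − 1)·e^ε
  with lognormal noise on the growth term only, so a zero rate yields an
  exactly flat normalized curve and zero noise yields an exact
  exponential. Default CV 5% matches typical luminescence assays.
- **Binned profiles**: bins tile each arm (so arm boundaries always fall
  on bin edges) at the arm's log2 ratio plus N(0, noise_sd).

Every simulator uses one seeded stream with per-sample/per-curve sub-seeds
drawn from it, so identical configurations are bit-identical and partial
re-runs stay reproducible.

What the generator does **not** emulate: missing values (the pipeline is
complete-case by construction), focal (sub-arm) copy-number events, GC or
mappability artifacts, mean–variance trends in intensities,
cancer-type heterogeneity in cohorts, or peptide-level quantification.
Passing tests therefore demonstrate correctness of the statistical
machinery under the stated models, not robustness to these real-data
complications.

## Problem sizes used in validation

The test suite and the acceptance script run at desk scale, chosen to make
Monte-Carlo bounds sharp while keeping a full run in the low minutes:
1000-gene cohorts with 200 patients for AADEPT calibration and recovery;
2200-gene genomes with a three-line polysomy panel for compensation
recovery (estimates averaged over the two trisomic lines); 100 replicate
profiles of 200 bins for breakpoint localization; 100 coverage replicates
at 2000 bootstrap draws for growth CIs; 2000 random sets for enrichment
type-I rates; 10,000 permutations for relevance p-values in the acceptance
run (the package default remains 100,000).

## Known limitations

- **Normalization bias**: median-of-ratios scaling absorbs a small part of
  a genuine arm-level shift (on the order of the shifted fraction times
  the shift, ~0.005–0.01 log2 units for one human-sized chromosome),
  slightly inflating compensation estimates. This is inherent to any
  location-based between-sample normalization; the
  `reference_samples` argument mitigates the reference side of it.
- **Homoscedastic residual bootstrap**: growth measurement noise is
  multiplicative, so pooled residual resampling mildly misstates
  late-timepoint variance; empirical CI coverage at CV 5% remains ≥ 90%.
- **Segmentation at low amplitude**: events much smaller than the noise sd
  with few bins can be missed; the permutation test controls false splits,
  not power.
- **Relevance penalty interpretation**: "largest same-sign G3 rank" is read
  as largest magnitude (sign-symmetric); for positive G2 sums both
  readings coincide.
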