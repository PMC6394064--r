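---
title: "Methods: discovering and verifying urinary kidney-specific mRNA markers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: discovering and verifying urinary kidney-specific mRNA markers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Urinary mRNAs shed by kidney cells are attractive non-invasive markers of
diabetic kidney disease (DKD) and other chronic kidney diseases, but a
transcript measured in urine can also come from the bladder urothelium, from
bladder tumours, or from inflammatory cells during urinary tract infection
(UTI). A candidate is only *kidney-specific* if it is abundant in diseased
kidney tissue **and** scarce in every other tissue that sheds cells into
urine. `uromark` implements this screening logic as a reusable pipeline:
pooled multi-tissue expression compendia are harmonized and quality
controlled, differential expression is assessed per contrast with an
empirical-Bayes moderated t-statistic, candidates are selected by two
cross-tissue rules, and clinical verification statistics (delta-Ct relative
expression, fold of medians, rank tests, correlations, ROC, replicate CV)
quantify how a selected marker behaves in patient cohorts.

Because the original tissue compendia are external microarray repositories,
every stage is exercised on synthetic data with *known planted truth*. The
generators are first-class, tested code: the point is that recovery of
planted signatures, variance priors, correlations and dilution responses can
be asserted quantitatively.

## Harmonization and quality control

Multi-generation arrays share only part of their probe sets, so pooling
starts from the feature intersection across platforms
(`intersect_platform_features`), sorted lexicographically so the output
never depends on input order. Quantile normalization then forces every
sample to the common distribution (the across-sample mean of sorted values).
Ties are resolved deterministically: tied values receive the *mean of the
reference quantiles across their tied ranks*, which keeps the map
order-invariant and makes normalization idempotent. Probe-level
summarization, where probe groups exist, is Tukey median polish
(`stats::medpolish`), reported as overall plus column effect. Convolution
background correction of probe intensities is out of scope — it requires
raw probe-level data, while this pipeline operates on expression matrices.

Three matrix-level QC screens mirror standard array diagnostics:

* **RLE screen** — relative log expression (value minus gene-wise median
  across samples). A dataset is flagged when the median of its samples'
  absolute RLE medians exceeds `bias_threshold` (default 0.15 log2; the
  scale of shifts that visibly bend an RLE boxplot, configurable because no
  universal cutoff exists).
* **Array metrics** — per-sample scale factor (median of 2%-trimmed
  linear-scale means over samples divided by the sample's own trimmed mean;
  the median target makes a single aberrant sample score 0.5 when doubled
  instead of dragging the reference with it) and fraction of features
  detected above a log2 threshold.
* **PCA batch score** — gene-centred SVD; for each leading PC we compare the
  variance of its sample scores explained by tissue class (biology R²) with
  the *incremental* variance explained by dataset labels beyond tissue class
  (batch R²). Datasets are nested within classes, so the raw dataset R²
  always contains the biology signal; the increment is the part only batch
  structure can explain. The flag fires when batch R² exceeds both the
  threshold (default 0.5 over 2 PCs) and the biology R² of the same PC.

## Differential expression

For each contrast (disease compartment versus normal kidney, bladder,
bladder cancer, or UTI leukocytes; log2 fold change oriented test minus
reference) we compute per-gene group means and the pooled residual variance
$s_g^2$ on $d_g = n_1 + n_2 - 2$ degrees of freedom. Gene-wise variances are
modelled as draws from a scaled inverse-chi-square prior with parameters
$(d_0, s_0^2)$, estimated by the log-F moment method: with
$e_g = \log s_g^2 - \psi(d_g/2) + \log(d_g/2)$,

$$\psi'(d_0/2) = \mathrm{var}(e) - \overline{\psi'(d_g/2)},
\qquad s_0^2 = \exp\{\bar e + \psi(d_0/2) - \log(d_0/2)\},$$

with the trigamma inverse obtained by Newton iteration (relative tolerance
1e-8, at most 50 steps, asymptotic starting values at the extremes). When
the spread of $e$ is no larger than its sampling noise the right-hand side
is non-positive, and the estimator returns $d_0 = \infty$ with
$s_0^2 = \exp(\bar e)$ — complete shrinkage to a common variance. Zero
residual variances (constant genes) are floored at 1e-8 before taking logs;
the floor sits far below any variance the generators produce.

The moderated statistic shrinks each gene's variance to
$\tilde s_g^2 = (d_0 s_0^2 + d_g s_g^2)/(d_0 + d_g)$ and refers
$t = \widehat{\mathrm{lfc}} / \sqrt{\tilde s_g^2 (1/n_1 + 1/n_2)}$ to a
Student distribution on $d_0 + d_g$ degrees of freedom (normal when
infinite). $d_0 = 0$ recovers the ordinary pooled t, $d_0 = \infty$ the
fully shrunk statistic; both limits are tested. P-values are two-sided and
adjusted transcriptome-wide by Benjamini–Hochberg; a gene is called *up*
when the adjusted p falls below `alpha` (default 0.05) and the linear fold
change exceeds `fc_min` (default 2). Direction is taken from the fold-change
sign rather than from one-sided tests, because the screen needs up-calls
from a symmetric two-class comparison.

## The two-rule candidate screen

Per kidney compartment (glomeruli, tubules):

* **Type 1** — up in disease vs normal kidney *and* vs bladder, bladder
  cancer and UTI leukocytes; low expression in all three confounder
  classes; ranked by the disease-vs-normal-kidney fold change.
* **Type 2** — up vs the three confounder tissues (no normal-kidney
  requirement); low expression in bladder cancer and UTI; ranked by the
  disease-vs-bladder fold change.

"Low expression" is operationalized as a class-wise percentile filter: a
gene passes a confounder class when its mean log2 expression there is below
the 25th percentile of all genes' means in that class. The percentile is
configurable; 100 disables the filter, in which case type-1 candidates
coincide with the four-way up-intersection — an identity the test suite
checks against exact set arithmetic (`venn_codifferential`, which also
reports all $2^n - 1$ Venn region counts). Ranking ties are broken
lexicographically by gene ID so tables are fully deterministic. `top_k`
defaults to 8 per rule per compartment, reproducing the scale of a
16-candidate screen over two compartments; the packaged fixture uses 20 so
that recovery of its 20 planted genes can be measured without truncation.

## Clinical verification statistics

Relative expression from qPCR is $2^{-\Delta Ct}$ with the reference equal
to the arithmetic mean of the housekeeping Cts (the geometric mean on the
linear scale); it is invariant to adding a constant to all Cts of a subject.
Group contrasts use the fold change of group medians (rounded half-up, 1
decimal, matching how such tables are printed), Kruskal–Wallis across
groups, and pairwise Wilcoxon rank-sum tests (normal approximation with tie
and continuity corrections) BH-adjusted across the pair family. All-tied
inputs return $H = 0$, $p = 1$ by convention so constant fixtures do not
crash a pipeline. Correlations are Spearman with the asymptotic t
approximation.

ROC analysis is empirical over all observed thresholds; the trapezoid AUC
equals the rank-sum statistic $U/(n_1 n_2)$ with ties counted one half (a
tested identity), the optimal cutoff maximizes the Youden index
(sensitivity + specificity, ties broken by higher sensitivity then lower
cutoff), the AUC p-value comes from the rank-sum normal approximation, and
the discriminative band uses the conventional ranges (0.6–0.7 poor, 0.7–0.8
moderate, 0.8–0.9 good, above 0.9 excellent).

Replicate reproducibility is the coefficient of variation $c_v = \sigma/\mu$
of Ct triplicates per input amount, as a percentage rounded half-up to two
decimals. The default $\sigma$ uses the n-denominator (population SD),
which reproduces six of the eight per-cell CVs of the published
dilution-series worked example exactly; the 500 ng housekeeping cell is
only consistent with the n−1 (sample) convention, available via
`sd_mode = "sample"`, and the 500 ng target-gene cell matches neither —
an internal inconsistency of the printed table that the package documents
rather than hides. Per-gene average CVs are arithmetic means of per-dilution
CVs.

## What the generators emulate — and what they do not

`simulate_compendium` produces log2 values as baseline + planted signature
effects + additive per-dataset batch shift + $N(0, \sigma_g^2)$ noise with
$\sigma_g^2 \sim s_0^2 d_0 / \chi^2_{d_0}$, and masks features absent from a
sample's platform as missing. Defaults are the packaged study conditions:
2000 genes, seven tissue classes, two datasets per class of six samples,
two platforms sharing 60% of features, batch shifts of SD 0.3 log2, prior
$(d_0 = 4, s_0^2 = 0.05)$, and planted sets of 20 kidney-disease genes
(+2 log2 in diseased compartments) and 30 + 30 confounder-high genes
(+3 log2 in bladder/bladder-cancer and UTI respectively).

Planted signatures carry an optional `down_classes` field: the kidney
signature is *depleted* 2 log2 below baseline in the confounder tissues.
This is the defining property of a kidney-specific transcript — high where
it originates, below background where it does not — and it is what makes
the percentile filter meaningful: a gene merely *average* in bladder is not
kidney-specific, and the filter correctly rejects it. Planted genes are
drawn from the cross-platform shared feature core, since a candidate absent
from one platform cannot survive the intersection stage.

The generators deliberately do **not** emulate probe-level structure
(multiple probes per gene, positional bias, raw intensity backgrounds),
non-additive batch distortions, correlated gene-gene noise, or heavy-tailed
outlier arrays. Passing tests therefore demonstrate that the pipeline's
logic is correct under its own model assumptions, not that real microarray
compendia satisfy those assumptions.

`simulate_cohort` draws group-wise log-normal marker values (configured
median and log-scale dispersion) and couples covariates through a Gaussian
copula, mapping a target Spearman $\rho$ to the latent correlation via
$2\sin(\pi\rho/6)$. Covariate-covariate correlations follow a single-factor
model (products of marker correlations), which keeps the latent matrix
positive semi-definite for any feasible targets; the simulator draws from
rank-deficient matrices by eigendecomposition, so $\rho = 1$ (comonotone)
works exactly. Configured correlations are within-group; the pooled cohort
correlation also contains the between-group gradient of medians, just as in
a real cohort. `simulate_dilution_series` uses the linear dilution response
$Ct = \text{intercept} - \text{slope}\cdot\log_{10}(\text{amount})$ with
Gaussian replicate noise; the default slope 3.32 is the theoretical value
for 100% amplification efficiency.

One global seed is expanded into fixed per-component substreams (platform
assignment, planted-set placement, variances, batch shifts, noise), so
regenerating one component leaves the others untouched and two runs with
the same configuration are byte-identical on disk.

## Numerical and design choices

* Rounding of reported ratios and CVs is half-up at the printed precision
  (1 dp for fold changes, 2 dp for CVs); internal computation is full
  precision. `round_half_up` exists because `round()` rounds half to even.
* Feature order after intersection, candidate tie-breaks, and Venn region
  naming are all lexicographic — deterministic output is treated as part of
  the contract and is tested by byte-comparing rerun outputs.
* TSV is the interchange format (`gene_id` first column, paired sample
  sheet); values are written with 17 significant digits so a round trip is
  exact to numerical precision. Missing (platform-absent) values are empty
  cells before harmonization and forbidden afterwards.
* Problem sizes in the test and acceptance suites (2000-gene compendia,
  5000-gene prior recovery, 20-replicate null calibrations, 200-instance
  ROC property checks) were chosen as the smallest sizes at which the
  Monte-Carlo tolerances stated alongside each check are comfortably
  meaningful; the full suite runs in well under a minute.
* Stochastic recovery checks (the 0.745-fold single-gene report, the cohort
  Spearman regime) average a handful of replicate simulations rather than
  relying on one draw, which makes the assertions reflect estimator bias
  rather than single-seed luck.

## Limitations

The pipeline assumes matrix-level inputs: probe-level QC (RNA degradation
slopes, probe-set residual diagnostics) must happen upstream. The
empirical-Bayes model assumes a single global variance prior; strongly
heteroscedastic designs (e.g. mixed tumour/normal compendia) may violate
it. The low-expression filter is relative (percentile within class), so it
cannot distinguish "absent" from "uniformly low" — with heavily filtered
input matrices the percentile should be tightened. ROC cutoffs are
in-sample optimal Youden points and are optimistically biased in small
cohorts; no resampling correction is applied. Finally, estimated glomerular
filtration rate is consumed as a covariate, never computed.
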