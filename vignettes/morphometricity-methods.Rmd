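---
title: "Methods: morphometricity, calibrated brain-wide association, and brain-based prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: morphometricity, calibrated brain-wide association, and brain-based prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(morphkit)
```

## Scope

morphkit implements the statistics that sit downstream of T1-weighted MRI
processing, once a pipeline (voxel-based morphometry or a surface
reconstruction) has produced an n x p table of gray-matter measurements:
feature QC and descriptive statistics, variance-component estimation of
*morphometricity*, mass-univariate brain-wide association (BWAS) with an
empirically calibrated family-wise error rate, spatial clustering of
significant features, replication analysis, and linear/BLUP brain-based
prediction. Image processing itself (segmentation, registration, surface
extraction) is out of scope: the package starts from a `feature_matrix` with
per-feature 3D coordinates and optional ROI labels.

Because individual-level imaging data of the scale this methodology targets
are access-restricted, the package ships a synthetic-data generator that
reproduces the statistical structure the analyses assume, so that every stage
is testable against known ground truth.

## The morphometricity model

For a trait $y$ measured on $n$ individuals with covariates $C$ and $p$
standardized brain features $Z$, the model is the standard variance-component
linear mixed model

$$ y = C\beta + g + \varepsilon, \qquad
   g \sim N(0, \sigma_g^2 A), \quad \varepsilon \sim N(0, \sigma_e^2 I), $$

where $A = ZZ'/p$ is the morphometric relatedness matrix (MRM) over the
standardized features. Morphometricity is
$m^2 = \sigma_g^2 / (\sigma_g^2 + \sigma_e^2)$, the fraction of trait
variance jointly captured by all brain features. `build_mrm()`
trace-normalizes $A$ to mean diagonal exactly 1; with several kernels in a
joint fit this puts all of them on a common variance scale, so per-kernel
variance fractions are comparable (the normalization is applied uniformly and
documented here because the exact parameterization used upstream of this
package is not fixed by any published formula we could adopt verbatim).

`morpho()` estimates the components by REML:

* **Single kernel.** The restricted likelihood is diagonalized exactly: with
  $T$ an orthonormal basis of the complement of the column space of $C$ and
  $\lambda_i, u_i$ the eigenpairs of $T'AT$, the rotated data are independent
  with variances $\sigma_g^2\lambda_i + \sigma_e^2$. The likelihood is then
  profiled over the ratio $\phi = \sigma_g^2/\sigma_e^2$ and maximized by 1-D
  search (Brent, tolerance $10^{-12}$ on the transformed ratio), which is
  exact up to that tolerance — the package's own tests require agreement with
  a brute-force likelihood grid at ratio resolution $10^{-4}$ to $10^{-6}$
  log-likelihood units. Standard errors come from the expected information of
  $(\sigma_g^2, \sigma_e^2)$ and the delta method for $m^2$.
* **Multiple kernels.** Average-information (AI) REML with a monotone line
  search: an AI step is halved until the restricted likelihood does not
  decrease, with an EM step (guaranteed uphill) as first move and as fallback
  when the AI matrix is singular; components are floored at
  $10^{-8}\,\mathrm{Var}(y)$ and components pinned at the floor with a
  negative score are treated as active constraints. Three variance splits are
  tried as starting points because near-collinear kernels (e.g. two
  processings of the same scans) otherwise admit poor local solutions.
  Convergence is declared at $|\Delta \log L| < 10^{-6}$ or 100 iterations;
  non-convergence flags the estimate rather than aborting.
* **Testing $\sigma_g^2 = 0$.** The null sits on the boundary of the
  parameter space, so the LRT reference is the 50:50 mixture
  $\tfrac12\chi^2_0 + \tfrac12\chi^2_1$. Note the resulting p value is *not*
  uniform under the null: it has an atom at 1 (about half the fits sit at
  $\hat m^2 = 0$) and is uniform on $(0, \tfrac12)$ otherwise. The test suite
  therefore checks type-I error control at conventional levels rather than
  distributional uniformity. The 95% CI for $m^2$ is
  $\hat m^2 \pm 1.96\,\mathrm{SE}$, truncated to $[0,1]$.

Binary or ordinal traits are fitted on the observed scale with the same
linear model — no liability-scale conversion — matching how such traits are
analyzed in the large-cohort literature this package serves. A
thresholded-liability mode for the *generator* exists but is off by default
for the same reason.

`shared_unique()` quantifies whether two feature sets (e.g. two processings)
capture the same trait variance: it fits each kernel alone and both jointly;
the rate of increase $m^2_{joint}/m^2_k$ is 1 when the added kernel is
redundant and approaches 2 when the two kernels tag disjoint halves of the
signal.

## BWAS and empirical FWER calibration

`run_bwas()` fits one linear model per feature, $y = b_i X_i + C\gamma + e$,
with features standardized to unit SD (effects are trait units per feature
SD). Implementation residualizes $y$ and all features on $C$ once and uses
the partial-regression identity; the tests require equality with per-feature
full regressions to $10^{-8}$. Two-sided p values use the $t$ reference with
$df = n - \mathrm{rank}(C) - 1$ at all $n$.

Bonferroni correction at $\alpha/p$ is valid under any dependence but
conservative when features are correlated. `simulate_null_calibration()`
draws standard-normal traits unrelated to the features (covariates stay in
the model), records each trait's minimum p value, and
`optimal_threshold()` returns the $\lfloor \alpha n_{traits}\rfloor$-th
smallest min-p — the order statistic, because it is the largest threshold
whose calibration-set FWER is at most $\alpha$; interpolating quantile
definitions differ by less than one rank and are available via
`method = "quantile"`. By construction the FWER on fresh null traits is
close to $\alpha$, with binomial noise of half-width
$1.96\sqrt{\alpha(1-\alpha)/n_{traits}} \approx 0.0135$ at
$n_{traits} = 1000$ *plus* comparable order-statistic noise in the threshold
itself.

**A note on non-normal features.** With *exactly* normal simulated traits the
per-feature $t$ statistics are exactly Student-$t$ conditional on any feature
values, a classical linear-model result — heavy-tailed features cannot
inflate the false-positive rate in that design, and the package's tests
confirm it. Heavy tails do inflate false positives when the trait itself
departs from normality (rare binary outcomes analyzed with linear models are
the practically important case): a high-leverage feature value multiplying a
rare outcome produces heavy-tailed test statistics. The package demonstrates
this signature with a rare-binary null trait against cubed-normal features
and shows that rank-based inverse normal transformation (RINT) of the
features removes it. This is the package's reading of the reported
sensitivity of BWAS false positives to non-normal measurements; the popular
intuition that heavy-tailed features alone inflate FWER for normal traits
does not survive the conditional-exactness argument.

RINT (`rint()`) maps within-column ranks through normal quantiles with the
Blom offset $(r - 3/8)/(n + 1/4)$ and average ranks for ties — the common
default in neuroimaging/genetics; no other variant is implied by the method
this package follows.

## Descriptive statistics

`feature_moments()` reports the classical moment estimators
(skewness $= m_3/m_2^{3/2}$, non-excess kurtosis $= m_4/m_2^2$, no bias
correction) so that a normal feature scores kurtosis 3. `sum_r2()` sums, for
every feature, the bias-adjusted squared correlation
$R^2_{adj} = R^2 - (1-R^2)/(N-2)$ with every *other* feature. Two deliberate
choices:

* The adjusted-$R^2$ formula is taken in the only reading consistent with an
  unbiased estimator whose raw version has upward bias of about $1/N$ (the
  source formula is typeset ambiguously).
* The self-pair ($r_{ii}=1$) is excluded: it would add a constant 1 and
  carries no information about correlation with *other* measurements. The
  literal sum-over-all-$j$ reading is available via `include_self = TRUE`.

The optional row subsample for `sum_r2()` (emulating computing on a reduced
"representative" participant subset) is a seeded uniform sample; stratified
sampling by site/sex is a hook deliberately left off for synthetic data,
which has no sites.

## Spatial clusters

`find_clusters()` groups significant features into clusters: each significant
feature is linked to its $k = 10$ nearest neighbours (Euclidean distance on
the supplied 3D coordinates, exact ties broken by feature index), edges are
symmetrized, and clusters are connected components, grown by breadth-first
search in ascending feature index for determinism.

The neighbour universe deserves a remark, because the natural-language
description of this search rule is genuinely ambiguous. If neighbours are
drawn *from the significant set itself*, every significant feature always
has $k$ neighbours no matter how distant, so singleton clusters are
impossible and sparse, well-separated signals merge into one component. That
contradicts both observed practice (large fractions of singleton clusters
are reported in this literature) and the geometry one wants from a spatial
cluster. The default is therefore `neighbours = "all"`: each significant
feature's $k$ nearest neighbours among *all* features, of which only the
significant ones become edges — isolated significant features then form
singletons. The within-significant reading remains available as
`neighbours = "significant"`.

`annotate_rois()` and `roi_robustness()` summarize clusters against a
supplied per-feature ROI labeling (any atlas, passed as a label vector):
a cluster hits every ROI any member belongs to, and robustness across
processings is the count of ROIs hit by at least two of them.

Cluster-level replication (`replicate_clusters()`) uses the pooled
Bonferroni threshold $0.05/\text{(total discovery clusters)}$ and requires
at least one member to pass it; sign consistency with the discovery effect
is required by default and switchable (`require_sign = FALSE`), since the
source procedure does not state a sign rule — both counts are reported.
Feature-level replication (`replicate_features()`) mirrors this with
$0.05/N_{SignifV}$, the pooled count of significant associations carried to
the replication sample.

## Prediction

`build_predictor()` turns BWAS results into linear scores under three
selection rules (top feature per cluster, all significant features, features
of size-one clusters only), with weights equal to the discovery BWAS betas
and standardization parameters frozen from the training sample. Scoring new
data standardizes with the *training* means/SDs; a missing feature is a hard
error, never imputed. Whether scores should standardize features at all is
not externally fixed; standardized is the default, raw values sit behind
`standardize = FALSE`.

`blup_predictor()` converts a fitted single-kernel `morpho` model into
per-feature best-linear-unbiased-prediction weights
$u = \sigma_g^2 W'V^{-1}(y - C\beta)$, with $W$ scaled so that $WW'$ equals
the trace-normalized training kernel. The equivalent kernel form
$g_* = A_{*,train}(A + \lambda I)^{-1}(y - C\beta)$, $\lambda =
\sigma_e^2/\sigma_g^2$, is exposed via `predict(fit, ..., form = "kernel")`
and must agree with the primal form to $10^{-8}$ (tested). Variance
components are reused from the discovery fit — no refit on evaluation data —
so BLUP needs no cross-validation.

`evaluate_prediction()` reports incremental $R^2$ (difference of nested
least-squares fits with and without the score, both containing the
covariates) and a likelihood-ratio test $n\log(RSS_{red}/RSS_{full})$
against $\chi^2_1$. `fraction_predicted()` divides the out-of-sample $R^2$
by the evaluation-sample morphometricity; because the right denominator is
debatable, pass the discovery-sample fit instead to get the other variant.
The ratio is reported only when the denominator is significantly positive.

## The synthetic-data generator

`sim_config()` + `simulate_features()` place $p$ features on a 3D lattice
and draw, per individual, a white-noise field smoothed by a separable
Gaussian kernel with reflecting boundaries ($\sigma = \mathrm{FWHM}/2.3548$,
the standard neuroimaging convention). Columns are rescaled to unit variance
(so marginals are comparable across smoothing levels) and shifted by a
per-feature baseline drawn from `baseline_range` (default 0.3–0.8, giving
the voxel-QC rules something meaningful to threshold, in the spirit of
gray-matter density values). Feature correlation decays with lattice
distance at a rate set by the FWHM; the tests verify the decay against the
analytic kernel-overlap values.

Choices worth knowing about:

* **Global scale.** An optional per-individual global component
  (`global_sd`, emulating overall head/brain size) is off by default: a
  nonzero default would impose uniform cross-feature correlation and
  invalidate the independent-features regime (FWHM 0) that the calibration
  tests rely on. Turn it on explicitly to study that confound.
* **Non-normality** is injected *after* smoothing via a per-column monotone
  sinh-arcsinh transform whose two parameters are solved from closed-form
  moments (Bessel-K formulas) to hit target skewness and kurtosis; rank
  order is preserved and extreme targets perturb correlations slightly
  (documented, not corrected). The transform family is a pragmatic stand-in:
  nothing pins down the empirical distribution family of real voxel
  intensities, and any two-parameter monotone family with moment control
  would serve. Feasibility requires kurtosis $\ge$ skewness$^2 + 1$.
* **Traits.** `simulate_trait()` builds $y = C\beta + g + \varepsilon$ with
  $g$ a weighted sum of standardized causal columns, rescaled so the
  in-sample variance ratio equals `target_m2` *exactly*. Causal layouts are
  `scattered` or `blobs(k, radius)`; blob centres are placed with pairwise
  separation $> 2(\text{radius}+1)$ when the lattice allows, each blob gets
  a coherent effect sign (mixed signs inside a spatially smooth blob would
  cancel) and an equal share of the causal variance, so every planted blob
  is detectable by construction — that is what makes blob membership usable
  as ground truth for the cluster search.
* **Seeds.** One master seed; each stage derives a child seed by a fixed
  offset (`child_seed()`), all below $2^{31}$, and the pipeline manifest
  logs them.

What the generator does **not** emulate: scanner/site batch structure beyond
a named covariate loading, registration or segmentation artifacts, spatial
non-stationarity of smoothness, and the empirical marginal distributions of
real pipelines. Tests passing on this generator therefore validate the
statistical machinery under its stated assumptions, not the behaviour of any
particular imaging pipeline on real scans.

## Problem sizes and numerical tolerances

The shipped tests and the acceptance script use desk-scale versions of the
study conditions: FWER calibration at $n = 500$, $p = 2000$, FWHM 3 with
1000 + 1000 null traits; parameter recovery at $n = 1000$, $p = 2000$ over
25 replicate seeds (mean $\hat m^2$ within $\pm 0.03$ of 0.3, $\ge 85\%$ CI
coverage; two-kernel 0.2/0.1 split within $\pm 0.05$); oracle equivalences
at $n \le 100$. These sizes are the package's chosen reference conditions:
large enough for the asymptotics the methods rely on, small enough to run
routinely. Degenerate inputs (constant features, empty significant sets,
zero-variance predictors, boundary variance components) return flagged or
empty results rather than errors wherever the downstream stage can proceed.

## Known limitations

* Single- and multi-kernel REML are dense ($O(n^3)$); no sparse or low-rank
  approximations are provided, so $n$ beyond a few thousand becomes slow.
* Missing values are handled by complete-case analysis only (mixed models
  downstream need complete cases); pairwise-complete correlation is
  deliberately unsupported.
* No Haseman–Elston / method-of-moments estimators, no permutation
  inference over real trait labels, no random-field theory, and no FDR
  procedures — the calibrated-threshold approach is the package's answer to
  multiplicity.
* The LRT p value for $m^2$ relies on the asymptotic boundary mixture;
  at very small $n$ it is approximate.
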