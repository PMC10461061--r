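---
title: "Methods: causal networks, niche curves, phylogenetic signal and projection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal networks, niche curves, phylogenetic signal and projection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soilniche)
```

This vignette is the package's account of the science it implements: the
models, their assumptions, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the numerical and design choices
made where reasonable alternatives existed.

## The causal network

`soilniche` models one bacterial taxon's relative abundance as the terminal
node of a recursive observed-variable structural equation model over nine
environmental drivers: three climate variables (mean annual temperature,
°C; humidity, %; precipitation, mm), three vegetation coverages (C3
macrothermal, C3 mesothermal, C4 megathermal; fractions), and three soil
variables (organic carbon, %; conductivity, dS/m; pH). In the default
topology (`default_sem_spec()`) climate, pH and conductivity are exogenous
and freely correlated; each vegetation coverage responds to the three
climate variables; organic carbon responds to conductivity, pH, humidity,
precipitation and C3 macrothermal coverage; and the taxon responds directly
to all nine drivers. The topology is data, not code: any acyclic network
over observed variables can be supplied via `sem_spec()`/`build_spec()`.
We chose this default because only two pieces of the published network are
pinned down unambiguously — organic carbon's five parents and the taxon's
nine direct links — while the remaining wiring is described only at the
level of "climate drives vegetation drives soil"; the default encodes that
reading and documents it.

Assumptions inherited from path analysis: linear equations, uncorrelated
normal residuals, no latent variables, and limited spatial dependence
between samples (sites are treated as exchangeable draws). Skewed drivers
should be log10-transformed first (`transform_env()` logs conductivity,
organic carbon, humidity, precipitation and the C3 coverages — never pH,
which is already a log scale); the transform refuses to run twice and
refuses nonpositive values unless an explicit `pseudo_offset` is supplied,
so data are never silently altered.

### Estimation and fit indices

For a recursive model with uncorrelated residuals, equation-wise ordinary
least squares is the maximum-likelihood estimator, so `fit_sem()` estimates
each equation by OLS rather than iterating a full-information optimizer;
the equivalence is verified in the test suite against a brute-force
minimizer of the ML discrepancy on a four-variable system (agreement to
1e-4). The implied covariance is assembled from the reduced form
$y=(I-B)^{-1}(\Gamma x+\zeta)$ and compared with the sample covariance
through $F_{ML}=\ln|\hat\Sigma|-\ln|S|+\mathrm{tr}(S\hat\Sigma^{-1})-p$.

Conventions, chosen once and used consistently:

* $S$ and all residual variances use the $n-1$ denominator and
  $\chi^2=(n-1)F_{ML}$ (the Wishart likelihood convention). Consistency
  matters more than the choice: it yields the perfect-fit identity
  ($S=\hat\Sigma\Rightarrow\chi^2=0$, CFI $=1$, RMSEA $=0$, SRMR $=0$)
  exactly, and a calibrated test (empirical rejection rate 0.050 at
  $\alpha=0.05$ over 500 true-topology replicates of $n=500$ in the test
  suite).
* CFI uses the independence baseline (variances free, covariances zero).
* RMSEA $=\sqrt{\max(\chi^2-df,0)/(df\,(n-1))}$.
* SRMR is the root mean square of covariance residuals standardized by the
  observed standard deviations, over the lower triangle including the
  diagonal (the common convention; no formula is fixed by the literature
  the model family comes from).
* Degrees of freedom count one free parameter per path, one residual
  variance per endogenous variable and the saturated exogenous block;
  means are saturated and excluded.
* Missing data: listwise deletion with a message. Zero-variance taxa are
  refused per equation; in `fit_many()` such failures are recorded per
  taxon and never abort the batch.

Standardized coefficients are `estimate * sd(parent) / sd(child)` with
sample standard deviations, so a one-sd increase in a parent moves the
child's prediction by that many of its own standard deviations; the
reconstruction identity (unstandardized from standardized and sds) holds to
1e-10 and is asserted in the tests.

`predict_conditional()` implements fitted-value semantics: the taxon's
prediction uses its equation's intercept and coefficients with *observed*
parent values, never the taxon column itself. `holdout_validate()` fits on
a seeded random subset (default 1,000 samples, matching the 1,000/381
split used with 1,381-site surveys) and reports Pearson *r* and
$R^2 = 1-\mathrm{SSE}/\mathrm{SST}$ on the held-out remainder.

## The synthetic-data generator

`generate_dataset()` draws exogenous drivers from a configured multivariate
normal and evaluates each endogenous variable as its structural linear
combination plus independent normal noise, in topological order, appending
taxon responses last. `default_generator_config()` fixes the packaged study
conditions: unit-variance exogenous drivers with moderate correlations
(climate intercorrelations −0.3 to 0.5, pH–conductivity 0.4), vegetation
and organic-carbon residual sds of 0.8, and a default taxon whose nine
direct paths are the published Synechococcophycideae standardized
coefficients with residual sd 1 — giving a taxon $R^2$ of about 0.3,
typical of phylum-level fits. The taxon intercept defaults to 10 so that
the `"truncate"` squash (clamping negative abundances to 0) essentially
never binds and the noise-free limit stays exactly linear; `"none"` and
`"logistic"` squashes are available when raw or \[0,1\] semantics are
wanted.

What the generator deliberately does **not** emulate: spatial
autocorrelation between sites, sequencing error, compositional closure of
whole communities (taxa are generated marginally), and non-normal driver
distributions. Passing tests therefore demonstrate that the estimators
recover the truth under the model's own assumptions — not that real soil
data satisfy those assumptions.

`generate_hof_gradient()` evaluates a HOF curve on a regular \[0,1\]
gradient and adds normal noise truncated at zero.
`generate_tree_and_trait()` draws a pure-birth tree rescaled to unit depth
and evolves a Brownian trait from a root value of 0, so a tip trait has
variance `brownian_sd^2` (verified against the Brownian identity over
1,000 replicates). `multinomial_counts()` emulates sequencing as one
multinomial draw per sample, which makes rarefaction and copy-number
correction testable against binomial/hypergeometric expectations.

## Preprocessing

`rarefy()` subsamples each sample without replacement to a common depth
(default 22,500 reads); samples below depth are dropped and reported, never
up-sampled — the standard semantics. Copy-number correction follows
rarefaction (the order used in the pipeline this reproduces), divides each
taxon by its 16S copy number (missing values default to 1, with a message)
and renormalizes to relative abundances. `aggregate_rank()` sums rows over
identical lineage prefixes; a taxon unassigned at or above the requested
rank pools under `Unclassified_<deepest assigned ancestor>` so column sums
are conserved exactly.

## HOF niche models

The seven-model hierarchy (`hof_curve()`): flat (I), monotone sigmoid
(II), sigmoid with plateau (III), symmetric unimodal (IV), skewed unimodal
(V), and bimodal (VI, VII). Types VI/VII are parameterized here as a
type-IV peak plus a second peak shifted by `d2` ∈ (0,1) with height
fraction `h` ∈ (0,1\]; VII gives the second peak its own width `b2`. The
bimodal extension is cited without formulas in the literature this family
comes from, so this parameterization is a documented choice that preserves
the "two niche optima" semantics.

Fitting (`fit_hof_all()`) is Gaussian nonlinear least squares on
max-scaled abundances over the \[0,1\]-rescaled gradient — relative
abundances are continuous, so the binomial/Poisson error families used for
presence data do not apply. Each type is optimized by BFGS with analytic
gradients from one data-driven heuristic start plus five random restarts
(unconstrained parameterization: log M, logit d2, logit h). Taxa with
fewer than 10 positive observations (the occurrence rule; read as ≥10
occupied samples) are skipped with a recorded reason. Model choice
(`select_model()`) is AICc-minimal — AICc rather than plain AIC because
per-gradient sample sizes are moderate — stabilised by re-selection on
five bootstrap resamples: if the AICc choice is not the modal bootstrap
choice the modal choice wins, ties going to the lower-complexity type.
The published workflow included a visual-inspection step; it is replaced
here by machine rules plus `autoplot()` diagnostics, for reproducibility.

Niche interpretation (`niche_metrics()`, dense 2,001-point grid): type I
and monotone II/III have no optimum; unimodal types take the interior
maximum of the fitted curve; bimodal fits whose interior optima all lie
within 5% of the gradient range ends (configurable `edge_tolerance`; the
rule is stated in its source only by example, e.g. pH 4 or 10) are
interpreted as having no optimum. Edges are the inflection points of the
fitted curve flanking the optimum, located by sign changes of the
numerical second derivative; a side with no interior inflection takes the
range end and is flagged.

The packaged recovery simulation uses a type-IV truth with
`M = 4, a = -2, b = 6, c = 1.6` (optimum 0.3), n = 300 gradient points and
noise sd 0.02 — noise at 2% of the peak, with the curve's tails more than
three noise sds above zero. The tail condition matters: when a strongly
peaked curve decays to within one noise sd of zero, the generator's
truncation at zero biases the tail observations upward and bimodal types
*correctly* pick up that lack of fit, so "strong signal" must include
tails that stay clear of the truncation floor. Under these conditions the
suite requires ≥90% IV-or-V selection and optimum RMSE < 0.03 gradient
units over 200 replicates (the symmetric truth is nested in type V, which
is why V is accepted as a twin).

## Phylogenetic signal

`abouheif_proximity()` builds the topology-only proximity: the product over
internal nodes on the tip-to-tip path of 1/(number of direct descendants).
Branch lengths are deliberately ignored — this is the original
construction, and it differs from branch-length-aware alternatives.
`cmean_test()` computes the Moran-form statistic
$C=(n/S_0)\sum_{i\ne j}a_{ij}z_iz_j/\sum_iz_i^2$ and a one-sided (greater)
permutation p-value with the add-one rule (default 999 permutations);
"greater" because trait conservation is the hypothesis of interest. On a
star tree the statistic is exactly $-1/(n-1)$ for any trait, a useful
degenerate check (note the permutation distribution is then a point mass,
so p-values are uninformative there by construction).

`local_moran()` (LIPA) row-normalizes the proximity and computes
$I_i=z_i\sum_jW_{ij}z_j/(\sum_kz_k^2/n)$; the average of the per-tip values
equals the global Moran statistic under the same weights (asserted
numerically). Significance is by conditional permutation (tip *i* held
fixed, all other values permuted), reported two-sided since both
conservation and divergence hotspots are of interest; a Benjamini–Hochberg
column is provided but the significance flag follows the conventional
unadjusted p < 0.05 display. `filter_taxa_for_signal()` applies the strict
"present in more than `min_samples` samples" occupancy rule (default 200).

## Trait space

`coefficient_matrix()` collects each successful fit's nine standardized
taxon paths in a fixed column order (climate, vegetation, soil).
`ternary_coordinates()` maps each row to soil/vegetation/climate
percentages — 100 × the family's absolute-coefficient sum over the total —
so the three axes sum to 100 and the transform is invariant to positive
rescaling of a row. `ward_cluster()` uses Euclidean distances with Ward's
minimum-variance linkage (`hclust` method `"ward.D2"`); the default of 10
groups matches the published grouping, and `k = "auto"` scans 2–15 and
maximizes average silhouette width. The published account mentions a
"misclassification" criterion alongside silhouette for choosing the group
count, but gives no operational definition, so silhouette alone decides in
auto mode.

## Projection under changed drivers

`project_future()` requires future values for every exogenous driver;
endogenous drivers not supplied in the scenario (future vegetation, future
organic carbon) are propagated through the fitted structural equations in
topological order — both modes are supported because external projections
of vegetation may or may not be available. Negative predicted abundances
are truncated to zero and counted (linear predictions are unbounded below;
the source is silent on this, and truncation is the conservative choice).
`lnfold_change()` replaces zeros in either matrix by half the lowest
positive *current* value over the taxon set passed in — the replacement is
per analysis call, matching the published per-class computation (half of
0.066 giving 0.033) — before taking `ln(future/current)`.
Community displacement stacks current and future samples, computes
Bray–Curtis dissimilarities, ordinates by PCoA and measures each site's
Euclidean move in the (axis 1, axis 2) plane. Gridded maps use
inverse-distance weighting (power 2, cutoff 2°, default 0.2° resolution):
the proprietary spline interpolator used in the original maps has no open
implementation, none of the downstream inference depends on the
interpolant, and IDW with a cutoff is transparent and exact at data
points.

Bray–Curtis and PCoA are delegated to `vegan` and `ape` — the standard
tools for these steps — behind the package's interfaces; the test suite
checks the hand-computable Bray–Curtis example and that PCoA reproduces a
planted planar configuration to Procrustes error < 1e-8. Negative
eigenvalues (possible for non-Euclidean dissimilarities) are reported and
their axes dropped.

## Problem sizes, determinism and limitations

Every stochastic operation takes a `seed` and restores the session RNG
state (via `withr`), so whole pipelines are reproducible from a single
integer. The simulation studies in the test suite use: 500 replicates of
n = 500 for χ² calibration; 200 replicates of n = 5,000 for coefficient
recovery (bias ≤ 0.02 on the standardized scale); 200 replicates of
n = 300 for HOF recovery; 500 permuted-trait replicates and 200 Brownian
replicates on 64-tip trees for the signal tests; n = 10,000 with a
calibrated true conditional R² of 0.5 for hold-out validation. These sizes
were chosen so each property is measured with comfortable Monte-Carlo
margins while the whole suite stays desk-scale.

Known limitations: no latent variables, robust estimators or spatial error
structures; linearity means projections extrapolate linearly outside the
observed driver range; the functional projection is a plain
community-weighted trait product (no hidden-state reconstruction or
nearest-taxon indices); and no command-line wrapper is shipped — the
exported functions and this vignette are the interface, as the package is
driven from R.
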