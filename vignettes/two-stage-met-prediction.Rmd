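---
title: "Predicting genotype performance in untested locations: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting genotype performance in untested locations: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the statistical machinery: the
two-stage model, what each tunable parameter means, how the simulators define
ground truth, the numerical choices inside the REML engine, and what the
test suite does and does not establish about real data.

## Why two stages

A multi-environment trial series couples two very different inference
problems: within a location, separating genotype signal from field trend
(replicates, rows, columns); across locations, separating genotype main
effects from genotype-by-location interaction. Fitting everything jointly is
possible but heavy and fragile; the stage-wise route fits each trial alone,
then carries the adjusted genotype means *and their precision* forward. The
price is an approximation: the full variance-covariance matrix
$\Omega_m$ of one location's adjusted means is summarized by the diagonal of
$\Omega_m^{-1}$, used as weights in the second stage. With resolvable
row-column designs and mostly-balanced data this diagonal approximation is
close, because the off-diagonal entries of $\Omega_m^{-1}$ are small relative
to its diagonal; `stage2_weights()` deliberately takes the diagonal of the
**full inverse**, not the reciprocal diagonal of $\Omega_m$ - the two differ
whenever means are correlated, and only the former reproduces generalized
least squares when $\Omega_m^{-1}$ happens to be diagonal.

### Stage I

Per location, `fit_rowcol_model()` fits
$y_{ijkl} = \mu + a_i + h_j + r_{jk} + c_{jl} + e_{ijkl}$
with fixed genotype cell means and independent random replicate, row-within-
replicate and column-within-replicate effects, by REML (via `lme4`). The
cell-means parameterization makes the adjusted means directly the fixed
effects and $\Omega_m$ the corresponding block of the inverse coefficient
matrix, with no contrast ambiguity. Rows with missing yield are dropped; a
genotype never observed at a location simply has no mean there and the
second stage can intersect genotype sets across locations.

Units: trials are commonly recorded in kg/ha while across-location results
read better in t/ha. Stage I runs in the input unit; the Stage I to
Stage II boundary (`stage2_weights()`) divides means by 1000 and
$\Omega_m$ by $10^6$, so all Stage II quantities - variance components,
MSEPD - are in t/ha and t$^2$/ha$^2$.

### Stage II

`build_stage2()` + `reml_fit()` fit, on the stacked means $y$ (location-major,
genotype within location),

$$y = 1\mu + t\beta + Z_1 a + Z_2 l + Z_3 s + Z_4 b + f,$$

* $a \sim N(0, \Gamma\sigma^2_a)$, with $\Gamma$ the identity or the
  pedigree numerator relationship matrix $A$;
* $l \sim N(0, I_M \sigma^2_l)$ - random locations are what make prediction
  for a *new* location meaningful (its BLUP is 0, its uncertainty priced in);
* $s \sim N(0, \Gamma \otimes \Pi)$ with $\Pi$ the identity
  ($I\sigma^2_s$), diagonal ($\Phi$), or factor-analytic
  ($\Sigma = \Lambda\Lambda' + \Phi$) structure over locations;
* with synthetic covariates, random per-genotype slopes $b$ joined with the
  intercepts as $(a, b) \sim N(0, G \otimes \Gamma)$, $G$ unstructured;
* $\mathrm{var}(f)$ **fixed** at $\mathrm{diag}(1/w)$ from Stage I.

No free residual scale multiplies the fixed diagonal. This is the fully
efficient weighting convention: the forwarded weights are treated as known.
A scale parameter would partly re-estimate what Stage I already estimated;
if the weights are distrusted, the right diagnostic is comparing Stage I
variance components across locations, not inflating the residual.

The twelve standard combinations (identity/diagonal/FA $\times$ without
SC/with pedigree/with SC/with both) are exposed as `grid_model("M1")` ...
`grid_model("M12")`.

## Pedigree kinship

`numerator_relationship()` uses the tabular recursion over the
topologically sorted pedigree; at a few hundred genotypes the dense matrix
is trivial and no sparse-inverse machinery is warranted. Selfing
(`parent1 == parent2`) is supported - required for a selfing crop. Parents
that never appear as entries are auto-completed as founders. Founders are
non-inbred by default (diagonal 1); `founders_inbred = TRUE` sets founder
diagonals to 2 for fully inbred line programs. Which convention a given
breeding program needs depends on how its founder lines were derived; for
highly homozygous material the inbred switch is the better description, but
the default stays at the textbook non-inbred recursion since the choice only
rescales $\sigma^2_a$ when relationship structure is homogeneous. If a
pedigree makes $A$ numerically singular, a logged ridge of $10^{-6}$ is
added before Cholesky use.

## Synthetic covariates by multivariate PLS

Dozens of environmental covariates (ECs) cannot be entered as individual
regressors with a handful of locations. `fit_pls()` therefore extracts a few
*synthetic covariates*: ECs are standardized to mean zero and unit variance
(sample, $n-1$, standard deviations, computed **only on training
locations**), then an orthogonal-scores (NIPALS) multivariate PLS regresses
the genotype-by-location mean matrix - each genotype a separate variate - on
the standardized panel. The component scores are the SC values per location.
Responses are column-centered and not scaled (all genotypes share the t/ha
unit). `project_location()` pushes a held-out location's standardized EC row
through the fitted weight/deflation sequence, so cross-validation never lets
the held-out location touch the standardization or the fit; the package
asserts this by mutating held-out data in tests.

Two reporting conventions needed a decision:

* *Variance explained* is defined on the standardized EC matrix (sum of
  squares absorbed by each deflation step over the initial total), the PLS
  biplot convention; the Y-side shares are also stored.
* *Coefficient ranking* reduces the $P \times I$ coefficient structure to
  one number per covariate: first-component weight times the sum of
  first-component response loadings. This is the natural "which covariates
  dominate the first SC" summary when one coefficient per EC is wanted; other
  aggregations (e.g. summing absolute multi-component coefficients) are
  possible and would reorder near-ties.

Inside cross-validation the SC columns are rescaled to unit standard
deviation over training locations. This is pure reparameterization (slope
scale trades off against score scale) and only conditions the optimizer.

## The REML engine

Collapsing the random-coefficient block gives the marginal covariance

$$V = (T G T' + \Pi) \otimes \Gamma + \sigma^2_l (I_M \otimes J_I) + D,$$

$T = [1 \mid t]$, $D$ the fixed residual diagonal. At a few hundred stacked
means, forming $V$ densely and factorizing it is simpler and more robust
than any structure-exploiting scheme, so the engine evaluates the REML
log-likelihood by Cholesky and maximizes it with `nlminb` using **analytic
gradients** assembled from the Kronecker blocks (the gradient of every
structure parameter reduces to sums of $\mathrm{tr}(P_{mm'}\Gamma)$-type
terms over location block pairs, computed once per iteration).

Numerical choices, in one place:

* *Parameterization*: variances as log-standard deviations; $G$ through its
  Cholesky factor with log diagonal; $\Lambda$ free with zeros imposed on the
  upper triangle ($\Lambda_{mk} = 0$ for $k > m$) for identification -
  the likelihood itself is rotation-invariant, which a test asserts.
* *Bounds*: specific variances and $\sigma^2_l$ are bounded below at
  $10^{-8}\,\mathrm{var}(y)$; an FA fit driven to that floor (Heywood case)
  is flagged on the result rather than failing.
* *Starting values*: total variance split in thirds across genotype,
  location and interaction; $\Phi$ from residual shares; the first column of
  $\Lambda$ from the leading eigenvector of the location-by-location
  covariance of the mean matrix. The FA order path (`fit_fa_order_path()`)
  warm-starts order $K{+}1$ from order $K$ and selects by AIC, ties toward
  the smaller order. AIC counts only free variance parameters (REML).
* *Convergence*: `nlminb` relative tolerance $10^{-10}$ (acceptance-style
  sweeps use $10^{-8}$), at most 500 iterations. Return codes like
  "singular convergence" - typical on ridge optima of nearly redundant
  structures - are accepted as converged only if the projected (KKT)
  gradient is numerically zero; otherwise the fit is flagged and
  cross-validation reports the fold.
* *Degenerate inputs*: a single location (location variance inestimable) or
  more variance parameters than observations error out before fitting.

BLUPs come from $\hat u = \mathrm{Cov}(u, y) V^{-1}(y - X\hat\beta)$, which a
test verifies against densely assembled Henderson mixed-model equations at
frozen parameters.

## Prediction and evaluation

For an unseen location, `predict_new_location()` returns
$z_i = \hat\mu + \sum_q t_{\mathrm{new},q}(\hat\beta_q + \hat b_{iq}) + \hat a_i$,
optionally plus the average of the genotype's interaction BLUPs over the
training locations (`main_plus_avg_interaction`). The averaging mode matters
for covariance-carrying structures (FA), where part of the genotype main
effect is absorbed into the interactions; for the identity structure both
modes coincide up to shrinkage noise.

MSEPD is evaluated over ordered pairs exactly as defined; the implementation
uses the algebraic identity
$\sum_{i \ne i'}((d_i - d_{i'})^2) = 2I\sum d_i^2 - 2(\sum d_i)^2$ per
location and is tested against a brute-force triple loop. MSEPD is invariant
to per-location additive shifts - deliberately: an unpredictable location
main effect should not dominate a ranking-oriented comparison. Spearman
correlations use average ranks for ties, are computed per location and then
averaged, with the between-location standard deviation over $\sqrt{M}$ as
standard error; constant vectors give an excluded, warned-about `NA`.

In `leave_one_location_out()`, FA folds keep the training-only
$\Lambda, \Phi$; the held-out location has no loadings, consistent with
predicting from main effects (+ SC). Non-converged folds are listed on the
result; `strict = TRUE` turns the pooled MSEPD into `NA` when any fold
failed, the default reports it over all folds with the failure list
attached.

## Simulated ground truth

The generators mirror the structures the models assume, so every stage is
testable without external data:

* `simulate_pedigree()` - founders plus generations of (possibly selfed)
  crosses;
* `simulate_ecs()` - ECs as a low-rank latent-factor matrix plus noise,
  shifted/scaled to covariate-specific units; the standardized first factor
  is exposed as the true environmental index;
* `simulate_gxl()` - genotype effects and interactions drawn with
  $\Gamma$-correlated, $\Pi$-structured covariance, SC effects through a
  true $\beta$ and per-genotype slopes on the index;
* `simulate_trials()` - randomized row-column plot layouts around the true
  cell means, in kg/ha;
* `simulate_means()` - directly forwarded Stage II means for fast checks.

One scenario seed expands into fixed per-component substreams, so changing
one component's draw does not perturb the others.

The `fullscale` scenario fixes the study scale the package targets: 6
locations, 100 genotypes from a 3-generation pedigree, 2 replicates of a
25 x 4 layout, 65 ECs. Default variance components (t$^2$/ha$^2$): plot
level $(\sigma^2_h, \sigma^2_r, \sigma^2_c, \sigma^2_e) =
(0.05, 0.02, 0.02, 0.10)$ - design effects noticeable but smaller than plot
error, typical for dryland cereal trials; second stage
$(\sigma^2_a, \sigma^2_l, \sigma^2_s) = (0.04, 0.09, 0.02)$ - locations more
variable than genotypes, interaction half the genotype variance; SC effect
$\beta = 0.15$ t/ha per index SD with slope variance $\sigma^2_b = 0.02$.
The `tiny` scenario (4 locations, 12 genotypes, direct means) exists for
fast structural checks, not for power: with three training locations a
per-genotype slope is essentially unidentifiable, and tests about SC
predictive gain therefore use six-location designs with the slope variance
dominating the residual interaction.

What the simulations do *not* emulate: spatial trend beyond rows/columns
(no AR1-type correlation), year effects, genotype-specific error variances,
non-Gaussian yields, and real envirotyping artifacts (collinearity blocks
with measurement error, missing stations). Passing tests show the machinery
recovers the structures it models under those idealizations - not that any
particular real series satisfies them.

## Problem sizes used by the test suite

Oracle comparisons run at small sizes where dense re-derivations are exact
(4-12 genotypes, 2-6 locations). Monte-Carlo checks use: 200 simulated
trials at the full 100-genotype scale for Stage I recovery (the replicate
variance has one degree of freedom per trial with two replicates, so its
Monte-Carlo spread - not estimator bias - sets the attainable tolerance
there); 100 datasets at 50 genotypes for FA order selection; 100 paired
seeds at 12 genotypes and 6 locations for the SC-gain comparison. These
sizes were chosen so each check is decisive for the property it probes
while the whole suite stays routinely runnable.

## Known limitations

* Stage II assumes a genotype set common to all locations after
  intersection; heavily unbalanced series would need the union set with
  missing-cell handling.
* The diagonal-weight approximation ignores Stage I mean covariances; with
  small, highly non-orthogonal trials a full-$\Omega_m$ second stage would
  differ more.
* No unstructured full $M \times M$ interaction covariance and no
  multi-year or multi-zone extensions; single-year, single-mega-environment
  series only.
* FA orders are limited to 3 and can exceed the information in very few
  locations; the AIC path mitigates but cannot cure overparameterization.
* Marker-based (genomic) relationship matrices are out of scope; $\Gamma$
  comes from pedigree only.
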