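---
title: "Methods: stratified instrumental-variable estimation of nonlinear exposure-outcome curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratified instrumental-variable estimation of nonlinear exposure-outcome curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lacecurve)
```

## The problem

Mendelian randomization uses a genetic variant (or a weighted allele score)
as an instrumental variable to estimate the causal effect of an exposure
$X$ on an outcome $Y$ in the presence of unmeasured confounding. Standard
IV estimators assume the exposure-outcome relationship is linear. When the
scientific question is the *shape* of that relationship — is there a
threshold? does the effect attenuate at high exposure? — a single global
slope is not enough, and a naive two-stage approach cannot help: an allele
score typically explains only 1–4% of exposure variance, so the fitted
exposure values from a first-stage regression span far too narrow a range
to reveal curvature.

`lacecurve` implements a stratified semiparametric approach. The key step
is to stratify the population not on the exposure itself (which would
induce spurious instrument-outcome associations, because the exposure is a
collider of the instrument and the confounders) but on the **IV-free
exposure**

$$x_0 = x - \hat\beta_{X|G}\, g,$$

the control-function residual after removing the genetically predicted
component. Under the assumption that the instrument's effect on the
exposure is linear and homogeneous, strata of $x_0$ preserve the IV
assumptions while sorting individuals by their non-genetic exposure level.

Within stratum $k$ the **localized average causal effect (LACE)** is a
ratio of coefficients,

$$\widehat{\mathrm{LACE}}_k = \frac{\hat\beta_{Y|G,k}}{\hat\beta_{X|G}},
\qquad
\mathrm{se}_k = \frac{\mathrm{se}(\hat\beta_{Y|G,k})}{|\hat\beta_{X|G}|},$$

where the instrument-outcome coefficient is re-estimated per stratum but
the instrument-exposure coefficient is estimated once, in the whole
population, and reused everywhere (including inside the bootstrap). The
standard error is the leading term of the delta-method expansion; the
denominator enters in absolute value so that standard errors do not change
sign with instrument orientation. Each LACE estimates the derivative of
the exposure-outcome function near that stratum's exposure level; the two
curve estimators below differ in how they assemble those derivatives into
a curve.

## Fractional-polynomial metaregression

Fractional polynomials of degree 1 and 2 over the standard power set
$P = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}$ (with $x^0$ read as $\log x$, and
repeated powers contributing an $x^p \log x$ term) form the model family.
Because the LACE are derivative estimates, the metaregression design is
the **derivative** of the candidate polynomial, evaluated at the stratum
mean exposures $\bar x_k$, and the fit is weighted least squares with
weights $1/\mathrm{se}_k^2$ and *no intercept* — the curve's constant
differentiates away, which is also why the curve itself is only identified
up to an additive constant and must be anchored ($f(x_{\mathrm{ref}}) = 0$)
at a user-chosen reference exposure.

The log-likelihood used for model comparison is the normal likelihood with
known per-stratum variances,

$$\ell = \sum_k \left[-\tfrac12 \log(2\pi v_k) -
\frac{(\widehat{\mathrm{LACE}}_k - \hat f'(\bar x_k))^2}{2 v_k}\right],
\qquad v_k = \mathrm{se}_k^2\ (+\ \tau^2),$$

the same likelihood a fixed-effects meta-regression maximizes. All
degree-1 models have one parameter and all degree-2 models two, so
within-degree comparison by raw likelihood is equivalent to AIC; degree 2
is preferred over degree 1 only when twice the log-likelihood gain exceeds
the 95th percentile of $\chi^2_2$. An alternative with estimated residual
dispersion (the profile likelihood of an ordinary weighted `lm`) was
considered and rejected: under a badly misspecified family (a threshold
relationship) both candidate models fit poorly, the dispersion estimate
absorbs the misfit, and the likelihood-ratio test of nonlinearity loses
most of its power; the known-variance likelihood keeps it. The
known-variance version is mildly conservative under the null (empirical
size around 0.03 at a nominal 0.05), which we consider the better side to
err on.

Random-effects metaregression adds a between-stratum variance $\tau^2$
estimated by the DerSimonian–Laird moment estimator (generalized to a
design matrix, truncated at zero) and refits with weights
$1/(\mathrm{se}_k^2 + \tau^2)$. Fixed effects are the default; analytic
95% bands use the normal multiplier 1.96 on
$\sqrt{d^\top V d}$ with $d$ the anchored basis vector, not $t$ quantiles,
consistent with the normal-likelihood framing.

Ties in the likelihood (rare outside of degenerate inputs) are broken
toward the lower degree, then toward powers closest to 1, i.e. toward the
most interpretable model. Extreme power/exposure combinations (e.g.
$x^{-2}$ near zero) are allowed to overflow and are reported as estimation
errors rather than silently clipped.

## Piecewise linear curve

The piecewise linear estimator assigns stratum $k$ a segment with slope
$\widehat{\mathrm{LACE}}_k$ and concatenates segments continuously. The
segment boundaries are not dictated by the method; we place them at the
observed-exposure midpoints between adjacent strata
($b_0 = \min x$, $b_K = \max x$,
$b_k = (\max_{i \in k} x_i + \min_{i \in k+1} x_i)/2$), which puts every
individual's exposure inside its own stratum's segment. Because strata are
formed on the IV-free exposure, observed-exposure ranges can overlap
slightly; with very many strata a midpoint can occasionally fall below its
predecessor, in which case it is collapsed onto the previous breakpoint
(a zero-width segment), preserving continuity and the slope-to-stratum
mapping. The whole curve is shifted so $f(x_{\mathrm{ref}}) = 0$.

Confidence bands come from a within-stratum bootstrap: individuals are
resampled with replacement independently inside each stratum, only the
instrument-outcome coefficients are re-estimated (strata memberships,
stratum mean exposures and $\hat\beta_{X|G}$ stay frozen at their original
values), the curve is rebuilt per replicate, and pointwise 2.5th/97.5th
empirical percentiles (linear-interpolation quantiles) are taken at the
stratum mean exposures. A resampled stratum in which the instrument is
constant is redrawn, up to a retry cap — a signal that the chosen number
of strata is too large for the variant's frequency.

## Tests of nonlinearity

Three tests operate on the LACE table:

* **Cochran Q**: $Q = \sum_k w_k (\widehat{\mathrm{LACE}}_k - \bar L)^2$
  with $w_k = 1/\mathrm{se}_k^2$ and $\bar L$ the inverse-variance-weighted
  mean, against $\chi^2_{K-1}$.
* **Quadratic trend**: weighted regression of the LACE on $\bar x_k$ with
  intercept; a Wald $z$ on the slope (equivalent to testing a quadratic
  exposure-outcome model). We use the normal reference rather than a $t$
  with $K-2$ df, consistent with the known-variance framing; at $K = 10$
  the difference is visible only in the far tail.
* **Fractional-polynomial likelihood ratio**: twice the log-likelihood gap
  between the best degree-1 polynomial and the linear model against
  $\chi^2_1$; the statistic is exactly zero when the best-fitting power is
  1.

A companion utility reports the *set* of near-best models: all same-degree
candidates whose twice-log-likelihood deficit against the best model is
below the 90th percentile of $\chi^2_m$ ($m$ = degree).

## The simulation module

`scenario_config()`/`generate_cohort()` implement the generative model

$$x_i = 2 + 0.25\, g_i + u_i + \varepsilon_{Xi}, \qquad
  y_i = h(x_i) + 0.8\, u_i + \varepsilon_{Yi},$$

with $g_i \sim \mathrm{Bin}(2, 0.3)$, $u_i \sim U(0,1)$ an unmeasured
confounder, $\varepsilon_{Xi} \sim \mathrm{Exp}(1)$,
$\varepsilon_{Yi} \sim N(0,1)$, and defaults $n = 10{,}000$, $K = 10$
strata, 500 replicates, 500 bootstrap samples. The exposure is bounded
away from zero (its minimum exceeds 2) so that log and negative-power
curves are well defined; the instrument explains roughly 2.5% of exposure
variance, a realistic figure for an allele score. The exposure-outcome
family $h$ covers degree-1/degree-2 fractional polynomials, linear,
quadratic, square-root, logarithmic, and a **threshold** relationship. The
threshold is implemented as the continuous hinge
$h(x) = \beta \max(x - 3.65, 0)$ (the knot sits at the population mean
exposure): a flat regime followed by a linear one, the canonical shape for
"harm only above a cutoff" questions.

Violation settings relax the homogeneity assumptions: individual-level
instrument effects $N(0.25, 0.1^2)$, individual-level causal coefficients
$N(\beta, 0.2^2)$ (for degree-2 curves only the second coefficient
varies), optionally correlated at 0.2; a rare, strong variant
(MAF 0.03, effect 0.75); and superadditive (increments 0.1 then 0.3) or
subadditive (0.3 then 0.1) genotype effects.

Reproducibility: a master seed draws one independent sub-seed per
replicate (plus one per replicate for its bootstrap), so results are
bit-identical regardless of execution order and replicates could be run in
parallel without changing the output.

### Evaluation conventions

The experiment drivers report the metrics a simulation study of these
estimators needs: bias and empirical/analytic SDs of the fitted
coefficients, coverage of 95% intervals, the proportion of replicates in
which the correct polynomial is the best-fitting or near-best model, test
rejection rates, and a curve-fit heuristic
$\sum_{k=1}^{10} |\hat{\bar y}_k - \bar y_k|$ — the absolute prediction
error summed over the ten decile mean exposures, always computed on ten
deciles no matter how many strata the estimator used. For comparisons
against the true curve, both the fitted and the true curve are anchored at
the **minimum observed exposure**; this makes the true anchored values of
the threshold model equal $h(\bar x_k)$ directly and is the convention
under which the piecewise estimates are essentially unbiased for
piecewise-true models.

Coverage of the piecewise bands and of the metaregression intervals is
assessed with analytic SEs for the polynomial coefficients and bootstrap
percentile bands for the piecewise curve, mirroring how each method would
be used in practice.

### Problem sizes

The defaults (500 replicates of $n = 10{,}000$, 10 strata) are the scale
at which the statistical properties of these estimators stabilize, and a
full coefficient-recovery or power experiment at that scale runs in a few
seconds on a single core because all per-stratum regressions use the
closed-form simple-regression path. Unit tests use smaller cohorts
(n = 2,000–4,000, 20–30 replicates) where only correctness, not
Monte-Carlo precision, is at stake.

### What the generator does and does not emulate

The simulated cohorts share the qualitative features of a biobank-scale
Mendelian randomization analysis — a weak instrument, skewed positive
exposure, unmeasured confounding acting on both exposure and outcome — but
they are idealized: a single perfectly measured instrument, no covariates,
no selection, no measurement error in the exposure, and an exactly
homogeneous causal function unless a violation setting says otherwise.
Passing tests therefore demonstrate that the estimators do what their
theory promises under those conditions; they do not certify behavior under
exposure measurement error (known to blur thresholds), population
stratification, or instrument misspecification beyond the violation
scenarios provided.

## Degenerate inputs and numerical choices

* Quantile strata are assigned by rank with stable original-order tie
  breaking; stratum sizes differ by at most one.
* `estimate_lace()` requires at least 3 individuals and a non-constant
  instrument per stratum, and names the offending stratum otherwise.
* The metaregression refuses fewer strata than coefficients + 1; model
  selection requires at least 4 strata.
* Bootstrap percentile bands are clipped to contain the point estimate, so
  the reported interval always brackets the curve.
* All tabular output is written with 12 significant digits; reading a
  written table reproduces the values to full precision.

## Known limitations

* The LACE interpretation rests on a homogeneous, linear instrument-
  exposure effect; the package tests this indirectly (heterogeneity of
  instrument-exposure associations across strata can be examined by
  running the nonlinearity tests with the exposure as the outcome) but
  cannot verify it.
* Only a single instrument (variant or score) is supported; multi-
  instrument two-stage estimators are out of scope.
* Degree-3+ polynomials are not offered; in practice degree 2 already
  covers the shapes these analyses distinguish.
* Uncertainty in the piecewise breakpoint locations is ignored, as the
  breakpoints are order statistics of a large sample and their variability
  is negligible relative to the slope uncertainty.
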