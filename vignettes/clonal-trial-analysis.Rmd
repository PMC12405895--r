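---
title: "Analysing multi-environment clonal trials with clonegx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing multi-environment clonal trials with clonegx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonegx)
```

## The problem

A clonal trial plants many ramets (rooted cuttings) of each candidate
genotype in randomized complete blocks at two or more sites. Because the
same genotypes are replicated within and across environments, the total
genetic value of each clone is estimable directly — no pedigree needed —
and so is the extent to which clone rankings change from site to site
(genotype-by-environment interaction, G×E). `clonegx` covers the full
analysis of such trials for growth traits measured on every tree and wood
traits measured on one tree per plot: variance components and BLUP
genotypic values, derived genetic parameters, two-trait index selection,
and per-clone stability.

## Model and estimation

For a single trait the observation model is

$$Y_{ijkl} = \mu + S_i + B(S)_{j(i)} + C_k + (S{\times}C)_{ik} +
  (B(S){\times}C)_{j(i)k} + \varepsilon_{ijkl},$$

with site and block-within-site fixed and four independent zero-mean normal
random strata: clone $\sigma^2_C$, site-by-clone $\sigma^2_{S\times C}$,
plot $\sigma^2_{B(S)\times C}$ (the block-by-clone interaction, i.e. the
experimental error of a multi-tree plot), and the within-plot residual
$\sigma^2_\varepsilon$. When only one measured tree remains per plot the
plot effect is confounded with the residual; `fit_clonal_model()` detects
this and drops the plot stratum (the table convention is a dash). The
single-site reduction (`fit_site_model()`) removes the site and
site-by-clone terms.

Estimation is REML on the profiled restricted likelihood: variance *ratios*
$\gamma_r = \sigma^2_r/\sigma^2_\varepsilon$ are optimized on the log scale
(Nelder–Mead, or Brent when one ratio; relative tolerance `1e-9`, at most
600 iterations), the residual variance is profiled analytically, and a
damped Newton polish with numerical derivatives sharpens the optimum to
well below test tolerances. Each evaluation solves the sparse mixed-model
equations with a reused symbolic Cholesky factorization, so a fit of a
3,500-tree trial takes about a second. Fixed effects use sum-to-zero
coding, which makes $\hat\mu$ the grand expectation and leaves clone BLUPs
centred near zero.

Numerical choices worth knowing:

* **Non-negativity and boundaries.** The log-ratio scale keeps components
  positive; ratios below $10^{-6}$ are reported as exactly 0 with a missing
  standard error (the "0 (.)" convention of variance-component tables) and
  their BLUPs as 0.
* **Degenerate data.** If all ramets of every clone agree exactly, the
  restricted likelihood is unbounded as
  $\sigma^2_\varepsilon \rightarrow 0$. The engine detects the collapse
  (ratio at its numerical bound $e^{18.5}$), pins the residual at a
  negligible floor, re-estimates the remaining components at that value —
  recovering the natural limit, e.g. the between-clone variance — and
  reports the residual as a boundary zero with no log-likelihood.
* **Component covariance.** The asymptotic covariance of the interior
  components is the inverse observed information, computed by scaled
  central differences (steps of 2% of each component; variance likelihoods
  are shallow, so absolute-step differencing loses all precision). It feeds
  every Delta-method standard error; boundary components are treated as
  known zeros there.
* **Likelihood-ratio tests.** Variance components sit on the boundary of
  the parameter space under the null, so `lrt_variance_component()` uses
  the one-tailed equal mixture $0.5\chi^2_0 + 0.5\chi^2_1$:
  $p = 0.5\,P(\chi^2_1 \ge LR)$, and $p = 0.0625$ exactly when the
  $\chi^2_1$ tail is 0.125.

The bivariate model (`fit_bivariate_model()`) stacks two traits with
trait-specific fixed effects and unstructured $2\times2$ covariance
matrices for clone, site-by-clone, and residual, the latter coupling only
the two measurements of the same tree; the plot stratum is omitted so the
same model serves every pair, including wood traits carried by one ramet
per plot. Covariances are parameterized by log-diagonal Cholesky factors
(positive semi-definite by construction); stratum correlations converging
to $|r| > 0.999$ are clamped and flagged rather than reported as spuriously
precise. Whether the marginal components should be constrained to the
univariate estimates is left open by the usual descriptions of this
analysis; here all nine parameters are estimated jointly, and on complete
balanced data the marginals agree with the univariate fits.

## Derived parameters

From a univariate fit: $CV_G = 100\,\sigma_C/\bar Y$; clonal repeatability
$H^2 = \sigma^2_C/\sigma^2_P$ with $\sigma^2_P$ the sum of the model's
components; type-B correlation
$r_B = \sigma^2_C/(\sigma^2_C+\sigma^2_{S\times C})$; and the interaction
ratio $\sigma^2_{S\times C}/\sigma^2_C$, flagged above 0.5 — the classical
threshold at which G×E materially erodes gains from joint selection, and
which corresponds to $r_B = 2/3 \approx 0.67$. From a bivariate fit: the
type-A genotypic correlation
$r_A = \sigma_C(Y_1,Y_2)/\sqrt{\sigma^2_C(Y_1)\sigma^2_C(Y_2)}$ and the
three-stratum phenotypic correlation (clone + site-by-clone + residual
covariances over the product of summed variances). Standard errors are
Delta-method with analytic gradients. Reported rounding follows the
conventions of variance-component tables (2 decimals for ratios, 1 for
percentages); full precision is kept internally.

The package ships the published REML variance components of four black
spruce breeding populations (`reference_components()`) as an arithmetic
consistency surface: the test suite recomputes every derived cell
($\sigma^2_P$, $H^2$, $r_B$, ratio, percentage shares) from the printed
components and matches the printed values after rounding. Thirteen cells
differ by exactly one unit in the last printed decimal because the source
derived them from unrounded components; these are asserted within one unit
and listed in `tests/testthat/test-acceptance.R`.

## Selection index

Clone ranking uses adjusted genotypic values $V_{G,adj} = \hat C_k + \bar Y$
(`adjusted_genotypic_values()`), standardized across clones with the sample
SD (`standardize_vg()`; the common alternative, the population SD, rescales
both traits identically and changes nothing downstream). The two-trait
index $SI = w_1 V_{G,1,std} + w_2 V_{G,2,std}$ is scanned over a weight
grid (step 0.01), reselecting the top $k = 10$ at every grid point; each
trait's relative gain is the selected group's mean genotypic value as a
percentage of the best single-trait selection. Because reselection makes
the curves step functions, they can cross more than once; the crossing is
defined as the mean of all interpolated zero crossings — identical to the
unique crossing when the curves are monotone, and exactly 0.5 for
swap-symmetric traits — then rounded to the nearest 0.05. Ties anywhere are
broken by clone identifier, so results are deterministic. Selection
differentials divide the selected group's mean genotypic value by the
overall trait mean, for any trait including ones outside the index.

## Stability indexes

Both stability measures work on the clones-by-sites matrix of per-site
adjusted genotypic values from the *multi-site* fit,
$V_{G,adj,ij} = \bar Y_{.j} + \hat C_i + \widehat{(S{\times}C)}_{ij}$
(`per_site_adjusted_vg()`); the composition of that matrix is a package
decision, since "clone BLUPs on each site" admits several readings, and the
phenotypic site mean puts the values on the observation scale.

* **HMRPGV**: the harmonic mean over sites of the clone's value relative to
  the site mean. The harmonic mean penalizes dips, so it blends mean
  performance with stability. The site reference mean defaults to the mean
  of the adjusted values at the site (option: phenotypic site mean; they
  coincide on balanced data).
* **BLUP-ecovalence**: the clone's contribution to the interaction sum of
  squares of the double-centered matrix,
  $W_i = \sum_j (V_{ij} - \bar V_{i.} - \bar V_{.j} + \bar V_{..})^2$,
  also expressed as a percentage of $\sum_i W_i$. Some descriptions print
  the last term with a minus sign; with that sign $W$ does not vanish for
  perfectly stable (parallel-profile) clones, contradicting the
  interpretation of low $W$ as stability, so the standard double-centered
  form is the default and the printed-sign variant is available as
  `centering = "printed_sign"` for comparison.
* **Significance**: $W$ is linearly related to the Shukla stability
  variance, $\hat\sigma^2_i = [n(n-1)W_i - \sum_j W_j] /
  [(n-1)(n-2)(E-1)]$; each clone is tested one-sided against the pooled
  interaction mean square with an approximate $F_{(E-1),\,(n-2)(E-1)}$
  ratio at $\alpha = 0.05$. With $E = 2$ environments the numerator has a
  single degree of freedom; the test is fragile there, the report carries
  `numerator_df` so users can see it, and simulation shows that moderate
  single-site disruptions (3 interaction SDs) are caught by the ecovalence
  *ranking* long before they reach formal significance — outright
  significance at high power requires much grosser disruptions.

## The simulator

`simulate_clone_trial()` draws data under exactly the model above: a
complete design (every clone in every block of both sites), fixed site
shifts (default $\pm5\%$ of the trait mean), seeded fixed block effects
(SD 2% of the mean), then clone, site-by-clone, plot and residual draws in
a fixed order from one stream, so a seed fully determines the table.
Defaults mirror the reference trial series: 2 sites, 10 blocks, 2-tree
plots, 100 clones from 55 families (family labels are cosmetic — family is
not a model term — and are assigned round-robin), trait means and variance
strata set to published REML estimates for boreal spruce (height mean
532 cm with strata 1159.3 / 176.5 / 1232.7 / 3439.9 cm²; Pilodyn and
acoustic velocity likewise), 10% independent ramet mortality, and wood
traits retained on one surviving ramet per plot. Real mortality is often
clustered (e.g. a drought year); `mortality_clustered = TRUE` removes whole
plots instead, as a stress-test variant. Ramet counts per clone are
exposed through the design constants rather than inferred per clone.
`simulate_bivariate_trial()` draws correlated clone, site-by-clone and
residual effects for a trait pair (no plot stratum), matching the bivariate
model.

What passing tests on these simulations do *not* show: the generator has no
spatial autocorrelation, no competition between neighbours, no
heteroscedasticity across sites, and independent (not clustered)
missingness by default — so the suite validates the estimators under the
stated model, not robustness to field artefacts beyond it.

## Problem sizes used in the test suite

The suite's simulation scales were chosen once as the smallest designs
that keep Monte-Carlo error well inside the asserted tolerances: the
parameter-recovery study runs 200 replicates of the full reference design
(88 clones, 2 sites, 10 blocks, 2-tree plots, 10% mortality); Delta-SE
calibration uses 60 replicates of a 40-clone reduction; bivariate recovery
uses 8 replicates of 120 clones with single-tree plots; the Shukla size
check uses 500 simulated value matrices of 80 clones; rank-agreement and
flag-count monotonicity use 12–15 replicates per configuration. The
12-clone selection fixture is enumerable exhaustively, which is what its
oracle does.

## Limitations

Breeding values (additive effects) are out of scope: with 1–2 clones per
family the clone-within-family structure cannot separate additive from
non-additive variance, so no pedigree model is fitted. The residual
variance is homogeneous across sites by model definition. Stability with
two sites rests on a 1-df contrast per clone; conclusions about individual
clones are correspondingly soft, which is why the package reports both the
index and the significance flag rather than a single verdict.
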