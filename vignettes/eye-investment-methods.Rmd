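---
title: "Methods: phylogenetic eye-body allometry and investment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phylogenetic eye-body allometry and investment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of its statistical machinery:
the models, the estimation choices, the synthetic-data generator that
stands in for real specimen data, and the places where a design decision
was genuinely open.

## The regression model

All trait values enter as base-10 logarithms of species means. Body size
is the cube root of wet mass (`RM`, mm-equivalent), so isometry between
eye diameter and body size sits at slope 1 and slopes below 1 are
hypoallometric. The core model is

$$y = X\beta + \varepsilon, \qquad
  \varepsilon \sim \mathcal N(0,\; \sigma^2 C(\lambda)),$$

where $C$ is the phylogenetic covariance of the pruned analysis tree
($C_{ij}$ = shared root-to-tip branch length, $C_{ii}$ = root-to-tip
distance) and Pagel's $\lambda \in [0,1]$ multiplies the off-diagonal
entries. $\lambda$ interpolates between a star phylogeny
($\lambda = 0$, ordinary least squares) and full Brownian covariance
($\lambda = 1$). The assumptions are those of any PGLS: a linear
relationship on the log scale, Gaussian residual variation whose
correlation follows shared ancestry, and a single $\lambda$ for the
whole residual field.

**Estimation.** The fit whitens through the Cholesky factor
$C(\lambda) = LL^\top$: coefficients are ordinary least squares on
$(L^{-1}X, L^{-1}y)$, which equals
$(X^\top C^{-1}X)^{-1}X^\top C^{-1}y$ without ever forming $C^{-1}$.
$\hat\lambda$ maximizes the profile log-likelihood (with $\beta$ and
$\sigma^2$ profiled out analytically) over a 21-point grid on $[0,1]$
followed by bounded scalar optimization in the bracketing interval,
absolute tolerance $10^{-6}$; the endpoints 0 and 1 always remain
candidates. ML (not REML) is used throughout. If the profile is flat
(a star tree has no information about $\lambda$), the fit flags it and
reports $\lambda = 0$ by convention.

**Conventions.** $\hat\sigma^2$ uses the ML divisor $n$ inside the
likelihood; coefficient standard errors use the residual-df divisor
$n - p$. $R^2 = 1 - \mathrm{RSS}/\mathrm{TSS}$ is computed in the
whitened space with TSS taken about the GLS-estimated mean under the
same $C(\hat\lambda)$ — the convention of the standard comparative
software this workflow mirrors. Factors are dummy-coded with treatment
contrasts and the alphabetically first state as reference.

**Outlier sensitivity.** Residuals are externally Studentized in the
whitened space, $t_i = e_i / (s_{(-i)}\sqrt{1 - h_{ii}})$ with the hat
matrix of the whitened design; with a diagonal covariance these equal
textbook OLS `rstudent` values. `iterative_outlier_refit()` repeatedly
refits (re-estimating $\lambda$), removes the single worst species with
$|t_i| > 3$ (alphabetical tie-break, so the procedure is deterministic),
and reports every removal and the coefficient drift. This is a
sensitivity check, not a cleaning step: the headline fits use all
species.

## SMA, isometry and the calibration transform

The standardized major axis treats both log axes symmetrically:
$|b_{\text{SMA}}| = s_y / s_x$ with the sign of the correlation (so
$b_{\text{SMA}} = b_{\text{OLS}} / r$, an identity the tests assert at
$10^{-10}$). The slope test against $b_0$ uses the correlation between
the residual axis $y - b_0 x$ and the fitted axis $y + b_0 x$;
$F = r'^2 (n-2)/(1 - r'^2)$ on $(1, n-2)$ df. With $b_0 = 1$ this is the
isometry test. The robust variant replaces the moments with iteratively
reweighted Huber estimates (tuning constant 1.345, weights from the
scaled SMA residual axis, convergence when coefficients move less than
$10^{-8}$, at most 100 iterations); on clean data the weights are ~1 and
the fit is close to least-squares SMA. Robustness is switched per fit,
never auto-detected.

Axial eye length cannot be measured on intact museum specimens, so
`ed_to_al_calibration()` fits the OLS transform
$AL = a + b \cdot ED$ on raw millimetres from paired fresh-specimen
measurements and applies it to species means (the choice of species
means over specimen values is logged; at the calibration's $R^2 \approx
0.96$ the difference is negligible).

## Ecology tests

Eye investment is $10^{\text{residual}}$ from the PGLS of log eye
diameter on log cube-root mass (variants relative to snout–vent length,
and corneal investment relative to eye diameter, are selectable). A
residual of 0.2 is therefore an eye $10^{0.2} \approx 1.6\times$ the
predicted diameter. Because residuals are taken on the log scale,
`log10(investment)` recovers the residual exactly.

Kruskal–Wallis tests use the tie-corrected $H$ with the $\chi^2_{k-1}$
approximation (no exact small-sample tables; a warning flags groups with
$n < 5$). The phylogenetic ANCOVA fits
`response ~ covariate * state` by PGLS (ML $\lambda$) and decomposes it
with sequential (Type I) sums of squares in the whitened space, in
formula order — covariate, state, interaction — so the state term is
tested after body size, and the sequential SS plus the residual SS
reconstruct the whitened total SS exactly. Missing states are handled by
listwise deletion within each ecological model only: a species missing
one trait still contributes to every other analysis.

## The synthetic-data generator

The generator emulates a museum study of ~220 species sampled across a
clade, with known ground truth:

| parameter | default | why |
|---|---|---|
| species | 220 | study scale |
| tree | Yule, rate 1, rescaled to unit depth | neutral clade shape; unit depth makes variances tip variances |
| slope / intercept | 0.82 / 0.5 | hypoallometric eye–body scaling; intercept puts a 10 g frog at ~6 mm eyes |
| $\lambda$ | 0.96 | strong phylogenetic residual signal |
| predictor variance | 0.09 log10² | log10 RM sd 0.3: masses spanning roughly 1–300 g |
| residual variance | set so the fitted eye–body $R^2 \approx 0.80$ | the habitat offsets are part of the residual field, so the noise variance is the $R^2$-implied total minus the stationary offset variance |
| habitat offsets | log10 of 0.65× (fossorial) … 1.24× (scansorial) | per-state investment factors used as additive truths |
| habitat process | Markov jumps to stationary frequencies; auto rate targets max(12, 0.085 n) transitions tree-wide | habitat use is strongly clade-conserved; the walk is redrawn (rate escalating) until every guild has ≥ 5 species, like a design that samples all guilds |
| specimens | 1–7 per species, lognormal noise cv 3% | caliper-scale measurement error; positive lengths are multiplicative |
| preservation | linear shrinkage 0.95 (mass by its cube) | preserved vs fresh contrast; 67 species get a fresh specimen with dissected axial length |

Cornea and snout–vent length follow their own scaling relations
(slopes 0.92 and 0.98, $\lambda$ 0.40 and 0.75, variances set from
$R^2 \approx 0.96$ analogues). Everything is reproducible bit-for-bit
from the seed (R's default Mersenne-Twister RNG); the ground truth is
attached to every dataset so recovery can be scored automatically.

**What it does not emulate.** Real anatomical covariance beyond simple
proportionality-plus-noise; biogeography; non-Gaussian residuals;
habitat states that covary with body size by construction (any such
correlation in a draw is chance). Passing recovery tests therefore shows
the estimators are correct under the stated model, not that the model is
right for any particular empirical dataset.

## Numerical choices and edge cases

- Tip labels: spaces and underscores are interchangeable on read;
  underscores internally.
- Grafted tips copy the sister's terminal branch length, which keeps the
  pair exchangeable (equal depths, mutual distance twice the pendant
  branch). Grafting is direct edge-matrix surgery, so existing branch
  lengths are bit-identical afterwards.
- Polytomy resolution inserts zero-length edges, so the induced
  covariance — and every downstream fit — is invariant to the (seeded)
  resolution.
- Phylogenetically identical tips (duplicate covariance rows) get a
  diagonal jitter of $10^{-8} \times$ tree depth, with a warning.
- A constant response in OLS reports $R^2 = F = 0$ rather than the
  numerical noise of a zero-variance fit; a constant sample in
  Kruskal–Wallis reports $H = 0$.
- Ties in the outlier scan are broken alphabetically; removal stops if
  it would leave $n \le p + 2$.

## Known limitations

- **Near-boundary $\lambda$ and plug-in F tests.** The sequential
  ANCOVA treats $\hat\lambda$ as known. When the true $\lambda$ is close
  to 1, $\hat\lambda$ overshoots to the boundary in a nontrivial
  fraction of replicates, and whitening at an overestimated $\lambda$
  inflates the contrasts between close relatives — the factor F test
  then runs liberal. The test suite calibrates the type-I error at an
  interior $\lambda$ (0.5), where the test holds its nominal 5% size;
  near the boundary, treat factor p-values as anticonservative and lean
  on the Kruskal–Wallis test, which does not depend on $\lambda$.
- **Attenuation between noisy proxies.** Regressing one proxy on
  another (eye diameter on snout–vent length) attenuates the slope when
  the predictor carries its own independent deviations, and the
  whitening magnifies this when those deviations are less
  phylogenetically structured than the shared body-size signal. The
  generator's independent-noise chain therefore recovers ED~SVL slopes
  somewhat below the product-implied value, while ED~RM (the canonical
  investment baseline) is unbiased.
- **Clumped states at moderate n.** With strongly clade-conserved
  states the effective number of independent state blocks is small, so
  per-state investment means have wide seed-to-seed spread; the
  acceptance script reports medians over replicate datasets for this
  reason (9 replicates of the full 220-species pipeline).
- Problem sizes in the shipped tests (trees of 20–220 tips, 250–500
  Monte-Carlo replicates for calibration properties) were chosen as the
  smallest sizes at which the statistical assertions are stable.
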