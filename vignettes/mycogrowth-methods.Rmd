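---
title: "Methods: growth modelling and mycorrhizal community analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: growth modelling and mycorrhizal community analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`mycogrowth` links annual tree growth to soil nitrogen availability and
to the diversity and turnover of arbuscular mycorrhizal fungal (AMF)
communities sampled around individual trees.  This vignette documents
the statistical machinery, the assumptions behind it, and the design
choices that were genuinely open.

## From ring widths to basal area increment

Each tree contributes up to two increment cores (north and south), each
measuring one radius.  `reconstruct_dbh()` averages the cores' ring
widths per year — each core is one radius, so twice the mean width is
the annual diameter increment — and works backwards from the
field-measured diameter at breast height (DBH) in the final year.
Basal area increment (BAI, cm² yr⁻¹) for year *y* is the annulus area

$$\mathrm{BAI}_y = \pi\left[\left(\tfrac{D_y}{2}\right)^2 -
\left(\tfrac{D_{y-1}}{2}\right)^2\right],$$

which telescopes: summed over a series it equals the basal-area
difference between the last and first diameters.  This identity is the
main internal consistency check.

Two quantities support chronology quality control.  The expressed
population signal, $\mathrm{EPS} = n\bar r / (1 + (n-1)\bar r)$, uses
the mean pairwise Pearson correlation $\bar r$ of raw ring-width series
over common years; the package does not detrend before correlating,
which is a documented limitation (standardization can raise or lower
$\bar r$ substantially in closed-canopy stands).  When a core misses
the pith, `estimate_pith_offset()` applies the geometric arc method:
for an innermost ring arc of chord $L$ and height $h$, the missing
radius is $L^2/(8h) + h/2$; arcs flatter than a tolerance are rejected
because the estimate diverges as $h \to 0$.

Bark is ignored throughout: the measured DBH is treated as wood
diameter.  Whether cores should be averaged before or after diameter
reconstruction is not determined by the data model; the package
averages increments first, which keeps the reconstruction exact when
the two cores bracket the true radius.

## The hierarchical growth model

For each species separately, BAI of tree $i$ in year $y$ follows a
log-normal likelihood

$$\mathrm{BAI}_{i,y} \sim \mathrm{logNormal}(D_{i,y},\ \sigma^2_{i,y}),$$

$$D_{i,y} = \alpha + \beta_1\,\mathrm{Nmin}_i +
\beta_2\,\mathrm{BAI}_{i,y-1} + \beta_3\,\ln \mathrm{DBH}_{i,y-1} +
\beta_4\,\mathrm{MayMinTemp}_y + \mathrm{SERE}_i,$$

with a variance that grows with tree size,
$\sigma^2_{i,y} = a + b\,\ln \mathrm{DBH}_{i,y-1}$, and spatially
explicit random effects (SERE) absorbing within-site dependence not
captured by the covariates.  The SERE vector is zero-mean multivariate
normal with an exponential distance-decay kernel, blocked by site:

$$\Sigma_{ij} = \sigma^2_{\mathrm{SERE}}\, e^{-\varphi\, d_{ij}}
\quad\text{(same site)},\qquad \Sigma_{ij}=0 \text{ across sites},$$

with $\varphi = e^\theta$.  Sites are far enough apart (kilometres)
that cross-site dependence is fixed at zero.  Log diameter enters both
the mean and the variance as the *previous* year's value — size at the
start of the growth year — with the same column used in both places.

Priors follow the weakly informative set standard for this model class,
with second parameters read as precisions (the JAGS convention):
$\alpha \sim U(0,5)$, $\beta_k \sim N(0,1)$,
$a \sim \mathrm{logN}(1, \mathrm{prec}\ 0.001)$,
$b \sim N(0, \mathrm{prec}\ 0.001)$, $\theta \sim N(0,1)$,
$\sigma^2_{\mathrm{SERE}} \sim U(0,10)$.  These are only weakly
informative if the covariates are standardized, so `build_design()`
z-scores the four covariates by default and stores the transform for
back-conversion; coefficients are therefore reported per standard
deviation of each covariate.

### Sampling and diagnostics

`run_mcmc()` is an adaptive Metropolis-within-Gibbs sampler.  Scalar
parameters take Gaussian random-walk proposals whose log step sizes
adapt in batches of 50 during burn-in toward a 0.44 acceptance rate and
are frozen afterwards.  The SERE vector is updated jointly by
elliptical slice sampling under its multivariate-normal prior, which
requires no tuning.  Proposals that would make
$a + b\,\ln\mathrm{DBH} \le 0$ on any row, or leave a prior's support,
are rejected outright (density $-\infty$).

Two parameterization ridges make naive component-wise sampling mix very
slowly: the intercept trades off against the mean of the random
effects, and the slope of any covariate with a strong tree-level
component (N mineralization exactly; lag BAI and log DBH approximately)
trades off against tree-level SERE contrasts.  The sampler therefore
adds joint moves that shift a scalar and absorb the corresponding
tree-level component into the SERE vector; for the intercept and for
tree-level covariates these moves leave the likelihood exactly
invariant and are accepted on the prior ratio alone.  With them, split
R-hat on all scalar parameters is at or below about 1.01 at 3 chains ×
3000 iterations on a 60-tree, 40-year design (the analysis default is 3
× 10,000 with the first half as burn-in and kept draws pooled up to
50,000).

Convergence is judged by split-chain R-hat ≤ 1.1 on every scalar
parameter (burn-in discarded, each chain split in half); this threshold
is a package choice of standard practice.  `compute_dic()` reports
$\mathrm{DIC} = \bar D + p_D$ with $p_D = \bar D - D(\bar\theta)$,
where the deviance is the data likelihood conditional on the random
effects and $\bar\theta$ averages all parameters (SERE elementwise).
Goodness of fit is the squared Pearson correlation between observed
$\ln\mathrm{BAI}$ and the posterior-mean linear predictor; because the
response is modelled on the log scale and summarized on both, the fit
object reports $R^2$ on the log and the natural scale.

## Richness and its regressions

Community analysis starts from the ASVs shared between the two host
maples: `filter_shared()` keeps taxa observed on at least one tree of
*each* species and, by default, on at least two trees overall.  The two
rules are exposed separately because they produce different community
sizes, and both counts are logged.  Chao1 richness per tree,

$$S_{\mathrm{Chao1}} = S_{obs} + \frac{F_1(F_1-1)}{2(F_2+1)}
\ \text{(bias-corrected, default)},\qquad
S_{obs} + \frac{F_1^2}{2F_2}\ \text{(classic)},$$

uses singleton ($F_1$) and doubleton ($F_2$) counts and requires
integer counts; the classic form falls back to the bias-corrected one
when $F_2 = 0$.  No rarefaction or coverage standardization is applied
— samples below a configurable read-depth floor are dropped instead,
and depth disparities are the user's to inspect.  Richness is then
regressed by ordinary least squares on per-tree mean BAI and on net N
mineralization, reporting the slope-test $F$ with $(1, n-2)$ degrees of
freedom and $\mathrm{adj}\,R^2 = 1 - (1-R^2)(n-1)/(n-2)$.

## Threshold indicator taxa analysis

For community turnover the package implements a from-scratch threshold
indicator taxa analysis on Hellinger-transformed abundances
($\sqrt{\text{count}/\text{sample total}}$).  For each taxon and each
candidate change point — midpoints between consecutive distinct sorted
gradient values leaving at least `min_split = 5` samples per side — the
Dufrêne–Legendre indicator value of the better-indicated group
($\mathrm{IndVal} = A \cdot B$, specificity times fidelity, on the 0–1
scale) is compared to a permutation null built by shuffling abundances
across samples; the score is $z = (\mathrm{IndVal}_{obs} -
\mu_{perm})/\sigma_{perm}$, and the change point maximizing $z$ is
reported, ties broken toward the gradient median.  Because $z$ is a
maximum over candidates, its null distribution is right-shifted
relative to a single-split z-score; significance is therefore *not*
judged on $z$, but on two bootstrap metrics: **purity**, the fraction
of `n_bootstrap` resamples whose best change point agrees in direction
with the observed one, and **reliability**, the fraction whose
permutation p-value (computed as $(1 + \#\{perm \ge obs\})/(1 +
n_{perm})$, never zero) is at most 0.05.  A taxon is significant when
both reach 0.95.  Bootstrap replicates in which the taxon disappears
are redrawn up to ten times and then counted as failures against both
metrics.  Virtual-taxon analysis sums ASV counts within VT before
transformation.  Community-level sum(z) change points are deliberately
not computed; only taxon-level results are reported.

## The synthetic-data generator

`simulate_study()` emulates the targeted field design: 12 even-aged
stands spanning net N mineralization of about 0.22–1.87 μg N g⁻¹ day⁻¹
(sites get evenly spaced levels, trees a small clamped jitter), five
trees per stand, two host species alternating, trees placed uniformly
in 100 m × 100 m boxes with stands 10 km apart so spatial dependence is
effectively within-site.  Growth series are drawn forward from exactly
the hierarchical model above; ring widths are emitted as two cores
whose mean equals the true radial increment, so diameter reconstruction
is exact by construction.  Initial diameters are uniform on 12–25 cm,
matching a >10 cm selection rule.

Two generator-specific choices matter.  First, dynamic covariates (lag
BAI, log DBH) cannot be z-scored empirically before they exist, so the
generator standardizes them with fixed reference constants
(`lag_center = 12`, `lag_scale = 20`, `lndbh_center = 3`,
`lndbh_scale = 0.4`); N mineralization and May temperature are z-scored
empirically.  Refitting with empirical standardization then
reparameterizes the intercept and the two dynamic-covariate slopes
linearly but leaves the nitrogen effect directly comparable, which is
what the parameter-recovery checks exercise.  Second, the lag feedback
is multiplicative on the log-normal scale and diverges if
$\beta_2/\mathrm{lag\_scale}$ times the equilibrium BAI approaches one;
the defaults ($\alpha = 1.8$, $\beta = (0.6, 0.2, 0.15, 0.1)$,
$a = 0.04$, $b = 0.01$, $\sigma^2_{\mathrm{SERE}} = 0.03$,
$\varphi = 0.1$ m⁻¹) sit in the stable regime and give equilibrium BAI
rising from roughly 2 to 20 cm² yr⁻¹ along the gradient — a realistic
span for canopy maples — with the simulation refusing to continue (with
the offending tree and year named) if a parameter choice diverges.

Communities are generated per tree: realized richness is
$\mathrm{round}(\text{intercept} + \text{slope}\cdot\mathrm{Nmin} +
\varepsilon)$ truncated to $[1, \text{pool}]$ (defaults 8 + 6·Nmin,
noise sd 1.5 taxa — about 9 to 19 taxa across the gradient); which taxa
are present is a weighted draw without replacement in which threshold
increasers carry a logistic occurrence weight rising from 0.1 to 0.9
across their planted change point (decreasers mirrored; change points
spread over the inner half of the gradient), and noise/baseline taxa a
constant weight.  Present taxa get log-normal abundance weights,
doubled on a threshold taxon's favoured side, and counts are
multinomial at the sequencing depth (default 5000 reads; depth is a
knob, not an inferred quantity).  The taxonomy map groups ASVs of a
common response type into virtual taxa (~3 ASVs per VT) and assigns a
configurable majority of VTs (default 60%) to the dominant genus
*Glomus*.

What the generator does *not* emulate: raw reads, chimeras, PCR or
primer bias, spatial autocorrelation of communities beyond the nitrogen
gradient, temporal community turnover, and overdispersion beyond the
multinomial.  Tests passing on these simulations therefore validate the
estimators' logic and calibration, not robustness to sequencing
artefacts.

## Numerical choices and degenerate inputs

* Covariance matrices get an escalating diagonal jitter (recorded) only
  if a Cholesky factorization fails; kernels at the default scales are
  comfortably positive definite.
* Variance-model support is enforced by rejection; there is no
  reparameterization of $(a, b)$.
* Zero-variance chains yield R-hat 1 with an explicit zero-variance
  flag rather than NaN; a single chain is an error.
* All-zero community samples transform to zero rows with a warning;
  Chao1 refuses non-integer input rather than silently rounding.
* Candidate change points with a zero permutation standard deviation
  are skipped and logged; taxa with no scorable candidate are counted
  as unscorable, not significant.
* Every stochastic entry point takes a seed, sub-seeds are derived by
  fixed offsets from it, and the whole pipeline writes an MD5 manifest
  so a rerun can be checked for bit-identical outputs.

## Problem sizes used by the shipped checks

The test suite exercises parameter recovery at the full study design
(12 sites × 5 trees × 40 years) with 3 chains × 3000 iterations — a
size at which the sampler's split R-hat is ≤ ~1.05 — and five
replicate studies; the threshold-taxa recovery harness uses 60 samples,
12 planted increasers, 3 decreasers and 25 noise taxa at 250
permutations × 500 bootstraps over five seeds; pipeline determinism is
checked on a compact configuration (6 sites × 4 trees), the property
being scale-free.  These sizes are the package's own trade-off between
statistical resolution and a test suite that runs in minutes;
analysis-grade defaults (3 × 10,000 iterations, 1000 bootstraps) remain
the function defaults.

## Known limitations

* EPS on raw widths, no detrending or crossdating; chronology building
  is assumed done upstream.
* The exponential-kernel SERE is one defensible reading of a spatial
  decay random effect; a conditional autoregressive alternative would
  be a different model, not a bug fix.
* Whether the growth-model $R^2$ belongs on the log or the natural BAI
  scale is ambiguous in general use, so both are reported.
* Chao1 is depth-sensitive and the package deliberately does not
  rarefy; comparisons across strongly unequal depths need care.
* TITAN-style analysis assumes abrupt monotone responses; smooth
  responders appear as weak, impure threshold taxa.
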