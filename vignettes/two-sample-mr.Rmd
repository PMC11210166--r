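---
title: "Two-sample Mendelian randomization with mrpipe: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect
$\theta$ of an exposure on an outcome from two independent GWAS: for each
genetic instrument $j$ we observe the exposure association
$(\hat\beta_{Xj}, \sigma_{Xj})$ in one cohort and the outcome association
$(\hat\beta_{Yj}, \sigma_{Yj})$ in another. Under the three instrumental
variable assumptions — relevance, independence from confounders, and
exclusion (no pathway to the outcome other than through the exposure) — the
per-variant Wald ratio $r_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ is a
consistent estimate of $\theta$, and the inverse-variance-weighted (IVW)
estimator pools them:

$$\hat\theta_{IVW} = \frac{\sum_j w_j r_j}{\sum_j w_j},\qquad
  w_j = \frac{\hat\beta_{Xj}^2}{\sigma_{Yj}^2},$$

which is algebraically the weighted least-squares slope of
$\hat\beta_{Yj}$ on $\hat\beta_{Xj}$ through the origin. Cochran's
$Q = \sum_j w_j (r_j - \hat\theta)^2$ measures heterogeneity among the
ratios; when $Q$ exceeds its $k-1$ degrees of freedom the multiplicative
random-effects model inflates the fixed-effect standard error
$1/\sqrt{\sum_j w_j}$ by $\sqrt{Q/(k-1)}$. The pipeline's `auto_by_q` rule
mirrors common practice: random effects exactly when the $Q$ test p-value
is below 0.05, fixed effects otherwise.

Exclusion-restriction violations (horizontal pleiotropy, direct effects
$\alpha_j$ of an instrument on the outcome) are the main threat. Three
complements are provided:

* **MR-Egger**: weighted regression of $\hat\beta_{Yj}$ on
  $\hat\beta_{Xj}$ with a free intercept, after orienting every pair so
  $\hat\beta_{Xj} \ge 0$. Under InSiDE (instrument strength independent of
  direct effects) the slope is consistent even with directional pleiotropy,
  and the intercept estimates the mean direct effect — its test is the
  directional-pleiotropy diagnostic.
* **Weighted median**: the ratio at cumulative normalized weight 0.5
  (linear interpolation between the bracketing order statistics, percentile
  convention $(\mathrm{cum}(w) - w_j/2)/\sum w$). Consistent while valid
  instruments carry at least half of the weight; the standard error comes
  from a seeded parametric bootstrap.
* **MR-PRESSO**: a leave-one-out residual-sum-of-squares framework. The
  global test compares the observed weighted RSS with a parametric null
  simulation; the outlier test compares each observed squared residual with
  its simulated distribution (Bonferroni-adjusted); the distortion test
  compares the raw and outlier-corrected IVW estimates against the
  distribution obtained by removing random subsets of the same size.
  The published description of the distortion null is loose; the
  random-subset reference is this package's concrete choice.

## Instrument vetting

Instruments are selected by a p-value threshold (default $5\times10^{-6}$,
the threshold used for the packaged instrument sets; note it is laxer than
the conventional genome-wide $5\times10^{-8}$, so it is a parameter, not a
constant), pruned by greedy LD clumping (sort by p, accept unless
$r^2 \ge$ 0.001 with an accepted variant inside a 10 Mb window; the window
is unbounded when coordinates are absent; ties on p broken
lexicographically by rsID so the result is order-invariant), and screened
against a local genotype–phenotype annotation table with case-insensitive
substring matching on a user blocklist — an offline stand-in for a
Phenoscanner-style query, whose exact exclusion criteria published analyses
rarely state.

Strength is reported three ways because published per-variant F columns are
not always computed the way the accompanying formula says. With
$MAF = \min(EAF, 1-EAF)$,

$$R^2 = 2\,(1-MAF)\,MAF \left(\frac{\beta}{SE\sqrt{N}}\right)^{\!2},\qquad
  F = \frac{N-k-1}{k}\,\frac{R^2}{1-R^2}.$$

`f_paper` evaluates this at the supplied instrument count $k$, `f_persnp`
at $k=1$, and `f_from_p` squares the standard-normal two-sided quantile of
the p-value (computed through the upper tail so $p \sim 10^{-19}$ does not
underflow). For the packaged tables only `f_from_p` reproduces the printed
F column (to under 1% per row — rounding of beta and SE to one or two
significant digits ruins the $R^2$ route), so `f_from_p` is the default for
filtering and reporting; all three are exposed.

## Harmonization

Both studies are aligned to a shared effect allele: direct matches pass
through, swapped alleles flip the outcome beta and frequency, and
complementary-strand reports are relabelled before the swap rule. For
palindromic variants (A/T, C/G) the alleles cannot resolve the strand;
orientation falls back on allele-frequency concordance and the variant is
dropped when either frequency is inside $[0.5-w, 0.5+w]$ (default
$w = 0.08$, standard practice — published analyses often leave their
palindromic policy unstated, so it is a parameter). A palindromic variant
with a missing frequency is dropped, conservatively. Proxy-variant
substitution for instruments missing from the outcome study is out of
scope; such variants are reported as dropped with a reason.

Two invariants pin the implementation down: harmonizing an
already-harmonized set is the identity, and relabeling any variant's
alleles in either study (EA↔NEA, $\beta \to -\beta$, $f \to 1-f$) never
changes a downstream estimate.

## The synthetic generator

`simulate_two_sample()` draws the world the estimators assume:
$EAF_j \sim U(0.05, 0.95)$, true $\beta_{Xj} \sim N(0, \sigma_X^2)$,
$SE = s/\sqrt{2\,p(1-p)\,N}$ (the standardized-trait approximation; the
trait scale $s$ is free because real cohorts code traits on arbitrary
scales — the packaged exposure tables themselves sit on two very different
scales), observed effects from their sampling distributions, and alleles
with configurable palindromic and strand-flip fractions, all recorded in a
truth ledger. Distinct RNG streams drive frequencies, effects, alleles,
pleiotropy and noise, so switching pleiotropy modes does not perturb the
instrument set.

Defaults state a world resembling the packaged analysis: $k = 23$
instruments, $\theta = 0.19$, $N_X = N_Y = 463\,010$, and
$\sigma_X = 0.015$, which puts typical instrument F in the 21–79 range of
the packaged tables. These were chosen once; green tests certify behavior
*in this stated world*. The generator has no LD between instruments
(post-clumping independence is assumed), no selection step (instruments are
taken as given rather than re-thresholded, so weak-instrument attrition is
milder than in a real pipeline), no sample overlap, and no binary-trait
link-function subtleties — conclusions about those features cannot be drawn
from these tests.

Two deliberate choices deserve a note:

* **Directional pleiotropy is oriented.** $\alpha_j =
  \mathrm{sign}(\beta_{Xj})\,\mu_\alpha + N(0, \sigma_\alpha^2)$. Defined
  in a fixed allele coding instead, the estimators' own orientation step
  (flip pairs to $\beta_X \ge 0$) would average the directional component
  away, and "directional" would be indistinguishable from balanced — the
  MR-Egger simulation literature constructs it the same way.
* **$\mu_\alpha = 0.01$ by power calibration.** The stated directional
  scenario is meant to be one the Egger intercept test detects reliably
  (at least 80% of replicates). Measured power at
  $\mu_\alpha = 0.004/0.006/0.008/0.010$ was 0.755/0.815/0.83/0.855 (200
  replicates); 0.01 — roughly three times the typical causal-path effect
  $\theta\sigma_X$ — is the default. Sign misclassification of weak
  instruments attenuates the realized intercept, which is why power grows
  slowly.

`recovery_experiment()` wraps the generator into a bias / empirical-SE /
coverage / interval-width table per (parameter cell, method), which is how
the suite checks that IVW coverage sits in $[0.92, 0.98]$ without
pleiotropy, that MR-Egger trades efficiency for robustness under
directional pleiotropy, and that the weighted median's intervals are no
tighter than IVW's.

## Numerical conventions and edge cases

* 95% intervals use the normal multiplier 1.96 everywhere; MR-Egger offers
  $t_{k-2}$ intervals as an option.
* Egger and weighted-median overdispersion follows the same multiplicative
  convention as random-effects IVW: SE inflation by the residual scale,
  truncated below at 1.
* `f_from_p`, and every simulated p-value, go through the upper-tail
  normal quantile/probability path; exact zero p-values on input are
  clamped to the smallest positive double with a warning.
* $\hat\beta_{Xj} = 0$ makes the Wald ratio undefined and is a named,
  per-variant error, not a silent drop.
* Every stochastic routine (weighted-median bootstrap, MR-PRESSO,
  the generator) requires an explicit seed and restores the caller's RNG
  state; identical seeds give bit-identical results.
* MR-PRESSO's global p is bounded below by $1/(n_{sim}+1)$; the distortion
  test is only reported when outliers were flagged.
* Degenerate geometry (all $\beta_X$ equal) leaves the Egger design matrix
  singular; the plot-data helper skips the Egger fit in that case rather
  than fabricating one.

## What is reproducible offline, and what is not

The packaged fixtures are the two published exposure-instrument tables
(23 + 10 variants) and the cohort metadata. From those alone the package
reproduces, at run time: the per-variant F column and its published range
(21.058 to 79.461, matched to under 1% per variant), the instrument counts, the F > 10 screen, and the
internal-consistency ORs obtained by exponentiating the midpoints of the
published log-scale intervals (1.209 and 1.001). The headline causal
results (IVW OR 1.209 with $p = 5.1\times10^{-5}$, Q p = 0.033, Egger
intercept $-0.0004$ with p = 0.196, no MR-PRESSO outliers) additionally
need the outcome-side associations of the 33 instruments with prostate
cancer; the source analysis drew them from an IEU Open GWAS dataset whose
accession is not recorded in the packaged metadata, so they are documented
as an explicit external-data recipe
(`inst/extdata/external_data_recipe.md`) rather than asserted by tests.

```{r example, eval = FALSE}
bph <- load_fixture("bph_instruments")
strength_summary(bph, n = 463010)
#> $f_min 21.63  $f_max 79.47  $n_strong 23  $k 23
```

## Known limitations

Single-variant records only (no multi-allelic sites), no LD-aware modelling
beyond greedy clumping against a user-supplied $r^2$ table, no
proxy-variant search, no Steiger filtering, no multivariable or
bidirectional MR, and no mode-based estimators. The delta-method Wald-ratio
SE ignores exposure-side noise, which is the field convention but
understates uncertainty for genuinely weak instruments.
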