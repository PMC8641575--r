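---
title: "Methods: two-sample Mendelian randomization in mrpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample Mendelian randomization in mrpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpipe)
```

## The model

Two-sample Mendelian randomization (MR) estimates the causal effect
$\theta$ of an exposure $X$ on an outcome $Y$ from GWAS summary statistics
alone. For each genetic instrument $j$ we observe the SNP–exposure
association $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ from one GWAS
and the SNP–outcome association
$\hat\beta_{Yj} \sim N(\Gamma_j, \sigma_{Yj}^2)$ from an independent
(non-overlapping) GWAS. Under the instrumental-variable assumptions the
true outcome association is

$$\Gamma_j = \theta\,\gamma_j + \alpha_j,$$

where $\alpha_j$ is the horizontal-pleiotropy (direct) effect of the
variant on the outcome; a valid instrument has $\alpha_j = 0$. Exposure
effects are expressed per 1 SD of exposure, outcome effects on the log-odds
scale for binary traits, so causal estimates for binary outcomes
exponentiate to odds ratios per SD.

Every estimator consumes a *harmonized set*: aligned vectors
$(\hat\beta_{Xj}, \sigma_{Xj}, \hat\beta_{Yj}, \sigma_{Yj})$ on a common
effect allele.

## Instrument selection

* **Significance filter.** Instruments are SNPs with $p < 5\times10^{-8}$
  (strict inequality). The filter is idempotent and audits every exclusion.
* **LD clumping.** Greedy: accept the smallest-$p$ remaining SNP; remove
  every remaining SNP on the same chromosome within 10,000 kb with
  $r^2 \ge 0.01$ against it; repeat. SNPs farther apart than the window are
  never clumped, whatever their $r^2$. Pairs missing from the LD table are
  treated as independent, which permits sparse desk-scale fixtures; a
  `strict` flag turns absence into an error instead. Ties in $p$ break by
  chromosome, then position, then identifier, so output is deterministic.
* **Proxies.** An instrument missing from the outcome GWAS may be replaced
  by the candidate with the highest $r^2$ strictly greater than 0.8; ties
  break by identifier. The pipeline assumes proxy-search output is reported
  on the instrument's allele coding, as proxy services provide.
* **Instrument strength.** $F = \frac{r^2}{1-r^2}\cdot\frac{n-k-1}{k}$ for
  $k$ instruments jointly explaining $r^2$ of exposure variance
  ($r^2$ per SNP on standardized traits: $2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2$).
  $F \le 10$ is flagged weak. The boundary counts as weak because the
  conventional reassurance is stated as $F > 10$.

## Harmonization

Outcome rows are matched by SNP identifier and reconciled to the exposure's
effect allele: identical pairs are kept, swapped pairs sign-flip
$\hat\beta_Y$ and reflect the EAF, and opposite-strand encodings are
complemented first. Palindromic SNPs (A/T, C/G) carry no strand information
in their alleles; they are kept only when the minor allele frequency is
strictly below 0.42 in *both* datasets and the two effect-allele
frequencies fall on the same side of 0.5 after alignment, and dropped
otherwise — never frequency-"corrected". A MAF of exactly 0.42 is dropped:
the convention defines "inferable" as MAF *smaller than* 0.42, and the
boundary itself is undefined, so the conservative side was chosen. Indels
and non-ACGT codes are rejected rather than guessed.

## Estimators

* **Wald ratio** $\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$, SE by the
  first-order delta method $\sigma_{Yj}/|\hat\beta_{Xj}|$ by default; a
  second-order option adds the
  $\hat\beta_{Yj}^2\sigma_{Xj}^2/\hat\beta_{Xj}^4$ term.
* **IVW** meta-analyzes the ratios with weights $w_j = 1/se_j^2$. The
  default random-effects flavor is *multiplicative over-dispersion*:
  $se_{\mathrm{RE}} = se_{\mathrm{FE}}\cdot\max\!\big(1, \sqrt{Q/(J-1)}\big)$,
  crediting over- but never under-dispersion — the convention of the
  standard summary-data MR toolkits. Additive (DerSimonian–Laird-style)
  random effects were deliberately not made the default because the
  source workflow's toolkit uses the multiplicative form. p-values are
  normal.
* **Cochran's Q / $I^2$**: $Q = \sum_j w_j(\hat\theta_j -
  \hat\theta_{\mathrm{IVW}})^2$ on $\chi^2_{J-1}$,
  $I^2 = \max(0, (Q-(J-1))/Q)\cdot 100$; the conventional heterogeneity
  flag combines $I^2 > 25\%$ with $p_Q < 0.05$.
* **MR-Egger** regresses $\hat\beta_Y$ on $\hat\beta_X$ with a free
  intercept (weights $\sigma_{Yj}^{-2}$) after orienting all
  $\hat\beta_X \ge 0$. The intercept estimates average directional
  pleiotropy under InSIDE; its $p < 0.05$ is the pleiotropy screen. SEs use
  the same multiplicative floor and p-values are $t_{J-2}$ rather than
  normal, for finite-sample honesty (noted in the result metadata).
* **Weighted median** interpolates the ordered ratios at the midpoint of
  standardized cumulative weights $p_j = (S_j - w_j/2)/S_J$; it is
  consistent when valid instruments carry $\ge 50\%$ of weight. Its SE is a
  parametric bootstrap (default 5,000 replicates, seed-deterministic).
* **Maximum likelihood** maximizes the joint normal likelihood over
  $(\theta, \gamma_1,\dots,\gamma_J)$; the $\gamma_j$ have a closed-form
  profile, leaving a 1-D optimization started at the IVW estimate, with SE
  from the observed profile information. Unlike first-order IVW it models
  the exposure-side sampling error.
* **Leave-one-out** recomputes IVW excluding each SNP and flags
  sign or significance changes.

IVW in ratio form with first-order weights is algebraically identical to
weighted regression of $\hat\beta_Y$ on $\hat\beta_X$ through the origin,
so no separate "regression form" switch exists; the SE convention is
recorded in the result metadata.

## MR-PRESSO

The global test statistic is the leave-one-out weighted residual sum of
squares
$\mathrm{RSS} = \sum_j \sigma_{Yj}^{-2}\big(\hat\beta_{Yj} -
\hat\theta_{(-j)}\hat\beta_{Xj}\big)^2$. Its null distribution is built by
parametric simulation (default 1,000 draws) from the leave-one-out fitted
model; the empirical p-value uses add-one smoothing,
$(1 + \#\{\mathrm{sim} \ge \mathrm{obs}\})/(1 + n_{\mathrm{sim}})$, so it
is never exactly zero. Per-SNP outlier p-values compare each observed
squared residual with its own simulated distribution, Bonferroni-adjusted
across the $J$ SNPs, calling outliers below 0.05. The corrected estimate is
exactly `mr_ivw()` on the set minus the outliers. The distortion test
compares the raw-to-corrected change with the distribution from removing
random subsets of the same size; it is advisory and never blocks the
corrected estimate.

## Multivariable MR and mediation

MVMR regresses $\hat\beta_Y$ on the $J \times k$ matrix of exposure effects
without intercept (weights $\sigma_{Yj}^{-2}$, multiplicative
over-dispersion floored at 1); each coefficient is a direct effect
conditional on the other exposures, and collinear exposure matrices raise
an explicit rank-deficiency error. With $k = 1$ this reproduces the
univariable IVW exactly — estimate and SE — which the tests assert to
machine precision.

Mediation uses the difference method: indirect = total − direct (identity
exact by construction), proportion mediated $\mathrm{PM} =$
indirect/total. Two intervals are offered:

* **Delta (default)**: $se_{\mathrm{ind}} = \sqrt{se_T^2 + se_D^2}$ and a
  delta-method PM variance, both under the approximation that the total and
  direct estimates are independent. They are not — they share the exposure
  instruments — so this interval is wide and over-covers. It is the only
  option when just summary results are available.
* **Joint parametric bootstrap**: when the per-SNP data are supplied,
  shared SNPs are resampled with the *same* draws in the univariable and
  multivariable fits, capturing their correlation; the PM interval is
  percentile-based and calibrated. The acceptance suite verifies its
  coverage.

PM outside $[0, 1]$ is reported with a warning, never clipped. For binary
outcomes the decomposition runs on the log-OR scale — the only scale the
estimators provide — and log-odds non-collapsibility means the decomposition
is approximate; the result metadata says so. The MVMR instrument set is the
union of per-exposure instruments, clumped jointly; the pipeline adjusts
for one mediator at a time, which is the default loop.

## Power and classification

Power uses the two-sided normal approximation
$\Phi(-z_{1-\alpha/2} + \mathrm{NCP}) + \Phi(-z_{1-\alpha/2} -
\mathrm{NCP})$, so a null effect returns exactly $\alpha$. Continuous
outcomes: $\mathrm{NCP} = \sqrt{n\,r^2}\,\beta_1$ with $n$ the outcome GWAS
size. Binary outcomes follow the published mRnd-style approximation: the
odds ratio is mapped to the observed binary scale,
$b = K\big(\mathrm{OR}/(1 + K(\mathrm{OR}-1)) - 1\big)$ with case
proportion $K$, variance $(K(1-K) - b^2)/(n r^2)$, and
$\mathrm{NCP} = b/\sqrt{\mathrm{var}}$. This formula is the known-variance
fixed-effect test: the default random-effects floor
$\max(1,\sqrt{Q/(J-1)})$ is deliberately conservative under homogeneity
(its expectation exceeds 1), so the simulation cross-check in the
acceptance suite matches the formula against the fixed-effect IVW, its
exact analogue.

Bonferroni classification partitions p-values at the *exact* threshold
$\alpha/(n_{\mathrm{exposures}} \times n_{\mathrm{outcomes}})$ — for the
default 3 × 13 family, $0.05/39 \approx 1.282\times10^{-3}$, conventionally
rounded to $1.3\times10^{-3}$ — into significant / suggestive (up to 0.05)
/ null. The exact value is used for classification; the rounded one is
attached for display, favoring reproducibility over typography.

## The synthetic generator: what it emulates and what it does not

`simulate_two_sample()` draws minor allele frequencies uniformly on a
configurable interval, instrument effects $\gamma_j \sim N(\mu_\gamma,
\sigma_\gamma)$, and sampling errors with the standardized-trait
approximation $se = 1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})\,n}$; binary
outcomes inflate the outcome variance by $1/(K(1-K))$. Pleiotropy enters
through a configurable invalid fraction with $\alpha_j \sim N(\mu_\alpha,
\sigma_\alpha)$ — balanced ($\mu_\alpha = 0$) or directional — drawn
independently of $\gamma_j$, i.e. the InSIDE setting that MR-Egger assumes.
`corrupt_alleles()` layers the three real-world encoding artefacts (allele
swaps, strand flips, palindromic rewrites at controllable EAF) with a log
so harmonization can be scored exactly.

Defaults describe the kind of study the package targets: ~100 independent
instruments, a biobank-scale exposure GWAS (n = 408,815), a consortium
outcome GWAS (n = 100,000), per-SNP effects ~0.02 SD (comfortably
genome-wide significant at that exposure size), case fraction 0.12 when
binary. The per-SNP effect-size distribution of real sedentary-behavior
traits is not published at this granularity, so these are conventional
choices, fixed once.

The generator does **not** emulate: LD among instruments (clumping is
exercised against explicit LD fixtures; all estimators assume
post-clumping independence), sample overlap between the two GWAS (a known
limitation of real two-sample designs), individual-level genotypes, minor
allele frequency spectra, or winner's-curse selection of instruments. A
green simulation test therefore establishes correctness of the estimator
arithmetic and calibration under the stated model — not robustness to
violations the generator cannot produce.

`simulate_mediation()` builds an exposure → mediator → outcome system with
separate instrument sets for exposure and mediator. Its defaults use
stronger instruments (per-SNP F of several hundred) than the two-sample
generator: the no-measurement-error (NOME) assumption then holds and the
decomposition is tested free of weak-instrument attenuation. That
attenuation is real and worth knowing about: with realistic instrument
strength the IVW and MVMR estimates shrink by roughly $1/F$, and the MVMR
direct effect slightly more than the univariable total (mediator
instruments contribute noise-only entries to the exposure column), which
nudges the estimated proportion mediated upward by a few tenths of a
percentage point. The acceptance suite documents this by testing the
decomposition in the near-NOME regime; the attenuation itself is a property
of summary-data MR, not of this implementation.

## Numerical choices

* Empirical p-values always use add-one smoothing; minimum
  $1/(n_{\mathrm{sim}}+1)$.
* All simulation-based routines (`simulate_*`, `mr_weighted_median`,
  `presso`, bootstrap `mediate`) take an explicit seed, run on a private
  RNG stream, and restore the caller's RNG state; same seed, same bytes.
  Statistics, not RNG streams, are the cross-language contract: the
  generator family is R's default Mersenne–Twister.
* The maximum-likelihood optimizer is 1-D BFGS on the profile likelihood
  from the IVW start; non-convergence is an error carrying the optimizer
  code, not a silent fallback.
* Wald ratios with $\hat\beta_X = 0$ are an explicit error; the bootstrap
  replaces exact zeros with machine epsilon to keep resampled medians
  finite.
* Degenerate inputs fail loudly: rank-deficient MVMR matrices, all-SNP
  outlier sets in MR-PRESSO, zero exposure variance in Egger, empty
  instrument sets in the pipeline (recorded per pair, the run continues).

## Known limitations

* No LD-aware simulation; clumping correctness rests on fixture-based
  tests against a brute-force oracle.
* No sample-overlap modelling; overlapping GWAS inflate type-I error in
  ways this package cannot detect.
* Proxy substitution trusts the allele correspondence of the proxy table;
  it cannot verify it from summary data.
* The mediation decomposition for binary outcomes inherits log-odds
  non-collapsibility.
* Steiger filtering, mode-based estimators, and penalized IVW variants are
  out of scope by design.
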