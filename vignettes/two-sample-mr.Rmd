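---
title: "Two-sample Mendelian randomization with mrpipe: models, conventions and validation"
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

## The problem and the model

Mendelian randomization (MR) uses genetic variants as instrumental
variables to estimate the causal effect of an exposure on an outcome from
observational data. Because alleles are assigned at conception, a valid
genetic instrument is immune to the confounding and reverse causation
that afflict ordinary epidemiological associations. mrpipe implements the
two-sample flavour, where the SNP–exposure associations
$(\hat\beta_{Xj}, \sigma_{Xj})$ and the SNP–outcome associations
$(\hat\beta_{Yj}, \sigma_{Yj})$ come from two separate GWAS of
(here) binary traits, both on the log-odds scale. The motivating use case
is cardiovascular: estimating the causal effect of calcific aortic valve
stenosis (CAVS) on atrial fibrillation (AF) from published GWAS summary
statistics.

A variant $j$ is a valid instrument if it (1) associates with the
exposure, (2) is independent of exposure–outcome confounders, and (3)
affects the outcome only through the exposure. Under these assumptions
each instrument yields a Wald ratio estimate of the causal effect
$\theta$:

$$\hat\theta_j = \frac{\hat\beta_{Yj}}{\hat\beta_{Xj}}, \qquad
  \mathrm{se}(\hat\theta_j) = \frac{\sigma_{Yj}}{|\hat\beta_{Xj}|},$$

using the first-order delta method (exposure-side uncertainty is screened
out by the instrument-strength filter rather than propagated; this is the
convention behind reported MR confidence intervals, and it is recorded
here so the choice is auditable).

The pooled estimators over $J$ instruments:

* **IVW** — the inverse-variance weighted mean of the Wald ratios with
  weights $w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$, identical to weighted
  least squares of $\hat\beta_Y$ on $\hat\beta_X$ through the origin with
  weights $1/\sigma_{Yj}^2$. It is the primary method and assumes no
  average pleiotropic effect. Fixed-effect SE is $(\sum_j w_j)^{-1/2}$;
  the multiplicative random-effects SE scales it by
  $\max\!\big(1, \sqrt{Q/(J-1)}\big)$ so it can never fall below the
  fixed SE. With `effects_model = "auto"` the random-effects model is
  used exactly when Cochran's Q test signals heterogeneity
  ($p < 0.05$), otherwise fixed — the standard decision rule.
* **MR-Egger** — weighted regression of $\hat\beta_Y$ on $\hat\beta_X$
  *with* an intercept, after orienting every instrument so
  $\hat\beta_X \ge 0$. Under InSIDE (instrument strength independent of
  direct effects) the slope is a pleiotropy-robust estimate of $\theta$
  and the intercept estimates the average directional pleiotropic
  effect; an intercept distinguishable from zero is evidence of
  directional pleiotropy.
* **Weighted median** — the 50% weighted quantile of the ordered Wald
  ratios with normalized weights $w_j \propto 1/\mathrm{se}(\hat\theta_j)^2$,
  consistent whenever at least half of the total weight comes from valid
  instruments. With cumulative sums $S_j = \sum_{k \le j} w_k - w_j/2$
  the estimate interpolates $\hat\theta$ linearly at $S = 0.5$. Its SE is
  a parametric bootstrap: resample
  $\hat\beta_{Xj} \sim N(\hat\beta_{Xj}, \sigma_{Xj}^2)$,
  $\hat\beta_{Yj} \sim N(\hat\beta_{Yj}, \sigma_{Yj}^2)$ and recompute.

Diagnostics: Cochran's
$Q = \sum_j w_j(\hat\theta_j - \hat\theta_{\mathrm{IVW}})^2$ on
$J-1$ degrees of freedom for the IVW fit, and the weighted residual sum
of squares of the Egger fit on $J-2$ degrees of freedom; leave-one-out
re-estimation; and the per-SNP Wald-ratio table behind the usual forest
plot.

## Instrument selection and harmonization

`run_analysis()` applies, in order:

1. **Genome-wide significance**: keep exposure records with
   $p < 5\times10^{-8}$ (strictly below; the threshold is configurable).
2. **LD clumping** (`ld_prune()`): greedy — repeatedly keep the remaining
   SNP with the smallest exposure p-value and discard every remaining SNP
   with $r^2 \ge$ 0.001 against it. Ties on p-value break
   lexicographically on SNP id, which makes the result invariant to input
   row order. The pairwise $r^2$ matrix is a user input (or simulated);
   computing it from a genotype reference panel is out of scope, and with
   no matrix supplied the input is treated as already clumped, which is
   how published instrument lists arrive.
3. **Harmonization** (`harmonize()`): inner join on SNP id; identical
   allele pairs pass through, swapped pairs negate the outcome effect and
   complement its frequency, and strand-complemented pairs are resolved
   the same way — but only for non-palindromic SNPs, where complementing
   is unambiguous. Palindromic SNPs (A/T, C/G) are excluded by default
   because the strand cannot be verified from alleles alone. An opt-in
   rescue keeps a palindromic SNP when both studies report its
   effect-allele frequency on the same side of 0.5 and beyond the 0.42
   cutoff (a frequency near 0.5 carries no strand information);
   it is off by default to match the conservative convention of dropping
   palindromes outright.
4. **Instrument strength**: per-SNP
   $F = (\hat\beta_X/\sigma_X)^2$, the one-degree-of-freedom
   approximation; instruments with $F < 10$ are excluded as weak. The
   boundary is inclusive ($F = 10$ is kept). A mean F is reported as an
   informal overall summary.

Every excluded SNP lands in an exclusion log with a reason, and the
pipeline-level log accounts for every candidate not among the final
instruments (including those absent from the outcome study), so
`n_candidates = n_instruments + n_exclusions` always holds.

## Tunable parameters

| parameter | default | unit / scale | why |
|---|---|---|---|
| `p_threshold` | 5e-8 | p-value | genome-wide significance convention |
| `r2_threshold` | 0.001 | $r^2$ | strict independence between instruments |
| `f_min` | 10 | F statistic | conventional weak-instrument screen |
| `drop_palindromic` | TRUE | — | strand safety over instrument count |
| `effects_model` | "auto" | — | heterogeneity-triggered fixed/random switch |
| `n_boot` | 1000 | replicates | weighted-median bootstrap SE |
| `bonferroni` | c(1, 1) | counts | exposures × outcomes tested; the corrected threshold is $0.05/(XY)$ |
| `seed` | — | integer | mandatory whenever the weighted median runs |

Estimates are reported on the log-odds scale with 95% CIs and mirrored as
odds ratios (`or = exp(b)` etc.). Reference distributions: standard
normal for IVW and weighted-median p-values and CIs; $t_{J-2}$ for the
MR-Egger slope and intercept, matching the small-sample correction usual
for Egger regression. Each estimate row records its reference
distribution in `ci_ref`. P-values supplied in input files are never
recomputed on read: published tables round beta, SE and p independently,
and silently replacing p would make reproduction of a published analysis
impossible.

## The synthetic-data generator

`simulate_two_sample()` draws GWAS summary statistics directly on the
log-odds scale: per SNP, a minor-allele frequency
$p_j \sim U(\texttt{maf\_range})$, a true exposure effect $\gamma_j$ with
$|\gamma_j| \sim U(\texttt{gamma\_range})$, a direct (pleiotropic) effect
$\alpha_j \sim N(\mu_\alpha, \sigma_\alpha^2)$ drawn independently of
$\gamma_j$ (so InSIDE holds by construction), and observed effects

$$\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2), \qquad
  \hat\beta_{Yj} \sim N(\theta\gamma_j + \alpha_j, \sigma_{Yj}^2),
  \qquad \sigma_{j} = (2np_j(1-p_j))^{-1/2}.$$

Setting $\mu_\alpha = \sigma_\alpha = 0$ makes every instrument valid
(assumptions 2 and 3 hold); $\sigma_\alpha > 0$ with $\mu_\alpha = 0$ is
balanced pleiotropy; $\mu_\alpha \ne 0$ is directional pleiotropy under
InSIDE. Configured fractions of SNPs receive palindromic allele pairs
and swapped allele order in the outcome file, so harmonization is
exercised rather than assumed.

Default study conditions emulate the motivating CAVS→AF analysis: 19
instruments, true $\theta = 0.1$ (OR $\approx 1.105$ per exposure
log-odds unit), and case-control GWAS of 9153/368124 (exposure) and
60620/970216 (outcome) cases/controls. Because the precision of a
log-odds estimate in a case-control GWAS is governed by the *effective*
sample size $4/(1/n_{\mathrm{cases}} + 1/n_{\mathrm{controls}})$, the
generator's `n_exp` and `n_out` default to the effective sizes 35705 and
228280. MAF in (0.1, 0.45) and $|\gamma|$ in (0.1, 0.35) give per-SNP F
statistics of roughly 60–1500 and keep every simulated instrument
comfortably genome-wide significant. True effect signs default to
positive (instrument lists are conventionally oriented to the
exposure-increasing allele); a `gamma_sign = "random"` option exists.

Numerical details worth knowing:

* Simulated p-values are floored at the smallest normalized double
  ($\approx$ 2.2e-308): at these sample sizes $|z|$ can exceed 40 and
  the two-sided normal p-value underflows to zero, which a validated
  record may not carry (real GWAS exports avoid literal zero the same
  way).
* All draws come from one seeded generator; the same `sim_config` is
  bit-for-bit reproducible, and the flip/palindrome assignment consumes
  RNG draws *after* the effect draws, so toggling those fractions leaves
  the simulated effects unchanged — harmonization of a flipped dataset
  must recover the unflipped effects exactly, and the tests assert it.

What the generator does **not** emulate: LD between instruments (it
simulates a post-clumping world; LD exists only in
`simulate_ld_matrix()`, a block-diagonal matrix for exercising the
pruner), winner's curse in instrument discovery, case-control
ascertainment, allele-frequency differences between studies, and
population stratification. Passing the recovery tests therefore shows
the estimators are correctly implemented and calibrated under their own
assumptions — not that those assumptions hold in any particular real
dataset.

## Validation strategy and problem sizes

The test suite validates each layer against an independent route:

* IVW against `lm()` weighted regression through the origin (agreement
  to 1e-10 over random instances); MR-Egger against a weighted `lm()`
  with intercept, including the dispersion floor
  ($\mathrm{SE}_{\mathrm{lm}}/\min(1,\hat\sigma)$ is algebraically the
  floored SE).
* The weighted median against a brute-force inversion of the
  piecewise-linear weighted quantile function by root finding,
  exhaustively over small $J$.
* Calibration by simulation under the default study conditions:
  IVW mean bias within ±0.01 and 95% CI coverage in [0.93, 0.97]
  ($J = 50$, $\theta = 0.1$ and $\theta = 0$, 1000 replicates); Q-test
  size in [0.03, 0.07] (1000 replicates); mean Egger intercept within
  ±0.01 of $\mu_\alpha = 0.05$ with the Egger slope less biased than
  IVW (500 replicates); three-estimator recovery within ±0.015 (300
  replicates). These replicate counts keep Monte Carlo error on a 5%
  rate near half a percentage point while the whole suite runs in a few
  minutes on one CPU.

The headline end-to-end check runs the full pipeline on a bundled,
deliberately imperfect synthetic fixture — 19 valid instruments plus two
palindromes, two sub-threshold SNPs and one SNP missing from the outcome
study (`inst/extdata/synthetic_*.tsv`, regenerable via
`analysis/01_build_fixture.R`, generator seed 193) — and compares
against a pre-registered golden report frozen at full precision. The
fixture is synthetic because the motivating study's per-SNP supplementary
table is not redistributable with the package; the golden test therefore
checks reproduction of the *pipeline's own* frozen results, not the
published table.

## Design choices where the design was open

* **Fixed/random auto rule inside leave-one-out**: re-evaluated within
  each $J-1$ subset rather than frozen from the full set, so every row
  is a self-contained analysis directly comparable to a from-scratch
  run (the tests enforce exact equality with recomputation).
* **Clumping tie-break**: lexicographic on SNP id at equal p-values —
  arbitrary, but stated, deterministic and order-invariant.
* **Bonferroni counts** are explicit config (`bonferroni = c(X, Y)`)
  defaulting to one exposure × one outcome; analyses that screen
  multiple exposure datasets against one outcome should set X
  accordingly.
* **Degenerate inputs**: a zero exposure effect cannot be an instrument
  (excluded at harmonization, an error in `mr_wald_ratio()`); a single
  instrument with `effects_model = "random"` falls back to fixed with a
  warning; collinear exposure effects abort MR-Egger; an estimator
  failure inside leave-one-out flags the row instead of dropping it.
* **Report rounding**: the human-readable summary prints odds ratios at
  3 decimals, the convention of published MR tables; all TSVs keep full
  double precision (17 significant digits) so round-trips are lossless.

## Known limitations

Only biallelic SNPs joined by ID are modelled (no indels, no genomic
coordinates, no proxy lookup); the $r^2$ matrix must be supplied, not
derived from genotypes; nonlinear causal effects and individual-level
analyses are out of scope; and MR-PRESSO-style outlier removal,
mode-based estimators and multivariable MR are deliberately not
implemented. The delta-method Wald SE ignores exposure-side uncertainty,
which is standard but optimistic for instruments near the F threshold.
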