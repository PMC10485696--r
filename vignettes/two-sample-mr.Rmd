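---
title: "Two-sample Mendelian randomization with mrkit: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-sample Mendelian randomization with mrkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrkit)
```

## The model

Two-sample Mendelian randomization treats genetic variants as instrumental
variables for a modifiable exposure. For variant $j$, the exposure GWAS
supplies $\hat\beta_{Xj} \sim N(\gamma_j, \sigma_{Xj}^2)$ and the outcome
GWAS, in a different sample, supplies
$\hat\beta_{Yj} \sim N(\Gamma_j, \sigma_{Yj}^2)$ with
$\Gamma_j = \beta\,\gamma_j + \alpha_j$, where $\beta$ is the causal
effect of interest and $\alpha_j$ is any horizontal-pleiotropy effect of
the variant on the outcome that bypasses the exposure. A valid instrument
has $\alpha_j = 0$, is strongly associated with the exposure, and is
independent of confounders.

Each variant yields a Wald ratio $\hat\beta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$
with first-order SE $\sigma_{Yj}/|\hat\beta_{Xj}|$ and weight
$w_j = \hat\beta_{Xj}^2/\sigma_{Yj}^2$. The three pooled estimators trade
efficiency against robustness:

* **IVW**, $\hat\beta = \sum w_j\hat\beta_j / \sum w_j$, is the efficient
  choice when every instrument is valid, and is algebraically the
  zero-intercept weighted least-squares fit of $\hat\beta_Y$ on
  $\hat\beta_X$ with weights $1/\sigma_Y^2$. Any nonzero mean pleiotropy
  biases it.
* **MR-Egger** frees the intercept of that regression: the slope remains
  consistent for $\beta$, and the intercept estimates the mean direct
  effect $\bar\alpha$, provided pleiotropy is independent of instrument
  strength (InSIDE). The price is much lower precision and sensitivity to
  the orientation convention, so instruments are canonicalized to
  $\hat\beta_{Xj} \ge 0$ before fitting.
* The **weighted median** of the Wald ratios is consistent while valid
  instruments carry at least half the total weight, whatever the invalid
  ones do. The estimate interpolates the ordered ratios at standardized
  cumulative weight $p_j = (S_j - w_j/2)/S_L = 0.5$; its SE comes from a
  parametric bootstrap that redraws every $\hat\beta_{Xj}$ and
  $\hat\beta_{Yj}$ from their reported sampling distributions.

The first-order Wald SE ignores the exposure-side noise
($\mathrm{NOME}$); with instrument F statistics in the 30–80 range, as in
the packaged example, the neglected term is of relative order $1/F$ and
immaterial. A second-order option exists in `wald_ratio()` but is off by
default because the first-order weights are what the conventional
estimators — and the published analyses this package mirrors — use.

## Harmonization and instrument selection

Exposure and outcome effects must refer to the same effect allele.
Directly matching and swapped allele pairs are resolved exactly; pairs
matching after strand complement are complemented first. Palindromic
variants (A/T, C/G) are unresolvable from alleles alone, so the package
uses allele-frequency agreement, and only when both frequencies are
decisive: outside the band $[0.42, 0.58]$ (window 0.08 around 0.5, the
common practice). Inside the band the variant is dropped by default —
misorienting a variant silently flips the sign of its contribution, a
worse failure than losing an instrument. When a table publishes only the
effect allele, harmonization falls back to effect-allele equality with a
warning and `palindromic = NA`; this is the situation for the packaged
seven-variant set, which is already allele-aligned.

Instrument selection applies the conventional screens — exposure
$p < 5\times10^{-8}$, $F = (\hat\beta_X/\sigma_X)^2 > 10$ — then greedy
LD clumping: candidates in ascending p-value order (ties broken by
variant id, for reproducibility) are kept iff their $r^2$ with every
variant already kept is below 0.1. The package accepts a precomputed
$r^2$ matrix and never computes LD from genotypes; pairs absent from the
matrix are assumed independent with a warning. An instrument set emptied
by filtering raises a dedicated condition (`mr_no_instruments`), distinct
from an empty input, because downstream estimation is impossible.

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `p_threshold` | `5e-8` | genome-wide significance |
| `r2_threshold` | `0.1` | independence after clumping |
| `f_threshold` | `10` | conventional weak-instrument screen |
| `palindrome_eaf_window` | `0.08` | ambiguous EAF band `[0.42, 0.58]` |
| `variance_model` (IVW) | multiplicative random effects | SE scales with $\hat\phi = \sqrt{Q/(L-1)}$ |
| `allow_underdispersion` | `TRUE` | $\hat\phi$ may fall below 1 |
| `se_model` (Egger) | `t`, $L-2$ df | two parameters estimated from few points |
| `n_boot`, `seed` | 1000, 20230825 | bootstrap SE stable to a few percent |
| `ci_z` | `qnorm(0.975)` | exact normal quantile; published tables round-trip with 1.96 |

Allowing underdispersion means the multiplicative random-effects SE can be
*smaller* than the fixed-effects SE when $Q < L-1$; this matches the
regression convention in which the residual scale is estimated rather
than floored, and is recorded in the output metadata. Setting
`allow_underdispersion = FALSE` recovers the floored convention. IVW and
weighted-median p-values are two-sided normal; Egger slope and intercept
use Student t with $L-2$ df.

## Heterogeneity and diagnostics

Cochran's $Q = \sum_j w_j(\hat\beta_j - \hat\beta_{IVW})^2$ has $L-1$ df
under homogeneity; the Egger version is the weighted residual sum of
squares with $L-2$ df (slope and intercept both estimated).
$I^2 = (Q - \mathrm{df})/Q$ is stored **signed** — it is negative
whenever $Q < \mathrm{df}$, i.e. less spread than chance predicts — and
is undefined at $Q = 0$. Some published tables display $|I^2|$; the
reporting layer offers that as a display switch
(`mr_heterogeneity(..., display_magnitude = TRUE)`) without altering the
stored value. The funnel plot uses precision $1/\mathrm{SE}(\hat\beta_j)$
on the vertical axis, the conventional construction. All figure content
is generated from the `mr_diagnostics()` tables, so every plotted number
is testable and figures cannot drift from tables.

## The packaged example and its documented discrepancies

The shipped fixture is the seven-variant instrument set from a published
analysis of aspirin use (GWAS n = 337,159) on hayfever / allergic
rhinitis (GWAS n = 83,529). Recomputing from the per-variant table
reproduces four of the seven published F statistics to $10^{-4}$ relative
error and the weighted-median estimate to 0.16% (−0.4162 vs −0.4155), and
the published OR/CI cells round-trip from the published (β, SE) pairs at
z = 1.96. The remaining published cells are *not* recoverable from the
per-variant table itself: three F statistics appear permuted across rows,
the published IVW (−0.349) and Egger (−0.3742, intercept 0.00021)
estimates differ from the weighted-least-squares values the table implies
(−0.3030; −0.7119, intercept +0.0032), and the published Q statistics
(2.148, 2.143) differ from the direct summation (5.65, 4.17).
`mr_reproduce_reference()` reports both values for every cell with a
`REPRODUCED` / `DOCUMENTED-DISCREPANCY` flag; the package deliberately
reports what the data imply rather than forcing agreement with the
published cells, and its exact-value tests pin only the reproducible
quantities. The published upper CI bounds for IVW and the weighted median
are internally inconsistent with $\exp(\beta + 1.96\,\mathrm{SE})$ and are
excluded from the comparison.

## The simulator: what it emulates and what it does not

`simulate_two_sample()` draws true instrument effects
$\gamma_j \sim N(0.01, 0.003^2)$ — the magnitude of genome-wide-significant
effects on a binary-coded biobank trait, matching the packaged example —
and SEs on the order of $10^{-3}$ (exposure) and $2.5\times10^{-3}$
(outcome), each jittered uniformly by ±20% so weights are not degenerate.
Pleiotropy is assigned to `round(invalid_fraction * L)` instruments:
directional via a nonzero mean, balanced via a zero-mean spread, and
InSIDE-violating via an added component proportional to the instrument's
own $\gamma_j$. All randomness descends from one master seed through
deterministic stream seeds (per stage, per replicate), so any replicate
of an experiment is independently reproducible and the generator leaves
the caller's RNG state untouched.

The simulator emulates the post-clumping state: independent instruments,
normal estimation noise, no sample overlap, no LD, no allele-coding
errors, and SEs configured directly rather than derived from sample size
and allele frequency (an optional realism the estimators never consume,
since they only read betas and SEs). Passing tests therefore demonstrate
estimator correctness under the two-sample MR model assumptions — they do
not certify behaviour under correlated instruments, winner's curse,
overlapping samples, or non-normal effect distributions.

`recovery_experiment()` summarizes bias, RMSE, empirical vs model SE,
coverage and rejection rate per estimator. The test suite runs it at
1000 replicates (IVW null calibration; type-I error within
[0.035, 0.065]) and 200 replicates for the pleiotropy contrasts, with
$L$ between 30 and 50 — sizes chosen so Monte-Carlo error is a small
fraction of the effects being detected.

## Numerical choices and degenerate inputs

* Wald ratio at $\hat\beta_X = 0$ is an error, not `Inf`; a single
  instrument degenerates IVW to the Wald ratio itself.
* The weighted-median interpolation clamps to the extreme ratio when 0.5
  falls outside $[p_1, p_L]$ (possible only with one dominant weight).
* Zero residual dispersion gives $\hat\phi = 0$; with underdispersion
  allowed the IVW SE is then 0 and estimation degenerates, which only
  occurs on exactly collinear inputs.
* Clumping ties in p-value break lexicographically by variant id, so
  selection is a pure function of the data, not of row order.
* Bootstrap replicates that redraw $\hat\beta_X$ near 0 can produce
  extreme ratios; they are kept, since deleting them would bias the SE —
  at the packaged example's instrument strength they are vanishingly
  rare.

## Limitations

Multivariable, bidirectional and mode-based MR, MR-PRESSO outlier
removal, Steiger directionality and proxy-SNP lookup are out of scope;
LD is consumed, never computed. The weighted median's protection fails
by construction once invalid instruments carry the majority of the
weight — the suite verifies accuracy at 30–40% invalid weight and makes
no guarantee at 60%.
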