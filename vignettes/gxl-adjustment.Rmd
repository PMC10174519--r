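---
title: "GxL-adjusted inference: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GxL-adjusted inference: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gxladjust)
```

## The problem

A single-laboratory mouse phenotyping study compares genotypes under one
specific set of environmental conditions, technicians, and equipment. When
another lab repeats the comparison, the genotype means shift by more than
sampling noise: genotypes respond differently to laboratory environments.
This genotype-by-lab (GxL) interaction is the dominant reason apparently
solid single-lab discoveries fail to replicate, and it does not shrink when
more animals are added within the one lab.

`gxladjust` implements the Random Lab Model treatment of this problem:
estimate the interaction from multi-lab data once, express it as a
dimensionless factor, and inflate the standard errors of future single-lab
comparisons by it.

## The Random Lab Model

For animal $i$ of genotype $g$ in lab $l$,

$$y_{gli} = \mu + \beta_g + L_l + (GL)_{gl} + \varepsilon_{gli},$$

with fixed genotype effects $\beta_g$ and independent Gaussian random
components $L_l \sim N(0, \sigma^2_L)$, $(GL)_{gl} \sim N(0,
\sigma^2_{GxL})$, $\varepsilon \sim N(0, \sigma^2)$. Additive lab effects
$L_l$ cancel in any within-lab comparison; the interaction does not. The
variance of a within-lab difference of genotype means becomes
$\sigma^2/n_1 + \sigma^2/n_2 + 2\sigma^2_{GxL}$.

`fit_random_lab_model()` estimates the components by REML through
`lme4::lmer` (`value ~ genotype + (1|lab) + (1|lab:genotype)`), which is the
standard engine for crossed random effects and handles unbalanced cells.
`method = "moments"` is a second, independent implementation — the balanced
two-way expected-mean-squares estimator
$\hat\sigma^2 = MS_{err}$, $\hat\sigma^2_{GxL} = (MS_{GxL} - MS_{err})/n$,
$\hat\sigma^2_L = (MS_L - MS_{GxL})/(nG)$ — kept primarily as a cross-check:
on balanced data the two agree to optimizer tolerance in the interior of the
parameter space, and the test suite asserts this. The moments estimator
refuses unbalanced designs rather than approximate them. Negative component
estimates are truncated at zero and recorded in the fit's `truncated` field;
`lmer` enforces the same boundary internally.

The three-way extension `fit_treatment_model()` adds treatment as a fixed
effect (with a fixed genotype-by-treatment interaction) and random TxL and
TxGxL terms; its EMS counterpart follows the analogous ladder of mean
squares.

## The GxL factor

$$\gamma = \sqrt{\sigma^2_{GxL} / \sigma^2}$$

is a ratio of two standard deviations measured on the same scale, hence
dimensionless: a $\gamma$ estimated from a database of labs transfers to a
new lab even if that lab's instrument uses different units, because the new
lab's own pooled SD $s_p$ carries the scale ($s_p^2\gamma^2$ estimates the
interaction variance in the new study). Typical magnitudes from multi-lab
mouse data: around 0.5–0.6 for body weight, near or above 1 for open-field
distance traveled. $\gamma^2 \approx 0.1$ is already comparable to the
$1/n$ sampling term of a 10-animal group.

A `gxl_factor` object carries $\gamma$ together with the source design's
dimensions $(n_L, n_S)$, because they set the degrees of freedom available
for the interaction estimate.

## The adjusted t test

$$T = \frac{\bar x - \bar y}{s_p\sqrt{1/n_1 + 1/n_2 + 2\gamma^2}}$$

referred to Student's $t$ with Satterthwaite degrees of freedom

$$\nu = \frac{(1/n_1+1/n_2+2\gamma^2)^2}
  {(1/n_1+1/n_2)^2/(n_1+n_2-2) + 4\gamma^4/\left[(n_L-1)(n_S-1)\right]},$$

which blends the single lab's error df with the $(n_L-1)(n_S-1)$ df behind
$\hat\gamma^2$. With $\gamma = 0$ the test reduces *exactly* to the pooled
two-sample t test (asserted to 1e-12 against `t.test(var.equal = TRUE)`).

**The df cap.** The raw Satterthwaite ratio exceeds $n_1+n_2-2$ when
$\gamma$ is small, because combining two variance estimates can nominally
"gain" degrees of freedom. Left uncapped, that gain can make an adjusted
p-value smaller than the unadjusted one and, at small group sizes, even
flip a nonsignificant comparison to significant — the opposite of what a
penalizing adjustment is for, and a violation of the monotonicity on which
the six-category classification relies. `satterthwaite_df()` therefore caps
$\nu$ at the pooled df. The cap leaves the canonical checkpoints untouched
($\nu(n_1{=}n_2{=}10, \gamma{=}0.5, 3\times6) = 18.000$ sits exactly at the
cap; $\nu(\gamma{=}2) = 10.50$ is far below it) and makes
$p_{adj} \ge p_{unadj}$ provable for every input: the adjusted test has a
larger standard error and no more degrees of freedom.

**Treatment-difference contrasts.** For
$(\bar x_T - \bar x_C) - (\bar y_T - \bar y_C)$ the lab, TxL and GxL terms
cancel; four independent TxGxL draws remain, inflating the variance by
$4s_p^2\gamma^2_{TxGxL}$. The Satterthwaite generalization used here —
$4\gamma^2$ in the numerator sum, $16\gamma^4$ over the interaction df,
pooled error df $n_{1T}+n_{1C}+n_{2T}+n_{2C}-4$, same cap — is the natural
extension of the two-group formula and is isolated in
`adjusted_treatment_contrast()` so sensitivity analyses can swap it out.

$\gamma$ is treated as a known plug-in constant throughout; its sampling
error enters only through the interaction df term. No uncertainty interval
is attached to $\hat\gamma$ itself.

## Multi-lab replicability calls

A genotype difference is called *replicable* when it is significant in the
multi-lab experiment under the Random Lab Model. `replicability_calls()`
estimates each pairwise difference by the unweighted average of per-lab cell
means (so additive lab effects cancel even in ragged designs) with variance

$$\widehat{se}^2 = \hat\sigma^2 \frac{1}{L^2}\sum_l\left(\tfrac{1}{n_{1l}}
  + \tfrac{1}{n_{2l}}\right) + \frac{2\hat\sigma^2_{GxL}}{L}.$$

For the reference distribution, this variance is re-expressed as a weighted
sum of the error mean square and the interaction mean square rather than of
the (correlated) component estimates. On balanced data the error-MS weight
vanishes and the call reduces to the exact classical balanced mixed-model
t test with $(L-1)(G-1)$ df; a naive Satterthwaite over the component
estimates ignores their correlation and was measurably anticonservative
(null call rate ≈ 0.07 instead of 0.05 at 3 labs × 6 genotypes × 10).
With the mean-square decomposition the simulated null call rate is 0.051
(1,000 replicates, $\gamma = 0.5$). Pairs with a genotype absent from some
lab are skipped with a warning. Each pair is tested at $\alpha$ with no
multiplicity adjustment by default — the toolkit deliberately leaves
multiple-testing control to the analyst — with a Tukey studentized-range
option (`multiplicity = "tukey"`) for those who want single-step control
over the pairwise family.

## Categories, type-I replicability error, power

Each comparison is cross-classified by (multi-lab call, single-lab
significance, adjusted significance) into categories A–F; the combination
"single-lab nonsignificant but adjusted significant" is impossible by the
monotonicity above and raises an integrity error. From the counts:

* type I replicability error, unadjusted: $(D+E)/(D+E+F)$;
* type I replicability error, adjusted: $D/(D+E+F)$;
* power for replicable discoveries: $(A+B)/(A+B+C)$ and $A/(A+B+C)$.

Proportions get exact Clopper–Pearson 95% intervals (`binom.test`); the
exact method reproduces the published interval (6–20) for 12/99 where a
Wald interval does not. The intervals treat decisions as independent, which
they are not exactly — comparisons sharing a genotype are correlated — so
they should be read as approximate. Display convention: percentages to one
decimal, CI bounds to integers, standard rounding. No
false-discovery-style "non-replicability rate" is computed: such a ratio
depends on the powers of the particular historical designs in the
denominator and does not transfer to future experiments.

## Power and sample size under GxL

The adjusted two-group test has noncentrality
$\delta = \text{effect}/(\sigma\sqrt{2/n + 2\gamma^2})$ and
`power_of_design()` evaluates exact two-sided noncentral-t power at the
Satterthwaite df (both rejection tails are counted; `power.t.test` drops
the far tail and sits a few thousandths lower at small $n$).

Because the $2\gamma^2$ term survives $n \to \infty$, power is capped:
the noncentrality converges to $\text{effect}/(\sigma\sqrt{2}\gamma)$ and
the df to $(n_L-1)(n_S-1)$. `power_limit()` returns this ceiling — often
strikingly low (for effect $= \sigma$ and $\gamma = 0.5$ estimated from a
3×6 design, the ceiling is 0.249, no matter how many animals are used).

`required_n()` follows the classical iterative recipe: compute the
classical $n$ at SD $\sigma$, inflate to
$\sigma_1 = \sigma\sqrt{1 + n\gamma^2}$ (so that $\sigma_1^2 \cdot 2/n$
reproduces the Random Lab Model variance), recompute, iterate to a fixed
point; a 2-cycle returns the larger fixed point with a flag. Two design
choices deserve note. First, the inflation is implemented relative to
$\sigma$; the dimensionally inconsistent absolute form
$\sigma_1 = \sqrt{\sigma^2 + n\gamma^2}$, which coincides only at
$\sigma = 1$, is available via `inflation = "absolute"` for comparison.
Second, after the iteration converges the result is polished to the
smallest integer whose `power_of_design()` (Satterthwaite df, not the
classical df used inside the iteration) meets the target, so that
`power_of_design(required_n) >= target` and `required_n - 1` fails it,
exactly. Targets above the ceiling return "unattainable" together with the
asymptotic power.

## The synthetic-data generator

`simulate_multilab()` draws balanced, fully crossed datasets directly from
the generative model: fixed genotype means, then $L_l$, $(GL)_{gl}$ (and
$TL$, $TGL$ with a treatment arm), then i.i.d. Gaussian animal noise, all
on the analysis scale. Defaults mirror the canonical multi-lab phenotyping
stratum: 3 labs × 6 genotypes × 10 animals per group, $\sigma = 1$,
$\sigma_L = 0.5$ (lab shifts of half a within-group SD are routine),
$\sigma_{GxL} = 0.57$ (the interaction-to-error ratio of a well-measured
physiological phenotype such as body weight; behavioral endpoints run
higher, up to $\gamma \gtrsim 1$), zero genotype effects (the null
configuration), and for the treatment arm $\sigma_{TxL} = \sigma_{TxGxL} =
0.3$, reflecting that three-way interactions run smaller than two-way ones.
One call generates one sex stratum; multi-stratum studies are assembled
from several calls with distinct seeds.

The seed fully determines the table. Cell-level random effects are drawn
before animal noise in a fixed order, so the same seed yields the same lab
and interaction effects regardless of group size. `simulate_single_lab()`
re-draws the full multi-lab experiment and slices one lab, so a simulated
single-lab study has a known across-lab truth and the lab slices partition
the multi-lab table exactly. `simulate_dropout()` deletes animals uniformly
at random to produce unbalanced designs for exercising REML.

What the generator does *not* emulate: non-Gaussian or heavy-tailed noise,
variance heterogeneity between genotypes or labs, batch/cohort structure
within labs, missingness correlated with phenotype, or the idiosyncratic
distributions of real MPD/IMPC endpoints. Tests passing under the generator
therefore validate the machinery under the model's own assumptions; they do
not certify behaviour under model misspecification.

## Numerical choices and degenerate inputs

* Percent phenotypes are logit transformed with values clipped to
  $[\epsilon, 1-\epsilon]$ on the proportion scale, $\epsilon = 10^{-3}$,
  so exact 0% and 100% stay finite; grip-strength-like positive measures
  use the cube root; a log transform is available (body weight defaults to
  the identity scale, with log as an option).
* Group SDs use the $n-1$ denominator everywhere; cells with fewer than 2
  animals are excluded from summaries with a warning record.
* Variance components are truncated at zero and flagged; a zero
  within-group variance makes $\gamma$ undefined and raises an error.
* p-values are clamped into $(0, 1]$; a zero estimate yields $p = 1$.
* `fit_random_lab_model` requires ≥ 2 labs, ≥ 2 genotypes seen in ≥ 2
  labs, and at least one cell with replication; treatment fits require both
  treatment levels in every lab.

## Problem sizes used by the test suite

The simulation-based tests run at the design the generator defaults to
(3 × 6 × 10): 2,000 replicates per $\gamma \in \{0.3, 0.6, 1.0\}$ for the
naive/adjusted single-lab rejection rates, 500 REML fits per $\gamma$ for
factor recovery, 2,000 replicates for CI coverage, 2,000 for the null
calibration of the multi-lab calls, and 30 meta-replicates (each pooling
three single-lab studies of 15 comparisons) for the end-to-end property
that adjustment lowers the type-I replicability error. The acceptance
script uses 1,000 replicates per rejection rate and 300 REML fits, sizes at
which the Monte-Carlo standard error (≈ 0.007 on a rejection rate) is well
inside the tolerances being checked.

## Known limitations

* $\gamma$ transfer assumes the single-lab study samples the same
  population of genotypes and conditions as the multi-lab source; a
  database of tightly standardized labs tends to yield smaller $\gamma$
  and hence weaker protection.
* The treatment-contrast df generalization is one reasonable Satterthwaite
  extension among several; it is isolated in one function for exactly that
  reason.
* Exact binomial CIs on the category proportions ignore dependence between
  comparisons sharing animals or genotypes.
* The moments estimator is balanced-only by design; real archival data
  almost always require the REML path.
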