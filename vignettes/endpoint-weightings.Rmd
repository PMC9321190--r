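---
title: "Endpoint weightings: model, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Endpoint weightings: model, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neglectweights)
```

## The behavioural model

A line bisection response is modelled as an affine function of the two
endpoint positions,

$$P = w_L L + w_R R + c + \varepsilon, \qquad \varepsilon \sim N(0, \sigma^2),$$

with all positions as horizontal coordinates in millimetres, rightward
positive, in an environmental reference frame. The weightings $w_L, w_R$
measure how strongly the response tracks each endpoint; an ideal bisector has
$(w_L, w_R) = (0.5, 0.5)$ and $c = 0$. The composite bias
$\mathrm{EWB} = w_R - w_L$ is positive when the right endpoint dominates, the
signature of left neglect. A severely neglecting responder approaches
$(0, 1)$ with a negative intercept: the mark sits a fixed distance inside the
right endpoint regardless of the line.

The model's key assumptions are linearity in $(L, R)$ and additive Gaussian
noise that does not depend on line length. Every estimator in the package is
translation-invariant (the origin of the coordinate frame is irrelevant) and
unchanged under uniform rescaling of all coordinates, which the test suite
asserts as properties.

Two consequences of the affine model organise the package:

1. **Length-slope identity.** On a design that varies line length about a
   fixed centre ($L = \text{centre} - \ell/2$, $R = \text{centre} + \ell/2$),
   the directional bisection error $\mathrm{DBE} = P - (L + R)/2$ satisfies
   $$\mathrm{DBE} = \tfrac{w_R - w_L}{2}\,\ell + (w_L + w_R - 1)\,
   \text{centre} + c,$$
   so EWB equals exactly twice the OLS slope of DBE on length. This is how
   EWB is recovered from the classical clinical design, in which $L$ and $R$
   covary perfectly and the separate weightings are not identifiable. It also
   explains the cross-over of errors to leftward on very short lines: with
   $\mathrm{EWB} > 0$ and $c < 0$, the line $\mathrm{DBE}(\ell)$ has positive
   slope and negative intercept, crossing zero at some intermediate length.

2. **Subjective-line reproduction.** If, after bisection, the remembered left
   endpoint is reconstructed as the mirror of the right endpoint about the
   chosen midpoint, then $\text{reproduced left} = 2P - R$, which is
   independent of the real left endpoint whenever $P$ itself is. The per-side
   slope of reproduced on real endpoint position (1 = perfect tracking, 0 =
   none) and $\mathrm{EWBr} = \text{slope}_R - \text{slope}_L$ quantify this
   in data.

## Estimators

`fit_bisection_weightings()` is OLS of `response_mm` on `left_mm` and
`right_mm`, always with an intercept (a "best-fitting straight line" is
affine; forcing the fit through the origin would confound the weightings with
the anchoring constant). `ewb_from_length_slope()` is OLS of trial-level DBE
on trial-level length; `EWB = 2 * slope`. `fit_reproduction_weightings()`
fits one univariate regression per probed side. `fit_participant()` and
`fit_cohort()` dispatch automatically: the full regression when the design is
identifiable, the length-slope route otherwise.

Numerical and procedural choices:

- **Identifiability check.** The centred $[L, R]$ design matrix is tested by
  singular values: smallest/largest $< 10^{-8}$ is treated as rank-deficient
  and raises a classed error pointing at the length-slope route. The
  threshold is far below any ratio a real jittered design produces and far
  above double-precision noise on an exactly collinear one.
- **Trial-level fitting.** The length slope is fitted to trial-level DBE, not
  per-length means. On balanced designs the two are identical (tested); on
  unbalanced data trial-level fitting weights each response equally, which is
  what the model warrants. `per_length_means = TRUE` reproduces the
  means-based workflow exactly when wanted.
- **Univariate reproduction slopes by default.** The per-side slope of
  reproduced on real position is the definitional estimator of tracking
  fidelity. On independent-endpoint designs a bivariate option (reproduced on
  both $L$ and $R$, own-side coefficient) is available, but it is not the
  default because it changes the estimand on correlated designs.
- **Pooling across lengths.** Each participant's reproduction slopes come
  from one pooled regression over all their trials, the only reading
  consistent with "the slope of the straight line" per side; per-length
  estimates would be based on 4 points each here.
- **No robust regression or trimming.** Plain OLS throughout; no outlier
  rule is part of the model, and silently trimming trials would change the
  estimand.
- Minimum data: 3 trials for any regression, 2 distinct lengths for the
  length slope, 3 probes per side with varying real positions for
  reproduction; violations raise classed errors rather than NA results.

## The synthetic cohort

`generate_cohort()` exists so that every downstream stage — estimators,
cut-offs, effect sizes, the pipeline — is testable end to end without any
external data. It emulates a small clinical study: two groups of
`n_per_group = 10` agents, lines of 25, 100 and 250 mm with four repetitions
each at a fixed centre, and both endpoints probed after every bisection (12
bisection + 24 reproduction trials per participant). An
`independent_endpoints` design mode (L ~ U(−150, −20), R ~ U(20, 150) mm by
default) supports the full-regression route.

Group parameter defaults, and why:

- **Controls:** $w_L = w_R = 0.5 \pm 0.02$, intercept $0 \pm 1$ mm, motor SD
  2 mm, veridical reproduction (SD 2 mm). Near-ideal bisectors with a little
  between-agent spread; the implied control EWB spread (SD $\approx 0.03$) is
  of the order seen in small control samples on this measure.
- **Neglect:** $w_L = 0.05 \pm 0.05$, $w_R = 0.75 \pm 0.10$ (mean EWB 0.70,
  left endpoint nearly ignored), intercept $-12 \pm 3$ mm, motor SD 4 mm,
  subjective-line reproduction (SD 4 mm). The intercept is the one parameter
  we set by a design argument rather than borrowing a typical value: with
  mean EWB 0.70 the expected 25-mm DBE is $0.35 \times 25 + c$, so $c$ must
  lie below $-8.75$ mm for the short-line cross-over to appear in
  expectation; $-12$ mm puts the expected 25-mm group mean at $-3.25$ mm,
  comfortably leftward, while leaving 100 and 250 mm strongly rightward.
  These are generative choices that produce the qualitative neglect
  phenomenology, not estimates of any particular sample.
- Noise is Gaussian and homoscedastic across line lengths, and reproduction
  noise is set equal to motor noise (same effector, same scale). Real
  patients plausibly violate both (e.g. noise growing with length, or
  length-dependent anchoring distance $R - P$); the simulator deliberately
  exposes anchoring only through $(w_L, w_R, c)$.
- **Randomness.** One root seed; each agent gets a deterministically derived
  substream (a fixed integer map into the 32-bit range), so a cohort is
  byte-reproducible and a subset of agents can be regenerated without
  disturbing the rest.

What passing tests on this cohort do *not* show: that real neglect data are
linear in the endpoints, that real noise is Gaussian, or that real effect
sizes are as large as the simulated ones (the default cohort separates the
groups more cleanly than a heterogeneous patient sample would). The
simulation validates the estimators and the pipeline plumbing, not the
clinical claims.

## Single-case statistics

`modified_t()` compares one score with a small control sample:
$t = (x - \bar{x}_c) / (s_c \sqrt{1 + 1/n})$ on $n - 1$ df, with the sample
SD on the $n-1$ denominator (required by the derivation). The inflation
factor treats the control mean and SD as estimates, so the false-positive
rate equals the nominal level at any control sample size — the suite checks
calibration on 10,000 simulated null cases against a 3-Monte-Carlo-SD band.
`neglect_cutoff()` inverts the test into a score threshold; case-above-cutoff
and $p < \alpha$ agree to numerical round-trip precision.

Defaults: $\alpha = 0.05$, one-tailed, upper tail — under the
rightward-positive convention, left neglect produces abnormally *high* DBE,
EWB and EWBr, and 0.05 one-tailed is the conventional level for this method.
Both are parameters, not assumptions.

## Group effect sizes

With group SDs as different as controls' and patients' on these measures, a
pooled standardizer is dominated by the patient variance. The package uses
the averaged-variance standardizer
$$d^*_s = \frac{m_1 - m_2}{\sqrt{(s_1^2 + s_2^2)/2}},$$
with a small-sample correction $g^*_s = J(\nu)\, d^*_s$, where
$J(\nu) = \Gamma(\nu/2) / \left(\sqrt{\nu/2}\, \Gamma((\nu-1)/2)\right)$
(computed via `lgamma` for stability; $J \in (0,1)$, $\to 1$ as
$\nu \to \infty$) and $\nu$ is the Welch degrees of freedom
$$\nu = \frac{(v_1/n_1 + v_2/n_2)^2}{(v_1/n_1)^2/(n_1-1) +
(v_2/n_2)^2/(n_2-1)}.$$
Both the uncorrected and corrected values are always reported, because
published tables are not always explicit about which was printed; summary
tables built from rounded means and SDs can differ from trial-level
recomputation by a percent or so in either direction, and the correction
itself lowers the value by several percent at $n = 10 + 10$.

The 95% CI inverts the noncentral-t distribution of the Welch statistic on
the same df (`uniroot` on the noncentrality parameter, tolerance $10^{-10}$,
then rescaled to $d$ units). This interval is asymmetric about the point
estimate; symmetric intervals of the kind produced by a normal-approximation
SE will not coincide with it, which is worth remembering when comparing
against intervals printed elsewhere. Degenerate input (both SDs zero) raises
an error rather than returning an infinity.

## The pipeline

`run_pipeline()` is a pure function of (input data or cohort spec, $\alpha$,
correction flag, fit method): simulate or ingest, fit every participant,
derive upper cut-offs for mean DBE, EWB and EWBr from the control
participants, flag everyone against them, build the summary table with
effect sizes, and compute the EWB–EWBr association ($r^2$, pooled and
neglect-only). Reruns write byte-identical outputs (the manifest records
seed, config and a config hash, deliberately no timestamp). With no usable
control sample the summary is still produced and the cut-offs are omitted
with a warning. Control participants are flagged against cut-offs derived
from the full control sample including themselves — a small liberality that
matters only if one screens the controls.

## Problem sizes in the test suite

The suite's simulation checks use sizes chosen to make Monte-Carlo bounds
sharp while keeping the default run fast: 200 replicates of 120 trials for
the agreement of the two EWB estimators under 4 mm motor noise; 500
replicates of 60 trials for parameter recovery (each parameter within
max(0.05, 2 SE) of truth, with the SE taken from the known design and
$\sigma$, in at least 95% of replicates); 10,000 null cases for single-case
calibration. The whole suite runs in well under a minute.

## Limitations

- The estimators assume one linear regime per participant; they will average
  over any length-dependent strategy change rather than detect it.
- EWB from the length-slope route and from the full regression are the same
  quantity only under the affine model; on real data the two designs can
  disagree for substantive reasons.
- No hierarchical pooling: each participant is fitted independently, so very
  few trials per participant give noisy weightings with no shrinkage.
- Single-case methods here cover abnormality of a single score only, not
  dissociations between tasks.
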