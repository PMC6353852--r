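---
title: "A Bayesian information-gain model of novelty-elicited emotion"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A Bayesian information-gain model of novelty-elicited emotion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(noveltyGain)
```

## The model and its assumptions

A novel event moves an observer from a pre-event belief to a post-event
belief. The package assumes both are Gaussian: a prior $N(\eta, s_p)$
over a stimulus feature, and a likelihood peaking at the observed sample
mean $\bar{x}$ with variance $s_l = \sigma^2/n$. The Gaussian assumption
is what makes everything downstream closed-form; it is motivated by the
observation that neural population codes can represent Gaussian
posteriors, but nothing here depends on that interpretation.

Arousal is identified with the **information gain** of the update: the
KL divergence of the posterior from the prior,

$$G(\delta, s_p, s_l) = \tfrac{1}{2}\left[\frac{s_p\,\delta^2}{(s_p+s_l)^2}
  + \ln\frac{s_p+s_l}{s_l} - \frac{s_p}{s_p+s_l}\right]
  = \alpha\,\delta^2 + \beta,$$

with prediction error $\delta = \bar{x}-\eta$. All gains are reported in
nats: the literature writes "log" without a base, and the natural log is
what makes the closed form exact against `kl_gaussian()`. The sign
convention $\delta = \bar{x} - \eta$ (reality minus expectation) is a
documentation choice only, since only $\delta^2$ enters $G$.

Two structural facts drive the psychology:

* $\alpha > 0$ always, so arousal grows with the squared prediction
  error;
* $\partial\beta/\partial s_p = s_p/(2(s_p+s_l)^2) > 0$, so at zero
  prediction error the more uncertain observer gains more. (Some prose
  accounts state this derivative with the opposite sign; the formula, and
  every downstream claim, require it positive, and the test suite asserts
  exactly that.)

Because higher uncertainty raises the intercept $\beta$ but lowers the
slope $\alpha$, two gain curves at uncertainties $s_{p1} \ne s_{p2}$ and
common noise $s_l$ intersect iff $s_{p1} s_{p2} > s_l^2$ — the **arousal
crossover effect**. `crossover_point()` solves the intersection
analytically; on the measure-zero boundary $s_{p1}s_{p2}=s_l^2$ the two
quadratics are parallel and the function reports `exists = FALSE` rather
than raising, because the configuration is mathematically meaningful.

## Valence

Valence is the sum of a reward and an aversion sigmoid of $G$
(`valence()`), with the structural constraints $G_r < G_a$ and
$h_r < h_a$. The model fixes no numeric values for the six parameters;
the shipped defaults ($G_r=2$, $G_a=6$, $h_r=1$, $h_a=1.5$, $c_r=c_a=1$)
were chosen once to satisfy both constraints and produce a clear
inverted U, and every one is overridable. Two numerical choices are
deliberate:

* **No baseline subtraction.** The formula gives
  $\mathrm{Valence}(0) = h_r/(1+e^{G_r}) - h_a/(1+e^{G_a}) \ne 0$; the
  package does not renormalise to force neutrality at zero gain. The
  "zero information, neutral valence" reading is an approximation that
  holds when both thresholds are large.
* **Optimum search.** `optimal_gain()` scans a 10,001-point grid and
  refines the bracketing cell with `stats::optimize()` to tolerance
  1e-8. The inverted-U property is asserted for the shipped defaults,
  not claimed universally: with $c_r(G_a/c_a - G_r/c_r)$ small the curve
  can be monotone even under both constraints.

## Desensitization

`simulate_exposures()` formalises repeated exposure as
update-and-repeat: the posterior becomes the next prior while $s_l$ is
held constant per run (whether familiarity should also shrink $s_l$ is
left open in the literature; holding it constant is the minimal
assumption). Uncertainty then follows the exact recursion
$s_{p,k} = 1/(1/s_{p,0} + k/s_l)$ independent of the data, and in the
noise-free case the prediction error shrinks geometrically,
$\delta_{k+1} = \delta_k\, s_l/(s_{p,k}+s_l)$. Per-step gain therefore
eventually declines — desensitization — and valence retraces the
inverted U from the high-gain side. Note the sweep through the valence
optimum is only visible when learning is slow ($s_l$ comparable to or
larger than $s_p$); with $s_l \ll s_p$ a single update collapses the
gain past the optimum.

Observation noise, when enabled, is Gaussian on $\bar{x}$ with
configurable sd and a mandatory seed; the variance trajectory is
unaffected (it is data-independent), only $\delta$ becomes stochastic.

## The synthetic experiment

`simulate_experiment()` replays, in silico, a 2×2 within-subject
audiovisual design: 8 percussion videos (familiar/unfamiliar instrument
× congruent/incongruent sound, two instruments per cell) shown in 20
randomised presentation sets per subject (160 trials; the sound-only
control uses 5 sets, 40 trials), ISIs uniform on 1000–2000 ms.

The condition → parameter mapping is a **modelling choice, not a
measured quantity**: familiarity sets $s_p$ (A: 0.2, B: 1.0), congruity
sets $\delta$ (X: 0, Y: 2.0), shared $s_l = 0.1$. The scale is borrowed
from the canonical gain-curve family; the only structural requirements,
enforced by validation, are $s_p(B) > s_p(A)$, $\delta(Y) > \delta(X)
\ge 0$, and (checked in tests) that $\delta(Y)$ lies beyond the
crossover point, so the model's predicted cell gains exhibit
$G(BX) > G(AX)$ and $G(AY) > G(BY)$.

Simulated measures:

* **Likert surprise ratings** — latent $1 + 0.6\,G$ plus subject offsets
  (sd 0.3) and trial noise (sd 0.5), discretised at fixed, equally
  spaced cut points 1.5/2.5/3.5 onto the 4-point scale. All values are
  invented realistic settings declared in
  `default_likert_config()`. Every trial produces a rating (the original
  protocol's rating-at-sets-1/10/20 timing is a detail the replica does
  not reproduce).
* **ERP epochs** — 500 Hz, −200 to +1500 ms around video onset. The
  half-open sampling convention (sample $i$ at $-200 + 2i$ ms,
  $i = 0\ldots849$; the +1500 ms endpoint excluded) removes an
  off-by-one ambiguity. Each epoch is a Gaussian P300 bump at sound
  onset (+500 ms) plus a jittered latency (350 ± 30 ms), width 50 ms,
  amplitude $2 + 3G$ µV plus a subject offset (sd 1 µV), a random linear
  drift (sd 1 µV/s) and white noise (sd 10 µV). Only Pz is synthesised
  (the dominant P300 site). The acquisition chain (0.1–20 Hz bandpass,
  3 s time constant) is not modelled.
* **P300 extraction** — baseline is the mean of the 200 ms pre-onset
  segment; epochs exceeding ±100 µV after baseline correction are
  rejected (correction first, so a constant offset cannot trigger
  rejection); the P300 is the largest positive peak 250–600 ms after
  sound onset, ties broken toward the earliest latency. Epochs are
  averaged per subject × condition before extraction, as in standard ERP
  practice.

What a green end-to-end test establishes: that *if* conditions map onto
(uncertainty, prediction error) as configured, the crossover pattern and
a significant familiarity × congruity interaction are recovered by the
full schedule → epochs → extraction → ANOVA pipeline in at least 90% of
seeded replicates at 9 subjects. It does not establish anything about
real EEG: the generator has no ocular artifacts beyond the threshold
rule, no 1/f background, no electrode covariance, and its effect sizes
are set by the mapping, not estimated from data.

## Statistics

`two_way_rm_anova()` is a fully within-subject engine: each effect is
tested against its own subject-interaction stratum, with sums of squares
computed from cell and marginal means. Design choices:

* multiple trials per subject × cell are averaged before the ANOVA;
* the averaged design must be complete — unbalanced input is an error,
  never imputed;
* no sphericity correction is applied: with 2-level factors every
  effect has 1 numerator df, so the correction is moot (the engine
  accepts larger factors, where users needing corrections should apply
  them externally);
* simple main effects use per-slice error strata (a pooled-error
  variant exists in the literature; per-slice is the more conservative
  and the more common follow-up to a significant interaction), and a
  zero-variance slice raises a degenerate-data error;
* a zero error stratum yields `F = Inf`, `p = 0` for a nonzero effect
  and `F = NaN`, `p = NA` when the effect is also zero.

`detect_crossover_pattern()` is deliberately strict: both inequalities
must hold strictly, and any exact tie returns `FALSE` with a `tie`
attribute.

## Tolerances and degenerate inputs

Algebraic identities (closed form vs composed KL, SS partition) are
tested at 1e-10 to 1e-8; quadrature comparisons at 1e-6, where the
quadrature error dominates; the crossover root at 1e-9 against
bisection. Zero or negative variances are rejected everywhere, never
clamped — silent clamping would mask invariant violations. Variances
have no imposed upper bound; flat-prior behaviour is exercised with
large finite values.

Seeds are explicit parameters of every stochastic entry point, and
seeded runs restore the caller's RNG state (no hidden global state).
Component generators accept `seed = NULL` to draw from the current
stream so that a single outer seed can drive a composite simulation.

## Known limitations

* The valence parameters are unconstrained by data; no fitting to
  behavioural ratings is provided (none exist in scope).
* The condition mapping's numeric scale is conventional; only its order
  relations are meaningful.
* The replica's statistical power statement is specific to the shipped
  generator settings and 9 subjects.
* Pre-exposure familiarisation (the five congruent-familiar viewings a
  protocol might include before the main session) is available by
  composing `simulate_exposures()` with a lowered starting `s_p`, but is
  off by default.
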