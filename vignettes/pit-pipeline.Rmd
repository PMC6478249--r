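---
title: "Models and methods behind the pitsim pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the pitsim pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pitsim)
```

`pitsim` implements an analysis pipeline for an aversive
Pavlovian-to-instrumental-transfer (PIT) paradigm: an instrumental coin
game crossed 2 (Approach/Withdraw) × 2 (Go/NoGo), a Pavlovian threat
conditioning phase with an electric-shock US, and a transfer phase in
which the instrumental task is played on CS-colored backgrounds. This
vignette records the models, the parameters that matter, and the design
choices that were genuinely open — the things a maintainer or reviewer
would want to know before trusting or changing a default.

## The coin game as a stochastic process

Only the coin's horizontal position matters for outcomes; vertical motion
is cosmetic timing. We model the position $x_t \in [0, 1]$ at the monitor
frame rate ($\Delta t = 1/60$ s) as

$$
x_{t+1} = x_{\mathrm{def}} + (x_t - x_{\mathrm{def}})\,e^{-\lambda \Delta t}
  + \varepsilon_t + \mathrm{press}_t \cdot \mathrm{dir} \cdot
  \mathcal N(\mu_k, \sigma_k^2),
\qquad \varepsilon_t \sim \mathcal N(0,\ \sigma_w^2 \Delta t),
$$

clamped to the screen. The first two terms are the simplest process with
a negative-exponential drift toward the default target: an
Ornstein–Uhlenbeck-type relaxation whose fixed point is the default
column. Each key press adds an independent Gaussian displacement directed
away from the default target. Two modeling decisions here were open and
are worth flagging:

* **Signed displacements.** Press displacements are full Gaussian draws,
  so a press can occasionally move the coin backwards. This keeps both
  failure modes of real play — falling short of the target and
  overshooting it — reachable, and costs nothing when
  $\sigma_k = 0.3\,\mu_k$ (a backward draw is a $3.3\sigma$ event).
* **Weak drift, small walk noise.** $\lambda = 0.05\,\mathrm{s^{-1}}$ and
  $\sigma_w = 0.002\ \mathrm{units}/\sqrt{\mathrm s}$. The drift must be
  weak enough that a responder capped at `max_press_rate` (9 presses/s)
  can out-push it over the 0.4-unit gap between targets within 5 s, and
  the walk noise small enough that an untouched NoGo coin stays inside
  its window for the whole response period (the unperturbed standard
  deviation after 5 s is ≈ 0.004 units, against a half-window of
  ≈ 0.028). Both are therefore consequences of the task's published
  behavior — NoGo trials succeed by doing nothing — rather than free
  dials.

Outcomes partition the screen: a final position within half a window
width (inclusive) of the desired target wins, within the punitive
target's window loses, anything else is incomplete. Window geometry is
validated at construction so the two windows can never overlap.

## Calibration

Two simulation statistics anchor the dynamics: the ideal responder needs
**32.12 key presses** on average to win a 5-s Go trial, and the target
window is about **four presses wide**. `calibrate_params()` fixes the
window at `window_in_presses * press_mu` and bisects on $\mu_k$ (holding
the $\sigma_k/\mu_k$ ratio), evaluating each candidate with a fixed-seed
Monte-Carlo estimate of `required_presses_stat()`, until the mean press
count among winning trials is within tolerance (0.5 presses) of the
target. Given the seed the procedure is deterministic; an unreachable
target is reported as a calibration failure rather than silently
returned. The packaged default `press_mu = 0.013793` is the output of
this procedure at 20,000 trials per step.

Only the mean is calibrated. The press-count dispersion is emergent, and
with $\sigma_k = 0.3\,\mu_k$ comes out at ≈ 1.6 presses against the
printed ± 1.80 — close, but not tuned to match, and honest about being a
consequence rather than a target.

The ideal responder is a bang-bang controller: press at the rate cap
whenever the coin is short of the desired window, stop inside it, let the
drift re-trigger pressing. Whether the original simulations used an
optimal controller or pilot data is not documented; the controller
reading is assumed because it makes "required presses" well defined.

## Responder policies and the synthetic cohort

Human-like play is modeled by a *free-running* responder: after a
log-normal first-press latency it presses with constant hazard,
independent of the coin's position. This is deliberately open-loop — the
press **rate** is the behavioral channel that carries the PIT effect, and
an open-loop responder transmits a configured rate increment to the
measured response rate without attenuation by feedback control. The price
is realism in the secondary measure: open-loop Go accuracy is far below
that of real participants, who steer with visual feedback. Tests that
exercise accuracy therefore use the ideal or absent policies, where
accuracy is meaningful; conclusions about accuracy in real data should
not be drawn from the human policy.

`sample_cohort()` draws subjects with Gaussian baseline Go rates
(6.0 ± 0.5 presses/s — near the rate an ideal player needs, so simulated
players are competent), a Gaussian individual Withdraw-Go CS+ increment,
and log-normal latencies (median 0.35 s, Withdraw + 0.08 s, matching the
observed approach/withdraw latency asymmetry). The generator sizes the
population increment $\delta$ analytically so that the *measured*
paired effect equals the configured `pit_d`:

$$
\delta = d \sqrt{\tau^2 + 2 V_{\mathrm{meas}}}, \qquad
V_{\mathrm{meas}} = \frac{1}{n_{\mathrm{trials}}}\left(
  \frac{\rho(1 - \rho'\Delta t)}{T} + \frac{\rho'^2\,
  \mathrm{Var}(L)}{T^2}\right),
$$

where $\tau$ is the between-subject SD of the increment, the first term
is binomial press noise over the response period $T$, and the second the
latency-induced variance ($\rho'$ is the hazard after compensating the
latency-shortened pressing window). Because $V_{\mathrm{meas}}$ depends
on the design's trial counts, the same `pit_d` is recovered under both
experiments' phase-3 structures. Unit tests verify the accounting: the
mean recovered *d* over cohorts of 200 subjects sits within 0.05 of the
target.

Psychophysiological readouts are generated at the condition level only
(one amplitude per subject per CS), as `amplitude = mean_cs + subject +
noise`; the defaults reproduce the confirmation-sample means (SCR
0.39/0.30 µS, pupil 3.16/3.02 mm, heart period 13.86/−15.52 ms), their
paired effect sizes (0.673 / 0.52 / 0.78), and per-level spreads
recovered from the reported standard errors at n = 35. Raw physiological
time series, trial-level amplitudes, learning dynamics within phases,
and extinction across the (nominally non-reinforced) transfer phase are
all outside what the generator emulates — passing tests say the
*pipeline* recovers what was put in, not that real data look like this.

Per-subject shock intensities come from `calibrate_us_intensity()`:
piecewise-linear interpolation of current as a function of rating,
evaluated at 85% of the rating scale. "85% of the threshold" admits a
second reading — 85% of the threshold *current* — which is exposed as
`interpolate_on = "current"`; the rating-scale reading is the default.
Non-monotone rating series use the first crossing from below, the
conservative (lower-current) tie-break.

## Behavioral measures

Response rate is presses per second averaged over the entire 5-s response
period; accuracy is the fraction of trials whose coin reached the
required target (for Withdraw, that means reaching the dot window, not
merely avoiding the machine — consistent with the three-way outcome
partition); first-press latency is measured from response onset. The
1-s preview admits no presses, so the latency clock starts at response
onset, not trial onset. On NoGo cells, latency is aggregated only over
incorrect trials (a correct NoGo trial has no presses to time); cells
with no qualifying press are `NA`, never zero. Aggregation runs
per-trial → per-subject-cell → group, so subjects are the error unit
throughout.

## Inferential layer

`rm_anova()` uses the classical univariate error-stratum decomposition
(`aov` with `Error(subject/(A*B*C))`): every within effect is tested
against its own subject × effect interaction. Three reporting choices:

* **Greenhouse–Geisser ε** is computed per effect from the
  between-subject covariance of that effect's cell scores (collapsed over
  the other factors), projected onto the effect's orthonormal contrast
  space. Effects with one degree of freedom have ε = 1 by construction —
  two-level factors cannot violate sphericity — and the corrected
  p-value is reported alongside the uncorrected one only when it can
  differ.
* **Generalized η²** uses the all-error denominator (effect SS over
  effect SS plus *every* error SS including the between-subject term),
  the convention that makes effect sizes comparable across designs with
  different factorizations.
* The confirmatory Withdraw-Go contrast supports a one-sided mode
  (matching the direction-specific power analysis); ANOVA follow-ups are
  two-sided. Where the original reports did not state sidedness, two-
  sided is assumed.

Cohen's *d* for paired data is defined on difference scores, so
`d = t/√n` exactly — the identity under which the published effect sizes
(0.40 from t(34) = 2.37; 0.61 from t(20) = 2.78) reproduce to the printed
digits. Bonferroni correction takes the family size as an explicit
argument because the planned family (e.g. two block-wise tests) can
exceed the number of p-values being corrected in a call.

## Predictive validity

Each measure's ability to separate CS+ from CS− is scored by a *reversed*
regression: the CS indicator (coded ±1; the coding does not affect RSS
orderings) is the dependent variable, the measure plus single-subject
intercepts the design. The residual sum of squares maps to
`AIC = n log(RSS/n) + 2(r+1)` — natural logarithm, the only base under
which the formula is used consistently — and measures are compared by
`LBF = (AIC − AIC_ref)/2` with |LBF| > 3 decisive. `compare_measures()`
refuses tables with different subject sets: with equal (n, r) the LBF
reduces to an RSS ratio, and the AIC ranking across measures provably
equals the |t| ranking of the paired contrasts, a property the test suite
checks on random data. A degenerate (constant) measure falls back to the
intercepts-only fit; an exactly zero RSS yields −Inf AIC with an explicit
warning rather than an error, since a perfect predictor is a legitimate
limit. Block-restricted measures (e.g. block 1 only) reuse the same
subjects, hence the same (n, r), so their evidence is comparable to the
full-phase measure.

Cross-measure dependence is assessed twice: correlations of per-subject
CS+ − CS− differences, and residual correlations after removing each CS
level's grand mean within each measure (pooled over subject × CS rows).

## Power

`power_paired_t()` evaluates the exact noncentral-t power of the paired
test (df = n − 1, noncentrality d√n) and `required_n()` returns the
smallest integer n meeting a target. This is the same model conventional
power software implements, so the published figure — 37 participants for
80% one-sided power at d = 0.42 — reproduces with no external tool:

```{r power}
required_n(d = 0.42, target_power = 0.80, alpha = 0.05, sided = "one")
power_paired_t(d = 0.42, n = 37, alpha = 0.05, sided = "one")
```

`mc_power()` is the package's own simulation oracle (paired differences
from $\mathcal N(d, 1)$); the suite checks agreement with the analytic
path within three Monte-Carlo standard errors across a parameter grid.
For two-sided tests the analytic path includes the opposite-tail
rejection mass, which `stats::power.t.test` neglects; the difference is
below $10^{-3}$ in practical ranges and is asserted, not hidden.

## Numerical choices and problem sizes

Degenerate inputs fail loudly: duplicated subject × cell rows,
incomplete designs, zero-variance difference scores, singular covariance
matrices, overlapping target windows and policy rates above the cap are
all errors, not warnings. Window membership is inclusive at the boundary.
Screen positions are clamped to [0, 1]; the clamp binds only in extreme
noise regimes. RNG discipline: the compiled trial kernel consumes R's
own stream (one walk draw per step, one displacement draw per press), so
a pure-R replay of the recursion reproduces compiled trajectories bit for
bit under a shared seed — this equivalence is under test, and everything
downstream is reproducible from a single `set.seed()`.

The test suite's Monte-Carlo sizes are chosen to hold sampling error well
below each assertion's tolerance while keeping the default run around
five minutes: 10,000 trials for outcome-probability checks, 5,000 trials
for the press-count statistic, 300 replicate 35-subject cohorts for
effect-size recovery and the measure-ranking majority, 2,000 null cohorts
for the type-I calibration of the a priori contrast (checked against a
3-standard-error binomial band around α), and 12 cohorts of 200 subjects
for the convergence check.

## Known limitations

* The human responder is open-loop; simulated Go accuracy is unrealistic
  and accuracy-based conclusions should come from the ideal policy or
  real data.
* The generator produces stationary behavior within a phase: no
  instrumental learning curves, no extinction of the PIT effect across
  transfer blocks (the block-1/block-2 asymmetry seen in real data is
  not emulated).
* Psychophysiology is condition-level Gaussian; skewness and floor
  effects of real SCR amplitudes are not modeled.
* The ANOVA layer covers fully within-subject balanced designs with up to
  three factors — the paradigm's designs — and does not implement
  between-subject factors or Huynh–Feldt correction.
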