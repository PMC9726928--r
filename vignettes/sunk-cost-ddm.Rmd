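---
title: "Sunk-cost sensitivity in a change-of-mind drift-diffusion agent"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sunk-cost sensitivity in a change-of-mind drift-diffusion agent}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sunkddm)
```

## The task and the model

In delay-based foraging tasks of the Restaurant-Row / Web-Surf family, a
subject cycles past reward sites. At each site an offer — a delay of 1 to
30 s, drawn uniformly and revealed on entry — can be *accepted* (entering a
wait zone where the delay counts down) or *skipped*. Once waiting, the
subject may still *quit*, rescinding the offer. Sunk-cost sensitivity is the
escalation of commitment with time already waited: at matched time
remaining, subjects that have waited longer are less likely to quit.

`sunkddm` implements the change-of-mind drift-diffusion account of this
behavior. Each trial draws an initial willingness to wait

$$W_0 = W_T + \mathcal{N}(0, \sigma_W),$$

with the offer-zone threshold $W_T = 18$ s by default. The offer is accepted
iff $W_0 \ge \text{offer}$, so the accept/skip psychometric is exactly
$\Phi((W_T - \text{offer})/\sigma_W)$. In the wait zone the decision
variable drifts once per second, $W(t) = W(t-1) + \mathcal{N}(0, \sigma_N)$,
and the agent quits at the first second ($t = 1 \dots \text{offer}-1$) where
$W(t)$ falls below the quit threshold $T_{WZ}(t)$. In the original model
$T_{WZ}$ starts at the offer on wait-zone entry and falls 1 s per second,
reaching 0 exactly when the countdown ends — an *expanding* lower bound that
moves away from $W_0$ at 1 s/s.

A note on the accept rule: the acceptance condition is $W_0 \ge
\text{offer}$, not $W_0 \ge W_T$. Only this reading produces a non-trivial
accept/skip psychometric (and hence the tangent-based $\sigma_W$ estimate),
guarantees agents enter the wait zone above the quit threshold, and
reproduces the attrition-bias structure; with a fixed-threshold rule the
accept curve is flat in the offer and the entire calibration machinery is
undefined.

Two components of the wait-zone process carry information about the time
already spent: the expanding bound (the gap $W - T_{WZ}$ grows 1 s/s), and
the one-sided bound structure (without an upper bound the variance of $W$
grows with time, letting survivors drift away from the threshold). The
package exposes knockouts of each: `twz_slope = 0` (flat bound at the
offer), `twz_init = "zero"` (bound pinned at 0 — quits all but vanish),
`twz_slope = +1` (a collapsing, anti-sunk bound), and
`upper_bound = "non_increasing"` (drift draws that would raise $W$ are
clipped to $W(t-1)$).

```{r variants}
bubble_of <- function(cfg) {
  sunk_cost_bubble(build_pearn_matrix(run_experiment(cfg)))$bubble_total
}
n <- 2e4  # small here; the analysis drivers use 2e5-1e6
c(original = bubble_of(sim_config(n_trials = n, seed = 1)),
  anti_sunk = bubble_of(sim_config(twz_slope = 1, n_trials = n, seed = 1)))
```

## The measures

All measures operate on a trial log (a `session_set`), whatever generated
it.

**p(Earn) matrix** (`build_pearn_matrix()`). Every accepted trial passes
through states (time-spent $s$, time-remaining $r$); `p_earn(s, r)` is the
probability that a trial observed in that state stays to earn. A quit at
second $q$ counts as a not-earn for the states $s = 0 \dots q-1$ it passed
through; no state is recorded at the quit second itself. Cells with fewer
than `min_count` passes are undefined (`NA`), never zero-filled; the default
`min_count = 1` suits simulation-scale runs, and ~5 is advisable for small
behavioral sessions.

**Sunk-cost bubble** (`sunk_cost_bubble()`). $B(s) = \sum_r [p(s,r) -
p(0,r)]$ over the time-remaining cells defined in both rows, and the total
bubble $\sum_{s \ge 1} B(s)$. We sum over *all* cells defined in both rows
rather than a fixed time-remaining window; the window is not pinned down by
any operational rule we could adopt, and the all-defined-cells convention is
the one every downstream result in the package is computed under.

**Baseline slope** (`baseline_slope()`): OLS slope of $p(0, r)$ on $r$ —
how steeply earning falls with countdown length before anything is sunk.

**Attrition bias** (`attrition_slope()`): each trial contributes its $W_0$
at every second it remains in the wait zone ($s = 0 \dots e-1$); the measure
is the OLS slope of the pooled scatter, computed from per-trial sufficient
statistics (identical to expanding the points, without materialising them).

**Thresholds and the psychometric** (`estimate_threshold()`,
`probit_accept_fit()`). The site threshold is a grid maximum-likelihood
estimate over integer candidates 0..30 s under a step psychometric with a
fixed lapse (default 0.05; the argmax is insensitive to its exact value, and
a jointly fitted lapse is deliberately avoided — with a step likelihood the
two parameters are barely identified on session-sized data). Ties break to
the midpoint of the maximising set. The probit fit is a two-parameter
maximum-likelihood probit of accept on offer; its *tangent* at the 50%
point is the analytic derivative $|\beta|\,\varphi(0)$. For model-generated
data the tangent estimates $\varphi(0)/\sigma_W$, so
$\sigma_W = a + b/\text{tangent}$ with $a = 0$, $b = \varphi(0) \approx
0.3989$ in the ideal limit; `calibrate_sigma_w_relation()` measures this
relation empirically across a $\sigma_W$ grid and `fit_hyperbolic()` fits
it. Simulated calibrations reproduce $b \approx 0.40$ and adjusted
$R^2 \approx 0.9997$; the empirical intercept stays within a few hundredths
of zero, as the closed form requires.

**Value-conditioned deltas** (`value_conditioned_deltas()`). With value $v =
\text{threshold} - r$, the per-cell $\Delta p$ at $v < 0$ (remaining delay
above threshold — a bad deal) is compared against $v > 0$ with a two-sample
Wilcoxon rank-sum test. "Rank test" is often used loosely for two distinct
procedures; this package applies the two-sample rank-sum here and the
one-sample signed-rank (against 0) in `mesh_comparison()`, and labels each
in its output. Cells are the analysis unit, unweighted; weighting by pass
counts changes emphasis but not the sign structure on simulation-scale data.

**Latency to accrual** (`latency_to_accrual()`): the smallest time-spent
whose bubble contribution exceeds `kappa_frac` (default 0.10) of the maximum
contribution with the next bin also above. The two-bin persistence guards
against single noisy bins; the 10% fraction is an operational choice — the
only rule stated for the original analyses is the outlier cutoff, which we
keep: latencies above 15 s are flagged as outliers.

## The experiment drivers

`run_parameter_sweep()` runs the $9 \times 4$ grid $\sigma_W \in \{0, 0.25,
0.5, 1, 3, 5, 8, 10, 20\} \times \sigma_N \in \{0, 2, 3, 5\}$.
`sweep_regressions()` fits the four OLS models (attrition, baseline slope
and bubble each on $\sigma_W + \sigma_N$; bubble on attrition) on the
per-cell means — one point per cell, so 36 points and 33 (or 34) residual
df. Per-predictor F statistics are squared coefficient t values, the
1-numerator-df partial F.

`run_reset_experiment()` models task variants without a usable offer zone:
accept-all agents that cannot quit for an imposed decision time DT, with
$W$ reset to $W_0$ when DT ends. Model 1 holds $T_{WZ}$ at the offer until
DT ends; model 2 lets it fall from entry. Over DT $\in \{0..10\}$ s
(defaults; the grid is configurable) the total bubble declines with DT in
both models, but the shapes differ sharply and that difference is the
discriminating statistic: model 2 bends strongly upward (large positive
quadratic coefficient — mid-range decision times less sensitive than the
linear trend, the curve flattening at long DT), while model 1 stays
near-linear with a quadratic coefficient close to zero. Both quadratic fits
have adjusted $R^2$ near 0.99–1.00. `linquad_convexity_fit()` reports
curvature in the standard second-derivative convention (positive quadratic
coefficient = convex / concave-up); because informal convex/concave labels
are used inconsistently across sources, the package always reports the
signed coefficient alongside the label, and the model-1-versus-model-2
contrast is asserted on the coefficient magnitudes and the model-2 sign,
which are unambiguous.

`mesh_comparison()` places subjects summarised by (baseline slope, bubble,
$\hat\sigma_W$) against the sweep mesh. The nearest-cell rule — candidates
matched on $\sigma_W$ first, then Euclidean distance on z-scored (baseline
slope, bubble) axes — is a convention this package fixes and records in its
output; the axes are standardised because the two measures live on scales
three orders of magnitude apart. Signed subject-minus-mesh differences are
tested against zero with one-sample Wilcoxon signed-rank tests; fewer than
6 subjects is flagged low-power, and an all-zero difference vector is
reported as degenerate rather than tested.

## The synthetic-session generator

`generate_sessions()` draws behavioral sessions from a per-second quit
*hazard* model — deliberately outside the drift-diffusion family, so
validating the measures does not reuse the machinery under test. Offers are
uniform on 1..30 over four sites; accepts follow a lapse-mixed probit
around per-site thresholds (defaults 12, 16, 20, 24 s with 4 s accept noise
and 2% lapses — heterogeneous but realistic site preferences spanning the
offer range); accepted trials quit each second with probability
$\text{logistic}(\text{logit}(h_0) + c_r (\text{offer}-t) + c_s t)$. The
defaults ($h_0 = 0.05$, $c_r = 0.10$, $c_s = -0.08$) give quit rates in the
tens of percent with escalating commitment. Because the model is fully
specified, $p(\text{Earn} \mid s, r)$ has the closed form
$\prod_{t=s+1}^{D-1}(1 - h(t))$ (`pearn_survival_oracle()`) — an analytic
oracle for the entire measurement chain — and the sign of $c_s$ fixes the
sign the measured bubble must recover: $c_s = 0$ makes the hazard a function
of time remaining only, so the bubble must vanish; $c_s < 0$ forces it
positive.

```{r synthetic}
g <- generate_sessions(behavior_gen_config(hazard_coef_spent = 0,
                                           n_trials = 2e4, seed = 2))
sunk_cost_bubble(build_pearn_matrix(g, min_count = 20))$bubble_total
```

What the generator does *not* emulate: session-level time budgets and
satiety, learning across trials, reward-flavor preferences beyond the
per-site thresholds, and reaction-time structure. Tests passing on these
sessions show the measures recover known generative structure; they do not
show that real subjects follow either generative model.

## Numerical and design choices

- **Time grid.** Everything runs on a discrete 1 s grid: quit checks at
  $t = 1 \dots \text{offer}-1$ only, reward at $t = \text{offer}$ with no
  final check (a final check would compare against $T_{WZ} = 0$ and could
  never fire in the original variant). Real-valued times in input logs are
  floored with a warning.
- **Inequalities.** Quitting is strict ($W < T_{WZ}$); acceptance is weak
  ($W_0 \ge \text{offer}$).
- **$T_{WZ}(0)$.** The bound starts at the offer on wait-zone entry — the
  only reading consistent with a -1 s/s slope reaching 0 at countdown end.
- **Decision time.** During DT, no quit checks run and $W$ holds at $W_0$;
  drawing and discarding drift would be distributionally identical, so the
  discarded draws are simply not made. The threshold function, not the
  drift, is what distinguishes the two reset models.
- **No flooring of variant bounds.** The anti-sunk bound grows without
  limit; the zero bound stays at zero. With the bound pinned at zero the
  quit rate is near zero (~3% at baseline parameters) but not exactly zero
  — $W$ can wander below 0.
- **Determinism.** Each experiment consumes one seeded stream in a fixed
  order (offers, $W_0$, per-second drift blocks), so identical
  configuration and seed reproduce the trial table bitwise. Campaign seeds
  derive deterministically from (base seed, cell index, replicate), keeping
  every sub-run below `2^31` and independently re-runnable.
- **Degenerate inputs.** All-accept/all-skip threshold data return the grid
  boundary with a degeneracy flag; perfectly separated probit fits return
  an infinite tangent flag and are dropped from calibration with a warning;
  bubble and baseline measures return `NA` with a diagnostic when no
  overlapping cells exist.
- **Problem sizes.** The analysis drivers use 2e5–1e6 trials per
  experiment; the test suite uses 1e3–1e5. Monte-Carlo noise in the bubble
  at 1e5 trials is a few units of summed probability, which the
  sign-recovery tests bound by propagating per-cell binomial variance
  rather than by fixed magic numbers.

## Known limitations

- The agent has no learning, no session-level economics, and no
  offer-zone deliberation time; it is a per-trial generative model.
- The flat-bound + non-increasing-drift knockout does not null the bubble:
  clipping the drift adds a downward trend in $W$, and with a flat bound
  the accepted margin $W_0 - \text{offer}$ shrinks with the offer, so this
  variant measures strongly *negative* — the knockout removes the positive
  sunk-cost channels but installs an anti-sunk one. The package reports
  what the mechanism produces.
- Per-subject $\sigma_N$ is not behaviorally identifiable with these
  measures; only $\sigma_W$ has a calibrated behavioral readout.
- The hyperbolic calibration intercept is a small-sample property of the
  tangent extraction; the package's analytic tangent keeps it within a few
  hundredths of zero, consistent with the closed form.
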