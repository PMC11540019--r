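---
title: "Dissociating need and motivation with event-driven latent models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating need and motivation with event-driven latent models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 3.5)
library(needmot)
```

## The scientific problem

Hypothalamic populations that drive feeding are hard to tell apart because
the psychological quantities they might encode — the homeostatic *need* for
food and the *motivation* to obtain it — rise and fall together in most
experiments. `needmot` implements a normative modeling framework that
separates them by their temporal signatures around discrete behavioral
events:

* **Need** is the *predicted deficit*: the current homeostatic deficit plus
  all predicted future changes. External events that predict a gain (seeking
  initiation, food contact) step need *down*; events that predict a loss
  (inaccessibility) step it *up*. Formally, over a trial,
  $N(t) = N(t_0) - R(t)$, where $R(t)$ accumulates a signed step $R_i$ at
  each predicted-gain/loss event ($R_i \ge 0$ for gains, $\le 0$ for
  losses).
* **Motivation** is the *leaky accumulation of need*, started when the goal
  becomes accessible at $t_0$:
  $M(t) = M(t_0) + \int_{t_0}^{t} \left[a\,N(s) - \mathrm{Leak}\right] ds$.
  Because need is piecewise constant, motivation is continuous and piecewise
  linear with slope $a N - \mathrm{Leak}$ on each interval; the package
  evaluates this closed form exactly rather than integrating numerically.
* Behavior is generated when motivation exceeds a threshold $K$:
  $B(t) = M(t) - K$.

Two constraints encode the event semantics. A predicted-*loss* event leaves
motivation unchanged (inaccessibility blocks the goal, so nothing more can
accumulate), which is why only need reacts in a pure-loss test. A voluntary
*abandon* event returns both latents to their pre-trial baseline; the reset
is instantaneous because only the constraint, not a time course, is
specified for it — `abandon_reset = "zero"` is available for the reading
where abandoning induces zero motivation rather than baseline motivation
(with a zero baseline the two coincide).

To compare these latents with fiber-photometry recordings of GCaMP6s
activity, each candidate latent is convolved with a calcium-kernel
(`gcamp_kernel()`): a double exponential
$k(t) \propto (1 - e^{-t/\tau_r}) e^{-t/\tau_d}$ with $\tau_r = 0.2$ s,
$\tau_d = 2.6$ s, 10-s support and unit peak. These values follow published
GCaMP6s kinetics and are configurable; no specific parameter set is
canonical, and all fitted quantities that matter (step signs, slope
changes, AIC ordering) are robust to moderate kernel changes because the
same kernel is applied to every candidate.

Two *inverted-sign controls* complete the candidate set: reflecting a
latent about its initial value (`build_inverted_trace()`) tests whether a
population merely mirrors the other population's signal, e.g. through
inhibitory projections. Inversion is defined as reflection about the
initial value (not global sign flipping) so that inverted and direct
candidates share baseline semantics.

## Model fitting

`fit_model()` minimizes the RMSE between the kernel-convolved latent plus a
free offset and an observed (z-scored) trace, using multi-start bounded
quasi-Newton (L-BFGS-B) optimization: the default 100 random starts match
the standard multi-start protocol, and every run is reproducible from
`(data, spec, n_starts, seed)`. Default box bounds are: step magnitudes
$[0, 10]$ z-units with signs fixed by event kind, $a, \mathrm{Leak} \in
[0, 10]$, baselines and offset $[-5, 5]$.

Because the predicted signal is *linear* in a small set of convolved basis
functions (indicator steps for need, accumulation ramps for motivation),
`latent_model_spec()` precomputes the design matrix once and evaluates each
candidate parameter vector as a matrix product; the first optimizer start
is the least-squares solution mapped back to the natural parameters and
clamped into the bounds. This makes fits fast and reliable without changing
the estimator: the reference path through `build_test_model()` and
`predict_signal()` is retained and the two agree to numerical precision
(this equivalence is itself a unit test).

Model comparison uses $AIC = N \ln(RSS/N) + 2K$ with $K$ the number of free
parameters actually optimized; the lowest AIC wins. Across subjects, AIC
matrices are compared with the Friedman rank test (`friedman_on_aic()`,
exact enumeration for small untied designs, chi-square otherwise), and a
block-permutation test (`permutation_test()`; 20 contiguous blocks,
1000 shuffles by default) provides an empirical p when data are too few for
the rank test.

Two fitting details mirror the photometry pipeline. Convolution with a
causal kernel produces an onset artifact, handled either by prepending
1.25 s of the early-trace mean (`pad_mean`, used for single-event tests;
the stated 125-of-50-samples rule at 100 Hz, generalized by duration at
other rates) or by discarding the first 5 s of the 10-s initial
inaccessibility (`crop_last5s`, used for the multi-event tests).
For the multi-event test the labeled consumption-end moment can lag the
true end of consummatory behavior (food retained in the mouth), so
`fit_with_delay()` refits over a 0–8 s delay grid and charges the chosen
delay one extra AIC parameter. For single-trial analyses `loo_cv()`
implements leave-one-out cross-validation with a pooled-training objective:
the training trials are fitted jointly by minimizing their summed RSS under
one shared parameter set — the natural pooling when nothing further is
specified — and held-out AICs are averaged per session.

## Optogenetic behavior models

Stimulating need-encoding versus motivation-encoding neurons predicts
different behavior dynamics. Behavior rasters (0.1-s bins, 1 while the
behavior occurs) are averaged across trials and smoothed with a centered
moving average (10 bins for the 10-s stimulation test) into a probability
curve. Two models are fitted with all probability-scale parameters bounded
in $[0, 1]$:

* **Need activation** (`need_behavior_model()`): the motivation level ramps
  up with slope $A$ during stimulation and decays through the remaining
  leak afterwards, clipped at the maintained-behavior threshold of 1; the
  decay rate may not exceed $A/4$ (enforced by reparameterizing
  $\mathrm{Leaky} = \mathrm{frac} \cdot A/4$). The printed model anchors
  the post-offset decay at the stimulation *onset*, which makes the curve
  discontinuous at the offset boundary; this form is the default and a
  continuity-preserving variant anchored at the offset is available
  (`anchor = "offset"`). Behavior persists after stimulation ends until
  the level falls below the generated-behavior threshold — the threshold
  acts as a gate (no behavior below it), which is what makes it a free
  parameter of the fit ($k = 5$).
* **Motivation activation** (`motivation_behavior_model()`): a delayed
  boxcar — probability steps up by $A_{stim}$ at onset (plus a fitted
  neural-to-behavior delay) and returns to baseline immediately at offset
  ($k = 3$).

The qualitative dissociation is post-offset persistence: need-driven
behavior outlasts the stimulus, motivation-driven behavior stops within a
bin of the delayed offset.

Normalization of the trial-averaged probability is a no-op for well-formed
0/1 rasters; the max-normalization applies only if a malformed raster
exceeds 1. Moving-average edges use shrinking windows rather than padding
so no artificial values enter the curve.

## The foraging simulation

The simulator asks *why* accumulation exists: could behavior be driven by
need directly? An agent on a 1-D track (food at 300 steps by default; the
geometry is unstated beyond "a long distance", so the track length is a
package choice) chooses go/stop against a threshold of 0.5, with dwell-time
holds of 50 steps after switching to stop and 10 after switching to go.
The homeostatic deficit rises by $10^{-5}$ per step (ID condition; in NID
it is constant except seeded uniform noise of $\pm 0.001$, a magnitude the
package chooses, with the leak lowered to 0.0008), and eating reduces it by
0.012 per step, never below zero.

Need is the normalized sum of discounted deficit with $\gamma = 0.99$,
weighted by an active predicted gain through $e = 0.1$
(`compute_need()`: $\mathrm{need} = \max(0, \mathrm{SDD}(1 - e))$ when a
gain is predicted). The forward projection inside the SDD is
*action-dependent* for the direct-need agent under the
`pred_changes_on_stop` condition: a moving agent projects a deficit that
decreases at the eating rate (it will reach the food), a stopped agent
projects a deficit that keeps rising. This operationalizes the stated
condition — prediction changes the moment the agent stops — using only
constants the model already has (eating rate, deficit increment). The
supplementary state equations behind the simulation are not available in
the source text, so this part of the module is an informed reconstruction
of the main-text description; the constant-deficit projection remains the
default of the exported `sdd()` operation. Under `pred_independent` the
prediction ignores motion entirely.

The accumulated-need agent integrates the unpredicted need into motivation
($M \leftarrow \max(0, M + a\,\mathrm{need} - \mathrm{Leak})$,
$a = 0.0015$, $\mathrm{Leak} = 0.001$) from the accessibility moment; its
prediction enters through that accumulation onset rather than through the
momentary signal, which is how the motivation side of the framework defines
target-dependence.

With the stated defaults the dynamics reproduce the normative claim:

* the **direct-need** agent dithers — while moving, the projected relief
  pushes need below threshold, so it stops; stopping restores the
  projection and need rises again — advancing only ~10 steps per 60-step
  cycle and acquiring food at step ~1750;
* the **accumulated-need** agent banks motivation while waiting, crosses
  threshold once (~step 980), and sustains a single go bout, acquiring at
  ~1280.

Direct need therefore delays acquisition, deterministically under ID
dynamics. The `with_inaccessible` condition reproduces the staged protocol
(deficit frozen at 0 for 100 steps, rising linearly to 1 over 500 steps of
inaccessibility, then access; the trajectory is tracked for 1000 steps
after the food is reached). `parameter_sweep()` crosses thresholds and
accumulation gains over $[0.1, 1]$ and $\gamma$ over $[0.9, 1)$.

## Synthetic data: what it emulates and what it does not

`generate_photometry_session()` produces ground-truth-labeled sessions:
jittered event schedules (truncated Gaussian jitter, order-preserving,
experimenter-scheduled accessibility kept fixed), the true latent built
from the generating model, kernel convolution, additive Gaussian noise in
z-units (an AR(1) option exists for correlated noise, off by default), and
per-trial z-scoring. Template schedules encode the described trial
structures — e.g. a 10-s initial inaccessibility before the accessibility
moment and a 30-s window for the multi-gain test; the multi-gain/loss
window is extended to 40 s so that an 8-s consumption-end delay cannot
collide with the final inaccessibility event.

The generator deliberately omits photobleaching, motion artifacts,
hemodynamic contamination, trial-to-trial amplitude variability and
session-level nonstationarity. Passing the closed-loop tests therefore
shows that the estimators are correct and well calibrated *under the
model's own assumptions*, not that real recordings satisfy those
assumptions. Realistic noise levels of the original recordings are
unknown; the default `noise_sd = 0.3` z-units was chosen to make the
selection harness non-trivial (single-trial fits are visibly noisy)
rather than to match any measured dataset, and the recovery harness uses
0.1 with 20-trial averages, the paper-scale trial count.

## Numerical choices and problem sizes

* Closed-form motivation is exact; the test suite verifies it against a
  forward-Euler oracle at $dt = 10^{-3}$ s within $10^{-6}$ on random
  schedules with millisecond-aligned events (left Riemann sums are exact
  for piecewise-constant integrands on the grid).
* Synthetic harnesses generate at 20 Hz over 30–40-s windows (600–800
  samples) and fit with 3–6 optimizer starts; these sizes were chosen so
  the full closed-loop suite runs in minutes while leaving the selection
  and recovery margins wide. Preprocessing of raw recordings still
  up-samples to 100 Hz per the pipeline contract.
* Degenerate inputs: zero-variance traces z-score to zeros with a warning;
  a perfect fit ($RSS = 0$) returns $-\infty$ AIC with a warning; empty
  traces, mismatched rates and malformed schedules raise classed errors.
* Ties in the Friedman test get mid-ranks with the classical tie
  correction; the identical-column case returns a zero statistic.
* The empirical permutation p uses the $\le$ convention without add-one
  smoothing; a rank of zero is reported as 0 and should be read as
  $p < 1/n_{perm}$.

## A worked example

```{r example}
library(needmot)

kernel <- gcamp_kernel(rate = 20)
truth <- list(n0 = 1, steps = c(0.8, 0.7, 0.9, -1.2), offset = 0.2)
spec <- session_spec("multi_gain_loss", n_trials = 6, "need", truth,
                     noise_sd = 0.3, rate = 20, kernel = kernel, seed = 1)
avg <- average_trials(generate_photometry_session(spec)$trials)

fits <- lapply(setNames(MODEL_NAMES, MODEL_NAMES), function(m) {
  ms <- latent_model_spec("multi_gain_loss", m, trial_schedule(avg),
                          kernel, rate = 20, mode = "crop_last5s")
  fit_model(avg, ms, n_starts = 3, seed = 7)
})
tidy(compare_fits(fits))
```

```{r simulation}
direct <- run_simulation("direct_need", "pred_changes_on_stop", "ID",
                         n_steps = 2500, seed = 1)
accumulated <- run_simulation("accumulated_need", "pred_changes_on_stop",
                              "ID", n_steps = 2500, seed = 1)
c(direct = acquisition_time(direct),
  accumulated = acquisition_time(accumulated))
autoplot(accumulated)
```

## Known limitations

* The exact supplementary state equations of the original framework are
  not reproduced here; the simulator implements the main-text description
  with the stated constants, and its projection rule is a reconstruction.
* Single-trial fits share parameters across training trials only through
  the LOO pooling; per-event $(a, \mathrm{Leak})$ variants are out of
  scope.
* $a$ and the step magnitudes of the motivation model are jointly
  unidentifiable (only products $a \cdot N$ enter the slopes); parameter
  *recovery* claims therefore fix the driving need at truth, while model
  *selection* uses the free parameterization and is unaffected.
* The manual trial-omission rule for overlong inter-event intervals has no
  stated threshold; schedules are generated valid instead, and no cap is
  applied by default.
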