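---
title: "Deep active inference for hierarchical scene construction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deep active inference for hierarchical scene construction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deepscene)
```

## The task and the model

`deepscene` simulates agents performing a *scene-construction* task. On each
trial, two random-dot-motion (RDM) patches occupy two of four quadrants of a
visual array. Each patch drifts in one of the four cardinal directions, and
the pair of (perpendicular) directions defines one of four scene types:
UP-RIGHT, RIGHT-DOWN, DOWN-LEFT, LEFT-UP. With 12 ordered placements of two
patches in four quadrants, the hidden scene state is one of
4 × 12 = 48 alternatives. The agent starts fixating a central location, can
saccade to any quadrant (locations 2–5) to inspect its contents, and reports
its guess by saccading to one of four choice locations (6–9), which ends the
trial with Correct or Incorrect feedback. No single patch identifies the
scene; the agent must actively sample at least two quadrants and combine
what it sees.

Both the agent's generative model and the environment are hierarchical
partially observed Markov decision processes over categorical variables, and
both perception and action come from minimizing free-energy functionals.

**Level 1** models the contents of a single fixation. Hidden factors: the
motion direction of the fixated patch (Null, UP, RIGHT, DOWN, LEFT; constant
within a fixation) and a controllable binary *sampling state*
(Keep-sampling / Break-sampling, with Break an absorbing sink that ends the
fixation). At each of up to `T1 = 20` steps the environment emits a motion
sample from the sharpened likelihood column of the true direction, and the
agent decides between the Keep and Break policies.

**Level 2** models the whole trial at the timescale of saccades. Hidden
factors: the 48-dimensional scene state (constant) and the eye position
(9 locations, controlled by eight single-step saccade policies). Its three
outcome modalities — the stimulus at the fixated location, trial feedback,
and a proprioceptive eye-position report — all have deterministic
likelihoods, identical in model and environment.

The two levels exchange information in both directions. Downward, Level 2's
predictive density over the stimulus at the saccade target (its scene
beliefs passed through the stimulus likelihood) becomes the *empirical
prior* over motion directions at Level 1. Upward, the final Level-1
direction posterior ascends as a graded ("inferred") observation of Level
2's stimulus modality. Belief updating itself stays strictly within each
level's own generative model; only these two quantities cross the interface.

## Sensory precision as motion coherence

RDM coherence is modeled by an inverse-temperature softmax applied to the
columns of the Level-1 motion likelihood. Each column starts one-hot on the
true direction; after softening with precision $p$ the true direction keeps
mass $e^p / (e^p + 3)$ and the other three directions share the rest evenly.

```{r coherence}
A <- sharpen_likelihood(diag(5), p = 5)
round(A[, 2], 4)   # ~0.98 on the true direction at p = 5
round(sharpen_likelihood(diag(5), p = 0.5)[, 2], 4)  # ~0.35 at p = 0.5
```

The Null state (empty quadrant, start or choice locations) is excluded from
the softening and is always observed unambiguously. The same sharpened
columns parameterize the environment's sampling process; by default the
process precision equals the model precision (they are exposed separately in
the configuration to allow mismatch experiments).

## Perception: free-energy minimization over categorical beliefs

Posterior beliefs factorize across hierarchical levels, hidden factors, and
time. For one level, the fixed point iterated by `infer_states()` sets the
log-belief over a factor at time $\tau$ to the sum of (i) the log-evidence
from each outcome modality when an observation for $\tau$ is available, with
the likelihood contracted over the other factors' current beliefs, and (ii)
the log forward message through the transition selected by the policy (the
initial prior at $\tau = 1$). Graded observations enter as the log of the
arithmetic mixture of likelihood columns, which reduces to the ordinary
column lookup for one-hot observations.

Two numerical choices matter here:

* **Log floor.** Every logarithm receives an additive floor of
  $e^{-16}$, keeping all free-energy quantities finite for the task's many
  deterministic (zero-entry) distributions. All log quantities are in nats.
* **No backward smoothing message.** A conventional smoothing pass would
  add the message $\log(B^\top q_{\tau+1})$. Under this task's deterministic
  transitions (identity scene and direction dynamics, relocation saccades) a
  full-strength backward message returns each belief's own forward
  information to it, and the time-factorized mean-field posterior then
  collapses onto its mode within a few sweeps — the agent becomes certain of
  whatever it weakly suspected. Since every behaviorally relevant quantity
  (the current-time posterior and the one-step-ahead prediction feeding the
  expected free energy) is exact under pure filtering, the backward message
  is omitted. For a single hidden factor the resulting update *is* the exact
  categorical Bayes filter, which is what the oracle tests verify.

The iteration runs at most `max_iters = 16` sweeps to a tolerance of
`1e-4` on the largest belief change; non-convergence returns the current
beliefs with a warning rather than an error.

## Action: expected free energy

Policies at both levels are single-step, so the policy space equals the
action space. The posterior over policies is
$Q(\pi) = \sigma(-F(\pi) - \gamma G(\pi))$, where $F(\pi)$ is the
variational free energy of the observation history (the evidence that a
policy is being pursued — equal across policies here, since single-step
policies share their past), $G(\pi)$ is the expected free energy of the next
observation, and the policy precision $\gamma$ scales $G$ only.

`expected_free_energy()` computes, per modality and summed:

* **risk** — KL divergence from predicted outcomes to the
  softmax-normalized preference column for that time step;
* **ambiguity** — expected conditional outcome entropy under predicted
  states;
* **epistemic value** — predicted outcome entropy minus ambiguity, i.e. the
  mutual information between states and outcomes (equivalently the expected
  divergence from prior to posterior, which the test suite verifies by
  enumeration);
* **instrumental value** — expected normalized log-preference of predicted
  outcomes.

Because both decompositions use the same normalized preferences, the
identity $G = \text{risk} + \text{ambiguity} =
-\text{epistemic} - \text{instrumental}$ holds to machine precision — the
usual additive preference-normalization constant is identically zero by
construction.

With $\gamma = 512$ at both levels, $Q(\pi)$ is nearly degenerate. The
simulation loops therefore *select* the most probable policy (uniformly
randomizing exact ties, e.g. the four symmetric quadrants at trial start)
rather than drawing a literal categorical sample; `select_action()` offers
both regimes. The deterministic regime is what makes the Keep/Break policy
differential (below) positive at every recorded pre-break step: the moment
Break overtakes Keep it is engaged, so no step with a negative differential
is ever recorded — sampled selection would occasionally keep sampling at a
(slightly) negative differential near the crossing.

## Preferences and the tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `p_model`, `p_process` | config | — | sensory precision (coherence) of model / environment |
| `pref_correct` | +2 | nats | relative log-preference for Correct feedback |
| `pref_incorrect` | −4 | nats | relative log-preference for Incorrect feedback |
| `kappa` | 0.005 | nats/step | slope of the linearly increasing Break-sampling preference |
| `T1` | 20 | steps | fixation horizon |
| `T2` | 10 | saccades | trial horizon |
| `gamma1`, `gamma2` | 512 | — | policy precisions |
| `prior_scene`, `prior_strength` | flat | — | scene-type prior manipulation (strength in [0.25, 1]) |

The feedback preferences (+2 / −4 nats) make the agent risk-averse: with a
flat scene prior it explores quadrants until its scene posterior is
confident enough (roughly 0.8 on the reported scene) that the expected risk
of categorizing drops below the risk of another fixation.

The urgency slope `kappa` deserves its own paragraph, because it is the one
genuinely free constant of the model. The Break preference grows as
$\kappa(\tau - 1)$ nats, encoding a rising cost of continued sampling; only
the qualitative form (linear increase) is constrained, not the slope. The
slope trades off against the size of the epistemic value of another motion
sample, which after the first observation is at most a few hundredths of a
nat. Slopes of order 0.1 or larger therefore truncate every fixation at one
step regardless of precision and no precision-dependence of dwell time can
arise at all. We calibrated the slope once against the qualitative target
the model exists to exhibit — an inverted-U of mean first-fixation dwell
time in sensory precision — scanning 0.25 down to 0.005 and freezing
`kappa = 0.005`, which gives a clear inverted-U (peak of roughly 5 steps at
interior precision, immediate breaks at both extremes) and fixations of
about 2–3 steps at $p = 5$. It was not revisited afterwards.

Preference schedules are built over a level's horizon `T`; the one-step
lookahead at the final step clamps the preference column index to `T`.

## The trial loop and its measurements

`run_trial()` iterates: evaluate the eight saccade policies, select one;
if the target is a quadrant, run a Level-1 episode there
(`run_level1_episode()`), whose break time and ascending posterior are
recorded; if the target is a choice location, record the categorization
(latency = the Level-2 step of that saccade, choice, feedback) and stop —
all quantitative analyses use behavior up to the first categorization only,
and a trial that never categorizes within `T2` steps is recorded as
non-responding and excluded from both the accuracy numerator and
denominator. An empty (Null) quadrant needs no special-casing: the Null
state is unambiguous, epistemic value collapses after one sample, and Break
follows immediately.

The experiment drivers measure:

* **categorization latency** — Level-2 steps before the choice saccade;
* **accuracy** — percent of responding trials whose first categorization
  drew Correct feedback;
* **break time** — Level-1 steps sampled in the *first* fixation of each
  trial (the model's analog of fixational dwell time);
* **policy differential** — $P_{\text{Keep}} - P_{\text{Break}}$ at each
  pre-break Level-1 step (reported for steps 1–10, averaged across prior
  strengths, which barely affect it).

```{r trial}
tr <- run_trial(list(p_model = 5), seed = 42)
tr
```

## What the generator emulates — and what it does not

The synthetic environment *is* the study design: scenes and configurations
drawn uniformly (or restricted for prior-manipulation experiments), motion
samples drawn i.i.d. from the sharpened likelihood of the true direction,
deterministic feedback. It does not emulate dot kinematograms at the pixel
level, temporal correlations within an RDM stream, dynamic scenes, learning
of likelihoods or transitions across trials, or oculomotor noise. Passing
tests therefore demonstrate the internal consistency of the inference
scheme and the qualitative phenomena it produces under these idealized
conditions — not quantitative predictions for human data.

## Simulation scales and reproducibility

The precision sweep defaults to 12 log-spaced precisions on $[0.1, 10]$ with
185 trials per level; the dwell analysis uses 250 trials per condition with
priors concentrated (strength 0.5–0.75) on a randomly drawn scene type, and
simulates only the first fixation of each trial, since nothing else enters
that analysis. The packaged test suite runs the same analyses at 60–185
trials per condition, sizes chosen so the full suite completes in a few
minutes on one core. Every driver derives independent per-trial seeds from
a master seed, so all outputs are bit-for-bit reproducible.

Two boundary behaviors are worth knowing. At the lowest precisions
(`p` near 0.1) a flat-priored agent can be structurally ambivalent: scene
beliefs never reach the confidence needed to categorize within `T2 = 10`
steps, most trials are non-responders, and the accuracy estimate for that
level rests on few trials. And at prior strength 1.0 the agent categorizes
at the first step without inspecting any quadrant — the prior alone carries
enough instrumental value.

## Known limitations

* Policies are single-step at both levels; there is no multi-step planning
  tree, and the expected free energy is evaluated one step ahead.
* Past-time beliefs are filtered, not smoothed, so recorded belief
  trajectories do not retrospectively revise earlier time steps.
* `gamma` is fixed, not inferred; there is no learning of model parameters.
* The mean-field product across factors is iterated, not exact, when
  several factors share a modality — exactness holds per factor and for the
  single-factor oracle models.
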