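---
title: "Modelling the development of goal-predictive gaze"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the development of goal-predictive gaze}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(eventgaze)
```

Infants watching a hand reach for an object begin, at some point in
development, to look at the object *before* the hand arrives. The age at
which this goal-predictive gaze appears depends on how familiar the actor is
(hands earlier than mechanical claws) and on whether the grasp is followed by
a salient action effect (lifting the object). `eventgaze` implements a
computational observer that reproduces this developmental pattern from three
interacting mechanisms: slowly learned probabilistic event schemata,
moment-to-moment Bayesian event inference with active gaze selection, and a
fast retrospective adaptation of the actor's inferred agency.

This vignette explains the model, the simulated world it observes, the
numerical choices made where the design was open, and what the package's own
analyses do and do not show.

## The simulated world

Two entities — an actor and a patient (goal object) — live in a unit cube.
Four event types compose every stimulus: `still` (both motionless), `random`
(the actor drifts in a fixed random direction, reflecting off the walls),
`reach` (the actor moves straight toward the patient until their distance
falls below a contact threshold), and `transport` (actor and patient move
together to a random goal location — the action effect). Training sequences
are `still`, `random -> still`, and `reach -> transport -> random` (a full
grasp); test stimuli are full grasps ("with action effect") or bare reaches
cut off at contact ("without action effect"). Sequences last 100–270
timesteps.

The observer receives an 18-dimensional vector per timestep: both positions
and velocities (3 components each), the relative position, the Euclidean
distance, the actor's *agency estimate* `ae` (0.2 ≈ canonical hand, 0.8 ≈
canonical claw) and the patient's shape (fixed at 0.5, a generic object).
Gaze matters through sensory precision: the fixated entity's position and
velocity components receive Gaussian noise with sd 0.001, the other
entity's with sd 0.1 (both under the "elsewhere" policy). The agency and
shape slots are internal estimates and are never noise-perturbed; derived
relative position and distance are recomputed from the noisy positions so
the vector stays internally consistent.

Geometry and kinematics are not dictated by the scenario description, so the
package fixes them once: entities spawn uniformly at least 0.4 apart inside
a 5% margin from the walls; speeds are constant per event, drawn from
[0.004, 0.012] units/timestep; the contact threshold is 0.01. These values
make reach events span tens of timesteps and land total lengths in the
100–270 range (segment lengths are sampled, and geometry re-sampled, so that
the range is always met). Three independent RNG streams (world, sensory
noise, policy) derive from one master seed, so e.g. switching the gaze
controller on or off never changes the stimulus geometry.

## Event schemata: 12 Gaussian density networks

Each event has three learnable components: a *start* density (first
observation of the event, conditioned on the gaze policy alone), a
*dynamics* density (next observation given the previous one), and an *end*
density (the event's boundary observation given a within-event reference
observation). Each component is a small feed-forward network — two hidden
layers of 32 tanh units — emitting a diagonal Gaussian: a linear mean head
and a softplus variance head floored at 1e-4 per dimension.

Two numerical choices deserve comment:

* **Variance floor 1e-4** (predictive sd at least 0.01, about one timestep's
  displacement). A network's irreducible mean-approximation error is of the
  same order; a much smaller floor lets that error masquerade as huge
  log-likelihood differences between events that are constant within a trial
  and carry no event information. The floor caps such artifacts at a nat or
  two per step while leaving genuine unfamiliarity rejections (tens of
  standard deviations) decisive. Pure residual noise below the floor is
  invisible to the filter, which is the intended trade.
* **Policy inputs start at zero weight.** Components that never receive
  training data (notably the end of `still`, which never terminates in the
  curriculum) remain exactly policy-neutral, so gaze preferences can only
  ever come from learned structure, and expected-free-energy ties break
  deterministically toward the actor.

End components are trained over the *whole* retrospective horizon: every
within-event observation is paired with the event's boundary observation as
the target. A reach's end density therefore concentrates on the contact
configuration (actor at the patient) no matter how far the reach has
progressed — which both lets the filter reject spurious boundary
interpretations mid-event and gives gaze selection its anticipatory pull
toward the patient (below). Training ends only on adjacent pairs was
explored and degrades into a permissive near-copy map that the filter
cannot distinguish from dynamics.

Fitting is supervised (event labels are known during training) and
incremental: after every sequence, each component with data takes Adam
updates on the negative log-likelihood of its batch. Start and end
components receive only a handful of rows per sequence, so their batches are
drawn from a rolling window of recent rows (64 boundary rows; 1024 dynamics
rows), which keeps the variance heads estimable while preserving the
recency that a drifting developmental stimulus distribution requires.
Components that appear in fewer sequences (reach, transport) catch up to
their peers' update counts so that calibration progresses at one rate for
all events; the step size decays exponentially (halving every 2000 updates,
floored at 3e-4) so means settle before variances sharpen. All of this is
configurable through `fit_control()`.

## Event inference

A recursive Bayesian filter maintains a posterior over the four events. Per
step, "the event stays" is scored by the event's dynamics density, "the
event changes" by the product of the new event's start density and the old
event's end density, and a sticky transition prior holds the diagonal at
0.9 (the remaining 0.1 split uniformly — the off-diagonal split is a package
choice; only the diagonal is prescribed). The printed update conditions on
the previous event; the package marginalises over the full previous
posterior, which is the form the sequence likelihood requires and makes the
filter a standard forward algorithm. Everything is accumulated in log space
with log-sum-exp; `filter_sequence()` returns the posterior trace and the
per-step predictive log-likelihood whose sum is the sequence log-likelihood.
Impossible transitions (e.g. a sequence opening with transport) are *not*
hard-coded; the learned start densities carry that structure.

The filter is verified against an independent oracle: exhaustive enumeration
of every event path on short toy problems with hand-set densities agrees
with the recursion to 1e-8 in log space.

## Active gaze selection

With outcome preferences assumed uniform, expected free energy reduces to
anticipated observation entropy. For each candidate policy the model sums,
under its current event posterior, the entropy of the event's dynamics
prediction (the within-event term) and — with the default one-boundary
horizon — the entropy of the event's end density plus the
transition-weighted entropies of the candidate successors' start densities.
Entropies of the boundary factors add because the boundary likelihood
factorises. The candidate policy acts purely through the policy input of
the density networks, which learned the gaze-dependent precision structure
during training; there is no explicit re-noising at decision time. Ties
break deterministically (actor, then patient, then elsewhere). Horizons
beyond one boundary are deliberately unsupported.

The anticipatory mechanism is concrete: once the posterior favours `reach`,
the end density predicts the contact configuration, and that prediction is
much sharper when the patient is fixated (the contact happens at the
patient's location) — so minimising anticipated entropy shifts gaze to the
patient before the actor arrives.

## Retrospective coherence optimisation

After each complete test trial the model may adapt the actor's agency
estimate: the candidate estimate is substituted into the agency slot of
every stored observation, the negative sequence log-likelihood is the loss,
and five classical-momentum gradient steps are taken (learning rate 1e-5,
momentum 0.3), with the estimate clipped to [0, 1]. The gradient is exact:
a forward-mode tangent is propagated through every network evaluation and
through the filter recursion itself (network parameters stay frozen). The
analytic gradient is validated against central finite differences to within
1% on random trials — the module's core correctness oracle. The loss and
gradient are recomputed at each of the five steps. Adaptation persists
across the 12 trials of one actor and condition and resets for a new one.

## The training and testing protocol

The full protocol trains for 30 phases of 100 sequences drawn uniformly
from the three training sequence types, each viewed under one uniformly
drawn fixed gaze policy. Grasping actors are initially hands (shape
~ Normal(0.2, 0.1²) truncated to [0, 1]); over phases an increasing share
is drawn uniformly on [0, 1]. The mixing weight rises *quadratically* from
0 to 1 — a package choice within the stated envelope (0 at phase 1, 1 at the
final phase, non-decreasing) that keeps grasping hand-dominated through
mid-training, the regime in which retrospective agency adaptation has
explanatory work to do. Random-motion and still actors are a 50/50
hand/claw mixture throughout. After every phase the model is tested: 12
trials per actor shape and condition, the agency estimate initialised to
the actor's shape, gaze chosen online by expected free energy.

The package's own analyses (tests and the acceptance script) run a *reduced*
protocol, `run_reduced_protocol()`: 12 phases x 100 sequences with the six
condition cells of `pattern_conditions()`. The per-phase sequence volume of
the full protocol is kept because the learned precision structure — and with
it the gaze behaviour — is sensitive to it; only the developmental axis is
shortened.

## Gaze metrics

`first_patient_gaze()` reports the first (optionally sustained) patient
fixation. `gaze_arrival_delta()` mirrors the infant measure, which scores
gaze *shifts* from the actor to the goal: contact time minus the onset of
the patient fixation that is held when the actor reaches the patient. Three
qualifications implement the shift semantics: the counted fixation must
follow an actor fixation (a trial whose gaze parks on the goal from onset
carries no shift to score), fixations shorter than 3 timesteps do not count
(simulated timesteps are far finer than a saccade, and eye-tracking
pipelines impose minimum fixation durations for the same reason), and a
fixation abandoned more than 5 steps before contact does not count either.
Positive deltas are predictive, negative reactive. The scalar developmental
summary is `criterion_phase()`: the earliest phase in which at least 7 of
12 trials are predictive. The hand/claw familiarity ordering is read off
the no-adaptation conditions, since the retrospective mechanism is designed
to equalise the shapes.

## What the synthetic world does and does not show

The generator produces exactly the event structure the model is meant to
segment, with position-coded roles, one actor and one patient, determinate
constant-velocity kinematics, and noise that depends only on gaze. Passing
the package's checks therefore demonstrates the *mechanisms* — supervised
schema learning, coherent filtering, uncertainty-driven gaze, coherence
adaptation — under the stated assumptions; it says nothing about pixel-level
vision, multi-object scenes, role assignment, or noise structure in real
infant data.

Two quantitative limitations of this realisation are worth stating plainly.
First, within-event observations carry little per-step event information:
all moving events are locally constant-velocity, and per-step displacements
(0.004–0.012) are comparable both to the model's attainable precision and
to the variance floor, so the filter's per-step argmax labelling leans
heavily on sequence starts and boundary re-anchoring and is well below
ceiling; the event-probability *contrasts* (hand vs claw, with vs without
adaptation) are robust, the absolute labelling accuracy is not. Second,
with a perfectly motionless patient, anticipated-entropy gaze selection is
intrinsically nearly tied between the two entities (fixating the
predictable patient compresses its dimensions as much as fixating the actor
compresses the actor's), so the *timing* summaries of gaze development are
sensitive to small realisation differences across training seeds, whereas
the posterior-level developmental patterns are stable.

## Reproducing the analyses

`scripts/acceptance.R --seed <int> --out <path>` runs the reduced protocol
from scratch and writes the headline quantities (label recovery,
early-phase reach-probability contrast, adaptation trajectory, criterion
phases) as JSON. The test suite recomputes the exact oracles (path
enumeration, closed-form density/entropy, finite-difference gradients,
transition arithmetic) and the same developmental patterns from one shared
reduced run.
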