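---
title: "A gated recurrent network that learns visual routines by reinforcement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A gated recurrent network that learns visual routines by reinforcement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

visroutines simulates how a recurrent neural network can learn multi-step
visual routines — curve tracing, visual search, and their compositions —
from nothing but trial-and-error and a scalar reward, using a learning rule
in which every factor is available locally at the synapse. This vignette
describes the model, the learning rule, the synthetic tasks, the analyses,
and the design decisions taken where the problem was genuinely open.

## The tasks

All stimuli live on a 15 x 15 pixel grid with four color channels (red,
brown, blue, green) and two extra input units beside the grid that carry
the red and brown color cues. Curves are self-avoiding paths of
4-adjacent pixels; distinct curves never touch 4-adjacently (diagonal
contact is allowed, so connectedness is unambiguous under the Von Neumann
neighborhood that also constrains every convolution kernel).

* **Trace**: the target curve starts with a red pixel and ends with a blue
  one; a distractor curve is all green with a blue end. The correct action
  is the eye movement to the target's blue end.
* **Search-then-trace**: two curves start with a red and a brown marker;
  a cue unit says which color to search for; the correct action is the
  blue end of the cued curve.
* **Trace-then-search**: the target curve starts at the single blue pixel
  and ends in a colored marker; the correct action is the external colored
  pixel that matches the marker.

Rewards are binary: 1 for the correct eye-movement target, 0 otherwise.
Stimuli are drawn fresh on every trial by rejection-sampled self-avoiding
walks (`sample_path()`), so networks can never memorize the training set.

## The network

Each of the three layers (retinotopic input, two hidden layers of four
features) contains two unit groups. *Feedforward* units X detect features:

$$X_l = \sigma(V_l * X_{l-1})$$

computed in one bottom-up sweep while the input stays clamped.
*Recurrent* units Y carry the task-driven response modulation. Their input
is gated multiplicatively by their feedforward twin,

$$Y_l(t) = \sigma\!\big(\varphi(X_l)\odot(U_{l+1}*Y_{l+1} + T_{l-1}*Y_{l-1}
           \;[+\;H_0*Y_0]) + D_l\big),$$

so modulation can never invade units whose feature is absent from the
image — activity spreads only along the representation of connected,
stimulated pixels. The input layer has lateral connections $H_0$
(a masked 3 x 3 kernel plus dense color links to the two extra units);
hidden layers receive feedback $U$ from above and drive $T$ from below.
The readout is linear in the settled recurrent state,
$Q = W_{hid}\cdot Y_2 + W_{in}\cdot Y_0$, one Q-value per selectable
position (225 grid cells + 2 external targets). Actions are chosen
greedily with probability $1-\epsilon$ and from the Boltzmann distribution
of the Q-values otherwise ($\epsilon = 0.05$).

The activation $\sigma$ is the identity up to a knee at 6 and
$\log(1.5x+1) + 6 - \log 10$ beyond, so activity is unbounded (long target
and distractor curves stay distinguishable) while its shrinking slope keeps
the fixed points of the relaxation stable. The relaxation runs until the
largest activity change falls below $10^{-5}$, at most 50 timesteps.

### Design choices in the recurrent dynamics

Four choices were genuinely open, and each is switchable in
`network_config()`:

* **Gate form** (`monotone_gate`). A gate that is a step-function
  approximation should pass active units at full strength; the package
  default is the monotone form $100x/(1+100x)$. The non-monotone bump
  $100x/(1+(100x)^2)$ (available as the alternative, and the default form
  of the standalone `gate_phi()` function) attenuates one-hot inputs about
  100-fold; networks then solve the tasks through minute activity
  differences amplified by very large readout weights, without any visible
  response modulation — none of the phenomenology this model exists to
  study survives that choice.
* **Base drive** (`feedforward_drive`). A purely multiplicative recurrent
  stream has the all-zero state as its attractor at small initial weights:
  nothing survives relaxation and, since every factor of the learning rule
  is proportional to an activity, no learning signal ever exists. The
  default `"input"` drive adds each feedforward unit's activity to its
  recurrent twin in the input layer only, so the retinotopic layer holds
  the base representation and the hidden recurrent stream carries pure
  modulation.
* **Excitatory recurrence** (`excitatory_recurrent`). With signed
  recurrent kernels, learning reliably discovers a mirror-image solution
  that labels the target curve by *suppressing* its representation to zero
  (with a base activity of 1, pushing to 0 is the cheapest contrast).
  Clipping the recurrent kernels at zero after every update makes
  modulation purely facilitatory — enhancement above the base, as observed
  in visual cortex — while the competition between eye-movement targets is
  carried by the signed readout weights.
* **Damping** (`relax_damping`). The raw update map develops exact
  period-2 flip-flops in trained networks (delayed winner-take-all
  feedback); the leaky update $y \leftarrow (1-\alpha)y + \alpha\,
  \sigma(\text{pre})$ with $\alpha = 0.5$ removes them without moving any
  fixed point.

A dense feedback projection from the last hidden layer onto the recurrent
input layer is available (`dense_skip_feedback`) but off by default: it
gives every grid cell one-step access to global context, and trained
networks then answer in 1-2 timesteps instead of by serial spread — the
accuracy-versus-timestep-cap curve goes flat, which defeats the serial
processing the tasks are meant to expose.

## RELEARNN: the learning rule

Each trial has three phases. First the network relaxes to its fixed point
and an action $a$ is selected. Second, the accessory (credit-assignment)
network — one accessory unit per regular unit, connected by the transposed
regular weights — is seeded with 1 at the chosen output unit and relaxes.
Each backward hop is weighted by the activation derivative at the target's
fixed-point pre-activation and by the gate value that scaled the forward
connection; at its fixed point the accessory activity of every unit equals
the influence of that unit on the chosen Q-value, $\partial Q_a / \partial
y_j^\infty$ (the package verifies this against finite-difference
re-relaxation oracles to relative error below $10^{-2}$, and in practice
to $10^{-6}$). Credit also reaches the feedforward stream through the gate
derivative, which is what lets the feature kernels $V$ learn. Third, the
reward arrives and the globally broadcast reward-prediction error
$\delta = r - Q_a$ gates a four-factor Hebbian update at every synapse:

$$\Delta w_{ij} = \beta\,\delta\; x_i^\infty \; y_j^{acc}\;
\sigma'(\text{pre}_j),$$

with learning rate $\beta = 0.02$. All four factors are local. The update
equals $\beta\delta\,\partial Q_a/\partial w_{ij}$ exactly, i.e. a step on
the true fixed-point policy-gradient surface, which the test suite checks
weight-by-weight against finite differences.

Numerical safeguards (all recorded per trial): the update is skipped when
the accessory iteration expands instead of contracting at its step cap
(the credit values are then meaningless), and $\delta$ is clamped to
$[-2, 2]$ so that a transiently mis-estimated Q-value produces a bounded
corrective update. Both guards exist because the relaxation is truncated
at 50 timesteps whether or not it has settled; an earlier policy of
skipping all such trials froze networks in broken high-Q states with no
way back.

## Curricula

Training mirrors how monkeys are trained: a red-blue pixel pair first,
then target + distractor curves growing one pixel at a time up to nine,
advancing whenever a frozen-weights test phase (500 trials, exploration
off) reaches 85% accuracy. The composite tasks prepend or append their
search component: search-then-trace starts with the same pixel-pair stage
and then uses cued marker curves; trace-then-search first learns blue-start
curve tracing toward a colored end marker and finally adds the two external
colored pixels as the selectable targets. Learning blocks of 500 trials
alternate with test phases; the block size is the package's choice (the
protocol only fixes the test phase). A trial budget (default 500,000)
bounds every run; exhausting it declares failure, never an error.

## Analyses

`evaluate_batch()` presents frozen stimuli and accumulates recurrent
input-layer activity per unit, per along-curve distance and per timestep,
keeping only correct trials. On top of it:

* `batch_modulation()` / `population_mi_summary()`: the modulation index
  $MI = (T - D)/\bigl((T+D)/2\bigr)$ per unit at the fixed point; pairs
  with no activity in either role are excluded and counted. Distance
  matching between target and distractor positions holds by construction
  because both curves have equal length.
* `latency_vs_distance()`: the 70%-of-maximum modulation latency per unit,
  compared between units 2 and 7 pixels along the curve (Mann-Whitney).
* `min_timesteps_to_criterion()`: the smallest relaxation cap that reaches
  85% accuracy — the serial-processing signature; undefined caps are
  reported as such, never fabricated.
* `credit_propagation_profile()`: accessory activity over accessory
  timesteps at graded distances from the selected eye-movement target, on
  both curves; credit travels opposite to the activity spread and is
  absent from the non-selected curve.
* `routine_stage_timecourse()`: per-element normalized modulation traces
  for the composite tasks (marker vs curve segments vs external targets)
  with element latencies, exposing the order of the elemental operations.

## What the generator emulates, and what it does not

The synthetic stimuli reproduce the task geometry exactly as defined:
discrete one-hot colored pixels, equal-length curve pairs, mutual
non-adjacency. They do not emulate continuous contours, orientation-tuned
elements, crossing curves, luminance variation, or eye-movement-induced
retinal shifts — none of which the model architecture could represent
anyway (it has no orientation selectivity, and eye movements are only
*selected*, not executed). Passing tests therefore demonstrate properties
of the model on its intended stimulus family, not performance on natural
images.

## Problem sizes and honest gaps

Defaults reproduce the study's conditions: 15 x 15 grids, curriculum to
length 9, 85% criterion over 500-trial frozen test phases, learning rate
0.02, exploration 0.05, 50-timestep relaxations. The test suite and the
acceptance script run the training-dependent analyses at desk scale on a
single CPU: three curve-tracing networks with bounded learning-trial
budgets (20,000 trials each in the test suite, 40,000 in the acceptance
script), one network per composite task (20,000 trials), evaluation
batches of 300-800 stimuli, and 200-250 trials per relaxation cap in the
timestep scans.

Under this implementation the curriculum is substantially slower than the
reference account: the seed-1 network needs roughly 235,000 learning
trials to pass the length-9 criterion (reference: 19,000 on average), its
mean modulation index at length 9 is around +0.1 (reference: 1.18), and
its minimal relaxation cap at length 9 is around 27 timesteps (reference:
13). The directionally correct signatures are all present — enhancement
rather than suppression, modulation latencies increasing with along-curve
distance, minimal timesteps increasing with curve length, generalization
to longer curves — but their magnitudes differ. The configuration space
that is unconstrained by the printed description (gate form, drive
placement, initialization scales of the input-layer families, damping,
readout signs) was explored systematically; no setting reproduced the
reference learning speed or modulation magnitude, so the package reports
its own measured values rather than tuned ones.
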