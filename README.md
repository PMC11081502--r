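# visroutines

Many visual tasks decompose into sequences of elemental operations —
search for a colored marker, trace the curve that starts there, report
what you find at its end. In the visual cortex of monkeys these
operations are visible as a late, recurrent enhancement of neural
activity that spreads over the task-relevant image elements, and the
output of one operation is handed to the next as a focus of enhanced
activity. `visroutines` is a simulator for studying how such routines can
be *learned* from reward alone: it implements a two-stream gated recurrent
convolutional network trained with RELEARNN, a biologically plausible
four-factor Hebbian rule, on three pixel-grid tasks (curve tracing,
search-then-trace, trace-then-search), together with the
neurophysiology-style analyses used to characterize the trained networks
(modulation index, modulation latency, minimal processing timesteps,
generalization to longer curves). It is aimed at computational
neuroscientists who want a compact, fully inspectable testbed for
attention-gated credit assignment in recurrent networks.

## The model in brief

Feedforward units form the *base representation*,
`X_l = σ(V_l * X_{l-1})`, and gate their recurrent twins multiplicatively,

    Y_l(t) = σ( φ(X_l) ⊙ ( U_{l+1} * Y_{l+1}(t-1) + T_{l-1} * Y_{l-1}(t) [+ H_0 * Y_0(t-1)] ) + D_l )

so task-driven modulation can only live on stimulated positions. All 3×3
kernels are masked to the Von Neumann neighborhood. The network relaxes to
a fixed point (at most 50 timesteps), reads out one Q-value per
eye-movement target, and selects an action ε-greedily with Boltzmann
exploration. Learning is RELEARNN: an accessory network with transposed
weights relaxes from the chosen output unit so that each accessory
activity equals `∂Q_a/∂y_j` at the fixed point, and every weight then
updates with four locally available factors,

    Δw_ij = β · δ · x_i · y_j^acc · σ'(pre_j),      δ = r − Q_a.

The update provably equals `β δ ∂Q_a/∂w_ij`; the test suite verifies this
against finite-difference re-relaxation oracles.

## A worked example

```r
library(visroutines)
set.seed(42)

s <- make_trace_stimulus(length = 9)
s
#> <vr_stimulus> task=trace, length=9, 1 distractor(s), correct action 23

net <- init_network(seed = 42)
which.max(network_q(net, s))   # untrained: picks an arbitrary position
#> [1] 192                      # (correct action is 23)

# train through the first two curriculum stages (lengths 2 and 3)
log <- run_curriculum(net, curriculum_config("trace", max_length = 3),
                      learning_config())
glance(log)
#> # A tibble: 1 × 5
#>   task  learned total_trials n_stages final_test_accuracy
#>   <chr> <lgl>          <int>    <int>               <dbl>
#> 1 trace TRUE            2500        2               0.866

test_phase(net, "trace", length = 3, n_trials = 500)
#> [1] 0.832
```

After 2,500 learning trials the network passes the 85% criterion on
red-green-blue curves of length 3 (the 0.866 above is the passing test
phase; the second call draws 500 fresh stimuli). Training to the full
length-9 criterion takes a few hundred thousand trials; `autoplot()` on
the training log shows the per-stage learning curves, and
`evaluate_batch()` + `batch_modulation()` quantify how strongly the
trained network enhances the representation of the target curve.

## Package layout

- `R/stimuli.R` — synthetic task stimuli (self-avoiding curves, spirals,
  color cues), encoding and reward.
- `src/core.cpp` — fixed-point relaxation, accessory relaxation and the
  four-factor update, written sparsity-aware over the gated active
  subgraph.
- `R/curriculum.R` — staged training, frozen test phases, generalization.
- `R/analysis.R` — modulation index, latencies, minimal timesteps, credit
  propagation, routine time courses.
- `R/harness.R` — checkpoints (JSON, bit-exact), run bundles, experiment
  recipes.
- `inst/cli/visroutines.R` — command-line front end
  (`genstim | train | test | analyze | reproduce`).
- `vignettes/visual-routines-model.Rmd` — the model, its assumptions, all
  tunable parameters, and known limitations.
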