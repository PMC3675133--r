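# thetahippo

A rate-coded neural network model of hippocampal episodic memory in which
the theta rhythm turns Hebbian circuitry into an error-driven learner.

## The problem

Classical models of hippocampal memory store patterns with Hebbian
plasticity: co-active neurons in CA3 wire together, and a partial cue later
pattern-completes to the stored engram. Hebbian storage, however, has sharp
capacity limits. Within each theta cycle (the 3–8 Hz hippocampal EEG
rhythm), the inputs that dominate CA1 alternate: at the theta **trough** the
entorhinal cortex (EC) drives CA1 through the monosynaptic pathway (MSP),
at the theta **peak** CA3 drives CA1 through the Schaffer collaterals, and
in a final **plus** phase the superficial EC layers impose the veridical
input on the deep EC layers. The difference between what a pathway produced
on CA1 and what the plus phase imposes is an error signal, one per pathway
— so the theta cycle lets the hippocampus train itself with error-driven
learning and no external teacher. `thetahippo` implements this circuit
(EC_in, dentate gyrus, CA3, CA1, EC_out), the phase-gated settling
dynamics, the two phase-contrast learning rules, and the capacity
experiments that compare error-driven against purely Hebbian learning.

It is aimed at computational neuroscientists who want a compact, fully
scripted, deterministic implementation of theta-phase error-driven learning
to probe, ablate and extend.

## The model in brief

Each unit is a conductance-based point neuron. The membrane potential
relaxes by

```
dVm/dt = ge (Ee − Vm) + gi (Ei − Vm) + gl (El − Vm)
```

with excitatory drive `ge` the *average* of weighted inputs over each open
incoming projection, a uniform within-layer (or within-slot) inhibitory
conductance `gi` computed by a k-winners-take-all (kWTA) rule, and constant
leak `gl = 0.1`. The rate output is thresholded and saturating,
`y = γ(Vm − Θ) / (γ(Vm − Θ) + 1)` for `Vm > Θ`, with gain `γ = 100` and
threshold `Θ = 0.5`.

Each input presentation runs three 30-step settling phases (90 steps per
theta cycle), with three projections gated per phase:

| phase        | EC_in→CA1 | CA3→CA1 | EC_in→EC_out |
|--------------|-----------|---------|--------------|
| theta trough | open      | closed  | closed       |
| theta peak   | closed    | open    | closed       |
| theta plus   | open      | closed  | open         |

Weight changes blend contrastive Hebbian learning (CHL) with a
conditional-PCA Hebbian rule:

```
Δw_ij = ε [ lmix · y⁺_j (x⁺_i − w_ij) + (1 − lmix) · (x⁺_i y⁺_j − x⁻_i y⁻_j) ]
```

where the minus phase is the trough for the MSP projections and the peak
for the Schaffer collaterals (`lmix = 0.001` in the error-driven condition,
`lmix = 1` for pure Hebbian learning). All other projections (EC→DG, EC→CA3,
DG→CA3, recurrent CA3) are purely Hebbian. Recall is scored with the
**Name Error**: the output of each EC slot is compared against the whole
slot vocabulary, and a pattern counts as wrong if any slot's closest
vocabulary entry is not the trained one.

## Worked example

Store 20 composite patterns (8 slots, a 100-entry vocabulary per slot) in a
network with 80 CA3 and 400 DG units, then cue recall with 25% of each
pattern deleted:

```r
library(thetahippo)

cfg   <- hippo_config(n_ca3 = 80)
vocab <- withr::with_seed(1, generate_vocabulary(100, 50, 10, 10))
min_pairwise_hamming(vocab)
#> [1] 10

train <- withr::with_seed(2, make_training_set(vocab, 20, n_slots = 8))
net   <- build_hippocampus(cfg, "full_error_driven", seed = 3)
res   <- withr::with_seed(4, train_and_test(net, train, vocab,
                                            n_epochs = 15, cue_seed = 5))
mean(res$error)
#> [1] 0

hebb  <- build_hippocampus(cfg, "full_hebbian", seed = 3)
res_h <- withr::with_seed(4, train_and_test(hebb, train, vocab,
                                            n_epochs = 15, cue_seed = 5))
mean(res_h$error)
#> [1] 1

withr::with_seed(6, bootstrap_compare(res$error, res_h$error, alpha = 0.005))
#> # A tibble: 1 × 5
#>   estimate p.value n_boot alpha significant
#>      <dbl>   <dbl>  <int> <dbl> <lgl>
#> 1       -1       0  10000 0.005 TRUE
```

The error-driven network recalls every pattern perfectly from partial cues
(`mean Name Error = 0`); the otherwise identical Hebbian network recalls
none (`mean Name Error = 1`), and the pooled bootstrap confirms the
difference. `capacity_sweep()` runs this comparison over grids of CA3 size
and training-set size (with DG held at 5× CA3), returns a tidy tibble with
`tidy()`/`glance()`/`autoplot()` methods, and is resumable from a
checkpoint file. A command-line front end is installed as `exec/thetahippo`
(subcommands `generate`, `train`, `sweep`, `compare`, `report`).

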