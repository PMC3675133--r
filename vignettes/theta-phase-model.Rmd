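---
title: "The theta-phase hippocampal model: methods and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The theta-phase hippocampal model: methods and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thetahippo)
```

This vignette is the package's account of the science it implements: the
circuit, the dynamics, the learning rules, what every tunable parameter
does and why its default is what it is, what the synthetic inputs do and do
not emulate, and where the design was genuinely open.

## The circuit

Five layers model the hippocampal loop:

* **EC_in** — superficial entorhinal cortex, the cortical input. It is
  organised into `n_slots` *slots* (default 8) of `slot_size` units
  (default 50), each slot standing for one separable cortical element
  (a modality, a feature bundle).
* **DG** — dentate gyrus, a very sparse pattern separator
  (2% winners).
* **CA3** — the autoassociative core: sparse conjunctive codes (15%
  winners), full recurrent collaterals (no autapses), inputs from EC_in
  (density 0.25) and DG (density 0.05). DG is always exactly `5 * n_ca3`
  units, preserving the anatomical DG:CA3 ratio while network size varies.
* **CA1** — slot-organised like EC, `units_per_ca1_slot` units per slot
  (default 160, 20% winners per slot).
* **EC_out** — deep entorhinal cortex, slot-organised, the model's output.

Two pathways carry the memory. The *trisynaptic pathway* (TSP:
EC_in→DG→CA3→CA1) binds the slots into a conjunctive code and
pattern-completes partial cues; its CA3→CA1 leg is the Schaffer collateral
projection. The *monosynaptic pathway* (MSP: EC_in→CA1, CA1→EC_out,
EC_out→CA1) is block-diagonal by slot and learns an invertible encoder:
each CA1 slot is a compact code for its EC slot that can be decoded back
out. EC_in→EC_out is a fixed one-to-one identity projection that imposes
the veridical input on the output layer during the plus phase; it is never
plastic.

## Unit dynamics

Each unit's membrane potential follows an explicit conductance-based
update,

$$ V_m \leftarrow V_m + dt\,[\,g_e(E_e - V_m) + g_i(E_i - V_m)
   + g_l(E_l - V_m)\,] $$

with reversal potentials $E_e = 1$, $E_i = E_l = 0.15$ and leak
$g_l = 0.1$. The fixed point is the conductance-weighted mean of the
reversal potentials. The rate output is
$y = \gamma\Delta/(\gamma\Delta + 1)$ for $\Delta = V_m - \Theta > 0$ and
zero otherwise, with gain $\gamma = 100$ and threshold $\Theta = 0.5$; it
is strictly increasing above threshold and saturates below 1.

**Excitation.** A projection's drive on a receiver is the *mean* of
`x_i w_ij` over its connected senders, scaled by
`drive_gain / (expected sender activity fraction)` (`drive_gain = 1.25`).
The normalisation makes a fully engaged pathway with mid-range weights
deliver a conductance near 1 regardless of how sparse its sender layer is;
without it, drive from sparse layers (DG especially) is orders of magnitude
too weak to reach threshold, and a layer fed by a single open pathway
(after averaging across projections) can become unreachable by any
inhibition level. When several projections are open onto one layer their
contributions are averaged with equal weight.

**Inhibition (kWTA).** Inhibition is a single conductance shared by all
units of a pool (a whole layer for DG/CA3, one slot for EC/CA1). For each
unit there is a *threshold conductance* — the inhibition that would hold it
exactly at threshold given its excitation — and the pool conductance is
placed between the k-th and (k+1)-th largest, at fraction `kwta_pt = 0.1`
above the (k+1)-th. The low placement gives winners a wider supra-threshold
margin, hence stronger, less noisy activations; at the originally tried
0.25 the marginal winners hovered near threshold and their near-zero rates
made the learning signals noisy. When the k-th and (k+1)-th threshold
conductances tie, the shared value is used and all tied units are silenced
— deterministic and conservative.

**Settling.** Every phase runs exactly 30 synchronous update sweeps (no
convergence test), so a training cycle is 90 steps. The integration step is
`dt_vm = 0.45`. This value matters more than it looks: the phase-contrast
rules compare end-of-phase snapshots, and those snapshots must be
*equilibria*, not transients. At `dt_vm = 0.2` a 30-step phase ends well
short of equilibrium for typical total conductances, the trough and plus
snapshots differ by residual transients rather than by informative
structure, and learning destabilises; at 0.45 the states are settled to
numerical precision for the conductance ranges the model visits while the
explicit update remains monotone (no overshoot oscillation was observed in
any configuration exercised by the tests).

## The theta cycle

Activations are reset at trough onset (rates to 0, potentials to the
resting/leak value) and carried over between phases:

1. **Theta trough (TT).** EC_in is clamped to the input; CA3→CA1 is fully
   inhibited; EC_in→EC_out is closed. CA1 settles under the direct
   entorhinal drive and EC_out under CA1 — the MSP's own reconstruction.
2. **Theta peak (TP).** EC_in→CA1 closes, CA3→CA1 opens. CA3 (driven by
   EC_in and DG throughout) now dominates CA1 — the attempted recall.
3. **Theta plus** (training only). Gates as at the trough, plus the
   EC_in→EC_out identity opens and imposes the veridical pattern on
   EC_out, which also feeds back into CA1 — the target state.

Recall (`recall()`, test mode) runs trough and peak only and reads EC_out
at the end of the peak, when the CA3-driven completion has propagated out.
The readout point is a package choice (trough readout is also exposed for
probing the MSP alone).

**Why the plus-phase target is a projection, not a clamp.** An earlier
build clamped EC_out to the binary input during the plus phase. That fails
structurally: a hard clamp at 1.0 is an activation level free settling can
never attain (the rate function saturates below 1), so the plus-phase
coproducts always exceed the trough coproducts, the decoder weights ratchet
monotonically to saturation, the drive across EC_out becomes uniform, and
the conservative kWTA tie rule then silences the entire layer. Driving
EC_out through a fixed identity projection with scale
`identity_scale = 0.9` imposes a target that is itself a settled, attainable
state: as the CA1→EC_out pathway learns, the trough state approaches the
plus state exactly and the error signal vanishes.

## Learning

After the plus phase, every plastic projection is updated once from the
phase snapshots:

* **MSP projections** (EC_in→CA1, CA1→EC_out, EC_out→CA1): contrastive
  Hebbian learning between the *plus* and *trough* snapshots.
* **Schaffer collaterals** (CA3→CA1): CHL between *plus* and *peak*.
* **All other projections**: the conditional-PCA Hebbian delta on plus
  activations only, with no error-driven component.

The blended rule is
$\Delta w = \varepsilon\,[\,l_{mix}\, y^+(x^+ - w) + (1 - l_{mix})(x^+y^+ - x^-y^-)\,]$,
with $l_{mix} = 0.001$ on error-driven pathways and $l_{mix} = 1$ in the
Hebbian comparison condition. Five conditions are exposed
(`hippo_conditions()`): fully error-driven, fully Hebbian, each pathway
error-driven alone, and an error-driven variant whose MSP is pretrained for
15 epochs with DG/CA3 silenced before integrated training.

Weight handling:

* Weights live in $[0, 1]$ (all principal connections are excitatory).
  `apply_delta()` hard-clips by default; the model configuration uses the
  soft bound (increases scaled by $1-w$, decreases by $w$), which keeps
  weights off the rails and removed a class of saturation instabilities in
  long runs.
* The base learning rate is $\varepsilon = 0.03$; trisynaptic projections
  (including the Schaffer collaterals) use a ×5 rate multiplier
  (`tsp_lr_scale`). A single shared rate cannot serve both pathways: each
  pattern is seen only `n_epochs` times, so the CA3→CA1 association must
  move far per presentation, while the MSP's slot code book must stay
  stable over thousands of cycles and drifts if its rate is that high.
  Per-projection rate constants are standard practice in this model
  family.
* The EC_out→CA1 backprojection has relative drive scale
  `ec_fb_scale = 0.05`. It exists so the imposed target can inform the CA1
  code during the plus phase, but it must stay weak: at full strength the
  CA1 code differs between phases (clean target feedback in plus, decoded
  output in the trough), the encoder chases a moving, phase-inconsistent
  target, and the slot code book collapses onto a few habitual winners.
* DG→CA3 is attenuated (`dg_ca3_scale = 0.3`) and the CA3 recurrents
  strengthened (`ca3_rec_scale = 2`). This is the encoding/retrieval
  balance: the mossy-fibre input is the pattern *separator* and, left at
  full strength, it re-separates partial cues into novel CA3 codes instead
  of letting the attractor complete them.
* Weights initialise uniformly on $[0.25, 0.75]$, seeded; masks (random
  partial connectivity for the diffuse projections, block-diagonal for the
  slot projections) are fixed at build time.

The MSP and its reciprocal projections are learned independently — no
weight tying — though the CHL update is symmetry-preserving (the same
coproduct difference drives both directions), so the learned components
mirror each other on top of their independent initialisations.

## Synthetic inputs

Inputs are composites over a per-slot *vocabulary*: 100 binary entries per
slot, each with exactly `n_active` ones, every pair at Hamming distance
≥ 10, drawn by rejection sampling. The slot geometry is 50 units with 10
active. That choice is forced by counting: with equal-sparsity entries the
distance constraint is an upper bound on pairwise support overlap
($d = 2(n_{active} - o)$), and for 6-active entries in 25 units a distance
floor of 10 demands overlap ≤ 1 — a pair-packing design that admits at most
$\binom{25}{2}/\binom{6}{2} = 20$ entries, far short of 100. At 10-of-50
the floor allows overlap ≤ 5, which uniform draws violate with probability
≈ 0.002, so a 100-entry vocabulary generates in ~120 attempts. The
entorhinal winners-per-slot equal `n_active`, keeping the generator and the
inhibition consistent.

A training set draws distinct slot-index combinations uniformly from the
$100^{n_{slots}}$ product space. Test cues delete 25% of a trained pattern;
the default mode removes two whole slots of eight (matching the slot-wise
scoring semantics), a unit-level deletion mode is exposed as the
alternative reading, and deletion only ever zeroes active units.

What the generator does *not* emulate: correlated slot content, graded
(non-binary) inputs, within-slot semantic structure, and any resemblance
between slots. Passing the capacity tests therefore speaks to storage and
completion of arbitrary high-entropy conjunctions, not to generalisation
over structured stimuli.

## Scoring and statistics

Recall is scored with the **Name Error**: per slot, cosine similarity
between the (graded) output and every vocabulary entry; the pattern is
correct only if every slot's unique argmax is its trained entry. Ties
involving the target count as incorrect, so an all-silent slot is wrong by
construction. Cosine is used because output activations are graded while
vocabulary entries are binary; Euclidean distance is exposed as an
alternative metric.

Condition comparisons use a pooled two-sided bootstrap on per-pattern
error values: both groups are redrawn with replacement, at their original
sizes, from the pooled values to form a null distribution of mean
differences; the p-value is the fraction at least as extreme as the
observed difference. Defaults: 10,000 resamples, significance at 0.005.

## Experiment harness and problem sizes

`capacity_sweep()` crosses conditions × CA3 sizes × set sizes × seeds,
building a fresh network and training-set draw per cell, with DG locked to
5× CA3 and identical inits, training sets and cues shared across conditions
within a cell (so conditions differ only in their learning rule). Results
are tidy tibbles, resumable from a plain-text checkpoint, with
`tidy()`/`glance()`/`autoplot()` methods.

The package's own reference checks run at deliberately scaled sizes: a
memorisation check at CA3 = 80 / DG = 400 with 20 patterns (mean Name
Error ≤ 0.2 expected; the frozen configuration measures 0.0), and a
comparative grid at CA3 = 40 / DG = 200, set sizes {40, 200}, 15 epochs,
3 seeds, over all five learning conditions. These sizes were chosen so the
full suite runs on a single CPU in well under half an hour while still
probing the qualitative phenomena of interest: the error-driven/Hebbian
contrast, the pathway ablations, and pretraining equivalence. The tests
report whatever the frozen configuration actually measures; see the
limitations below for where this implementation's behaviour departs from
the idealised expectations.

## Known limitations

* **Capacity ceiling at high per-slot load.** The monosynaptic code book
  stays stable for roughly a thousand-plus training cycles at the default
  rates; beyond that (e.g. 200+ patterns drawing on ~90 of the 100
  vocabulary entries per slot, 15 epochs) slow weight diffusion erodes slot
  codes and both learning conditions approach ceiling error. The original
  implementation heritage this model simplifies (netinput scaling, weight
  contrast enhancement, richer activation machinery) buys a higher ceiling;
  within this package the error-driven advantage is therefore clearest at
  small-to-mid set sizes, and comparisons at the largest sizes can
  saturate for both rules.
* **The Hebbian monosynaptic pathway is near chance here.** In this
  simplified rendition a purely Hebbian MSP cannot learn a usable slot
  decoder (the fully Hebbian condition sits near ceiling error even at
  small set sizes), so the ablation in which only the Schaffer collaterals
  are error-driven inherits the Hebbian MSP's decoding failure and lands
  near the Hebbian condition rather than near the fully error-driven one.
  Both error signals are necessary in this implementation; richer Hebbian
  machinery (sender-activity renormalisation, weight contrast enhancement)
  would be needed for a serviceable Hebbian MSP.
* Discretised theta: three settling snapshots, not a continuous
  oscillation; no phase reset, no within-phase timing.
* Pooled uniform inhibition, not explicit interneurons; fixed-duration
  settling; no noise.
* No subiculum or CA2; no claims about entorhinal laminar physiology; no
  spatial/navigation phenomena.
* One theta cycle per pattern presentation; no spacing, interference or
  consolidation dynamics across sessions.
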