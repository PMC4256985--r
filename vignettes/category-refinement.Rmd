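---
title: "Category learning and refinement with modulatory feedback"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Category learning and refinement with modulatory feedback}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(corticat)
```

## The model

`corticat` simulates a three-layer network of abstract cortical columns
that learns visual categories and their subcategories without supervision.
Layer 1 is a replica of the input image (N = H·W units, default
100 × 100). Layer 2 copies layer 1 through a one-to-one connection scheme
and normalizes it divisively. Layer 3 holds M category cells, fully and
bidirectionally connected to layer 2.

Every column is a three-stage cascade:

1. **Filtering** — a weighted sum `r = Σ K_j s_j` of its inputs.
2. **Modulation** — re-entrant feedback multiplies the driving signal,
   `r_fb = r (1 + net_fb)`. The asymmetry is essential: feedback can only
   amplify existing activity, never create it. A silent input pixel stays
   silent no matter how strong the feedback.
3. **Pool normalization** — divisive (shunting) inhibition by the pooled
   activity of the layer, solved at steady state:
   `x_j = β raw_j / (α + q_j)`, `q_j = Σ_k Λ_jk transfer(x_k)`.

Layer-2 activities pass through a rectification `g_u(u) = max(u, 0)`;
layer-3 responses through a logistic `g_v(v) = 1/(1 + exp(κ_log(μ_log −
v)))`. A winner-take-all (WTA) over `g_v` selects the single most active
category cell per sweep; ties break toward the lowest index so runs are
deterministic.

Each stimulus presentation is one training step consisting of two sweeps:

* **Feedforward sweep.** The (noisy) stimulus drives layer 2 and layer 3;
  the winner adapts.
* **Feedback sweep.** The winner's projective field `w_out` is compared
  against the current layer-2 activity to form the **residual template**
  `res_j = [g_u(u_j) − w_out,kj]⁺` — the part of the input the winning
  category does *not* predict. The input is then re-presented with its
  gain multiplied by `(1 + λ res_j)`, the network re-settles, and the new
  winner adapts.

Two Hebbian rules with complementary normalizations do the learning, both
gated by the WTA so only the winner's weights move:

* **Instar (Oja-type)** on the receptive fields:
  `ẇ_in = η_in g_v (g_u − g_v w_in)`. The forgetting term `g_v² w` bounds
  growth; under a linear response the rule conserves weight energy
  (‖w‖² → 1), which `oja_linear()` exposes in isolation.
* **Outstar** on the projective fields:
  `ẇ_out = η_out g_v (g_u − w_out)`. A convex-combination tracker whose
  fixed point is the *average expected input* of the cell — exactly the
  prediction needed for the residual. On a feedback sweep the outstar
  therefore tracks the unmodulated feedforward activity: a projective
  field that learned the amplified re-representation would absorb the
  very residual it generated and quench the feedback signal within a few
  dozen steps. The instar, by contrast, does learn the modulated
  activity on feedback sweeps — that is precisely how a freshly
  recruited cell acquires a variant-specific receptive field.

Together they form an associative memory: `w_in` assigns an input to its
best-matching category; `w_out` broadcasts what that category expects to
see. While a category is coherent the residual is small and the feedback
sweep reproduces the feedforward sweep. As the category's average
sharpens, the residual concentrates on the variant-specific part of each
exemplar; once the amplified difference is large enough, a previously
unused cell wins the feedback sweep and becomes that variant's
subcategory cell. Recruiting fresh cells rather than overwriting trained
ones is the model's answer to the stability–plasticity dilemma.

## Stimuli

`stimulus_set()` generates two categories of binary 100 × 100 pictograms
with intensities in [0, 1]:

* **Category A** — four faces: identical annular head outline and eyes,
  differing only in the mouth stroke (straight, smile, frown, open).
* **Category B** — four squares: identical hollow outline enclosing one
  bar, horizontal (top/bottom) or vertical (left/right). Bar regions are
  pairwise disjoint so each variant carries unique evidence.

Exact stroke geometry is a package design choice (exposed through
`face_geometry()` / `square_geometry()`); what is normative is the
union/intersection structure — a substantial shared core per category plus
a smaller variant-specific part — and a foreground energy of roughly 1200–
1600 active pixels, which puts the logistic midpoint `μ_log = 700` at
about half the input energy of one stimulus. Per presentation,
independent Gaussian noise (σ = 0.05) is added and clipped to [0, 1];
noise is drawn fresh each step from a per-step seed, so streams are
bit-reproducible.

What the generator does *not* emulate: gray-level natural images, any
V1-like preprocessing front-end, geometric variability (translation,
scale, rotation), or occlusion. Passing tests therefore demonstrate the
feedback mechanism on idealized, pixel-aligned pattern classes, not
robustness on real imagery.

## Parameters

| Parameter | Default | Meaning |
|---|---|---|
| `eta_in`, `eta_out` | 2⁻⁴ (2⁻⁵ in slow presets) | learning rates (per-step Euler step size) |
| `lambda` | 2⁵ | feedback gain on the residual template |
| `kappa_log`, `mu_log` | 0.0075, 700 (800 in slow presets) | logistic steepness / midpoint |
| `init_mu`, `init_sigma` | 0.75, 0.1 (0.5, 0.1 slow) | weight initialization, clamped at 0 |
| `alpha_u`, `beta_u` | 1, 1.4 | layer-2 decay and input scale |
| `alpha_v`, `beta_v` | 1, 1 | layer-3 decay and input scale |
| `pool_l2` | box, radius 15, gain 1.5, global 14 | layer-2 pool kernel |
| `pool_l3` | uniform (summing), gain 0.05 | layer-3 pool kernel |
| σ (noise) | 0.05 | per-presentation pixel noise |

The decay/scale constants and the pool kernels are not pinned by the
model's defining equations, so they are calibration choices of this
package, made once against two operating-point requirements and then
frozen:

1. **Feedforward scale.** For a clean stimulus, layer-2 output should
   approximately preserve the stimulus scale so that an uncommitted cell
   (weights ≈ `init_mu`) responds near the logistic midpoint — this is
   what makes "μ_log ≈ half the input energy" meaningful. With the box +
   global pool below, `beta_u = 1.4` restores the scale the divisive
   terms remove.
2. **Biased competition under amplification.** During the feedback sweep
   the amplified (unpredicted) part of the input must *redistribute*
   activity rather than inflate it: the pool has a local box component
   (radius 15, window-normalized, gain 1.5) that makes the amplified
   region inhibit itself — capping the weights a subcategory cell can
   acquire — and a global component (gain 14) through which the amplified
   part suppresses the shared structure. The suppression is what lets an
   uncommitted cell out-compete the overall-category cell exactly when
   the residual is large, and the self-inhibition is what keeps
   subcategory cells from later out-competing the overall cell on clean
   feedforward probes.

A uniform all-to-all kernel at layer 2 cannot satisfy both requirements
at once: made strong enough to compress the amplified pattern it divides
clean-stimulus activity several-fold, detaching the printed `μ_log` from
the input-energy scale; made weak it leaves amplified activity inflated
and subcategory cells eventually capture the feedforward competition.
The neighborhood pool resolves this tension and is also the more literal
reading of pooling "in the neighborhood of location j". At layer 3 the
pool spans all M cells uniformly; its gain only rescales the common
divisor of all cells and barely affects the competition, so it is kept
small.

## Numerical choices

* Steady states of the shunting dynamics are found by damped fixed-point
  iteration (damping 0.5, tolerance 1e−8, cap 500 iterations;
  non-convergence is an error, not a warning). The single-unit case has
  the closed form `x = (−α + √(α² + 4βr))/2`, which the test suite uses
  as an oracle.
* Learning is discrete-time: one Euler step per sweep with η as step
  size. The instar rule can transiently push small weights negative at
  finite step size, so updates are clamped at 0 — a documented deviation
  from the continuous-time rule, which stays non-negative.
* Pool sums include the target cell itself; WTA ties break to the lowest
  index; all randomness (initialization, presentation order, noise) flows
  from the single run seed.

## The four protocols

`preset(1..4)` reproduces the four training protocols: (1) barred
squares, blocked in runs of 100, M = 6, slow learning (η = 2⁻⁵,
μ_log = 800, init 0.5); (2) faces in random order, M = 6, defaults;
(3) protocol 2 with λ = 0 — the feedback ablation; (4) both categories,
blocked, M = 12, 1000 steps, protocol-1 parameters.

Run lengths for protocols 1–3 are not uniquely determined by the
protocol descriptions; we fix protocol 1 at 800 steps (two epochs of the
four blocks). The first epoch establishes the overall category cell and
most subcategories; the variant that was absorbed into the overall cell
while it formed (the first block) is only re-encountered — and its
subcategory recruited — in the second epoch. Protocols 2–3 use 400
steps; protocol 4 runs the 1000 steps of its description. Recruitment
*times* are seed-dependent and are not used as stopping criteria.

```{r exp3, eval = FALSE}
fit <- run_experiment(preset(3, seed = 1))
glance(fit)       # 1 recruited cell, no subcategories: the ablation result
classify_cells(fit)
```

## Reading out the result

`classify_cells()` assigns roles from winner statistics on clean,
noise-free probes with learning disabled (so probing never perturbs the
state), repeated twice to confirm stability: the cell that wins the
feedforward sweep for *every* variant of a category is its **overall**
cell; a cell that wins the feedback sweep for exactly one variant is that
variant's **subcategory** cell; never-recruited cells are **unused**;
anything else is reported **ambiguous** rather than silently resolved.
The classifier inspects only the final state by design — transient
blended representations during early training (the overall cell first
absorbs everything) are visible in the trace, not in the role table.

## Known limitations

* The feedforward/feedback margins that keep the overall cell the
  feedforward winner while subcategory cells own the feedback sweep are
  properties of the calibrated operating point, not theorems; at strongly
  different pool gains, stimulus energies or λ the same equations settle
  into exemplar-style coding (each variant captured by its own cell) or
  into a single category with no refinement (the λ = 0 limit).
* Long blocked training slowly oscillates the overall cell's weight mass
  (feedback-sweep updates at saturated activation pull it down,
  feedforward-only blocks push it up), which can delay recruitment by a
  block; the two-epoch protocol-1 run absorbs this.
* Under a stationary random schedule at the default (fast) learning
  rates, subcategory cells eventually also win the feedforward sweep for
  their variant — their receptive-field mass converges slightly above
  the overall cell's overlap with any single variant. Protocol 2 at 400
  steps therefore yields four clean subcategory cells but reports no
  overall cell on the final probe; the overall-plus-subcategory division
  of labor is a property of the blocked protocols (1 and 4) and of the
  transient in random ones.
* Continuous-time trajectories, spiking dynamics, softmax (soft-WTA)
  gating and hierarchies deeper than the two adaptive layers are out of
  scope; the softmax alternative is mentioned in the literature but only
  hard WTA is implemented.
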