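---
title: "An agent-based model of toxicant-induced liver fibrosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of toxicant-induced liver fibrosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lobulefib)
```

## The model

`lobulefib` simulates the initiation and progression of liver fibrosis in a
single hepatic lobule after repeated injections of a metabolically activated
toxin (CCl₄). The guiding idea is that fibrosis is a disease of the *repair
loop*, not of the injury itself: dead hepatocytes recruit and polarise
macrophages, macrophage cytokines transform stellate cells into
collagen-producing myofibroblasts, and collagen — once deposited — blocks
the regeneration that would otherwise erase the damage.

The lobule is a `height x width` lattice (101 × 101 by default) with one
3 × 3 central-vein block at the centre and four 3 × 3 portal tracts at the
corners. Two layers live on it:

* an **occupancy layer** holding at most one space-occupying agent per cell
  — hepatocyte, dead cell (necrotic or apoptotic), collagen deposit
  (myofibroblast- or portal-fibroblast-origin), or a structural vein/tract
  site — and
* a **resident layer** of non-occupying agents — Kupffer cells (quiescent,
  M1 or M2), hepatic stellate cells, myofibroblasts and portal fibroblasts —
  any number of which may share a cell with anything.

Four diffusible mediators (CCl₄, HMGB1, TNF-α, TGF-β) are concentration
lattices updated by a *share kernel*: each cell keeps `1 − p` of its value
and sends `p/8` towards each of its eight Moore neighbours, followed by
first-order decay. Shares aimed across the boundary are lost — the lattice
is a tissue section, not a periodic medium. On a torus (available for
verification) the kernel conserves mass exactly; with absorbing walls total
mass is non-increasing.

One simulation step executes, in order: toxin injection (if scheduled);
hepatocyte death checks; HMGB1 release by necrotic dead cells; Kupffer-cell
replenishment at the portal tracts and the Kupffer-cell phase (move,
phagocytose, activate, M1→M2 switch, secrete); stellate-cell activation;
collagen secretion; hepatocyte proliferation; ageing and lifespan culling;
and field diffusion + decay. Within the Kupffer phase all cells move
simultaneously and phagocytosis conflicts are resolved in a uniformly
shuffled order (one eater per dead cell); candidate parents in the
proliferation phase and active fibroblasts likewise act in shuffled order,
so no lattice-scan direction is ever privileged. Threshold tests inside a
phase read a snapshot of the relevant field taken at the start of that
phase.

All randomness — initial placement, movement, tie-breaks, replenishment —
flows from the single run RNG, so a configuration plus a seed reproduces a
trajectory bit for bit. Positions are 1-based `(row, col)` pairs, the native
indexing of the language's matrices.

## Zonation and dosing

CCl₄ is toxic only after metabolic activation, which is strongest in the
pericentral zone. The model realises this with a single mechanism: a
zonation weight `z(x) = exp(−d(x)/λ)`, where `d` is the Euclidean distance
to the nearest central-vein site and `λ` defaults to a quarter of the
lattice width. Each injection deposits its dose across the lattice
proportionally to `z` (normalised so the total added equals the dose), and a
hepatocyte dies of necrosis when `z · [CCl₄]` exceeds the necrosis
threshold. Peripheral cells therefore see both less toxin and less
activation; injury begins, and stays anchored, pericentrally.

Because the toxin field is deterministic given the schedule, the necrosis
geometry is quantised into rings around the vein block. With the default
calibration:

* a **single injection never kills** — so an 18-step interval, which lets
  the field decay back between doses, never produces any injury or collagen;
* the **second injection** (step 10) kills the innermost ring of ~16
  hepatocytes;
* the **third injection** (step 20) crosses three further zonation rings and
  kills ~60 cells, ~44 of them previously untouched — the decisive event
  separating a resolving injury from progressive fibrosis.

## The inflammatory cascade and its calibration

No quantitative parameters are available for this system at the level the
model operates, so every rate and threshold is a calibration constant
(`default_calibration()`, one file). The calibration was fixed once, against
the reference dynamics of the default run, and is not per-experiment. The
reasoning behind the main choices:

* **Dose (2200 a.u.) and CCl₄ decay (0.08/step).** Chosen inside the window
  derived from the deterministic field dynamics so that the four injection
  intervals order as observed: 6-step dosing ignites early and strongly,
  10-step dosing ignites at the third injection, 14-step dosing first
  crosses the threshold around step 28 and stays marginal, and 18-step
  dosing never crosses at all.
* **Dead-cell lifespan (11 steps).** Dead cells are removed by phagocytosis
  or, failing that, age out. With injury confined to steps 10–11 in the
  two-injection scenario, the last debris disappears around step 20.
* **Kupffer activation.** Phagocytosis by a quiescent Kupffer cell activates
  it; at the 15% default Kupffer ratio a dead cell is found within a few
  steps, so the first activated cell appears shortly after the first
  necrosis (~step 11). The HMGB1 threshold (9 a.u.) is deliberately high:
  in the default run clearance keeps the DAMP field below it, and it only
  matters when clearance fails (see the Kupffer-ratio sweep).
* **M1 duration τ = 4 steps, secretion 0.8 (TNF-α) and 0.9 (TGF-β)/step.**
  The third-injection cohort of M1 cells is the largest synchronous cohort
  of the run, so total TNF-α mass peaks at ~24–25; their M2 successors push
  TGF-β past the collagen threshold at ~25, which dates the collagen onset.
  TNF-α levels stay below the apoptosis threshold throughout the default
  run: inflammation smoulders rather than spreads (see Limitations).
* **Stellate threshold 0.3 a.u.** Conversion requires the regional TNF-α of
  an activation cohort, not a single wandering M1 cell, and is confined to
  the pericentral region where myofibroblast-origin collagen then
  accumulates.
* **Myofibroblasts die after 3 deposits; 2 neighbouring deposits block
  replication.** Read literally ("one deposit, then death"; "3 deposits
  block"), the fibrotic feedback never engages: total collagen stays around
  ten deposits, every blank is refilled within a cycle, and the necrosis
  ring keeps re-killing at full strength forever. Three deposits per
  myofibroblast and a 2-deposit block let collagen progressively retire the
  pericentral ring from the injury cycle, which is also what keeps the
  late-run dynamics quiet. Both remain configurable.
* **Replication cooldown 4 steps.** Fast enough that the ring repopulates
  between injections (sustaining the 10-step dead-cell rhythm), slow enough
  that regeneration does not mask injury.
* **Kupffer replenishment 0.5/tract/step; lifespans of long-lived classes
  set far beyond the horizon; Kupffer ages initialised uniformly** so that
  no artificial cohort of simultaneous natural deaths exists.

Initial ratios follow the commonly observed lobule composition — Kupffer
cells 15% and stellate cells 5% of all placed cells — with hepatocytes
filling every non-structural cell and portal fibroblasts ringing each tract.

## What the experiments show

* `exp_timecourse()`: the reference run. Necrosis from step 10, the
  third-injection activation burst at ~21–24, TNF-α mass peak ~24–25,
  collagen onset ~25, dead-cell counts pulsing with the dosing rhythm.
* `exp_interval_sweep()`: endpoint collagen decreases with the injection
  interval; the 18-step arm stays collagen-free. The mechanism is the
  deterministic dose-accumulation window described above.
* `exp_injection_count()`: two injections resolve (debris gone by ~20,
  essentially no collagen); three injections produce a dead-cell surge at
  step 20 and fibrosis that keeps progressing after the final dose.
* `exp_kc_sweep()`: at 0.15% initial Kupffer cells debris persists and
  HMGB1 — now uncleared — eventually becomes the activator, so collagen
  appears late or not at all within the horizon; blank space rises steeply
  between 0.15% and 7%.
* `exp_hsc_sweep()`: myofibroblast-origin collagen scales strongly with the
  initial stellate ratio.

## Numerical and statistical choices

Onset of a series is dated as the first step strictly exceeding 5% of its
final value; peaks take the earliest argmax; the dominant period is the
median gap between local maxima above 10% of the global maximum. Ensemble
statistics are means over fixed seed sets; the packaged acceptance script
uses 40 replicates because two of the summary statistics (TNF-α peak step,
collagen onset) have occasional late-cycle outliers — seeds in which the
third-injection cohort happens to be weak and a later injection cycle
briefly dominates — with a per-seed frequency near 13%.

Degenerate inputs are handled explicitly: a zero dose yields a provably
quiet run (no death, activation, HMGB1 or collagen); zero-ratio classes
yield empty registries; `n_steps = 0` records only the initial state; an
all-zero series has no onset and no period.

## What the generator does and does not emulate

The simulator *is* the data generator: there is no external data. It
emulates the spatial logic of hepatotoxic injury — pericentral onset,
macrophage-gated progression, origin-tagged collagen — under idealised
conditions: a square lobule section with absorbing walls, one vein, four
corner tracts, homogeneous cell behaviour within a class, and thresholds
rather than dose–response curves. Passing tests therefore show that the
implemented rules produce the documented population dynamics; they do not
show that real lobules obey these rates, and none of the arbitrary
concentration units map to measured concentrations.

## Known limitations

* **No apoptotic spread.** With the calibration required for the
  interval and injection-count contrasts, TNF-α never crosses the apoptosis
  threshold, so inflammation-driven cell death — present in the rule set —
  is dormant in the default run, and early myofibroblast transformation
  before the first necrosis cannot occur.
* **Portal-fibroblast collagen is structurally absent** on the default
  geometry: the corner tracts lie ~71 cells from the vein, and TGF-β can
  reach them neither by the share kernel (a few cells per hundred steps)
  nor by macrophage migration within the horizon. Periportal fibrosis and
  central–portal bridging are outside what this lattice scale can express.
* **No regression.** Collagen is never removed; the model cannot describe
  healing, only progression.
* **Transient blanks at high Kupffer ratios.** Very high phagocytosis rates
  clear debris instantly, but proliferation refills the space within a few
  steps, so the model does not sustain the large persistent blank areas
  reported for extreme macrophage excess.
* One step has no defined real-time duration; all outputs are in steps.

## A minimal run

```{r example, eval = FALSE}
run <- simulate_lobule(sim_config(n_steps = 120, seed = 1))
tail(run$timecourse[, c("step", "hepatocytes", "dead_total",
                        "kc_activated", "collagen_mfb")], 3)
img <- render_snapshot(run$final_state, snapshot_style(hide_hepatocytes = TRUE))
```
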