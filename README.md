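# lobulefib

Agent-based simulation of toxicant-induced liver fibrosis on a 2-D lobule
lattice.

Repeated exposure to a metabolically activated hepatotoxin (CCl₄) injures the
pericentral parenchyma; the inflammatory response to that injury — not the
toxin itself — is what drives collagen deposition. `lobulefib` models this
loop at the level of individual cells on a grid:

1. **Injury.** Injected CCl₄ diffuses over the lattice and kills hepatocytes
   where the zonation-weighted concentration exceeds a threshold (necrosis,
   pericentral); TNF-α above threshold kills them anywhere (apoptosis).
2. **Sensing.** Kupffer cells random-walk, phagocytose dead cells and become
   activated by doing so — or by HMGB1, the DAMP that necrotic (never
   apoptotic) dead cells release when clearance is insufficient.
3. **Signalling.** Activated Kupffer cells secrete TNF-α while M1, then
   switch to M2 and secrete TGF-β. TNF-α transforms hepatic stellate cells
   into myofibroblasts in place.
4. **Fibrosis.** Myofibroblasts and portal fibroblasts deposit origin-tagged
   collagen into vacant space wherever TGF-β exceeds threshold;
   myofibroblasts die after a few deposits, collagen never regresses, and
   collagen-rich neighbourhoods block hepatocyte regeneration.

Space-occupying agents (hepatocytes, dead cells, collagen, vascular
structures) exclude each other from a grid cell; Kupffer cells, stellate
cells and fibroblasts share cells freely. Four mediator fields (CCl₄, HMGB1,
TNF-α, TGF-β) evolve by an eight-neighbour share kernel — each cell keeps
`(1 − p)` of its value and sends `p/8` towards each Moore neighbour — plus
first-order decay.

## Worked example

```r
library(lobulefib)

cfg <- sim_config(n_steps = 120, seed = 2)   # 101 x 101 lobule, injections
run <- simulate_lobule(cfg)                  # every 10 steps
run
#> <fibrosis_run> 120 steps on a 101 x 101 lobule (seed 2)
#>   final: hep 10090, dead 27, activated KC 43, MFB 2, collagen 20 (mfb) + 0 (portal)

peak_step(run$timecourse$tnf_mass)           # TNF-alpha mass peaks at step
#> [1] 24                                    # 24: the 3rd injection ignites
onset_step(run$timecourse$collagen_mfb)      # collagen starts accumulating
#> [1] 25                                    # right after the M1->M2 switch
dominant_period(run$timecourse$dead_total)   # median spacing of dead-cell
#> [1] 6                                    # peaks (ensemble mean ~9-10)
```

The numbers mean: after the third injection (step 20) the accumulated DAMP
signal and the fresh outer ring of necrosis activate a cohort of Kupffer
cells; their TNF-α output peaks a few steps later (24), their successors'
TGF-β starts collagen deposition at ~25, and dead-cell counts pulse with the
10-step dosing rhythm (clearance noise can split individual peaks, as in
this replicate; the ensemble mean sits near 10).

The four sensitivity studies:

```r
exp_interval_sweep(seeds = 1:5)$endpoint     # collagen vs injection interval
#>   interval collagen_total                 # (18-step interval: none at all)
#> 1        6           51.8
#> 2       10           19.4
#> 3       14            6.0
#> 4       18            0.0
exp_injection_count(seeds = 1:5)$summary     # 2 vs 3 injections
#>   dead_last_step_2inj dead_surge_step_3inj collagen_end_2inj collagen_end_3inj
#> 1                19.6                   20               0.2               5.4
```

With two injections the injury resolves (last dead cell ~step 20, no
fibrosis); the third injection triggers a dead-cell surge at step 20 and
collagen accumulates even after dosing stops. `exp_kc_sweep()` and
`exp_hsc_sweep()` vary the initial Kupffer- and stellate-cell ratios.

A command-line front end is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/lobulesim", package="lobulefib"))') \
    simulate --seed 1 --out outdir
```

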