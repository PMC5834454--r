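# npcmimic

Coarse-grained simulation and conductance modelling of DNA-origami
nuclear-pore mimics.

## What this is for

Artificial nuclear pore complexes can be built by grafting intrinsically
disordered FG-nucleoporins (FG-Nups) at addressable anchor sites inside a
DNA-origami ring and docking the ring on a solid-state nanopore. The key
scientific questions are spatial and electrical: how densely do the grafted
proteins fill the ring (and how does that change when the hydrophobic
residues F, I, L, V are mutated to serine), and how much ionic current does
the protein-filled ring block?

`npcmimic` implements the full computational side of such experiments, for
researchers modelling or analysing NPC-mimic data:

* a **one-bead-per-residue force field** for disordered proteins — stiff
  harmonic bonds (`r0 = 0.38` nm), a hydrophobicity-scaled Lennard-Jones
  attraction built on experimental partition energies renormalized to
  `h in [0, 1]`, and Debye-screened electrostatics with a
  distance-dependent dielectric;
* a compiled **Langevin dynamics engine** (BAOAB) for chains tethered to a
  bead-built ring scaffold, with energy minimization and gradual switch-on
  of the long-range terms;
* **density mapping**: time-averaged 3D mass density on a (0.5 nm)^3 grid
  and its cylindrical reductions rho(r,z), rho(r,theta), rho(r), plus
  circularly averaged intensity profiles of 2D images;
* the **density-based conductance model**: for a bare pore

  `G = sigma_bare * [4l/(pi d^2) + 1/d]^(-1)`,

  with protein reducing the local conductivity linearly,
  `sigma(r) = sigma_bare (1 - rho(r)/rho_crit)` (`rho_crit = 85` mg/ml,
  clamped at 0), integrated over the pore cross-section, and a
  ring-on-pore variant that splits the access resistance into a
  protein-loaded top half and a bare bottom half:

  `G = [4l/(pi d^2 sigma_pore) + 1/(2 d sigma_access) + 1/(2 d sigma_bare)]^(-1)`;

* **signal analysis** for the two experimental readouts: nanopore current
  traces (1 kHz Gaussian low-pass, segmentation at voltage-reversal zaps,
  conductance-histogram level detection, event selection, notched-box
  blockade statistics, IV fits) and TIRF photobleaching traces
  (change-point step counting);
* seeded **synthetic-data generators** for every input: FG-like sequences
  and their FILV->S mutants, current traces with programmed docking events,
  bleaching staircases, and closed-form density fields — each emitting its
  ground truth for recovery tests.

Everything is tidyverse-shaped: data frames in, tibbles out, `autoplot()`
methods for every result type, `tidy()`/`glance()` for fitted objects.

## Worked example

Simulate a desk-scale ring (8 chains of 60 residues), compare the
hydrophobic FG-like sequence with its FILV->S mutant, and convert the
densities into conductances:

```r
library(npcmimic)

wt  <- generate_fg_sequence(60, seed = 1)
mut <- mutate_filv_to_s(wt)
substr(wt, 1, 24)
#> [1] "FSFGGQPTTEGGTSANTPSAFSFG"

run_wt  <- simulate_ring_variant(wt,  seed = 1001)  # ~40 s
run_mut <- simulate_ring_variant(mut, seed = 1001)

central_density(radial_profile(run_wt$rz,  zmax = 3.5), r_max = 7)
#> [1] 66.00219
central_density(radial_profile(run_mut$rz, zmax = 3.5), r_max = 7)
#> [1] 57.14687
```

The hydrophobic chains pack roughly 66 mg/ml into the ring lumen versus
about 57 mg/ml for the hydrophilic mutant — the cohesive network the
wild-type FG domain forms. Feeding the radial density profiles into the
conductance model:

```r
pm <- pore_model(diameter = 14)           # desk-scale pore
g_wt <- coated_pore_conductance(radial_profile(run_wt$rz, zmax = 3.5),
                                radial_profile(run_wt$rz, zwindow = c(3.5, 20)),
                                pm)
glance(g_wt)
#>      G G_bare fraction reduction_pct    equation
#> 1 6.65   21.4    0.312          68.8 coated pore
```

so the wild-type blocks more current than the mutant (whose conductance
comes out near 9.2 nS on the same pore). Analysing a synthetic docking
trace end to end:

```r
gen <- generate_current_trace(baseline_nS = 37.8, ring_nS = 32.9,
                              n_events = 3, seed = 11)
events <- select_events(extract_docking_events(gen$trace))
summarize_blockades(events)$median
#> [1] 0.8702142    # programmed G_ring/G_pore = 32.9/37.8 = 0.8704
```

and counting fluorophores from a photobleaching staircase:

```r
bl <- generate_bleach_trace(n_steps = 8, seed = 42)
count_bleach_steps(bl$intensity)$n_steps
#> [1] 8
```

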