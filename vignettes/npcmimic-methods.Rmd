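---
title: "Methods: coarse-grained modelling of DNA-origami nuclear-pore mimics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coarse-grained modelling of DNA-origami nuclear-pore mimics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(npcmimic)
```

## The system

Biomimetic nuclear pore complexes can be built by grafting intrinsically
disordered FG-nucleoporins (FG-Nups) at defined anchor points on the inner
face of a DNA-origami ring and docking the ring onto a solid-state nanopore.
Two protein variants are of interest: a wild-type FG-Nup rich in
phenylalanine-glycine repeats, and a hydrophilic mutant in which every F, I,
L and V is replaced by serine (`mutate_filv_to_s()`). The package models the
grafted-protein physics at one bead per residue, maps the time-averaged
protein density inside the ring, converts that density into an ionic
conductance, and analyses the two experimental signal types this system
produces: nanopore current traces with docking events and TIRF
photobleaching staircases.

## The one-bead-per-residue force field

Each residue is a bead at the position of its alpha-carbon. The interaction
terms, all in (nm, Da, kJ/mol, ps) units:

* **Bonds.** Stiff harmonic springs, `E = k/2 (r - r0)^2`, with
  `r0 = 0.38` nm. The default `k = 8000` kJ mol^-1 nm^-2 keeps RMS
  bond-length fluctuations below 5% of `r0` at 300 K
  (`sqrt(kT/k)/r0 = 4.6%`).
* **Hydrophobic attraction.** A hydrophobicity-scaled 12-6 Lennard-Jones
  potential in the Ashbaugh-Hatch split: the repulsive core is always
  present, and the attractive well depth is `eps_max * (h_i + h_j)/2`. The
  per-residue hydrophobicities `h` come from experimental octanol/water
  side-chain partition energies (Fauchere-Pliska scale, shipped as a
  plain-text table in `inst/extdata/`) renormalized onto [0, 1]
  (`normalize_hydrophobicity()`): arginine maps to 0, tryptophan to 1,
  phenylalanine to 0.86, serine to 0.30. The potential is truncated at
  1.5 nm with a force shift so energy and force vanish continuously there;
  at this 2.5-sigma cutoff the shift makes the realized well depth about 7%
  shallower than the nominal `eps_max` (the effect vanishes as the cutoff
  grows).
* **Electrostatics.** Debye-screened Coulomb (Yukawa),
  `E = ke q_i q_j exp(-r/lambda_D) / (eps(r) r)`, with charges +1 for K/R,
  -1 for D/E, 0 for H (the standard neutral-pH CG convention; termini are
  uncharged because the protein is conjugated at an N-terminal cysteine).
  `screening_length()` computes `lambda_D` from the buffer: 0.8 nm at
  150 mM monovalent salt, 0.5 nm in the 250 mM KCl + 50 mM MgCl2
  measurement buffer. Solvent polarity uses a saturating
  distance-dependent dielectric `eps(r) = 80 (1 - 0.85 exp(-r/0.5 nm))`
  (constant `eps = 80` is available); values stay in (1, 80.5]. Inside the
  simulated system the Yukawa energy is shifted to zero at 6 Debye lengths
  for continuity.
* **Bending/torsion.** The chain-stiffness term of this model family is
  defined through tabulated virtual-bond-angle and dihedral potentials.
  The tables themselves are not part of this package's sources, so
  `bending_tables()` accepts arbitrary user tables (cubic-spline
  interpolated, evaluated by `bending_torsion_energy()`), and the term is
  **off by default**; the dynamics engine integrates the model without it
  and refuses a force field with tables enabled rather than silently
  dropping them. For the brush/network observables studied here the
  dominant physics is excluded volume, hydrophobic cohesion and screening.

### Choosing `eps_max`

The absolute hydrophobic energy scale is the one genuinely free parameter.
We set `eps_max = 3` kJ/mol (~1.2 kT at 300 K) so that an F-F contact is
worth about 1 kT and the sequence-averaged contact of an FG-like domain
(~0.4 kT) sits near the coil-globule transition. That is the regime in
which FG domains are known to behave: dilute, cohesive, liquid-like
networks at protein densities of tens of mg/ml. Substantially larger
values (e.g. 10 kJ/mol) drive 60-residue chains into dense collapsed
globules pinned at their anchors, which is not the physics of FG-Nup
assemblies; the parameter is exposed in `hydrophobic_spec()` so other
published parametrizations can be dropped in.

## Scaffold, membrane and assembly

`build_ring()` tiles a cylindrical shell (default 13.85 nm tall, 36 nm
outer diameter) with inert 2.6 nm beads and places 8 or 32 anchor points on
the inner surface at mid-height, equally spaced in angle and pointing
radially inward. Scaffold beads carry `h = 0` and no charge: they interact
with protein only through excluded volume.

`build_membrane_pore()` represents the SiN membrane as analytic repulsive
walls: a slab of thickness `l = 20` nm pierced by a coaxial cylindrical
pore (`d = 20` nm default). In the ring-on-pore frame the ring center
defines `z = 0` and the ring (~14 nm tall) rests on top of the membrane, so
the slab occupies about [-27, -7] nm. The *density windows* used by the
conductance model below are a separate convention and are kept exactly as
the analysis defines them.

`assemble_system()` grafts chains at evenly strided anchors (8 chains on a
32-anchor ring occupy every 4th site), fixes bead 1 of each chain at its
anchor, and grows the remaining beads as self-avoiding random walks biased
inward; initialization is bit-reproducible under a seed. The box
(100 x 100 x 140 nm for the full system) has soft harmonic walls far from
the structure; there are no periodic boundaries.

## Dynamics

`run_dynamics()` integrates underdamped Langevin dynamics with the BAOAB
splitting; scaffold beads and anchored beads are frozen. Defaults:
`dt = 0.02` ps (the stiff-bond period is ~0.77 ps, so `omega dt = 0.16`),
`T = 300` K, friction `0.5` ps^-1 (chosen low to accelerate configurational
sampling; only equilibrium averages are used). Long-range terms
(hydrophobic attraction and electrostatics) are switched on linearly over
the start of the discarded window after a steepest-descent minimization
(`minimize()`) removes initialization overlaps — bonded and excluded-volume
terms always act at full strength. Thermostat noise comes from a pinned
integer-state RNG (xoshiro256++) seeded from R's RNG, so a protocol seed
fixes the trajectory bit-for-bit across platforms.

Two problem sizes are encoded. The *desk scale* used by the test suite and
the acceptance script is 8 chains x 60 residues grafted in a reduced ring
(7 nm tall, 20 nm outer diameter — chosen so that 60-residue chains, with a
23 nm contour length, can reach and cross the ring axis just as the
full-length Nups span the 34 nm ring) run for 2e5 steps with the first 2e4
discarded. The *production scale* — 32 full-length chains in the full ring for
5e7 steps (first 5e6 discarded; `production_scale_protocol()`) — is encoded as
configuration but not executed by the tests; absolute densities of the full
system are expected only from that configuration and from the exact
literature bending/torsion tables, which is why the desk-scale checks are
directional, not absolute.

## Density mapping

`accumulate_density()` bins protein-bead centers (no kernel smearing,
half-open cells) into (0.5 nm)^3 cells, averages over frames and multiplies
by the bead masses; the unit conversion is pinned in one place
(1 Da/nm^3 = 1.66053906660 mg/ml). Bead masses are the natural per-residue
masses by default, with a uniform 120 Da mode (the FG-domain average) for
parity with bead-mass-agnostic analyses; the grid records which mode was
used. Reductions: `circumferential_average()` gives rho(r, z) on radial
bins one cell wide (value = plain mean over contributing cells; the per-bin
cell counts are kept so mass integrals over the reduced maps remain exact),
`z_average()` gives rho(r, theta) over |z| <= 25 nm, `radial_profile()`
gives rho(r) over a stated z window, and `integrated_mass()` integrates the
ring interior (r <= 18 nm, |z| <= 25 nm by default).
`radial_intensity_profile()` applies the same circular averaging to 2D
micrograph-like images, normalizing the background (outermost 10% of
radii) to zero — the machinery for ring-interior intensity ratios.

For the desk-scale variant comparison, the "central z-averaged density" is
the cell-weighted mean of rho(r) over the ring lumen (r up to the inner
radius, |z| within the ring half-height): this is the region probed by both
the EM intensity comparison and the docked-ring conductance, and for the
short desk ring it is the statistically stable summary (chains spill above
and below the ring in both variants, as the full system also does).

## Density-based conductance model

For a bare cylindrical pore, `G = sigma_bare [4l/(pi d^2) + 1/d]^-1` (pore
resistance + access resistance; `bare_pore_conductance()`). Protein reduces
the local conductivity linearly, `sigma(r) = sigma_bare (1 - rho(r)/85
mg/ml)`, clamped to zero at and beyond the critical density
(`local_conductivity()`); radially integrating sigma(r) over the pore cross
section gives the region conductivity (`region_conductivity()`; the
profile's native 0.5 nm bins are integrated exactly as a step function,
zero density assumed beyond the last bin). A coated pore uses the density
averaged over |z| <= 10 nm for the pore term and 10 < |z| < 40 nm for the
access term. A ring docked on a pore has asymmetric access resistance —
protein on top, none below:
`G = [4l/(pi d^2 sigma_pore) + 1/(2 d sigma_access) + 1/(2 d
sigma_bare)]^-1`, with the pore-region density window (-27, 7) nm and the
top access window (-7, 33) nm in the ring frame (the windows overlap over
the ring interior; they are kept exactly as the analysis defines them).
`sigma_bare = 4.30` nS/nm is the measured bulk conductivity of the
measurement buffer. The model deliberately ignores ionic leakage through
the DNA ring itself, so computed conductances sit below measured ones — a
known, documented bias; comparisons should therefore be made between
variants, not against absolute measured values.

## Signal analysis

Current traces (nA, with the applied-voltage channel in mV) are filtered
with a Gaussian low-pass whose -3 dB point is 1 kHz and whose DC gain is
exactly 1; segments between voltage-reversal "zaps" (10 ms reversals that
release a docked ring) are analysed independently after stripping a 20 ms
guard. Within a segment the conductance histogram (1000 bins/nS, 25-bin
moving-average smoothing — the smoothing width is not pinned by the
analysis convention, so it is config-exposed) is scanned for peaks at least
0.75 nS apart with at least 1% of the tallest peak's height; the
highest-conductance peak is the open-pore baseline and the ring conductance
is the mean of the remaining peaks. Events are kept when their baseline
lies within 0.75 nS of the file's median baseline and they last at least
0.3 s. `summarize_blockades()` reports Matlab-convention notched-box
statistics: type-7 (linear-interpolation) quartiles, notch half-width
`1.57 IQR/sqrt(n)`, whiskers at 1.5 IQR (~ +-2.7 sigma). IV sweeps
(-200..200 mV in 2.5 mV steps) are fit by ordinary least squares
(`fit_iv()`).

Photobleaching staircases (2 Hz frames) are counted by offline change-point
detection: binary segmentation with an L2 cost and penalty
`3.5 sigma^2 log n`, where sigma is estimated from the median absolute
successive difference. The penalty factor trades missed 1-frame steps
against false positives; at step SNR 5 it resolves bleaching events one
frame apart while keeping the false-positive rate per trace well below 1%.
The fitted level sequence is forced monotone non-increasing (upward jumps
are merged) and the remaining downward change-points are counted. Fused
events — two fluorophores bleaching within the same frame — are
irreducibly undercounted, which reproduces the low-side tail seen in
experimental copy-number histograms.

## Synthetic data generators

Every input has a seeded generator that also emits its ground truth, and
recovery tests consume only the generated artifact:

* `generate_fg_sequence()` builds FG-domain-like sequences: FSFG motifs
  evenly interspersed in hydrophilic spacers (G/S/T/N/Q/A/P), default 25%
  of residues in motifs and 5% charged (K/E balanced) — the low charge
  density characteristic of cohesive FG domains.
* `generate_current_trace()` emulates docking experiments: piecewise
  constant conductance (baseline/docked), 10 ms voltage-reversal zaps, and
  additive white Gaussian current noise. Real traces additionally carry
  1/f and capacitive components that this generator does not emulate, so
  passing recovery tests demonstrate correctness of the estimator, not
  robustness to every instrumental artifact.
* `generate_bleach_trace()` draws per-fluorophore exponential bleaching
  times (default mean lifetime 250 s, typical of oxygen-scavenged Cy5 at
  moderate excitation, recorded at 2 Hz) on a staircase with Gaussian
  noise. Real recordings also show blinking and baseline drift, which are
  not emulated.
* `generate_density_field()` produces closed-form (uniform, Gaussian,
  annular) 3D density fields for exercising the reductions and the
  conductance quadrature against analytic truth.

## Numerical choices and degenerate inputs

Half-open cell binning; cell-count-weighted reductions so mass is conserved
exactly through 3D -> (r,z) -> rho(r); step-function quadrature on the
density profile's native bins (no interpolation artifacts); collinear bead
triplets get zero bending force by convention; coincident beads are
rejected with the offending pair; trajectories abort if any bead moves more
than 1 nm in one step (timestep too large); minimization reports
convergence or the iteration stop; all-equal partition energies are
rejected as a degenerate hydrophobicity scale; zero ionic strength is
rejected (infinite screening length).

## Known limitations

* Absolute conductances are biased low (no DNA-ring leakage path).
* The desk-scale system supports directional variant comparisons only;
  absolute densities of the full 32-chain system require the production-scale
  configuration and the literature stiffness tables.
* No solvent, no pH titration, no atomistic detail; bending/torsion off by
  default.
* The bare-pore geometry term assumes a cylindrical pore; real pores are
  hourglass-shaped.
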