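# bandfib

Design and multiscale simulation of synthetic banded-fiber collagens.

Fibrillar collagens owe much of their biology to a supramolecular feature:
triple helices pack offset and parallel into fibers with alternating
gap/overlap bands (the D-period of Type I collagen). `bandfib` is an R
toolkit for engineering that behaviour into synthetic collagens and for
simulating the result across scales. It is aimed at protein designers and
biomaterials researchers who want to specify band geometry on paper, sanity
check the assembly mechanism computationally, and compare simulated fibers
with TEM/AFM/cryoET measurements.

A designed chain is a module grammar string, e.g. `P10-B-P10`: two adhesive
blocks — hydrophobic (Pro-Pro-Gly)<sub>n</sub>, or electrostatic
(Pro-Arg-Gly)<sub>n</sub>/(Glu-Pro-Gly)<sub>n</sub> pairs padded to 15
residues — flanking a functional-driver block (Scl2-like fragment classes
A/B/C; synthetic stand-ins are generated, real sequences can be supplied by
FASTA). On top of the grammar the package implements:

* **Banding competence rules** — two adhesive flanks required; hydrophobic
  flanks assemble for n ≥ 8 triplets, electrostatic flanks at their full 5
  charged triplets.
* **Band geometry** — overlap = adhesive residues × 0.29 nm, gap = driver
  residues × 0.29 nm, period = their sum.
* **Stagger scoring** — a discrete sliding-register score: ±1 for
  charged pairs (K/R vs D/E) within ±3 residues, +1 for hydrophobic pairs
  (V, M, I, L, F, P) within ±2, scanned at every one-residue shift,
  optionally with the 156-residue lattice gap of the natural Type I
  arrangement.
* **Rigid-body packing energetics** — idealized 7/2-class triple-helix
  models; 12-6 Lennard-Jones (6 Å cutoff) plus screened Coulomb
  (ε(d) = 4d, 12 Å cutoff) interaction energy over the five pose
  parameters (Ω, θ, φ, r, Δh), optimized by Metropolis simulated annealing
  (16,000 steps, 40 → 0.001 by default) with Arg/Glu rotamer sampling and
  salt-bridge detection.
* **DLA fiber assembly** — rods of 1 nm spheres (one per adhesive triplet,
  25/27 per driver triplet) diffusing on a 3D hexagonal lattice with the
  cylinder-drag step anisotropy P<sub>z</sub>/P<sub>xy</sub> = 4L/(πD),
  sticking via adhesive-adhesive lateral contacts in full module register.
* **Period estimators** — FFT (with detrending and parabolic peak
  interpolation) and real-space band counting, compared by a pooled
  two-sample t-test.

## Worked example

```r
library(bandfib)

design <- parse_design("P10-B-P10")
classify_banding(design)
#> <competence_verdict> P10BP10: banding-competent (ok)

predict_bands(design)
#> <band_prediction> P10BP10: overlap 8.70 nm, gap 23.49 nm, period 32.19 nm

rod <- rod_from_design(design)
rod
#> <rod_model> P10BP10: (10 adhesive, 25 driver, 10 adhesive) = 45 spheres, period 35

agg <- run_dla(rod, sim_config(n_rods = 300, seed = 1))
agg
#> <dla_aggregate> 300 rods x 45 spheres; length 675 nm, thickness 14.8 nm

trace <- detrend_band_trace(axial_band_trace(agg, central = 0.5))
fft_periodicity(trace, detrend = "none")
#> <period_estimate> 34.39 nm (fft)
realspace_periodicity(trace)
#> <period_estimate> 34.89 nm (realspace)
```

Reading the numbers: the 30-residue adhesive predicts an 8.7 nm overlap
band and the 81-residue driver a 23.5 nm gap band (32.19 nm period). The
coarse-grained fiber grown from 300 rods is a few hundred nm long, thicker
in the middle than at the ends, and its axial density is periodic at the
rod repeat of 35 spheres (= 35 nm), which both estimators recover within
about 2% of each other.

`run_pipeline()` chains all stages (design → predict → score → pack →
simulate → measure) under one master seed and writes FASTA, CSV, PDB, PNG
and a provenance-stamped `summary.json`.

## Vignette

`vignettes/banded-fiber-design.Rmd` documents the models, the tunable
parameters and their defaults, the numerical conventions (scoring windows,
tie-breaks, annealer schedule, estimator detrending), what the synthetic
fragment generator does and does not emulate, and known limitations.
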