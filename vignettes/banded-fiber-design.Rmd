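---
title: "Designing and simulating synthetic banded-fiber collagens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and simulating synthetic banded-fiber collagens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bandfib)
```

## The design problem

Natural fibrillar collagens assemble from offset, parallel-packed triple
helices into fibers with an alternating gap/overlap banding pattern. A
synthetic collagen chain that reproduces this behaviour can be written as a
small grammar of modules: two terminal *adhesive* blocks that drive
inter-helix association and form the overlap band, flanking a tailorable
*functional-driver* block that forms the gap band. Adhesive blocks are
either hydrophobic — (Pro-Pro-Gly)~n~, written `Pn` — or electrostatic: an
N-terminal (Pro-Arg-Gly) block `Rn` paired with a C-terminal (Glu-Pro-Gly)
block `En`, each padded with Pro-Pro-Gly triplets to a fixed 15 residues.
Driver blocks are bacterial collagen-like fragments of three compositional
classes: A (chargeless), B (carrying one integrin-binding GFPGER motif) and
C (charge-rich, net-neutral).

`bandfib` implements this grammar and the multiscale computational chain
around it: band-geometry prediction, sequence-level stagger scoring,
atomic-level rigid-body packing energetics, and coarse-grained fiber
assembly by diffusion-limited aggregation (DLA), with banding-period
estimators to close the loop.

```{r grammar}
design <- parse_design("P10-B-P10")
design
classify_banding(design)
```

### Banding-competence rules

Two adhesive modules must flank the driver; single, leading, trailing or
interleaved adhesives do not produce a productive overlap interface.
Hydrophobic flanks promote banded assembly from 8 triplets upward;
electrostatic flanks need their full 5 charged triplets. The classifier
encodes exactly these rules and reports an enumerated reason code for
failures, which the pipeline surfaces in strict mode.

### Synthetic driver fragments

The real driver fragments are Scl2-derived sequences; the generator in
`make_fragment()` stands in for them with random Xaa-Yaa-Gly triplets drawn
from an uncharged pool (A/S/T/Q/N), constrained per class: A has zero
charged residues, B embeds the GFPGER motif once (as the triplet pair
FPG-ERG, with the leading Gly supplied by the preceding triplet — which is
why a B fragment needs at least three triplets), and C charges ~40% of its
X/Y positions with an exactly balanced K/R vs D/E split. The stand-ins
reproduce the compositional classes and lengths, not the actual Scl2
sequences; any conclusion that depends on the true sequences (e.g. real
driver-driver interaction hot spots) is outside what these fragments can
show. Real fragments can be supplied through FASTA and a custom fragment
library.

## Band geometry

Each residue spans 0.29 nm along the triple-helix axis, so band widths
follow directly from residue counts: the overlap band is one adhesive
module, the gap band the full driver, and the period their sum.

```{r geometry}
predict_bands(design)
predict_bands(parse_design("P10-B-B-P10"))$period_nm
```

The 111-residue repeat of P10BP10 predicts a 32.19 nm period and the
192-residue repeat of P10BBP10 a 55.68 nm period. A shipped table of
measured bandwidths (TEM/AFM/cryoET) supports systematic
prediction-vs-measurement reports; deviations beyond a configurable 25%
flag are reported, not errors — the known outlier is the R5BE5 overlap,
measured distinctly wider (5.8 nm) than its 15-residue prediction
(4.35 nm).

## Stagger scoring

The discrete stagger score slides one chain along another one residue at a
time. Charged residues (K/R vs D/E) score +1 for opposite pairs and −1 for
like pairs within a ±3-residue window; hydrophobic residues (V, M, I, L,
F, P) score +1 pairwise within ±2. Every ordered pair inside its window is
counted once, and a residue may take part in several pairs; this counting
convention is frozen by a literal brute-force oracle in the test suite.
Two further conventions the underlying description leaves open were fixed
as: tie-breaks in `top_poses()` prefer smaller |shift|, then the positive
shift; and the periodic self-association mode inserts a literal 156-residue
unscored gap after each molecule (the "0.6 D" label and 156 do not quite
agree arithmetically — the residue count is taken at face value and is
configurable).

One consequence of the windowed counting on a Gly-every-third lattice is
worth knowing: for proline-rich sequences the score at stagger ±1 slightly
exceeds stagger 0, because the ±2 hydrophobic window then captures the
i±3 triplet repeat. The global peak cluster of a P~n~XP~n~ self-scan
therefore sits within a couple of residues of exact full overlap — still
far from, and clearly distinguished from, the adhesive-on-adhesive register
one period away.

## Rigid-body packing energetics

`build_triple_helix()` constructs an idealized triple helix rather than
editing a crystal template: three chains on a left-handed 7/2-class
superhelix (−34.29° twist per residue), 2.9 Å rise per residue, 120°
inter-chain rotation with a one-residue axial stagger, glycine C-alphas at
a smaller radius so Gly faces the core. Backbone and sidechain heavy atoms
are placed from local-frame offsets; Arg and Glu sidechains carry a small
backbone-independent rotamer set (three orientations each). This is a
deliberately coarse rigid model — adequate for ranking packing interfaces
and detecting salt bridges, not for crystallographic detail.

The interaction energy between two helices is the inter-model sum of a
12-6 Lennard-Jones term (Lorentz-Berthelot combination, 6.0 Å cutoff) and
a Coulomb term with distance-dependent dielectric ε(d) = 4d and a 12 Å
cutoff — the standard implicit-screening choice for rigid vacuum docking.
Parameters are an embedded ff14SB-family heavy-atom table with hydrogens
subsumed into heavy-atom charges; each residue's charges sum to its formal
charge. Intra-helix terms are excluded (both models are internally rigid).

Poses have five parameters: tilt Ω ∈ {0°, 180°}, revolution θ, self-rotation
φ, inter-axial distance r, axial offset Δh. `optimize_pose()` anneals them
(plus discrete rotamer swaps, 20% of proposals when available) under a
geometric 16,000-step, 40 → 0.001 schedule by default. Three numerical
choices stabilise the quench on this rough landscape: move widths shrink
with √(T/T₀) down to a 0.3 floor; Δh reflects at ±half the helix length
(no-overlap poses have no interface to score); and every quarter of the
schedule the chain returns to the best-so-far state if it has wandered
above it. Default move half-widths are ±10° (θ, φ), ±0.5 Å (r), ±1.0 Å
(Δh).

```{r pack, eval = FALSE}
series <- energy_series(c(5, 8, 10, 12), "P", seeds = 1:5,
                        anneal = anneal_config(steps = 3000))
energy_threshold_report(series)
```

Association energies strengthen monotonically with adhesive length, and
electrostatic R/E modules pack at larger inter-axial separations than
hydrophobic ones while forming ~3–3.5 Å Arg-Glu salt bridges. Those
ordering properties are asserted in the tests; absolute kcal/mol values
are reported against a configurable −30 to −50 kcal/mol assembly-threshold
band but never asserted, because this force-field/builder combination is
not the all-atom pipeline such values would need.

## Coarse-grained assembly by DLA

A design is reduced to a rigid rod of 1 nm spheres: one sphere per
adhesive triplet, and round(25/27 × n) spheres for a driver of n triplets
(low-proline triplets rise ~0.9 nm, which maps the canonical 27-triplet
driver to 25 spheres). A P10BP10 rod is thus (10, 25, 10) = 45 spheres
with an axial repeat (period) of 35 spheres.

Rods diffuse on a 3D hexagonal lattice (hexagonal close packing in x–y,
±1 nm steps in z), staying axis-parallel. Viscous drag on a cylinder gives
the step anisotropy P_axial/P_lateral = 4L/(πD) — 57.3 for a 45-sphere
rod, so diffusion is overwhelmingly axial sliding. A walker sticks when
its adhesive spheres laterally contact aggregate adhesive spheres of
compatible type (P–P, or R–E only) in full module register (base offset ≡
0 mod the period; the contact count required defaults to one full adhesive
module and is configurable). Launch circles sit 5 nm outside the
aggregate, walkers straying beyond 3× the launch radius or 10⁶ steps are
relaunched.

Full-register sticking makes the axial structure exactly 35-periodic:
overlap bins carry roughly twice the packing density of gap bins, which is
the physical origin of the TEM banding contrast (stain infiltrates the
sparse gap zones). Aggregates are thicker in the middle and tapered — the
signature DLA morphology — and mean length and thickness grow with rod
count while the aspect ratio moves only slowly.

```{r dla, eval = FALSE}
rod <- rod_from_design(design)
agg <- run_dla(rod, sim_config(n_rods = 300, seed = 1))
fiber_dimensions(agg)
fft_periodicity(detrend_band_trace(axial_band_trace(agg, central = 0.5)),
                detrend = "none")
```

The electrostatic variant stacks strictly staggered: R–R and E–E contacts
are disallowed, so laterally adjacent rods must be offset by a non-zero
multiple of the period, putting Arg modules against Glu modules.

"Fiber length and width" of an ensemble are summarised per rod count as
both the simple mean and a placed-rod-weighted mean (the weighting
convention is not pinned down by the source description; within a count
group the two coincide).

## Period estimation

Banding periods are measured two ways. The FFT estimator detrends
(linear, or moving-average for envelope-dominated aggregate profiles —
the empirical-mode-decomposition denoising used for AFM data elsewhere is
deliberately not reproduced; the detrend method is recorded in the
estimate), takes the dominant non-DC Fourier bin, refines it by parabolic
interpolation, and falls back to a subharmonic when a harmonic carries the
peak (square-wave-like band profiles put substantial power in the second
harmonic; the fallback requires the subharmonic to hold ≥60% of the peak
magnitude). The real-space estimator smooths lightly (3-sample moving
average, so single-sample noise spikes are not counted as bands),
thresholds at the midpoint of the 10th and 90th intensity percentiles,
detects band onsets as upward crossings, and divides the spanned length by
the number of periods. Onsets rather than band centers define the
convention. A pooled two-sample t-test (`compare_periods()`) quantifies
whether the two estimators disagree.

On noiseless rectangular traces both estimators are exact (FFT to within
one sample of interpolation); on simulated 300-rod aggregates they agree
within 3%.

```{r metrics}
tr <- synth_band_trace(35, duty = 10 / 35, n_periods = 12)
fft_periodicity(tr, detrend = "none")
realspace_periodicity(tr)
```

## Reproducibility and problem sizes

Every stochastic stage takes an explicit seed; `run_pipeline()` derives
per-stage seeds from one master seed, making whole runs bit-reproducible.
The test suite exercises the simulator at 300 rods × 20 replicates and the
annealer at 3,000-step schedules over 5 seeds (the 2-triplet grid
cross-check runs the full 16,000-step default) — sizes chosen so the
properties under test (monotonicity, banding period, taper, estimator
agreement) are stable without simulating the full 3,000-rod, 100-replicate
production ladder, which `ensemble_run()` supports unchanged.

## Known limitations

* Driver fragments are synthetic stand-ins; sequence-specific driver
  effects are out of reach (supply real sequences via FASTA to study them).
* The helix builder is idealized; energies are ranking scores, not
  calibrated free energies, and hydrogen-bond directionality is absent.
* Rods are rigid and axis-parallel; long multi-fragment designs whose
  flexibility matters (the regime where rigid-rod DLA is known to diverge
  from observation) are outside the model.
* The DLA lattice is single-occupancy with irreversible sticking; no
  detachment, annealing of defects, or solvent hydrodynamics beyond the
  4L/(πD) step anisotropy.
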