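---
title: "Methods: conformational metrics for transmembrane helix dimerization"
author: "tmdimer authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conformational metrics for transmembrane helix dimerization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tmdimer)
```

## Scope and model

`tmdimer` quantifies the association of two membrane-embedded α-helical
transmembrane domains (TMDs) from coarse-grained (CG) bead trajectories.
The motivating systems are the TMDs of the insulin-receptor family:
49-residue constructs (IR numbering 940–988, IGF1R 919–967) represented
by one backbone ("BB") bead per residue, embedded in a ~4 nm membrane
slab built in the xy plane of a periodic 20 × 20 nm patch. The package
does not simulate CG force-field dynamics; it analyzes trajectories
produced elsewhere, and ships a Brownian-dynamics (BD) generator whose
only role is to produce synthetic trajectories with known, controllable
statistical structure for testing.

All in-memory lengths are nm, times ps, angles degrees and energies
kcal/mol; Å-based formats (PDB, DCD) are converted at the I/O boundary.

## Geometry definitions and their conventions

**Helix axis.** The axis of a helix over a residue span is the first
principal component (SVD) of its backbone-bead coordinates. This is a
standard, parameter-free estimator that is exact on collinear beads and
stable on ideal helices; its sign is fixed so the axis points toward the
extracellular side (+z), which makes the reported axis invariant to the
order in which beads are listed. Kink angles instead orient both
sub-axes N→C, so a straight helix reads 0° and a hairpin would read
towards 180°.

**Tilt and crossing angles.** Both are folded to [0°, 90°] through an
absolute cosine. The crossing angle is therefore unsigned: right- versus
left-handed packing is deliberately not resolved, because the analyses
this package supports report only non-negative angle ranges. The
membrane normal is the laboratory +z axis; the slab is never tilted, so
no leaflet-surface fitting is attempted.

**Inter-helical distance d_HH.** Distance between the centres of mass
(equal bead masses) of the two *measurement spans*, which differ by
receptor: IR 953–979, IGF1R 937–959. The tilt spans differ slightly for
IR (957–979); both span sets are preset keys
(`tmd_preset("IR")`) and individually overridable — they are honoured as
given rather than reconciled. The minimum-image convention is applied in
x and y only: helices span the membrane and never wrap in z.

**Dimer criterion.** A frame is dimerized when d_HH ≤ 1.3 nm, with the
boundary read inclusively so the state is well defined at the cutoff.
`detect_dimerization` is monotone in the cutoff and applies no smoothing
by default; an optional minimum-dwell filter exists but is off, so a
genuine transient dissociation can never be silently hidden.

**Crossing point.** The mutual closest approach of the two axis lines
is solved in closed form; the reported residue is the backbone bead
nearest the mid-point of the closest-approach segment. A residue is only
reported when the lines pass within 1.5 nm — slightly above the dimer
criterion so every dimerized frame localizes a crossing — and never for
exactly parallel axes.

## Surface area

Buried surface area is computed with the Shrake–Rupley method directly
on the CG beads: each bead is expanded by the probe radius (default
0.185 nm, about half a CG water bead) and covered by a deterministic
Fibonacci-lattice quadrature (default 960 points/bead; the single-sphere
area converges to well under 0.5% at this resolution, and halving or
doubling the count is a cheap convergence check). BSA is
SASA(A) + SASA(B) − SASA(A∪B), clipped at zero after a
quadrature-tolerance check. Bare backbone rods only graze each other at
crossing points, so synthetic BSA values are far below those of a
side-chain-resolved interface; only the dimerized-versus-dissociated
*trend* is meaningful on synthetic data, and that is what the tests
assert.

## Free-energy profiles

Angle histograms use fixed-width bins (default 2.5°, resolving a
0–50° tilt range into ~20 bins) with the half-open convention — a value
exactly on an edge belongs to the bin on its right — and an explicit
overflow tally so out-of-range values are counted, never dropped.
Boltzmann inversion sets U = −k_B T ln P per occupied bin
(k_B T = 0.5961 kcal/mol at 300 K) and shifts the occupied minimum to
zero; empty bins stay undefined (NA) rather than being clamped, because
a cap value distorts minimum searches. With replicate simulations the
profiles are inverted per replicate and then averaged bin-wise (mean and
sd), not pooled — a bin empty in any replicate is undefined in the mean.

## RMSF

Each frame is Kabsch-superposed onto a reference over the align-span
backbone beads; the reference is the mean structure after a single
alignment pass to the first frame (no iterative refinement — for the
rigid-core helices this changes nothing measurable and keeps the
procedure deterministic in one pass). The Kabsch rotation enforces a
proper rotation (determinant +1), and the RMSD it induces is checked in
the tests against an independent quaternion-grid minimization and
against `bio3d`'s superposition.

## Clustering

Dimerized frames are clustered with the GROMOS neighbour-counting
algorithm: the frame with the most neighbours within the RMSD cutoff
seeds a cluster, it and its neighbours are removed, and the procedure
repeats. Ties in the neighbour count are broken by the lowest frame
index (the algorithm's published form leaves ties open; an explicit rule
makes results reproducible). The RMSD uses the backbone beads of both
chains jointly, treating the dimer as one rigid body. The conventional
cutoff for CG dimer ensembles, 0.9 nm, is the package default.

## The synthetic generator

`simulate_bd` is a statistical test harness, not a physical model: its
purpose is to produce trajectories whose ground truth is known exactly.

- Each helix's in-plane centre of mass performs overdamped Brownian
  motion (default lateral diffusion 1e-4 nm²/ps, a realistic order for a
  TM helix in a lipid bilayer) under a Gaussian association well
  (default depth 5 kcal/mol, centre 1.0 nm, width 0.3 nm) plus a
  harmonic core repulsion. With these defaults a pair started 3.5 nm
  apart reliably associates within a few hundred ns of BD time and then
  holds a stable dimer, emulating diffusive search followed by stable
  association.
- Tilt, crossing and kink angles follow Ornstein–Uhlenbeck dynamics on
  harmonic potentials, integrated with the *exact* OU update
  (exponential relaxation plus matched noise), so the stationary
  variance equals k_B T/k at any time step — this is what makes the
  equipartition test sharp. Defaults: k_θ = 0.02 kcal/mol/deg² about
  θ₀ = 30° (variance ≈ 29.8 deg², i.e. an ~11° wide tilt distribution),
  k_Ω = 0.05 about Ω₀ = 25°, active only while dimerized.
- While dimerized, the pair's mean azimuth relaxes toward the inter-COM
  direction ("interface lock"). Without this, the attack angle between
  the separation vector and the tilt plane diffuses freely and a single
  imposed packing mode fragments into a continuum of structures — a
  freedom no real, interface-stabilized dimer has.
- Bead positions are regenerated each saved frame from the reduced state
  as rigid rods (optionally kinked at a pivot residue) with per-bead
  Gaussian jitter that is larger outside the membrane-embedded span
  (default 0.02 nm core / 0.08 nm termini), reproducing the stiff-core,
  floppy-termini RMSF signature of membrane-embedded helices.
- Frames are saved every 50 ps by default, matching the frame spacing
  conventional for CG production runs; `dt` defaults to 10 ps.
  Everything is deterministic under a fixed seed, and a temperature of
  zero freezes all stochastic terms.

What the generator does *not* emulate: explicit lipids, water and ions
(the membrane enters only as slab geometry and as composition
bookkeeping), force-field energetics, side-chain packing, helix
unfolding, or the coupling between translation and rotation that a real
bilayer imposes. Tests passing on BD data therefore validate the
*analysis machinery* — estimator correctness, state logic, statistical
recovery — not any biological claim about real ensembles.

**Starting systems.** `build_initial_system` reproduces the five
standard starting orientations per receptor (initial d_HH 7.2, 3.5, 2.4,
3.5, 3.1 nm; tilt 45° except the upright O5; crossing 45° for O3) as
ideal helices (0.23 nm helix radius, 0.15 nm rise, 100°/residue twist)
with N-termini toward +z. An ideal helix with a non-integer number of
turns biases a principal-component axis fit by a fraction of a degree,
so the builder iterates a small corrective rotation until the *measured*
axis matches the target, then translates chain B so the *measured*
span-centroid distance equals the requested d_HH exactly. Closure is
thus exact by construction, to numerical precision. The recorded system
sizes in atoms and the 2.5 nm closest-residue placement gap are carried
as metadata; solvent packing is not modelled, and the builder reports
the actually-achieved closest-bead gap instead.

**Membrane bookkeeping.** The plasma-membrane mimic is an asymmetric
1600-lipid bilayer (800/leaflet: outer 360 CHOL, 248 POPC, 136 POSM,
56 POPE; inner 328 CHOL, 168 POPE, 120 POPC, 80 POPS, 72 POSM,
32 POPI), 15312 CG waters and 150 mM salt. POPS and POPI carry −1 each,
so electroneutrality fixes Na⁺ = Cl⁻ + 112 (314 for 202 Cl⁻).
`composition_report` checks these identities for any composition.

## Choices made where the design was open

- **Trajectory formats.** DCD is read and written natively (and
  cross-checked against an independent reader); XTC's compressed-integer
  encoding is not supported, and a documented plain-text format serves
  as the universal fallback. GRO files carry no chain records, so chains
  are inferred from a drop in residue numbering.
- **Unsigned crossing angle.** Only non-negative angle ranges are
  reported downstream; resolving handedness would require a sign
  convention with no consumer in this pipeline.
- **Packing-mode rule.** The X/V/parallel labels are an explicit
  operationalization: X when Ω > 15° with a localized crossing residue;
  parallel when Ω ≤ 5° and d_HH < 1.0 nm; V when Ω ≤ 15° with a kink
  above 15° and d_HH in 1.0–1.3 nm; otherwise unclassified. The
  thresholds come from the printed ranges of the corresponding
  configuration families (X/V contact at 1–1.3 nm, parallel at
  0.8–1 nm, X-shaped crossings above 15°) and are all config-exposed,
  since the original assignment was done by clustering plus inspection
  rather than by rule.
- **Fixture-scale cluster cutoff.** The two-mode BD fixture separates
  its planted basins by ~0.6 nm RMSD with ~0.1–0.25 nm intra-basin
  spread — tighter than the structural diversity of real CG ensembles,
  for which the 0.9 nm default is calibrated. Fixture tests therefore
  cluster at 0.35 nm, chosen between the two scales; the default is
  untouched.
- **Kink estimator tolerance.** With per-bead noise σ = 0.02 nm and a
  7-residue halfspan, straight-line error propagation gives an ~1.4° rms
  direction error per sub-axis; the tests assert recovery of a
  constructed 30° bend at tolerances derived from that budget, not from
  observed scatter.

## Problem sizes used by the tests and the acceptance script

Unit tests run on systems of 2–98 beads and trajectories of 3–2000
frames. The statistical checks use: 10⁵ Gaussian samples for the
free-energy recovery (minimum within one 2.5° bin of 30°, curvature
within 15%); 6 × 10⁴ BD steps for equipartition (variance within 20% of
k_B T/k_θ, ~5800 effectively independent samples); 2 × 10⁴ BD steps for
the association fixture (first passage plus > 90% dimer occupancy over
the final half); and a 600-frame two-mode fixture for the 70/30
population recovery (within 10 points). These sizes were chosen so each
statistical tolerance sits several standard errors away from its
threshold.

## Known limitations

- The crossing angle is unsigned; left/right-handed packings are
  indistinguishable.
- SASA on backbone-only models underestimates interface burial badly;
  add side-chain beads (radii via `bead_topology`) when absolute BSA
  matters.
- The BD generator's interface lock imposes symmetric azimuths; it
  cannot emulate asymmetric interfaces in which one helix rotates
  independently.
- The full pairwise RMSD matrix is held in memory; clustering more than
  ~20k frames requires striding (`--stride`/`stride`), which preserves
  populations but not per-frame labels.
- Triclinic boxes are rejected; the pipeline assumes an orthorhombic
  membrane patch.
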