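# tmdimer

Conformational analysis of transmembrane-domain (TMD) dimerization in
coarse-grained (CG) bead trajectories.

Single-pass α-helical TMDs of receptor tyrosine kinases — the insulin
receptor (IR) and the insulin-like growth factor-1 receptor (IGF1R) are
the motivating systems — associate laterally in the membrane, and the
geometry of the resulting helix–helix dimer (tilted X-shaped crossings
versus upright V-shaped or parallel packing) carries mechanistic meaning
for receptor activation. `tmdimer` implements the complete conformational
metrics pipeline used to characterize such dimers in CG molecular
dynamics output, plus a synthetic two-helix Brownian-dynamics (BD)
generator and a deterministic system builder so that every stage of the
analysis is testable at desk scale without access to large MD ensembles.

The package is for structural bioinformaticians and simulators who have
bead-level trajectories of two membrane-embedded helices (one backbone
"BB" bead per residue, optional side-chain beads) and want reproducible,
scriptable dimerization metrics in R.

## The metrics

With helix axes **u**₁, **u**₂ fitted as the first principal component
of each helix's backbone beads over a configurable residue span, and the
membrane normal **n** = +z:

- **Inter-helical distance** d_HH: Euclidean distance between the
  centres of mass of the two measurement spans (IR: residues 953–979;
  IGF1R: 937–959), minimum-image corrected in the membrane plane. A
  frame is **dimerized** when d_HH ≤ 1.3 nm (inclusive).
- **Tilt angle** θ = arccos |**u**ᵢ·**n**| ∈ [0°, 90°] (IR tilt span
  957–979; IGF1R 937–959).
- **Crossing angle** Ω = arccos |**u**₁·**u**₂| ∈ [0°, 90°] (unsigned;
  handedness is not resolved).
- **Kink angle**: angle between sub-axes fitted on either side of a
  pivot residue (IR: G960/P961 region, pivot 960; IGF1R: P941).
- **Crossing point**: the residue whose backbone bead lies nearest the
  mutual closest approach of the two axis lines.
- **Free-energy profiles** by Boltzmann inversion of an angle histogram,
  U = −k_B T ln P(θ), min-shifted to zero, with k_B T(300 K) = 0.5961
  kcal/mol; replicate profiles are averaged after inversion.
- **RMSF** per residue after Kabsch superposition onto the trajectory
  mean structure.
- **Buried surface area** BSA = SASA(A) + SASA(B) − SASA(A∪B) with
  Shrake–Rupley quadrature on probe-expanded beads (probe 0.185 nm,
  960 points/bead by default).
- **Clustering** of dimerized frames with the GROMOS (Daura)
  neighbour-counting algorithm on pairwise Kabsch RMSDs (default cutoff
  0.9 nm), and a rule-based **packing-mode classifier**
  (X / V / parallel) operating on (Ω, d_HH, kink).

## Worked example

Build a standard starting system (two IR TMD helices 3.5 nm apart,
tilted 45°), generate an associating BD trajectory, and analyze it:

```r
library(tmdimer)

b  <- build_initial_system(system_spec("IR", "O2"))
print(b$topology)
#> Bead topology: 98 beads, chains A+B
#>   chain A: residues 940-988 (49 beads)
#>   chain B: residues 940-988 (49 beads)

tr <- simulate_bd(b$topology, b$frame,
                  bd_params(seed = 11, n_steps = 20000, save_interval = 100))
print(tr)
#> Trajectory: 2000 frames x 98 beads, t = 100..200000 ps

g  <- pair_geometry(tr)                       # d_HH, tilt, crossing, kinks
st <- detect_dimerization(g$dhh, times = g$time)
print(st)
#> State series: 2000 frames, 92.4% dimerized, first passage frame 123

cl <- cluster_dimer_states(tr, st, cutoff = 0.35, stride = 4, geometry = g)
print(cl$clusters)
#> Daura clustering at 0.35 nm: 4 clusters over 462 frames
#>   C1: 98.3% (center frame 25)
#>   ...

pmf <- pmf_with_replicates(list(c(g$theta1, g$theta2)), "theta")
summary(pmf)$minimum
#> [1] 31.25
```

Reading the output: the helices diffuse, meet, and first cross the
1.3 nm dimer criterion at frame 123 (12.3 ns); the dimer then persists
(92.4% of all frames dimerized). Nearly all dimerized frames fall into
one structural cluster, as expected for a generator holding a single
packing basin, and the tilt free-energy profile has its minimum at
31.25° — within one 2.5° bin of the 30° tilt preference imposed on the
generator. (The 0.35 nm cluster cutoff matches the synthetic fixture's
structural diversity; for real CG ensembles the conventional 0.9 nm
default applies.)

A command-line front end with the same functionality is installed at
`inst/scripts/tmdimer` (subcommands `build`, `simulate`, `fixtures`,
`geometry`, `states`, `pmf`, `rmsf`, `cluster`, `contacts`, `bsa`,
`classify`, `run`).

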