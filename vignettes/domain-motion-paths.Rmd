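---
title: "Smoothest activation paths on pose-grid energy landscapes"
author: "domainpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Smoothest activation paths on pose-grid energy landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(domainpath)
```

## The problem

Multi-domain signaling proteins such as the Janus kinases are regulated
by large rigid-body rearrangements: in the autoinhibited state the
catalytic tyrosine-kinase (TK) domain is locked in a cavity formed by
the FERM, SH2 and pseudokinase (PK) domains, and activation requires the
TK domain to detach and swing around the PK domain to a new binding
site.  Simulating that transition atomistically is out of reach for
routine work, but because the mobile domain moves essentially as a rigid
body, the transition can be coarse-grained to two coordinates: a radial
*separation* of the mobile domain from its anchor and an in-plane
*rotation* about the anchor.  `domainpath` implements this
coarse-graining end to end:

1. **posegrid** — build the rotation plane from three mass centers and
   generate every (rotation, separation) pose of the mobile domain;
2. **landscape** — attach a total energy to every pose, imported from an
   external engine or synthesized;
3. **pathfinder** — find the energetically *smoothest* activation path
   across that grid with a minimum-variance reformulation of Dijkstra's
   algorithm;
4. **structio** — the accompanying trajectory statistics (RMSD, RMSF,
   hydrogen-bond occupancy) used to characterize the end states.

## Geometry of the pose grid

Let `O` be the anchor domain's mass center, `A` the mobile domain's mass
center in the inhibited state and `C` its mass center in the activated
state.  These three points define the motion plane.  The orthonormal
frame is `u = (A-O)/|A-O|`, `v` the in-plane direction orthogonal to `u`
with a positive component toward `C`, and the normal `n = u × v`.  A
pose with separation `s` and rotation `θ` translates the mobile domain
by `s·u` and then rotates it rigidly about the axis through `O` along
`n`, so position and orientation co-rotate and the same face keeps
pointing at the anchor.  The mobile mass center therefore lands at

```
O + (|OA| + s) · (cos θ · u + sin θ · v)        (the "radius law")
```

which the test suite verifies to 1e-6 Å for all poses.  Separation is a
*center* displacement measured from the inhibited position: this is the
only convention under which an equal-radii construction (`|OB| = |OC|`
after the initial separation) makes the final rotation land the mobile
center exactly on `C`, which the tests also verify.

The default grid is separations 9–25 Å in 1 Å steps (17 columns) by
rotations 0°–145° in 5° steps (30 rows), i.e. 510 poses and a 30×17
energy matrix.  Grid indices are 1-based, row 1 = 0°, column 1 = 9 Å.
Poses are generated from the fixed inhibited reference; per-pose energy
minimization belongs to an external molecular-mechanics engine, whose
minimized energies can be imported with `read_energy_matrix()`.

```{r geometry}
s <- toy_two_domain_structure(seed = 1)
C <- toy_activated_center(s, separation = 9, angle = 145)
man <- generate_pose_grid(s, "anchor", "mobile", C)
nrow(man)
attr(man, "frame")
```

## Energy matrices

The matrix rows follow rotation, columns separation; units are kcal/mol
throughout.  Heatmaps are conventionally drawn relative to the
inhibited-state energy (`relative_energies()`), which changes no path:
every path-related quantity in the package is invariant under a global
energy shift, and the suite tests that.

Two sources of energies ship with the package:

* `simple_nonbonded_score()` — a screened-Coulomb (`k·q_i·q_j/(ε·r)`,
  `k = 332.06 kcal·Å/(mol·e²)`, default `ε = 80`) plus 12-6
  Lennard-Jones inter-domain sum.  It exists so the whole pipeline runs
  at desk scale; its *absolute* values are not physical energies and are
  documented as such.  Anything quantitative should import externally
  minimized energies instead.
* `synthetic_landscape()` — a parametric generator described next.

Masked (non-finite) grid values mark infeasible poses; the solver treats
them as untraversable rather than interpolating, because interpolation
would invent physics.

## The synthetic landscape generator

The generator emulates the robust, qualitative features of a kinase
activation map: a smooth basin tilting downward along rotation (the
activated end below the inhibited end, so activation is
thermodynamically downhill) plus a rotational barrier ridge at
intermediate rotations whose amplitude decays with separation.  The
defaults are fixed study conditions, chosen once:

| parameter | default | units | rationale |
|---|---|---|---|
| `rows`, `cols` | 30, 17 | – | the canonical 0–145° × 9–25 Å grid |
| `basin_slope` | 1 | kcal/mol/row | net drop of 29 kcal/mol, activated below inhibited |
| `barrier_height` | 20 | kcal/mol | a barrier far above thermal scale but small against the net drop |
| `barrier_rows` | 13:16 | – | 60°–75° at 5°/row: a mid-rotation barrier |
| `barrier_decay_col` | 12 | – | 20 Å: beyond this separation the barrier is undetectable |
| `noise_sd` | 0 | kcal/mol | the idealized landscape; roughness is an explicit knob |

The ridge has a Gaussian row profile (sd = half the span of
`barrier_rows`) and decays exponentially with column, reaching 1% of
`barrier_height` at `barrier_decay_col` and **exactly zero beyond it**.
The clamp is a deliberate design decision, not a numerical shortcut: if
the ridge kept a strictly positive tail at every separation, ever-larger
separation would always be marginally favorable and the optimal path
would keep drifting outward *through* the barrier rows, which is not the
behavior the generator is meant to emulate — a real barrier genuinely
vanishes once the domains are far enough apart, and only then can a path
bypass it by separating first.  For the same reason the default is
noise-free: i.i.d. roughness makes the ridge-free columns statistically
exchangeable, so the position of the path's maximum separation becomes a
noise artifact rather than a property of the landscape.  With the
defaults the smoothest path shows the signature behavior
deterministically: it separates to its maximum distance *before* the
barrier rows, crosses in the ridge-free zone and re-approaches.

```{r wt-path}
wt <- synthetic_landscape()
p <- smoothest_path(wt)
p
```

What the generator does **not** emulate: any separation-dependent
attraction (its basin is column-independent, so separating costs
nothing), correlated roughness, steric clashes, or the per-pose
minimization of a real protocol.  Passing tests on it therefore
demonstrate the *solver's* correctness and the geometric construction,
not the energetics of any real protein.

Three presets (`preset_landscape()`) sketch regulatory regimes seen in
kinase mutants: `"wt"`, `"stair"` (raised inhibited-state energy, a
narrower barrier that can be skirted gradually — gain-of-function-like)
and `"locked"` (a barrier persisting to large separation with a
stabilized inhibited state — loss-of-function-like).  They differ only
in barrier/offset parameters, which are recorded in the matrix file
header.

## The smoothest path

A path starts at (row 1, column 1) — the inhibited pose after the
initial separation — and ends at (row 30, column 1), advancing one
rotation row per step while the separation column changes by −2…+3
(clipped at the edges).  Every feasible path therefore has exactly 29
steps, and the sum of its per-step energy changes telescopes to
`E_goal − E_start` regardless of route, so *total* energy consumption
cannot rank paths.  The smoothest path instead minimizes the sample
variance of the step changes

```
σ² = Σ_i (ΔE_i − ΔĒ)² / (n − 1),      ΔĒ = (E_goal − E_start)/n,  n = 29.
```

Because the endpoints fix `ΔĒ`, the variance decomposes into a sum of
per-edge costs `(ΔE_i − ΔĒ)²`, which restores the recursive structure a
shortest-path algorithm needs.  Equivalently, minimizing `Σ ΔE_i²`
selects the same paths — the two objectives differ by the
path-independent constant `n·ΔĒ²` — and the suite checks that
equivalence on random grids.  Minimizing squared deviations also
penalizes barriers: a route that climbs and descends an extra barrier
strictly increases `Σ ΔE_i²`, so among candidate routes the solver
always prefers the one with no barrier or the lowest barrier.

Two exact solvers are implemented and cross-checked: label-setting
(Dijkstra) and, because rotation strictly increases (a layered DAG),
layer-by-layer dynamic programming.  Ties in cumulative weight are
broken deterministically — smaller per-step |column change|, then
smaller predecessor column — and weight comparisons use exact double
arithmetic with no epsilon, so results are reproducible across
platforms.  An exhaustive enumeration oracle (`brute_force_smoothest()`,
capped at 10 rotation rows) provides the independent ground truth; the
suite checks exact agreement on hundreds of seeded random grids.

Reported per path: σ² (the smoothness), the mean step, `Σ ΔE_i²`, the
total climb `Σ max(ΔE_i, 0)` (the cumulative barrier) and the maximum
barrier `max_i E_i − E_start`.

## Structural statistics

* **RMSD** — `rmsd(x, ref, superpose, weights)` computes the weighted
  root-mean-square deviation; with `superpose = TRUE` a weighted
  least-squares rigid fit (Kabsch, via SVD with a determinant guard
  against reflections) is applied first, so pure rigid-body motions give
  exactly zero.  The independent cross-check in the tests is bio3d's
  fitting route.
* **RMSF** — per-atom fluctuation about the *time-average* position,
  `sqrt(mean_t |r_i(t) − r̄_i|²)`, i.e. with squared deviations under
  the root: the variant without the square is dimensionally inconsistent
  (Å^1/2) and is not implemented.  No superposition is applied
  internally; align frames first if needed.
* **Hydrogen-bond occupancy** — a donor–acceptor pair is bonded in a
  frame when the donor–acceptor distance is ≤ 3.5 Å and the
  donor–H···acceptor arrangement deviates from linearity by ≤ 20°
  (both configurable; the angle is measured at the hydrogen, taking the
  most favorable attached hydrogen).  Hydrogens are assigned to donors
  by covalent distance (< 1.2 Å) in the first frame; heavy atoms
  without one are not donors.  Pair occupancy is the percentage of
  frames bonded; residue-pair occupancy sums the atom pairs the two
  residues contribute; per-residue occupancy sums over all partners on
  either side and is deliberately allowed to exceed 100% — a residue
  holding two persistent partners scores 200%.  Same-residue pairs are
  excluded.  The analysis is stride-agnostic: occupancies are
  percentages of whatever frames are supplied.

## Numerical choices and degenerate inputs

* Frame construction rejects coincident or collinear mass centers
  (triangle area ≤ 1e-6 Å²); basis orthonormality is tested to 1e-9.
* Rigidity and the radius law are asserted to 1e-6 Å; pure-geometry
  identities (landing on `C`) hold to ~1e-14 in practice.
* The measured inhibited→activated angle is compared with the
  configured grid extent; a discrepancy > 5° logs a warning but the
  grid uses the configured extent.
* Atom pairs closer than 1e-3 Å make the non-bonded scorer fail loudly
  (overlap) rather than return a huge number.
* Matrix files store full `%.17g` precision, so write→read round-trips
  are bit-exact; ragged rows and non-numeric cells are rejected with row
  and column coordinates.
* Unknown element symbols fall back to the mass of carbon with a
  warning; structures with insertion codes are rejected because
  range-based domain partitions would be ambiguous.

## Problem sizes in the test suite

The suite runs the full 510-pose geometry checks, the solver-vs-oracle
comparison on 260 seeded random grids of 3–6 rotation rows, 75 full
30×17 solver runs (Dijkstra vs DP), the objective-equivalence check on
130 random grids and a 100-matrix lossless I/O property — about 15
seconds total.  These sizes were chosen to give overwhelming coverage of
the discrete structures involved (every edge case of the movement rule
occurs many times) while staying instant for interactive use.

## Limitations

* Motion is restricted to the plane of the three mass centers: no
  out-of-plane excursions, no internal flexibility of the mobile domain,
  no clash relaxation.
* The built-in scorer is a stand-in; conclusions about a real system
  require imported energies from a proper engine.
* The path model fixes endpoints at the first separation column and one
  row per rotation step; it does not enumerate alternative endpoint
  conventions or k-best paths (the oracle exists only as a correctness
  check at small sizes).
* Trajectory statistics assume identical atom ordering across frames;
  no binary trajectory formats are read (multi-model PDB only).
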