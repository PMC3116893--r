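---
title: "Methods: elastic-network modes, ensemble statistics and free-energy bookkeeping"
author: "modescope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: elastic-network modes, ensemble statistics and free-energy bookkeeping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modescope)
```

modescope analyzes protein conformational ensembles the way one studies
an auto-inhibited kinase: which collective motions a conformation
permits, whether a simulated ensemble has converged, which inter-region
contacts persist, how free-energy differences propagate, and whether
displacing a region opens surface pockets toward a functional site.
This vignette is the package's account of the underlying models, the
parameters that matter, the numerical choices, and what the synthetic
test bed does and does not establish.

## The elastic network and its normal modes

`build_hessian()` constructs the standard anisotropic elastic network:
every atom pair within a distance cutoff (default **12 Å**) is joined by
a spring of uniform force constant γ (default **1**, arbitrary units).
For a pair at separation vector **d** the off-diagonal 3×3 block is
`−γ ddᵀ/|d|²`; diagonal blocks accumulate the negatives, so every 3×3
super-row sums to zero and rigid translations cost nothing. Optional
mass weighting applies `M^{-1/2} H M^{-1/2}`. The harmonic-network
assumption replaces an all-atom force-field Hessian; it preserves the
*definitions* of every downstream statistic while being parameter-free
and fast, at the price of physical frequencies — `compute_modes()`
therefore reports frequencies as √eigenvalue in relative units, and a
low-frequency selection criterion is honored as "the *n* lowest
non-zero modes" (default **97**).

Degeneracy is handled explicitly: eigenvalues below `1e-8 ×` the
largest are counted as zero modes; exactly six are expected for a
non-collinear structure, and any surplus (collinear or fragmented
geometry) raises a warning rather than being silently absorbed.
An atom with no neighbor inside the cutoff is reported by index; a
fully disconnected network is an error.

### Per-mode statistics

For mode *l*, the per-atom squared amplitude is
`u_i² = a_xi² + a_yi² + a_zi²`. Two statistics summarize it over a
named region:

* **Degree of collectivity** `k = (1/n) exp(−Σ u_i² ln u_i²)` with
  `0·ln 0 := 0`. With the squared amplitudes renormalized to sum to 1
  over the analysis subset (the default, `renormalize = TRUE`), the
  bounds `1/n ≤ k ≤ 1` hold *exactly*: a single moving atom gives
  `1/n`, uniform motion gives 1. Whether the normalization should run
  over the subset or the whole structure is a genuinely open
  convention; the subset choice was adopted because it makes the
  stated bounds exact for subset analyses, and the whole-structure
  alternative remains available via `renormalize = FALSE`. A mode with
  zero amplitude on the subset has no defined collectivity and is
  reported as `NA`, never as 0.

* **Fragment resultant displacement**, the norm of the vector sum of
  the mode's (x, y, z) components over a fragment: large when the
  fragment translates coherently, exactly zero for antisymmetric
  motion. Raw norms are divided by the maximum over a *pooled* mode
  ensemble (e.g. 97 modes from each of several conformations), so the
  pooled maximum is 1.00 and ranks are dense; ties break toward the
  earlier pool entry and lower mode index, keeping rank 1 unique. Max
  normalization was chosen over mass weighting or per-atom averaging
  because it reproduces a 0–1 range with interpretable ranks without
  extra conventions; an all-zero pool leaves the normalized column
  `NA`.

### Mode-following displacement

`displace_along_mode()` generates conformers `x₀ + a·v` on an amplitude
grid (default **−4 … 4 Å, step 0.1 Å** — 81 conformers). The direction
is un-mass-weighted if needed and scaled so that the all-atom RMSD from
the origin equals |a| *exactly*; this linear-extrapolation-with-RMSD
convention replaces restrained-minimization mode following, which would
require a force field. The contract is exactly testable; the price is
that large-amplitude conformers are not energy-relaxed and can contain
distorted local geometry.

## Ensemble statistics

Superposition is Kabsch via SVD with the determinant correction, so
reflections are never returned; fewer than 3 atoms or collinear input
is an error. Average structures are computed by a **fixed two-pass**
fit→average→refit iteration — enough for visual convergence on
harmonic-like ensembles while keeping every result deterministic.

`trajectory_pca()` diagonalizes the positional covariance (population
normalization) of fitted coordinates; eigenvalue sums equal the total
fitted variance to 1e-9 relative, tiny negative eigenvalues are clipped
to zero, and a constant trajectory returns all-zero eigenvalues with
the cumulative-variance vector defined as 1. `n_modes_for_variance()`
defaults to the 90% criterion. Subspace agreement uses RMSIP.

The convergence analysis follows the ensemble-splitting idea: per seed,
pick a random not-yet-covered frame as a reference until every frame is
within the RMSD cutoff *r* of some reference; assign each frame to its
*nearest* reference (nearest, not first-within-*r*, because the
clustering step needs a deterministic tie rule); split the trajectory
into halves by frame index (odd counts give the extra frame to the
first half); a reference with an empty group in either half is a *lone
reference*. Frames outside all references cannot occur — picking
continues until covered, which resolves an ambiguity in two-step
descriptions of the method. Five seeds (default `1:5`) guard against
an unlucky picking order. On synthetic two-state ensembles the verdict
is sharp: blocked layouts produce lone references on every seed,
shuffled layouts none.

## Contacts, occupancy and surface area

H-bond criteria default to `H···A ≤ 2.5 Å`, `D···A ≤ 3.5 Å`,
`∠DHA ≥ 120°` — standard HBPLUS-compatible ranges; the literature the
pipeline descends from cites geometric criteria without printing
values, so all three are configurable. Donors are N/O with an attached
H (≤ 1.25 Å), acceptors are N/O, same-residue pairs are excluded.
Structures without hydrogens fall back to a D–A distance plus
90°-cone heuristic on the donor's bonded neighbors, with a logged
notice and unordered-pair deduplication (directionality is unknowable
without H). Hydrophobic contacts are apolar heavy-atom pairs
(C/S; the backbone carbonyl C is excluded by name since it is bonded
to O) within **4.5 Å** across different residues.

Occupancy maps count, per residue pair, the fraction of *productive*
frames (times strictly after the relaxation period) with at least one
qualifying event; pairs below the **0.15** display threshold are
dropped. `productive_time()` does the companion bookkeeping: two 50-ns
replicas minus a 2-ns relaxation each pool to 96 ns.

SASA is Shrake–Rupley quadrature: **960** golden-spiral points per
atom on the probe-expanded sphere (probe **1.5 Å**), giving ~1%
quadrature error on an isolated sphere. Note that quadrature SASA is
local-occlusion only: an atom inside a large empty cavity counts as
accessible unless the cavity is narrower than twice the expanded
radius.

## Free-energy bookkeeping and errors

The package consumes per-frame component tables (internal,
electrostatic, van der Waals, generalized-Born polar and surface-area
nonpolar terms, plus translational/rotational/vibrational entropies) —
it never evaluates those energies itself, since they are the outputs of
end-point free-energy codes. The identities
`E_gas = E_int + E_ele + E_vdw`, `H = E_gas + G_gb + G_sa`,
`G = H − TS` hold row-wise by construction. Entropy columns may be
sparse (vibrational entropies are typically evaluated on a frame
subset): they are averaged over their own frame grid, and when the
grids differ the G error combines the H and TS errors in quadrature
rather than pretending a per-frame G series exists.

Errors on time-series means use the Straatsma form
`err² = (var/T)(1 + 2 Σ ρ_k)`. The autocorrelation sum must be
truncated somewhere; the initial-positive-sequence rule (stop at the
first non-positive ordinate) was chosen because it is standard,
parameter-free, and testable: on stationary AR(1) series the estimator
lands within a few percent of the closed form
`(σ/√T)·√((1+φ)/(1−φ))`, and in the i.i.d. limit it reduces to sd/√T.
The truncated sum is reported as the correlation length τ in frames.
A constant series has error 0 and τ 0 — a result, not a failure.

Binding cycles (`binding_cycle()`) compute
`ΔG_bind = G_complex − G_receptor − G_ligand` per form and the
mutational difference `ΔΔG = ΔG_bind^mut − ΔG_bind^wt`, with ΔΔH
decomposing exactly into gas + polar + nonpolar parts. Sign
convention: more negative G is more stable, and ΔΔG < 0 means the
ligand is more tightly bound in the wild-type. Single-point legs are
accepted and carry zero error.

## Pockets

Detection is grid/buriedness scanning rather than alpha-sphere
clustering: self-contained, no external binary, and adequate for the
qualitative question asked of it (does a cavity exist, where, roughly
how big). A lattice (spacing **0.8 Å**) covers the padded bounding
box; points inside any vdW+probe sphere (probe **1.4 Å**) are protein;
a solvent point is kept when enclosed by protein on both sides along
at least **5 of 7** scan axes (x, y, z, four space diagonals); kept
points cluster by 26-connectivity and clusters under **30** points are
dropped. Volume is point count × spacing³. Both strictness parameters
are monotone by construction: raising `burial_min` never adds volume,
raising `min_points` never adds pockets. Detection is exactly
invariant under 90° lattice rotations up to the lattice-origin shift
(a few cells of volume) and stable within a few percent under
arbitrary rotation of a smooth cavity.

Pocket adjacency links pockets whose point sets approach within a
merge distance (default **2 × spacing**); `pocket_path()` labels
pockets by contact (< **4.5 Å**) with user-supplied site and start
selections and reports whether one connected component touches both.
The two-chamber test fixture is a sealed shell with a one-atom-thick
internal wall: probe expansion on both wall faces separates the two
interior clusters by roughly twice the expanded carbon radius (~6 Å),
so the path test passes an explicit `merge_dist = 7` derived from that
construction — the default merge distance is deliberately too strict
to jump a solid wall, and the test also asserts that it does *not*
connect the chambers.

## The synthetic test bed

Generators are pure functions of (parameters, seed); the package never
reads data it did not create during tests.

* `make_toy_chain()`: pseudo-helical Cα chains with the canonical
  3.8 Å spacing (±0.01 Å seeded jitter), the geometry substrate for
  network models.
* `make_ideal_helix()`: N/H/CA/C/O backbones from standard internal
  coordinates (φ = −57°, ψ = −47°), which place O(i)···H–N(i+4) in
  hydrogen-bonding geometry — the H-bond detector's ground truth. (The
  O(i)–N(i+1) pair is a covalent 1,3 contact at ~2.25 Å in *any*
  conformation; the discriminating fact is that its H points away, so
  the angle criterion rejects it.)
* `sample_enm_ensemble()`: Gaussian frames with the analytic
  covariance `scale × H⁺` (rigid modes excluded so superposition is
  not confounded with internal motion). Sampling the stationary
  distribution directly, instead of integrating dynamics, is what
  makes PCA and fluctuation oracles exact.
* `make_two_state_trajectory()`: blocked vs shuffled layouts emulate
  unconverged vs well-mixed ensembles with controllable separation.
* `make_ar1_series()`: the error estimator's exact oracle, with
  `ar1_true_se()` as the closed form.
* `make_cavity_structure()` / `make_double_cavity_structure()`:
  spherical shells with a known center, mouth aperture, or internal
  dividing wall — construction-truth for the pocket detector.

Problem sizes used by the tests are deliberate: 100-residue chains and
97-mode sets for the pooled-metric bookkeeping (four conformations ×
97 modes = 388 values), 5000-frame ensembles for covariance/PCA/tensor
recovery, series of 10⁵ for the error-model checks — sizes at which
the law-of-large-numbers tolerances (15% on covariance, 0.9 RMSIP,
10–20% on standard errors) have comfortable margins on one CPU.

One amplitude choice deserves its rationale: the PCA-recovery
experiments sample with `scale = λ₁`, putting the softest mode's RMS
amplitude at 1 Å — the scale of real backbone fluctuations. Harmonic
sampling is defined in Cartesian mode coordinates, so amplitudes far
beyond this (several Å on a 20-residue chain) are geometrically
nonlinear: per-frame superposition then mixes rigid-body response into
the apparent internal motion and degrades subspace recovery. That
degradation is a property of linear mode extrapolation, not of the PCA
implementation.

What passing these tests does **not** show: that a harmonic network
reproduces force-field modes of a real kinase, that Gaussian ensembles
capture anharmonic or multi-basin MD behavior, that the geometric
H-bond thresholds match any particular assignment program, or that
grid pockets coincide with alpha-sphere pockets on real surfaces. The
synthetic bed validates the *statistics and bookkeeping*; scientific
claims about a real system still require real ensembles.

## Known limitations

* PDB only (via bio3d for reading); mmCIF and binary trajectory
  formats (DCD/XTC) are documented extension points, not features.
  Insertion codes are rejected; alternate locations keep the
  highest-occupancy copy (first on ties).
* Residue numbering is author-assigned, 1-based, closed intervals —
  matching kinase-domain conventions (KIT 547–935) — and `write_structure()`
  refuses residue numbers above 9999 rather than emitting hybrid-36.
* Mode displacement does no energy relaxation; extreme-amplitude
  conformers are geometric extrapolations.
* The fallback H-bond heuristic without hydrogens is deliberately
  permissive; protonate structures for serious contact analysis.
* Elements are inferred from atom names when the PDB element column is
  absent; exotic hetero-atoms default to carbon-like radii.
* `vdw` radii, masses and the apolar flag come from a small bundled
  element table, not a force field.
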