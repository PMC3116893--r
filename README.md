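# modescope

Elastic-network normal modes, ensemble statistics and free-energy
bookkeeping for protein conformational analysis, built around the
cytoplasmic region of the receptor tyrosine kinase KIT (residues
547–935), whose auto-inhibitory juxta-membrane region (JMR) and
activation loop are the canonical use case for every selection default
in the package.

It is aimed at structural bioinformaticians who have conformational
ensembles (MD-style multi-model PDB trajectories) and per-frame
MM-GBSA-style energy tables, and who want the analysis layer on top:
which collective motions a conformation allows, whether an ensemble has
converged, which inter-region contacts persist, and how free-energy
differences propagate through a binding cycle — all with statistics
whose error bars respect time correlation.

## What it computes

**Elastic-network normal modes.** An anisotropic network (uniform
springs γ between atoms within a cutoff, default 12 Å) is diagonalized;
the six rigid-body modes are discarded and the *n* lowest non-zero modes
retained (default 97). Per mode *l* with per-atom squared amplitudes
`u_i² = a_xi² + a_yi² + a_zi²` (renormalized over an atom subset of size
*n*):

- degree of collectivity `k_l = (1/n) · exp(−Σ_i u_i² ln u_i²)`,
  ranging from 1/n (one atom carries the motion) to 1 (all atoms move
  equally);
- fragment resultant displacement `d_F = ‖Σ_{i∈M} (a_xi, a_yi, a_zi)‖`
  over a fragment *M*, normalized by the maximum over a pooled mode
  ensemble and ranked within the pool;
- mode-following conformer generation: coordinates `x₀ + a·v` on an
  amplitude grid (default −4…4 Å, step 0.1 Å) with *v* scaled so the
  all-atom RMSD from the origin equals |a| exactly.

**Ensemble statistics.** Kabsch superposition (proper rotations only),
per-frame RMSD series, anisotropic per-atom fluctuation tensors,
quasi-harmonic PCA of the fitted coordinate covariance with
eigenvector-overlap and RMSIP subspace comparison, and the
reference-structure convergence analysis: random reference picking under
an RMSD cutoff *r*, nearest-reference clustering, and counting *lone
references* — references unrepresented in one half of the trajectory —
across five random seeds.

**Interactions.** Geometric H-bond detection (H···A ≤ 2.5 Å,
D···A ≤ 3.5 Å, ∠DHA ≥ 120°, configurable), apolar-pair hydrophobic
contacts (≤ 4.5 Å), residue-pair occupancy maps over productive frames
with the 15% display threshold, and Shrake–Rupley solvent accessible
surface areas (probe 1.5 Å).

**Free-energy bookkeeping.** From per-frame component tables:
`E_gas = E_int + E_ele + E_vdw`, `H = E_gas + G_gb + G_sa`,
`G = H − TS`; time-series means carry Straatsma errors
`err² = (var/T)(1 + 2Σ_k ρ_k)` with the autocorrelation sum truncated at
its first non-positive ordinate; stability differences and binding
thermodynamic cycles (ΔG_bind = G_complex − G_receptor − G_ligand;
ΔΔG = ΔG_bind^mut − ΔG_bind^wt) propagate errors in quadrature.

**Pockets.** Grid/buriedness (LIGSITE-style) cavity detection with
7-axis scanning and 26-connectivity clustering, plus "path-of-pockets"
queries: does a connected chain of adjacent pockets link a start region
to a declared catalytic/substrate site?

**Synthetic ground truth.** Generators for pseudo-helical Cα chains,
ideal α-helical backbones, Gaussian ensembles with the analytic
elastic-network covariance, blocked/shuffled two-state trajectories,
stationary AR(1) energy series with closed-form standard errors, and
cavity shells with known centers — every analysis stage is tested
against constructions whose truth is known exactly.

## Worked example

```r
library(modescope)

chain <- make_toy_chain(60, seed = 1)
modes <- compute_modes(build_hessian(chain, cutoff = 12), n_modes = 20)
#> mode_set: 20 modes over 60 atoms (6 zero modes discarded)

k  <- collectivity(modes, subset = 41:60)
fd <- fragment_displacement(modes, fragment = 41:60)
head(data.frame(mode = 1:20, eigenvalue = round(modes$eigenvalues, 4),
                k = round(k, 3), d_norm = round(fd$d_norm, 3)), 5)
#>   mode eigenvalue     k d_norm
#> 1    1     0.0003 0.533  0.455
#> 2    2     0.0003 0.536  0.454
#> 3    3     0.0021 0.709  0.146
#> 4    4     0.0021 0.716  0.147
#> 5    5     0.0037 0.936  0.056
```

The two softest (near-degenerate bending) modes move the terminal
fragment most coherently (`d_norm` ≈ 0.45) at moderate collectivity,
while mode 5 spreads its amplitude over nearly all fragment atoms
(`k` = 0.94) without net displacement — the two statistics separate
"moves far" from "moves together".

```r
ens <- sample_enm_ensemble(chain, modes, scale = modes$eigenvalues[1],
                           n_frames = 500, seed = 2)
pc <- trajectory_pca(ens)
#> trajectory_pca: 180 modes, total variance 2.616 A^2, 4 modes reach 90%
rmsip(pc$eigenvectors, modes$vectors[, 1:5], 5)
#> [1] 0.998

as.data.frame(convergence_analysis(ens, cutoff = 1.5))
#>   seed n_references n_lone_references
#> 1    1            1                 0
#> ...
```

PCA recovers the generating mode subspace (RMSIP 0.998), and the
single-basin ensemble is declared converged (one reference, no lone
references) for all five seeds.

```r
x <- make_ar1_series(mean = -120, sigma = 4, phi = 0.8, n = 2400, seed = 3)
estimate_with_error(x)
#> -120.0830 +/- 0.2129 (n = 2400, tau = 3.10 frames)
ar1_true_se(4, 0.8, 2400)
#> [1] 0.2449
```

The Straatsma error (±0.21 kcal/mol) is 2.6× the naive sd/√n and close
to the closed-form AR(1) value; a naive error bar here would be badly
overconfident.

```r
cav <- make_cavity_structure(shell_radius = 8, aperture_deg = 40,
                             n_atoms = 200, seed = 1)
detect_pockets(cav)
#> pocket_set: 1 pocket(s), spacing 0.80 A
#>   #1: 1042 points, 533.5 A^3, centroid (-0.0, -0.0, 0.2)
```

The detector finds the constructed cavity with its centroid 0.2 Å from
the true center.

A full multi-stage run (`run_pipeline()`, or
`inst/scripts/run_pipeline.R` from a shell) writes per-stage TSV/PDB
outputs plus a `manifest.txt` that pins the resolved configuration,
package version and output checksums.

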