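# Shared fixtures and independent oracles, built in code at test time.

# random normalized 3N-vector mode matrix (columns unit length)
random_mode_matrix <- function(n_atoms, n_modes, seed = 1L) {
  set.seed(seed)
  V <- matrix(rnorm(3L * n_atoms * n_modes), ncol = n_modes)
  sweep(V, 2L, sqrt(colSums(V^2)), "/")
}

# well-formed random energy table
random_energy_df <- function(n = 40L, seed = 1L, entropy = TRUE) {
  set.seed(seed)
  df <- data.frame(time_ps = seq(20, by = 20, length.out = n),
                   E_int = rnorm(n, 10), E_ele = rnorm(n, -20),
                   E_vdw = rnorm(n, 5), G_gb = rnorm(n, -3),
                   G_sa = rnorm(n, 1))
  if (entropy) {
    df$TS_trans <- rnorm(n, 1); df$TS_rot <- rnorm(n, 1)
    df$TS_vib <- rnorm(n, 2)
  }
  df
}

# brute-force rigid-body RMSD minimization over a coarse-to-fine Euler
# grid (independent oracle for the Kabsch superposition)
brute_force_min_rmsd <- function(mobile, reference, coarse_deg = 15,
                                 refinements = 4L) {
  P <- sweep(mobile, 2L, colMeans(mobile))
  Q <- sweep(reference, 2L, colMeans(reference))
  rot <- function(a, b, g) {
    ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
    cg <- cos(g); sg <- sin(g)
    Rz1 <- matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3L)
    Ry <- matrix(c(cb, 0, -sb, 0, 1, 0, sb, 0, cb), 3L)
    Rz2 <- matrix(c(cg, sg, 0, -sg, cg, 0, 0, 0, 1), 3L)
    Rz1 %*% Ry %*% Rz2
  }
  eval_rmsd <- function(a, b, g) sqrt(mean(rowSums((P %*% rot(a, b, g) - Q)^2)))
  step <- coarse_deg * pi / 180
  ctr <- c(pi, pi / 2, pi)
  span <- c(pi, pi / 2, pi)
  best <- c(0, 0, 0); best_val <- Inf
  for (lev in seq_len(refinements + 1L)) {
    as <- seq(ctr[1] - span[1], ctr[1] + span[1], by = step)
    bs <- seq(ctr[2] - span[2], ctr[2] + span[2], by = step)
    gs <- seq(ctr[3] - span[3], ctr[3] + span[3], by = step)
    for (a in as) for (b in bs) for (g in gs) {
      v <- eval_rmsd(a, b, g)
      if (v < best_val) { best_val <- v; best <- c(a, b, g) }
    }
    ctr <- best
    span <- rep(2 * step, 3L)
    step <- step / 4
  }
  best_val
}

# rigid rotation matrix from an axis-angle (for invariance tests)
rotation_about <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3L)
  diag(3L) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# two structures with identical topology, ~8 A apart after fitting
two_state_pair <- function(n_res = 20L, seed = 5L) {
  A <- make_toy_chain(n_res, seed = seed)
  set.seed(seed + 100L)
  B <- structure_model(A$atoms,
                       A$xyz + matrix(rnorm(3L * n_res, sd = 8), ncol = 3L))
  list(A = A, B = B)
}
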