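test_that("superposition is exact on congruent sets and rejects reflections", {
  ch <- make_toy_chain(12, seed = 1)
  R <- rotation_about(c(1, 2, 3), 1.1)
  moved <- ch$xyz %*% R + matrix(c(5, -3, 2), 12, 3, byrow = TRUE)
  fit <- superpose(moved, ch$xyz)
  expect_lt(fit$rmsd, 1e-9)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # chiral 4-point set: mirror image cannot be superposed
  chiral <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1.3, 0), c(0.2, 0.3, 1.7))
  mirror <- chiral %*% diag(c(-1, 1, 1))
  expect_gt(superpose(mirror, chiral)$rmsd, 0.1)
  expect_error(superpose(chiral[1:2, ], chiral[1:2, ]), "3 atoms")
  coll <- cbind(0:3, 0, 0)
  expect_error(superpose(coll, coll), "collinear")
})

test_that("superposition RMSD matches a rotation-grid brute-force oracle", {
  set.seed(42)
  for (rep in 1:3) {
    P <- matrix(rnorm(15, sd = 2), 5, 3)
    Q <- matrix(rnorm(15, sd = 2), 5, 3)
    expect_equal(superpose(P, Q)$rmsd, brute_force_min_rmsd(P, Q),
                 tolerance = 1e-3)
  }
})

test_that("superposition agrees with an independent reference implementation", {
  set.seed(7)
  P <- matrix(rnorm(30, sd = 3), 10, 3)
  Q <- matrix(rnorm(30, sd = 3), 10, 3)
  ours <- superpose(P, Q)$rmsd
  fitted <- bio3d::fit.xyz(as.vector(t(Q)), as.vector(t(P)),
                           fixed.inds = 1:30, mobile.inds = 1:30)
  ref <- sqrt(mean(colSums(matrix((fitted - as.vector(t(Q)))^2, nrow = 3))))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("RMSD series report fitted deviations with rigid-body invariance", {
  ch <- make_toy_chain(15, seed = 1)
  const <- trajectory(ch, array(ch$xyz, dim = c(15, 3, 4)))
  expect_equal(as.numeric(rmsd_series(const)), rep(0, 4), tolerance = 1e-9)
  st <- two_state_pair(15)
  tb <- make_two_state_trajectory(st$A, st$B, 20, "blocked", jitter = 0,
                                  seed = 1)
  rs <- rmsd_series(tb, reference = st$A$xyz)
  dAB <- superpose(st$B$xyz, st$A$xyz)$rmsd
  expect_equal(as.numeric(rs), rep(c(0, dAB), each = 10), tolerance = 1e-9)
  # rigidly transforming every frame leaves the series unchanged
  R <- rotation_about(c(0, 1, 1), 0.7)
  rot <- tb
  for (f in 1:20) rot$coords[, , f] <- tb$coords[, , f] %*% R + 4
  expect_lt(max(abs(rmsd_series(rot, st$A$xyz) - rs)), 1e-9)
  expect_error(rmsd_series(tb, selection = integer(0)), "empty")
})

test_that("fluctuation tensors recover isotropic jitter and satisfy the trace identity", {
  ch <- make_toy_chain(20, seed = 1)
  const <- trajectory(ch, array(ch$xyz, dim = c(20, 3, 3)))
  ft0 <- fluctuation_tensors(const)
  expect_lt(max(abs(ft0$tensors)), 1e-18)
  set.seed(9)
  nf <- 5000L
  co <- array(rep(ch$xyz, nf) + rnorm(20 * 3 * nf, sd = 0.5),
              dim = c(20, 3, nf))
  tr <- trajectory(ch, co)
  ft <- fluctuation_tensors(tr)
  # interior atoms: ~0.25 I A^2 (superposition absorbs some edge variance)
  for (a in 8:12) {
    expect_equal(diag(ft$tensors[a, , ]), rep(0.25, 3), tolerance = 0.15)
    off <- ft$tensors[a, , ][upper.tri(diag(3))]
    expect_lt(max(abs(off)), 0.25 * 0.15)
  }
  msf_direct <- vapply(seq_len(20), function(a) sum(diag(ft$tensors[a, , ])),
                       numeric(1))
  expect_equal(ft$msf, msf_direct, tolerance = 1e-12)
  expect_error(fluctuation_tensors(trajectory(ch, array(ch$xyz, c(20, 3, 1)))),
               "2 frames")
})

test_that("trajectory PCA recovers a single generating mode and conserves variance", {
  ch <- make_toy_chain(20, seed = 1)
  modes <- compute_modes(build_hessian(ch, cutoff = 10), 54)
  one <- modes
  one$vectors <- modes$vectors[, 1L, drop = FALSE]
  one$eigenvalues <- modes$eigenvalues[1L]
  tr <- sample_enm_ensemble(ch, one, scale = modes$eigenvalues[1L],
                            n_frames = 5000, seed = 13)
  pc <- trajectory_pca(tr)
  expect_gte(abs(sum(pc$eigenvectors[, 1L] * modes$vectors[, 1L])), 0.95)
  expect_equal(n_modes_for_variance(pc, 0.9), 1L)
  # trace identity: eigenvalue sum equals total fitted variance
  expect_equal(sum(pc$eigenvalues), pc$total_variance, tolerance = 1e-9)
  # constant trajectory: all eigenvalues zero
  const <- trajectory(ch, array(ch$xyz, dim = c(20, 3, 3)))
  expect_lt(max(trajectory_pca(const)$eigenvalues), 1e-18)
  # fraction 1.0 requests the covariance rank
  expect_lte(n_modes_for_variance(pc, 1.0), length(pc$eigenvalues))
  expect_error(trajectory_pca(trajectory(ch, array(ch$xyz, c(20, 3, 1)))),
               "2 frames")
})

test_that("PCA subspace recovery reaches RMSIP >= 0.9 for separated generating modes", {
  ch <- make_toy_chain(20, seed = 1)
  modes <- compute_modes(build_hessian(ch, cutoff = 10), 54)
  k <- 3L
  gen <- modes
  gen$vectors <- modes$vectors[, seq_len(k), drop = FALSE]
  gen$eigenvalues <- modes$eigenvalues[seq_len(k)]
  tr <- sample_enm_ensemble(ch, gen, scale = modes$eigenvalues[1L],
                            n_frames = 5000, seed = 17)
  pc <- trajectory_pca(tr)
  expect_gte(rmsip(pc$eigenvectors, modes$vectors[, seq_len(k)], k), 0.9)
})

test_that("convergence analysis flags blocked two-state ensembles and clears shuffled ones", {
  ch <- make_toy_chain(15, seed = 1)
  const <- trajectory(ch, array(ch$xyz, dim = c(15, 3, 8)))
  cr <- convergence_analysis(const, cutoff = 1)
  expect_true(all(cr$n_references == 1L))
  expect_true(all(cr$n_lone_references == 0L))
  st <- two_state_pair(15)
  tb <- make_two_state_trajectory(st$A, st$B, 60, "blocked", jitter = 0.3,
                                  seed = 4)
  ts <- make_two_state_trajectory(st$A, st$B, 60, "shuffled", jitter = 0.3,
                                  seed = 4)
  cutoff <- superpose(st$B$xyz, st$A$xyz)$rmsd / 4
  cb <- convergence_analysis(tb, cutoff = cutoff)
  cs <- convergence_analysis(ts, cutoff = cutoff)
  expect_true(all(cb$n_references >= 2L))
  expect_true(all(cb$n_lone_references == cb$n_references))  # every ref lone
  expect_true(all(cs$n_lone_references == 0L))
  expect_true(all(cs$n_references >= 2L))
  # lone references never exceed references; identical seeds reproduce
  expect_true(all(cb$n_lone_references <= cb$n_references))
  expect_identical(as.data.frame(cb),
                   as.data.frame(convergence_analysis(tb, cutoff = cutoff)))
})
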