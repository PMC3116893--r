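test_that("elastic-network Hessian has the analytic two-body spectrum and zero row sums", {
  pair <- structure_model(
    data.frame(atom_name = "CA", residue_name = "ALA", residue_number = 1:2),
    rbind(c(0, 0, 0), c(5, 0, 0)))
  h <- build_hessian(pair, cutoff = 10, gamma = 1)
  ev <- eigen(h$hessian, symmetric = TRUE)$values
  expect_equal(sum(ev > 1e-10), 1L)            # a single non-zero eigenvalue
  expect_equal(max(ev), 2, tolerance = 1e-12)  # 2 * gamma for a unit spring
  ch <- make_toy_chain(20, seed = 1)
  hc <- build_hessian(ch, cutoff = 10)
  expect_equal(max(abs(hc$hessian - t(hc$hessian))), 0)
  # translation invariance: each 3 x 3 super-row sums to zero
  n <- 20L
  rs <- sapply(seq_len(n), function(i) {
    rows <- (3 * (i - 1) + 1):(3 * i)
    blocks <- sapply(seq_len(n), function(j)
      hc$hessian[rows, (3 * (j - 1) + 1):(3 * j)])
    max(abs(rowSums(matrix(blocks, nrow = 3))))
  })
  expect_lt(max(rs), 1e-12)
  # a stray atom outside everyone's cutoff is reported, not dropped
  stray <- structure_model(
    data.frame(atom_name = "CA", residue_name = "ALA", residue_number = 1:21),
    rbind(ch$xyz, c(500, 500, 500)))
  expect_warning(build_hessian(stray, cutoff = 10), "no neighbor")
  expect_error(build_hessian(pair, cutoff = 1), "disconnected")
})

test_that("mode computation discards exactly the rigid-body modes", {
  ch <- make_toy_chain(20, seed = 1)
  m <- compute_modes(build_hessian(ch, cutoff = 10), 10)
  expect_equal(m$n_zero_modes, 6L)
  ov <- crossprod(m$vectors)
  expect_lt(max(abs(ov - diag(10))), 1e-8)
  expect_true(all(diff(m$eigenvalues) >= 0))
  expect_error(compute_modes(build_hessian(ch, cutoff = 10), 60), "exceeds")
  # 97 lowest non-zero modes on a 200-atom chain
  big <- make_toy_chain(200, seed = 1)
  m97 <- compute_modes(build_hessian(big), 97)
  expect_equal(ncol(m97$vectors), 97L)
  # collinear geometry: extra zero modes reported, not silently dropped
  lin <- structure_model(
    data.frame(atom_name = "CA", residue_name = "ALA", residue_number = 1:3),
    cbind(c(0, 3.8, 7.6), 0, 0))
  expect_warning(compute_modes(build_hessian(lin, cutoff = 10), 2),
                 "degenerate")
})

test_that("collectivity matches its entropy definition, limits and bounds", {
  n <- 10L
  # uniform motion over the subset attains k = 1 exactly
  u <- rep(1 / sqrt(3 * n), 3 * n)
  expect_equal(collectivity(matrix(u, ncol = 1)), 1, tolerance = 1e-12)
  # motion confined to one atom attains k = 1/n exactly
  v <- c(1, rep(0, 3 * n - 1))
  expect_equal(collectivity(matrix(v, ncol = 1)), 1 / n, tolerance = 1e-12)
  # brute-force oracle: re-evaluate the entropy sum term by term
  V <- random_mode_matrix(n, 25, seed = 11)
  k_direct <- apply(V, 2L, function(col) {
    u2 <- rowSums(matrix(col, ncol = 3L, byrow = TRUE)^2)
    u2 <- u2 / sum(u2)
    s <- 0
    for (ui in u2) if (ui > 0) s <- s - ui * log(ui)
    exp(s) / n
  })
  expect_equal(collectivity(V), k_direct, tolerance = 1e-12)
  # bounds over a large random ensemble
  Vbig <- random_mode_matrix(100, 1000, seed = 2)
  k <- collectivity(Vbig)
  expect_true(all(k <= 1 + 1e-12))
  expect_true(all(k >= 1 / 100))
  # invariance to global rescaling of the mode vector
  expect_equal(collectivity(V * 7), collectivity(V), tolerance = 1e-12)
  # zero amplitude on the subset: missing value, not 0
  z <- matrix(c(rep(0, 6), 1, rep(0, 3 * n - 7)), ncol = 1)
  expect_true(is.na(collectivity(z, subset = 1:2)))
})

test_that("fragment resultant displacement sums components and normalizes over the pool", {
  n <- 12L
  frag <- 3:7
  # translation of the fragment along +x by component c: ||sum|| = m * c
  cmp <- 0.2
  v <- numeric(3 * n)
  v[3 * (frag - 1) + 1] <- cmp
  fd <- fragment_displacement(matrix(v, ncol = 1), frag)
  expect_equal(fd$d_raw, length(frag) * cmp, tolerance = 1e-12)
  expect_equal(fd$d_norm, 1)
  # antisymmetric motion cancels exactly (normalization then undefined)
  va <- numeric(3 * n)
  va[3 * (3:4 - 1) + 1] <- 1
  va[3 * (5:6 - 1) + 1] <- -1
  fd0 <- fragment_displacement(matrix(va, ncol = 1), 3:6)
  expect_equal(fd0$d_raw, 0)
  expect_true(is.na(fd0$d_norm))
  # pooled normalization: exactly one rank-1 mode; ties broken by lower index
  A <- random_mode_matrix(n, 5, seed = 1)
  pool <- list(A, A)                       # duplicated ensemble forces ties
  fd1 <- fragment_displacement(pool[[1L]], frag, pool = pool)
  expect_equal(sum(fd1$rank == 1L), 1L)
  expect_equal(max(fd1$d_norm), 1)
  fd_all <- mode_metrics(pool, subset = frag, fragment = frag)
  expect_equal(sum(fd_all$rank_d == 1L), 1L)
  expect_lt(fd_all$set[fd_all$rank_d == 1L], 2L)  # the earlier copy wins
  expect_error(fragment_displacement(A, integer(0)), "empty")
})

test_that("mode overlaps are scalar products with orthonormal completeness", {
  ch <- make_toy_chain(15, seed = 1)
  m <- compute_modes(build_hessian(ch, cutoff = 10), 12)
  self <- mode_overlap(m, m)
  expect_equal(self, diag(12), tolerance = 1e-8, ignore_attr = TRUE)
  # orthogonal complement within the same eigenbasis
  h <- build_hessian(ch, cutoff = 10)
  eg <- eigen(h$hessian, symmetric = TRUE)
  V <- eg$vectors[, rev(seq_len(ncol(eg$vectors)))]
  expect_lt(max(abs(mode_overlap(m, V[, 19:25]))), 1e-8)
  # completeness: overlap rows against a full rotated basis have unit norm
  full <- V[, 7:45]
  expect_equal(rowSums(mode_overlap(m, full)^2), rep(1, 12),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(mode_overlap(m, random_mode_matrix(5, 2)), "mismatch")
})

test_that("mode displacement honors the RMSD-amplitude contract", {
  ch <- make_toy_chain(20, seed = 1)
  m <- compute_modes(build_hessian(ch, cutoff = 10), 10)
  tr <- displace_along_mode(ch, m, 2, c(-2.5, 0, 2.5))
  expect_equal(frame_coords(tr, 2), ch$xyz, ignore_attr = TRUE)
  rms <- sqrt(mean(rowSums((frame_coords(tr, 3) - ch$xyz)^2)))
  expect_equal(rms, 2.5, tolerance = 1e-6)
  # default grid: 81 conformations, +/- pairs equidistant from the origin
  full <- displace_along_mode(ch, m, 1)
  expect_equal(n_frames(full), 81L)
  d_minus <- sqrt(mean(rowSums((frame_coords(full, 1) - ch$xyz)^2)))
  d_plus <- sqrt(mean(rowSums((frame_coords(full, 81) - ch$xyz)^2)))
  expect_equal(d_minus, d_plus, tolerance = 1e-9)
  expect_error(displace_along_mode(ch, m, 1, c(0, NA)), "finite")
})

test_that("zero-mode count and low-frequency collectivity hold across seeds", {
  for (s in 1:5) {
    ch <- make_toy_chain(15L + 3L * s, seed = s)
    n <- nrow(ch$xyz)
    m <- compute_modes(build_hessian(ch, cutoff = 10), 3L * n - 6L)
    expect_equal(m$n_zero_modes, 6L)
    k <- collectivity(m)
    expect_true(all(k > 0 & k <= 1 + 1e-12))
    # the softest internal mode is more collective than the stiffest one
    expect_gt(k[1L], k[length(k)])
  }
})
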