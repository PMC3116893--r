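# Elastic-network normal modes and per-mode statistics.
#
# The network is the standard anisotropic elastic network: identical
# springs (force constant gamma) between every atom pair within a distance
# cutoff. Its Hessian eigenvectors are the normal modes; the six zero
# modes are rigid-body translations/rotations. Per-mode statistics are the
# degree of collectivity (entropy of the per-atom squared amplitudes) and
# the fragment resultant displacement (norm of the vector sum of the
# mode's atomic components over a fragment).

#' Build an anisotropic elastic-network Hessian
#'
#' @param structure `structure_model`.
#' @param selection atom indices to include (default: all atoms).
#' @param cutoff spring distance cutoff in A (default 12).
#' @param gamma uniform spring force constant (default 1, arbitrary units).
#' @param mass_weighted apply `M^(-1/2) H M^(-1/2)` mass weighting.
#' @return `enm_hessian`: the 3N x 3N symmetric matrix plus the geometry it
#'   was built from.
#' @export
build_hessian <- function(structure, selection = NULL, cutoff = 12, gamma = 1,
                          mass_weighted = FALSE) {
  stopifnot(inherits(structure, "structure_model"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(selection)) selection <- seq_len(nrow(structure$xyz))
  xyz <- structure$xyz[selection, , drop = FALSE]
  masses <- structure$atoms$mass[selection]
  n <- nrow(xyz)
  if (n < 2L) stop("need at least 2 atoms")
  d2 <- as.matrix(stats::dist(xyz))^2
  neigh <- d2 <= cutoff^2 & d2 > 0
  deg <- rowSums(neigh)
  if (all(deg == 0)) stop("fully disconnected network: no atom pair within cutoff")
  if (any(deg == 0))
    warning(sprintf("%d atom(s) have no neighbor within %.1f A (indices: %s)",
                    sum(deg == 0), cutoff,
                    paste(which(deg == 0), collapse = ",")))
  H <- matrix(0, 3L * n, 3L * n)
  for (i in seq_len(n - 1L)) {
    js <- which(neigh[i, ] & seq_len(n) > i)
    for (j in js) {
      dv <- xyz[j, ] - xyz[i, ]
      blk <- -gamma * tcrossprod(dv) / sum(dv^2)
      ii <- (3L * (i - 1L) + 1L):(3L * i)
      jj <- (3L * (j - 1L) + 1L):(3L * j)
      H[ii, jj] <- H[ii, jj] + blk
      H[jj, ii] <- H[jj, ii] + blk
      H[ii, ii] <- H[ii, ii] - blk
      H[jj, jj] <- H[jj, jj] - blk
    }
  }
  if (mass_weighted) {
    w <- 1 / sqrt(rep(masses, each = 3L))
    H <- H * tcrossprod(w)
  }
  structure(list(hessian = H, xyz = xyz, masses = masses,
                 selection = selection, cutoff = cutoff, gamma = gamma,
                 mass_weighted = mass_weighted),
            class = "enm_hessian")
}

#' Diagonalize an elastic-network Hessian
#'
#' Discards the near-zero rigid-body modes (six for any non-collinear 3-D
#' structure; more are reported with a warning, never silently dropped)
#' and returns the lowest-eigenvalue internal modes. Frequencies are
#' reported as sqrt(eigenvalue) in relative units; "the n lowest non-zero
#' modes" is the retained set (default 97).
#'
#' @param hess `enm_hessian` from [build_hessian()].
#' @param n_modes number of non-zero modes to keep (default 97; capped at
#'   3N minus the zero modes).
#' @return `mode_set` with orthonormal columns `vectors` (3N x n_modes),
#'   ascending `eigenvalues`, `frequencies`, and bookkeeping fields.
#' @export
compute_modes <- function(hess, n_modes = 97L) {
  stopifnot(inherits(hess, "enm_hessian"))
  eg <- eigen(hess$hessian, symmetric = TRUE)
  ev <- rev(eg$values)
  V <- eg$vectors[, rev(seq_along(ev)), drop = FALSE]
  tol <- 1e-8 * max(ev)
  n_zero <- sum(ev < tol)
  if (n_zero > 6L)
    warning(sprintf("%d near-zero modes found (expected 6): degenerate geometry",
                    n_zero))
  avail <- length(ev) - n_zero
  if (n_modes > avail)
    stop(sprintf("n_modes = %d exceeds the %d available non-zero modes",
                 n_modes, avail))
  keep <- (n_zero + 1L):(n_zero + n_modes)
  structure(list(vectors = V[, keep, drop = FALSE],
                 eigenvalues = ev[keep],
                 frequencies = sqrt(pmax(ev[keep], 0)),
                 n_atoms = length(hess$masses),
                 masses = hess$masses,
                 mass_weighted = hess$mass_weighted,
                 n_zero_modes = n_zero,
                 xyz = hess$xyz),
            class = "mode_set")
}

#' @export
print.mode_set <- function(x, ...) {
  cat(sprintf("mode_set: %d modes over %d atoms (%d zero modes discarded%s)\n",
              ncol(x$vectors), x$n_atoms, x$n_zero_modes,
              if (x$mass_weighted) ", mass-weighted" else ""))
  invisible(x)
}

.mode_matrix <- function(modes) {
  if (inherits(modes, "mode_set")) modes$vectors
  else as.matrix(modes)
}

# per-atom squared amplitudes u_i^2, one column per mode
.atom_sq_amplitudes <- function(V) {
  n <- nrow(V) / 3L
  idx <- rep(seq_len(n), each = 3L)
  rowsum(V^2, idx)
}

#' Degree of collectivity of each mode
#'
#' For mode l with per-atom squared amplitudes u_i^2 over a subset of n
#' atoms, k_l = (1/n) exp(-sum u_i^2 ln u_i^2) with 0 ln 0 := 0. With
#' `renormalize = TRUE` (default) the u_i^2 are renormalized to sum to 1
#' over the subset, so 1/n <= k <= 1 exactly: k = 1/n when a single atom
#' carries all the motion, k = 1 when all atoms move equally.
#'
#' @param modes `mode_set` or a 3N x M matrix of mode vectors.
#' @param subset atom indices (within the mode set's atoms) to evaluate
#'   over; default all atoms.
#' @param renormalize renormalize squared amplitudes over the subset.
#' @return numeric vector, one k per mode; `NA` for a mode with zero
#'   amplitude on the subset.
#' @export
collectivity <- function(modes, subset = NULL, renormalize = TRUE) {
  V <- .mode_matrix(modes)
  u2 <- .atom_sq_amplitudes(V)
  if (!is.null(subset)) u2 <- u2[subset, , drop = FALSE]
  if (nrow(u2) == 0L) stop("empty subset")
  n <- nrow(u2)
  tot <- colSums(u2)
  if (renormalize) u2 <- sweep(u2, 2L, tot, "/")
  h <- -colSums(ifelse(u2 > 0, u2 * log(u2), 0))
  k <- exp(h) / n
  k[tot == 0] <- NA_real_
  k
}

#' Fragment resultant displacement of each mode
#'
#' The raw value is the Euclidean norm of the vector sum of the mode's
#' (x, y, z) atomic components over the fragment: large when the fragment
#' moves coherently in one direction, zero when the motion cancels.
#' Normalized values divide by the maximum over the pooled mode ensemble,
#' so exactly one pooled mode attains 1.0 (ties broken by lower pooled
#' index); ranks are dense within the pool.
#'
#' @param modes `mode_set` or 3N x M matrix.
#' @param fragment atom indices of the fragment.
#' @param pool list of mode sets defining the pooled ensemble for
#'   normalization and ranking; defaults to `list(modes)`.
#' @return data.frame(mode_index, d_raw, d_norm, rank).
#' @export
fragment_displacement <- function(modes, fragment, pool = list(modes)) {
  if (length(fragment) == 0L) stop("empty fragment")
  raw_of <- function(m) {
    V <- .mode_matrix(m)
    n <- nrow(V) / 3L
    if (any(fragment < 1L | fragment > n)) stop("fragment indices out of range")
    rows <- as.vector(rbind(3L * (fragment - 1L) + 1L,
                            3L * (fragment - 1L) + 2L,
                            3L * fragment))
    Vf <- V[rows, , drop = FALSE]
    comp <- rowsum(Vf, rep(1:3, times = length(fragment)))
    sqrt(colSums(comp^2))
  }
  pooled <- unlist(lapply(pool, raw_of))
  if (length(pooled) == 0L) stop("empty pooled mode ensemble")
  d_raw <- raw_of(modes)
  dmax <- max(pooled)   # all-zero pool: normalization undefined, reported NA
  # pooled rank: ties broken by lower pooled index (earlier set / lower mode)
  pooled_rank <- integer(length(pooled))
  pooled_rank[order(-pooled, seq_along(pooled))] <- seq_along(pooled)
  # locate this set's modes inside the pool
  self_at <- which(vapply(pool, identical, logical(1L), y = modes))[1L]
  if (is.na(self_at)) {
    rk <- rank(-d_raw, ties.method = "first")
  } else {
    before <- if (self_at > 1L)
      sum(vapply(pool[seq_len(self_at - 1L)],
                 function(m) ncol(.mode_matrix(m)), integer(1L))) else 0L
    rk <- pooled_rank[before + seq_along(d_raw)]
  }
  data.frame(mode_index = seq_along(d_raw),
             d_raw = d_raw,
             d_norm = if (dmax > 0) d_raw / dmax else NA_real_,
             rank = rk)
}

#' Pairwise overlaps between two mode bases
#'
#' Entry (i, j) is the scalar product of mode i of `modesA` with mode j of
#' `modesB`, in [-1, 1] for normalized modes.
#'
#' @param modesA,modesB `mode_set`s or 3N x M matrices of equal row
#'   dimension.
#' @return numeric matrix.
#' @export
mode_overlap <- function(modesA, modesB) {
  A <- .mode_matrix(modesA); B <- .mode_matrix(modesB)
  if (nrow(A) != nrow(B)) stop("mode dimension mismatch")
  crossprod(A, B)
}

#' Root mean square inner product between two subspaces
#'
#' RMSIP over the first `n_modes` columns of each basis; 1 for identical
#' subspaces, ~sqrt(n_modes/3N) for random ones.
#'
#' @inheritParams mode_overlap
#' @param n_modes subspace dimension.
#' @export
rmsip <- function(modesA, modesB, n_modes) {
  A <- .mode_matrix(modesA)[, seq_len(n_modes), drop = FALSE]
  B <- .mode_matrix(modesB)[, seq_len(n_modes), drop = FALSE]
  sqrt(sum(crossprod(A, B)^2) / n_modes)
}

#' Displace a structure along one normal mode
#'
#' Linear mode-following: coordinates are x0 + a * v with the mode
#' direction scaled so the all-atom RMSD from the origin equals |a|
#' exactly. Mass-weighted modes are converted back to Cartesian directions
#' before scaling. The default amplitude grid is -4 to 4 A in 0.1 A steps
#' (81 conformations).
#'
#' @param structure `structure_model` the mode set was computed on.
#' @param modes `mode_set`.
#' @param mode_index which mode to follow.
#' @param amplitudes amplitude grid in A.
#' @return `trajectory` of displaced conformations, with the amplitude
#'   grid in attribute `"amplitudes"`.
#' @export
displace_along_mode <- function(structure, modes, mode_index,
                                amplitudes = seq(-4, 4, by = 0.1)) {
  stopifnot(inherits(modes, "mode_set"))
  if (any(!is.finite(amplitudes))) stop("non-finite amplitude")
  n <- modes$n_atoms
  if (nrow(structure$xyz) != n) stop("structure does not match the mode set")
  v <- modes$vectors[, mode_index]
  if (modes$mass_weighted) v <- v / sqrt(rep(modes$masses, each = 3L))
  v <- v / sqrt(sum(v^2))
  u <- matrix(v, ncol = 3L, byrow = TRUE) * sqrt(n)   # RMSD(a*u) = |a|
  coords <- array(NA_real_, dim = c(n, 3L, length(amplitudes)))
  for (k in seq_along(amplitudes))
    coords[, , k] <- structure$xyz + amplitudes[k] * u
  tr <- trajectory(structure, coords)
  attr(tr, "amplitudes") <- amplitudes
  tr
}

#' Per-mode metric table over a pooled mode ensemble
#'
#' Convenience wrapper producing, for each mode of each set in `pool`, its
#' eigenvalue, subset collectivity, fragment resultant displacement (raw
#' and pool-normalized) and dense ranks of both metrics within the pool --
#' the tabulation used to compare mode ensembles from several
#' conformations.
#'
#' @param pool list of `mode_set`s (pooled ensemble).
#' @param subset atom indices for the collectivity statistic.
#' @param fragment atom indices for the resultant displacement.
#' @return data.frame(set, mode_index, eigenvalue, k_subset, d_raw,
#'   d_norm, rank_k, rank_d).
#' @export
mode_metrics <- function(pool, subset = NULL, fragment) {
  if (!is.list(pool) || length(pool) == 0L) stop("pool must be a nonempty list")
  rows <- lapply(seq_along(pool), function(s) {
    m <- pool[[s]]
    fd <- fragment_displacement(m, fragment)     # raw values only
    ev <- if (inherits(m, "mode_set")) m$eigenvalues
          else rep(NA_real_, ncol(.mode_matrix(m)))
    data.frame(set = s,
               mode_index = fd$mode_index,
               eigenvalue = ev,
               k_subset = collectivity(m, subset),
               d_raw = fd$d_raw)
  })
  out <- do.call(rbind, rows)
  dmax <- max(out$d_raw)
  out$d_norm <- if (dmax > 0) out$d_raw / dmax else NA_real_
  # dense pooled ranks, ties broken by pool order then mode index
  out$rank_d <- integer(nrow(out))
  out$rank_d[order(-out$d_raw, seq_len(nrow(out)))] <- seq_len(nrow(out))
  out$rank_k <- integer(nrow(out))
  out$rank_k[order(-out$k_subset, seq_len(nrow(out)))] <- seq_len(nrow(out))
  out[, c("set", "mode_index", "eigenvalue", "k_subset",
          "d_raw", "d_norm", "rank_k", "rank_d")]
}
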