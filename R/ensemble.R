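# Ensemble statistics: least-squares superposition, RMSD series,
# anisotropic fluctuation tensors, quasi-harmonic PCA and the
# reference-structure convergence analysis.

.centroid <- function(x, w = NULL) {
  if (is.null(w)) colMeans(x) else colSums(x * w) / sum(w)
}

.check_fit_input <- function(x, nm) {
  if (nrow(x) < 3L) stop(nm, ": need at least 3 atoms")
  sv <- svd(scale(x, scale = FALSE), nu = 0L, nv = 0L)$d
  if (sv[2L] < 1e-8 * max(sv[1L], 1e-12)) stop(nm, ": collinear atoms")
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Proper rotation only (determinant +1, reflections forbidden), optional
#' per-atom weights. The fitted mobile coordinates are
#' `mobile %*% rotation + translation` (row-vector convention).
#'
#' @param mobile,reference N x 3 coordinate matrices, N >= 3 and
#'   non-collinear.
#' @param weights optional nonnegative per-atom weights.
#' @return list(rotation, translation, rmsd) with the post-fit RMSD in A.
#' @export
superpose <- function(mobile, reference, weights = NULL) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (nrow(mobile) != nrow(reference)) stop("atom count mismatch")
  .check_fit_input(mobile, "mobile"); .check_fit_input(reference, "reference")
  if (is.null(weights)) weights <- rep(1, nrow(mobile))
  cm <- .centroid(mobile, weights); cr <- .centroid(reference, weights)
  P <- sweep(mobile, 2L, cm); Q <- sweep(reference, 2L, cr)
  H <- crossprod(P * weights, Q)
  sv <- svd(H)
  d <- sign(det(sv$u %*% t(sv$v)))
  R <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fitted <- P %*% R
  rmsd <- sqrt(sum(weights * rowSums((fitted - Q)^2)) / sum(weights))
  list(rotation = R, translation = as.numeric(cr - cm %*% R), rmsd = rmsd)
}

.apply_fit <- function(coords, fit) sweep(coords %*% fit$rotation, 2L,
                                          -fit$translation)

.rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Fit every frame onto an iteratively refined average structure
# (fit -> average -> refit, fixed number of iterations), fitting on
# `fit_sel` and transforming all atoms. Returns fitted coords + average.
.fit_frames <- function(coords, fit_sel = NULL, iterations = 2L,
                        reference = NULL) {
  n <- dim(coords)[1L]; nf <- dim(coords)[3L]
  if (is.null(fit_sel)) fit_sel <- seq_len(n)
  ref <- if (is.null(reference)) coords[fit_sel, , 1L, drop = FALSE][, , 1L]
         else reference[fit_sel, , drop = FALSE]
  out <- coords
  for (it in seq_len(iterations)) {
    for (f in seq_len(nf)) {
      ft <- superpose(coords[fit_sel, , f], ref)
      out[, , f] <- .apply_fit(coords[, , f], ft)
    }
    ref <- apply(out[fit_sel, , , drop = FALSE], c(1L, 2L), mean)
  }
  list(coords = out, mean = apply(out, c(1L, 2L), mean))
}

#' Per-frame RMSD series
#'
#' Each frame is rigid-body fitted on `fit_selection`, and the RMSD is
#' reported on `selection`, against either the first frame, the (2-pass
#' iterative) average structure, or an explicit coordinate matrix.
#'
#' @param traj `trajectory`.
#' @param reference `"first"`, `"average"`, or an N x 3 matrix over the
#'   full topology.
#' @param selection atom indices to report RMSD on (default: all).
#' @param fit_selection atom indices to fit on (default: `selection`).
#' @return numeric vector of per-frame RMSDs (A), with frame times as
#'   names.
#' @export
rmsd_series <- function(traj, reference = "first", selection = NULL,
                        fit_selection = selection) {
  stopifnot(inherits(traj, "trajectory"))
  n <- dim(traj$coords)[1L]
  if (is.null(selection)) selection <- seq_len(n)
  if (length(selection) == 0L) stop("empty selection")
  if (is.null(fit_selection)) fit_selection <- selection
  ref <- if (is.matrix(reference)) reference
         else if (identical(reference, "first")) traj$coords[, , 1L]
         else if (identical(reference, "average"))
           .fit_frames(traj$coords, fit_selection)$mean
         else stop("reference must be 'first', 'average', or a matrix")
  out <- vapply(seq_len(n_frames(traj)), function(f) {
    ft <- superpose(traj$coords[fit_selection, , f],
                    ref[fit_selection, , drop = FALSE])
    fitted <- .apply_fit(traj$coords[selection, , f], ft)
    .rmsd(fitted, ref[selection, , drop = FALSE])
  }, numeric(1L))
  names(out) <- traj$times
  out
}

#' Anisotropic per-atom fluctuation tensors
#'
#' After a two-pass fit of every frame onto the ensemble average, returns
#' each selected atom's 3 x 3 positional covariance (A^2, population
#' normalization). The tensor trace is the atom's mean-square fluctuation;
#' its eigenvectors/eigenvalues are the fluctuation ellipsoid axes.
#'
#' @param traj `trajectory` with >= 2 frames.
#' @param selection atom indices (default: all).
#' @return `fluctuation_tensor_set`: list(tensors = n x 3 x 3 array,
#'   msf = per-atom mean-square fluctuation, selection).
#' @export
fluctuation_tensors <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  n <- dim(traj$coords)[1L]
  if (is.null(selection)) selection <- seq_len(n)
  ft <- .fit_frames(traj$coords, selection)
  nf <- n_frames(traj)
  tens <- array(0, dim = c(length(selection), 3L, 3L))
  for (k in seq_along(selection)) {
    a <- selection[k]
    X <- t(ft$coords[a, , ])                     # F x 3
    Xc <- sweep(X, 2L, colMeans(X))
    tens[k, , ] <- crossprod(Xc) / nf
  }
  structure(list(tensors = tens,
                 msf = vapply(seq_along(selection),
                              function(k) sum(diag(tens[k, , ])), numeric(1L)),
                 selection = selection),
            class = "fluctuation_tensor_set")
}

#' Principal component analysis of a trajectory
#'
#' Quasi-harmonic PCA: frames are fitted (two-pass) onto their average on
#' `selection`, and the 3n x 3n positional covariance of the selected
#' atoms is diagonalized. Modes are sorted by descending eigenvalue (A^2).
#'
#' @param traj `trajectory` with > 1 frame.
#' @param selection atom indices (default: all).
#' @return `trajectory_pca`: mean_structure (n x 3), eigenvalues,
#'   eigenvectors (3n columns, orthonormal), cumulative_variance.
#' @export
trajectory_pca <- function(traj, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  if (n_frames(traj) < 2L) stop("need at least 2 frames")
  n <- dim(traj$coords)[1L]
  if (is.null(selection)) selection <- seq_len(n)
  ft <- .fit_frames(traj$coords, selection)
  nf <- n_frames(traj)
  X <- t(apply(ft$coords[selection, , , drop = FALSE], 3L,
               function(m) as.vector(t(m))))    # F x 3n (x1,y1,z1,...)
  mu <- colMeans(X)
  Xc <- sweep(X, 2L, mu)
  C <- crossprod(Xc) / nf
  eg <- eigen(C, symmetric = TRUE)
  ev <- pmax(eg$values, 0)
  tot <- sum(ev)
  cumvar <- if (tot > 0) cumsum(ev) / tot else rep(1, length(ev))
  structure(list(mean_structure = matrix(mu, ncol = 3L, byrow = TRUE),
                 eigenvalues = ev,
                 eigenvectors = eg$vectors,
                 cumulative_variance = cumvar,
                 selection = selection,
                 total_variance = tot),
            class = "trajectory_pca")
}

#' @export
print.trajectory_pca <- function(x, ...) {
  m90 <- n_modes_for_variance(x, 0.9)
  cat(sprintf("trajectory_pca: %d modes, total variance %.3f A^2, %d modes reach 90%%\n",
              length(x$eigenvalues), x$total_variance, m90))
  invisible(x)
}

#' Number of PCA modes needed to reach a variance fraction
#'
#' Smallest m whose cumulative variance fraction is at least `fraction`
#' (default 0.9, the usual criterion for "describing 90% of the total
#' fluctuations").
#'
#' @param pca `trajectory_pca`.
#' @param fraction target fraction in (0, 1].
#' @export
n_modes_for_variance <- function(pca, fraction = 0.9) {
  stopifnot(fraction > 0, fraction <= 1)
  which(pca$cumulative_variance >= fraction - 1e-12)[1L]
}

#' Reference-structure convergence analysis
#'
#' Ensemble-based convergence check: per seed, reference frames are picked
#' at random among frames not yet within RMSD cutoff `r` of any chosen
#' reference, until every frame is covered; each frame is then assigned to
#' its nearest reference. The trajectory is split into halves by frame
#' index (odd counts give the extra frame to the first half), and a
#' reference whose group is empty in either half is a *lone reference* --
#' the signature of an unconverged (e.g. two-state, blocked) ensemble. A
#' well-mixed ensemble yields no lone references.
#'
#' @param traj `trajectory` with >= 4 frames.
#' @param cutoff RMSD cutoff r in A (> 0).
#' @param seeds integer seeds, one analysis per seed (default 1:5).
#' @param selection atom indices for the RMSD (default: CA atoms, falling
#'   back to all atoms when the topology has none).
#' @return `convergence_report` data.frame(seed, n_references,
#'   n_lone_references), with per-seed reference frame indices in
#'   attribute `"references"` and the cutoff in `"cutoff"`.
#' @export
convergence_analysis <- function(traj, cutoff, seeds = 1:5, selection = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  nf <- n_frames(traj)
  if (nf < 4L) stop("need at least 4 frames")
  if (cutoff <= 0) stop("cutoff must be > 0")
  if (is.null(selection)) {
    at <- traj$topology$atoms
    selection <- which(at$atom_name == "CA" & at$element != "H")
    if (length(selection) == 0L) selection <- seq_len(dim(traj$coords)[1L])
  }
  D <- matrix(0, nf, nf)
  for (i in seq_len(nf - 1L)) for (j in (i + 1L):nf) {
    D[i, j] <- D[j, i] <- superpose(traj$coords[selection, , j],
                                    traj$coords[selection, , i])$rmsd
  }
  half1 <- seq_len(ceiling(nf / 2))
  refs_by_seed <- list()
  rows <- lapply(seeds, function(s) {
    refs <- .with_seed(s, {
      r <- integer(0L)
      covered <- rep(FALSE, nf)
      while (!all(covered)) {
        cand <- which(!covered)
        pick <- cand[sample.int(length(cand), 1L)]
        r <- c(r, pick)
        covered <- covered | (D[pick, ] <= cutoff)
      }
      r
    })
    assign_to <- refs[apply(D[refs, , drop = FALSE], 2L, which.min)]
    lone <- sum(vapply(refs, function(rf) {
      g <- which(assign_to == rf)
      length(intersect(g, half1)) == 0L || length(setdiff(g, half1)) == 0L
    }, logical(1L)))
    refs_by_seed[[as.character(s)]] <<- refs
    data.frame(seed = s, n_references = length(refs),
               n_lone_references = lone)
  })
  out <- do.call(rbind, rows)
  attr(out, "references") <- refs_by_seed
  attr(out, "cutoff") <- cutoff
  class(out) <- c("convergence_report", class(out))
  out
}
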