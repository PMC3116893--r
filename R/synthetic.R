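# Synthetic ground-truth generators.
#
# These emulate the statistical structure the downstream analyses assume
# (Gaussian ensembles with an elastic-network covariance, two-state
# trajectories with controlled separation, AR(1) energy series with a
# closed-form standard error, cavity shells with a known center, ideal
# helices for H-bond geometry), so every stage can be tested against known
# truth. Every generator is a pure function of (parameters, seed).

# Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}

.ca_atoms <- function(n, first_residue = 1L) {
  data.frame(
    serial         = seq_len(n),
    atom_name      = "CA",
    residue_name   = "ALA",
    residue_number = seq.int(first_residue, length.out = n),
    chain_id       = "A",
    element        = "C",
    stringsAsFactors = FALSE)
}

#' Pseudo-helical C-alpha toy chain
#'
#' Non-collinear CA-only chain with the canonical 3.8 A consecutive
#' CA-CA spacing (within 0.01 A; a small seeded jitter breaks exact
#' symmetry so repeated structures differ between seeds).
#'
#' @param n_residues number of residues (>= 3).
#' @param seed RNG seed.
#' @param first_residue residue number of the first residue (default 1).
#' @return `structure_model` of `n_residues` CA atoms.
#' @export
make_toy_chain <- function(n_residues, seed = 1L, first_residue = 1L) {
  if (n_residues < 3L) stop("n_residues must be >= 3")
  # helix with consecutive spacing exactly 3.8 A:
  # chord^2 = (2 R sin(theta/2))^2 + rise^2
  R <- 2.0; theta <- 100 * pi / 180
  rise <- sqrt(3.8^2 - (2 * R * sin(theta / 2))^2)
  i <- seq_len(n_residues) - 1L
  xyz <- cbind(R * cos(i * theta), R * sin(i * theta), rise * i)
  jit <- .with_seed(seed, matrix(stats::rnorm(3L * n_residues, sd = 0.002),
                                 ncol = 3L))
  structure_model(.ca_atoms(n_residues, first_residue), xyz + jit)
}

# internal NeRF: place D given A-B-C with bond |CD|, angle BCD, torsion ABCD
.place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  unitv <- function(v) v / sqrt(sum(v^2))
  cr <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                         a[3] * b[1] - a[1] * b[3],
                         a[1] * b[2] - a[2] * b[1])
  th <- angle_deg * pi / 180
  chi <- torsion_deg * pi / 180
  bc <- unitv(C - B)
  n <- unitv(cr(B - A, bc))
  m <- cr(n, bc)
  C + bond * (-cos(th) * bc + sin(th) * (cos(chi) * m + sin(chi) * n))
}

#' Ideal alpha-helical backbone
#'
#' Backbone atoms N, H, CA, C, O built from standard internal coordinates
#' (phi = -57, psi = -47, omega = 180; rise ~1.5 A, ~100 deg/residue), the
#' geometry that places each carbonyl O(i) within hydrogen-bonding distance
#' of the amide N-H of residue i+4. Fixture for H-bond detection.
#'
#' @param n_residues number of residues (>= 6).
#' @return `structure_model` with 5 atoms per residue.
#' @export
make_ideal_helix <- function(n_residues) {
  if (n_residues < 6L) stop("n_residues must be >= 6")
  phi <- -57; psi <- -47; omega <- 180
  bNC <- 1.329; bCAC <- 1.525; bNCA <- 1.458; bCO <- 1.231; bNH <- 1.01
  aCACN <- 116.2; aCNCA <- 121.7; aNCAC <- 111.2; aCACO <- 120.5
  unitv <- function(v) v / sqrt(sum(v^2))
  N <- matrix(NA_real_, n_residues, 3); CA <- N; C <- N; O <- N; H <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(bNCA, 0, 0)
  C[1, ] <- .place_atom(c(0, 1, 0), N[1, ], CA[1, ], bCAC, aNCAC, 0)
  for (i in 2:n_residues) {
    N[i, ] <- .place_atom(N[i - 1, ], CA[i - 1, ], C[i - 1, ], bNC, aCACN, psi)
    CA[i, ] <- .place_atom(CA[i - 1, ], C[i - 1, ], N[i, ], bNCA, aCNCA, omega)
    C[i, ] <- .place_atom(C[i - 1, ], N[i, ], CA[i, ], bCAC, aNCAC, phi)
  }
  for (i in seq_len(n_residues)) {
    O[i, ] <- .place_atom(N[i, ], CA[i, ], C[i, ], bCO, aCACO, psi + 180)
    if (i == 1L) {
      H[i, ] <- N[i, ] + bNH * unitv(-(unitv(CA[i, ] - N[i, ]) + c(0, 0, 1)))
    } else {
      # sp2 amide H in the peptide plane, bisecting CA-N and C(i-1)-N
      H[i, ] <- N[i, ] + bNH *
        unitv(-(unitv(CA[i, ] - N[i, ]) + unitv(C[i - 1, ] - N[i, ])))
    }
  }
  per <- c("N", "H", "CA", "C", "O")
  atoms <- data.frame(
    serial         = seq_len(5L * n_residues),
    atom_name      = rep(per, n_residues),
    residue_name   = "ALA",
    residue_number = rep(seq_len(n_residues), each = 5L),
    chain_id       = "A",
    element        = rep(c("N", "H", "C", "C", "O"), n_residues),
    stringsAsFactors = FALSE)
  xyz <- matrix(NA_real_, 5L * n_residues, 3L)
  for (i in seq_len(n_residues)) {
    xyz[(i - 1L) * 5L + 1:5, ] <- rbind(N[i, ], H[i, ], CA[i, ], C[i, ], O[i, ])
  }
  structure_model(atoms, xyz)
}

#' Sample a Gaussian ensemble from elastic-network modes
#'
#' Frames are the input structure plus independent Gaussian displacements
#' along the non-zero modes, with per-mode variance `scale / eigenvalue`.
#' The resulting ensemble has the analytic covariance
#' `scale * pseudoinverse(Hessian)`, the stationary distribution a harmonic
#' network implies; rigid-body modes are excluded so superposition is not
#' confounded with internal motion.
#'
#' @param structure `structure_model` the modes were computed on.
#' @param modes `mode_set` from [compute_modes()] on the same structure.
#' @param scale variance scale in A^2 (kT in spring-constant units).
#' @param n_frames number of frames.
#' @param seed RNG seed.
#' @return `trajectory`.
#' @export
sample_enm_ensemble <- function(structure, modes, scale = 1, n_frames = 100L,
                                seed = 1L) {
  stopifnot(inherits(structure, "structure_model"), inherits(modes, "mode_set"))
  if (scale <= 0) stop("scale must be > 0")
  n <- nrow(structure$xyz)
  if (modes$n_atoms != n) stop("modes do not match the structure")
  V <- modes$vectors
  if (modes$mass_weighted) {
    V <- V / sqrt(rep(modes$masses, each = 3L))
    V <- sweep(V, 2L, sqrt(colSums(V^2)), "/")
  }
  sdv <- sqrt(scale / modes$eigenvalues)
  Z <- .with_seed(seed,
                  matrix(stats::rnorm(length(sdv) * n_frames), nrow = length(sdv)))
  D <- V %*% (Z * sdv)                      # 3N x F displacements
  x0 <- as.vector(t(structure$xyz))         # x1,y1,z1,x2,...
  coords <- array(NA_real_, dim = c(n, 3L, n_frames))
  for (f in seq_len(n_frames))
    coords[, , f] <- matrix(x0 + D[, f], ncol = 3L, byrow = TRUE)
  trajectory(structure, coords)
}

#' Two-state synthetic trajectory
#'
#' Half the frames near structure A, half near structure B, either as two
#' contiguous blocks (`layout = "blocked"`, the signature of an
#' unconverged simulation) or randomly interleaved (`"shuffled"`, the
#' well-mixed control), with optional per-coordinate Gaussian jitter.
#'
#' @param structA,structB `structure_model`s sharing a topology.
#' @param n_frames even number of frames.
#' @param layout `"blocked"` or `"shuffled"`.
#' @param jitter Gaussian sd in A added to every coordinate (0 = none).
#' @param seed RNG seed.
#' @return `trajectory` with a logical `state` attribute (TRUE = A).
#' @export
make_two_state_trajectory <- function(structA, structB, n_frames = 100L,
                                      layout = c("blocked", "shuffled"),
                                      jitter = 0, seed = 1L) {
  layout <- match.arg(layout)
  if (n_frames %% 2L != 0L) stop("n_frames must be even")
  if (nrow(structA$xyz) != nrow(structB$xyz))
    stop("topology mismatch between the two states")
  n <- nrow(structA$xyz)
  state <- rep(c(TRUE, FALSE), each = n_frames / 2L)
  coords <- array(NA_real_, dim = c(n, 3L, n_frames))
  .with_seed(seed, {
    if (layout == "shuffled") state <- sample(state)
    for (f in seq_len(n_frames)) {
      base <- if (state[f]) structA$xyz else structB$xyz
      if (jitter > 0)
        base <- base + matrix(stats::rnorm(3L * n, sd = jitter), ncol = 3L)
      coords[, , f] <- base
    }
  })
  tr <- trajectory(structA, coords)
  attr(tr, "state") <- state
  tr
}

#' Stationary AR(1) scalar series
#'
#' First-order autoregressive series with marginal mean `mean`, marginal
#' standard deviation `sigma` and lag-1 autocorrelation `phi`. The true
#' standard error of its sample mean is closed-form,
#' `(sigma / sqrt(n)) * sqrt((1 + phi) / (1 - phi))`, which makes this the
#' exact oracle for the autocorrelation-aware error estimator.
#'
#' @param mean marginal mean.
#' @param sigma marginal sd (>= 0).
#' @param phi lag-1 autocorrelation, |phi| < 1.
#' @param n series length.
#' @param seed RNG seed.
#' @return numeric vector of length `n`.
#' @export
make_ar1_series <- function(mean = 0, sigma = 1, phi = 0, n = 1000L, seed = 1L) {
  if (abs(phi) >= 1) stop("|phi| must be < 1")
  if (sigma < 0) stop("sigma must be >= 0")
  if (sigma == 0) return(rep(mean, n))
  .with_seed(seed, {
    z <- numeric(n)
    z[1L] <- stats::rnorm(1L, sd = sigma)        # exact stationary start
    if (n > 1L) {
      eps <- stats::rnorm(n - 1L, sd = sigma * sqrt(1 - phi^2))
      for (t in 2:n) z[t] <- phi * z[t - 1L] + eps[t - 1L]
    }
    mean + z
  })
}

#' True standard error of an AR(1) sample mean
#' @inheritParams make_ar1_series
#' @export
ar1_true_se <- function(sigma, phi, n) {
  (sigma / sqrt(n)) * sqrt((1 + phi) / (1 - phi))
}

# quasi-uniform points on the unit sphere (Fibonacci lattice)
.fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  cbind(r * cos(ga * (i - 0.5)), r * sin(ga * (i - 0.5)), z)
}

#' Spherical-shell cavity fixture
#'
#' Carbon pseudo-atoms quasi-uniform on a sphere of radius `shell_radius`
#' centered at the origin, with a spherical cap of half-angle
#' `aperture_deg` around +z removed to form the cavity mouth. The cavity
#' center is the origin by construction, which is the ground truth pocket
#' detection is tested against.
#'
#' @param shell_radius shell radius in A.
#' @param aperture_deg mouth half-angle in degrees, in (0, 120).
#' @param n_atoms atoms placed on the full sphere before cap removal.
#' @param seed RNG seed (small radial/tangential jitter).
#' @return `structure_model`.
#' @export
make_cavity_structure <- function(shell_radius = 8, aperture_deg = 40,
                                  n_atoms = 200L, seed = 1L) {
  if (aperture_deg <= 0 || aperture_deg >= 120)
    stop("aperture_deg must be in (0, 120)")
  pts <- .fibonacci_sphere(n_atoms)
  keep <- acos(pmin(1, pmax(-1, pts[, 3L]))) > aperture_deg * pi / 180
  pts <- pts[keep, , drop = FALSE]
  if (nrow(pts) < 20L) stop("parameters yield fewer than 20 atoms")
  rad <- .with_seed(seed, shell_radius + stats::rnorm(nrow(pts), sd = 0.03))
  xyz <- pts * rad
  atoms <- .ca_atoms(nrow(pts))
  atoms$residue_name <- "CAV"
  structure_model(atoms, xyz)
}

#' Two-chamber cavity fixture
#'
#' A sealed spherical shell with an internal one-atom-thick dividing wall
#' (plane x = 0): two enclosed chambers whose interiors are separated only
#' by the wall's solvent-exclusion zone. The construction truth is two
#' pockets with centroids near (-shell_radius/2, 0, 0) and
#' (+shell_radius/2, 0, 0), adjacent across the wall.
#'
#' @param shell_radius shell radius in A.
#' @param n_shell atoms on the shell.
#' @param wall_spacing lattice spacing of the dividing wall in A.
#' @param seed RNG seed.
#' @return `structure_model`; wall atoms carry residue name `WAL`.
#' @export
make_double_cavity_structure <- function(shell_radius = 8, n_shell = 350L,
                                         wall_spacing = 1.8, seed = 1L) {
  pts <- .fibonacci_sphere(n_shell)
  rad <- .with_seed(seed, shell_radius + stats::rnorm(n_shell, sd = 0.03))
  shell <- pts * rad
  g <- seq(-shell_radius, shell_radius, by = wall_spacing)
  wall <- as.matrix(expand.grid(x = 0, y = g, z = g))
  wall <- wall[sqrt(wall[, 2L]^2 + wall[, 3L]^2) < shell_radius - 0.5, ,
               drop = FALSE]
  xyz <- rbind(shell, wall)
  atoms <- .ca_atoms(nrow(xyz))
  atoms$residue_name <- rep(c("CAV", "WAL"), c(nrow(shell), nrow(wall)))
  structure_model(atoms, xyz)
}
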