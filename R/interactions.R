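# Geometric hydrogen-bond and hydrophobic-contact detection, trajectory
# occupancy maps, and Shrake-Rupley solvent accessible surface areas.

.default_hbond_criteria <- function() {
  list(d_HA_max = 2.5, d_DA_max = 3.5, angle_DHA_min = 120)
}

.angle_deg <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# D-H...A events on one coordinate set. Donors: N/O with an attached H
# (H within 1.25 A); acceptors: N/O. Same-residue pairs excluded.
# Without hydrogens, falls back to a D-A distance + 90-degree-cone
# heuristic on the donor's bonded heavy atom (logged notice).
.hbond_events <- function(atoms, xyz, criteria) {
  cr <- utils::modifyList(.default_hbond_criteria(), criteria)
  pol <- which(atoms$element %in% c("N", "O"))
  hyd <- which(atoms$element == "H")
  res <- atoms$residue_number
  empty <- data.frame(type = character(0), donor = integer(0),
                      hydrogen = integer(0), acceptor = integer(0),
                      donor_res = integer(0), acceptor_res = integer(0),
                      distance = numeric(0), angle = numeric(0))
  if (length(pol) < 2L) return(empty)
  out <- list()
  if (length(hyd) > 0L) {
    for (h in hyd) {
      dd <- sqrt(colSums((t(xyz[pol, , drop = FALSE]) - xyz[h, ])^2))
      if (min(dd) > 1.25) next                       # H not on a polar atom
      D <- pol[which.min(dd)]
      da <- sqrt(colSums((t(xyz[pol, , drop = FALSE]) - xyz[h, ])^2))
      for (k in seq_along(pol)) {
        A <- pol[k]
        if (A == D || res[A] == res[D]) next
        dHA <- da[k]
        if (dHA > cr$d_HA_max) next
        dDA <- sqrt(sum((xyz[A, ] - xyz[D, ])^2))
        if (dDA > cr$d_DA_max) next
        ang <- .angle_deg(xyz[D, ], xyz[h, ], xyz[A, ])
        if (ang < cr$angle_DHA_min) next
        out[[length(out) + 1L]] <- data.frame(
          type = "hbond", donor = D, hydrogen = h, acceptor = A,
          donor_res = res[D], acceptor_res = res[A],
          distance = dHA, angle = ang)
      }
    }
  } else {
    message("no hydrogens in topology: using D-A distance + 90-degree cone heuristic")
    heavy <- which(atoms$element != "H")
    seen <- character(0)   # donor/acceptor roles are ambiguous without H
    for (D in pol) {
      dh <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[D, ])^2))
      ante <- heavy[dh > 1e-6 & dh < 1.8]
      for (A in pol) {
        if (A == D || res[A] == res[D]) next
        dDA <- sqrt(sum((xyz[A, ] - xyz[D, ])^2))
        if (dDA > cr$d_DA_max) next
        if (length(ante) > 0L) {
          angs <- vapply(ante, function(b) .angle_deg(xyz[b, ], xyz[D, ], xyz[A, ]),
                         numeric(1L))
          if (all(angs < 90)) next
        }
        key <- paste(min(D, A), max(D, A))
        if (key %in% seen) next
        seen <- c(seen, key)
        out[[length(out) + 1L]] <- data.frame(
          type = "hbond", donor = D, hydrogen = NA_integer_, acceptor = A,
          donor_res = res[D], acceptor_res = res[A],
          distance = dDA, angle = NA_real_)
      }
    }
  }
  if (length(out) == 0L) empty else do.call(rbind, out)
}

#' Detect hydrogen bonds on one conformation
#'
#' Geometric D-H...A criteria: H...A distance, donor-acceptor distance and
#' D-H-A angle must all pass (defaults 2.5 A, 3.5 A, 120 degrees --
#' HBPLUS-compatible ranges, all configurable). Structures without
#' hydrogens fall back to a donor-acceptor distance plus 90-degree-cone
#' heuristic, with a logged notice.
#'
#' @param structure `structure_model` (or a trajectory topology).
#' @param coords optional N x 3 coordinates overriding the structure's.
#' @param criteria named list overriding `d_HA_max`, `d_DA_max`,
#'   `angle_DHA_min`.
#' @return data.frame of events (donor/hydrogen/acceptor atom indices,
#'   residue numbers, distance, angle).
#' @export
detect_hbonds <- function(structure, coords = NULL, criteria = list()) {
  stopifnot(inherits(structure, "structure_model"))
  xyz <- if (is.null(coords)) structure$xyz else as.matrix(coords)
  .hbond_events(structure$atoms, xyz, criteria)
}

.hydrophobic_events <- function(atoms, xyz, d_max) {
  ap <- which(atoms$apolar & atoms$element != "H")
  empty <- data.frame(type = character(0), atom_i = integer(0),
                      atom_j = integer(0), res_i = integer(0),
                      res_j = integer(0), distance = numeric(0))
  if (length(ap) < 2L) return(empty)
  d <- as.matrix(stats::dist(xyz[ap, , drop = FALSE]))
  res <- atoms$residue_number[ap]
  sel <- which(upper.tri(d) & d <= d_max & outer(res, res, "!="), arr.ind = TRUE)
  if (nrow(sel) == 0L) return(empty)
  data.frame(type = "hydrophobic",
             atom_i = ap[sel[, 1L]], atom_j = ap[sel[, 2L]],
             res_i = res[sel[, 1L]], res_j = res[sel[, 2L]],
             distance = d[sel])
}

#' Detect hydrophobic contacts on one conformation
#'
#' Apolar heavy-atom pairs (carbon/sulfur, see the apolar flag) in
#' different residues within `d_max` (default 4.5 A, a LIGPLOT-style
#' convention).
#'
#' @inheritParams detect_hbonds
#' @param d_max contact distance cutoff in A.
#' @return data.frame of contact events.
#' @export
detect_hydrophobic <- function(structure, coords = NULL, d_max = 4.5) {
  stopifnot(inherits(structure, "structure_model"))
  xyz <- if (is.null(coords)) structure$xyz else as.matrix(coords)
  .hydrophobic_events(structure$atoms, xyz, d_max)
}

#' Pooled productive simulation time
#'
#' Total analysis time after discarding an initial relaxation period from
#' each replica: `sum(replica_lengths - relaxation)`. With the usual two
#' 50-ns replicas and a 2-ns relaxation this is the 96-ns denominator used
#' for contact occupancies.
#'
#' @param replica_lengths per-replica simulation lengths (ns).
#' @param relaxation relaxation period discarded from each replica (ns).
#' @return total productive time, same units as the inputs.
#' @export
productive_time <- function(replica_lengths = c(50, 50), relaxation = 2) {
  if (any(replica_lengths <= relaxation))
    stop("relaxation period exceeds a replica length")
  sum(replica_lengths - relaxation)
}

#' Contact occupancy map between two regions over a trajectory
#'
#' For every residue pair (one residue in each region) the occupancy is
#' the fraction of productive frames (times > `relaxation_ps`) in which at
#' least one qualifying contact of the requested type exists. Pairs below
#' `threshold` (default 0.15, i.e. 15% of the productive time) are
#' dropped.
#'
#' @param traj `trajectory`.
#' @param regionA,regionB disjoint regions (labels, intervals, or atom
#'   index vectors).
#' @param type `"hbond"` or `"hydrophobic"`.
#' @param threshold occupancy threshold in [0, 1].
#' @param relaxation_ps frames at or before this time are excluded from
#'   the denominator.
#' @param criteria H-bond criteria overrides (hbond type).
#' @param d_max hydrophobic contact cutoff in A.
#' @param region_map map used to resolve region labels.
#' @return data.frame(res_a, res_b, type, occupancy) sorted by decreasing
#'   occupancy, with attributes `threshold` and `n_productive_frames`.
#' @export
occupancy_map <- function(traj, regionA, regionB,
                          type = c("hbond", "hydrophobic"),
                          threshold = 0.15, relaxation_ps = 0,
                          criteria = list(), d_max = 4.5,
                          region_map = default_region_map()) {
  type <- match.arg(type)
  stopifnot(inherits(traj, "trajectory"))
  topo <- traj$topology
  idxA <- if (is.numeric(regionA) && length(regionA) > 2L) as.integer(regionA)
          else select_atoms(topo, regionA, "all", region_map)
  idxB <- if (is.numeric(regionB) && length(regionB) > 2L) as.integer(regionB)
          else select_atoms(topo, regionB, "all", region_map)
  if (length(intersect(idxA, idxB)) > 0L) stop("regions must be disjoint")
  frames <- which(traj$times > relaxation_ps)
  if (length(frames) == 0L) stop("no productive frames")
  sub <- sort(c(idxA, idxB))
  atoms <- topo$atoms[sub, , drop = FALSE]
  inA <- sub %in% idxA
  resA_set <- unique(atoms$residue_number[inA])
  resB_set <- unique(atoms$residue_number[!inA])
  counts <- new.env(parent = emptyenv())
  for (f in frames) {
    xyz <- traj$coords[sub, , f]
    ev <- if (type == "hbond") .hbond_events(atoms, xyz, criteria)
          else .hydrophobic_events(atoms, xyz, d_max)
    if (nrow(ev) == 0L) next
    if (type == "hbond") {
      r1 <- ev$donor_res; r2 <- ev$acceptor_res
    } else {
      r1 <- ev$res_i; r2 <- ev$res_j
    }
    a_side <- ifelse(r1 %in% resA_set & r2 %in% resB_set, r1,
                     ifelse(r2 %in% resA_set & r1 %in% resB_set, r2, NA))
    b_side <- ifelse(r1 %in% resA_set & r2 %in% resB_set, r2,
                     ifelse(r2 %in% resA_set & r1 %in% resB_set, r1, NA))
    ok <- !is.na(a_side)
    if (!any(ok)) next
    keys <- unique(paste(a_side[ok], b_side[ok], sep = "_"))
    for (k in keys)
      assign(k, (if (exists(k, envir = counts)) get(k, envir = counts) else 0L) + 1L,
             envir = counts)
  }
  keys <- ls(counts)
  if (length(keys) == 0L) {
    out <- data.frame(res_a = integer(0), res_b = integer(0),
                      type = character(0), occupancy = numeric(0))
  } else {
    parts <- do.call(rbind, strsplit(keys, "_"))
    occ <- vapply(keys, get, numeric(1L), envir = counts) / length(frames)
    out <- data.frame(res_a = as.integer(parts[, 1L]),
                      res_b = as.integer(parts[, 2L]),
                      type = type, occupancy = occ, row.names = NULL)
    out <- out[out$occupancy >= threshold, , drop = FALSE]
    out <- out[order(-out$occupancy, out$res_a, out$res_b), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "threshold") <- threshold
  attr(out, "n_productive_frames") <- length(frames)
  out
}

# golden-spiral quadrature points on the unit sphere
.sphere_points <- function(n) .fibonacci_sphere(n)

#' Shrake-Rupley solvent accessible surface area
#'
#' Quadrature SASA: `n_sphere_points` test points on each atom's expanded
#' sphere (vdW radius + probe); a point is accessible when it lies outside
#' every other atom's expanded sphere. Default probe 1.5 A, 960 points per
#' atom (quadrature error well under 1%).
#'
#' @inheritParams detect_hbonds
#' @param probe probe sphere radius in A (>= 0).
#' @param n_sphere_points quadrature points per atom.
#' @return list(atom = per-atom areas in A^2, residue = data.frame
#'   (residue_number, area)).
#' @export
sasa <- function(structure, coords = NULL, probe = 1.5, n_sphere_points = 960L) {
  stopifnot(inherits(structure, "structure_model"))
  if (probe < 0) stop("probe radius must be >= 0")
  xyz <- if (is.null(coords)) structure$xyz else as.matrix(coords)
  r <- structure$atoms$vdw_radius + probe
  n <- nrow(xyz)
  pts <- .sphere_points(n_sphere_points)
  d <- as.matrix(stats::dist(xyz))
  area <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(d[i, ] < r[i] + r & seq_len(n) != i)
    p <- sweep(pts * r[i], 2L, xyz[i, ], "+")
    if (length(nb) > 0L) {
      acc <- rep(TRUE, n_sphere_points)
      for (j in nb) {
        acc[acc] <- colSums((t(p[acc, , drop = FALSE]) - xyz[j, ])^2) > r[j]^2
        if (!any(acc)) break
      }
      frac <- mean(acc)
    } else frac <- 1
    area[i] <- frac * 4 * pi * r[i]^2
  }
  res <- rowsum(area, structure$atoms$residue_number)
  list(atom = area,
       residue = data.frame(residue_number = as.integer(rownames(res)),
                            area = as.numeric(res)))
}
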