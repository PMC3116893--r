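# Grid-based pocket detection (LIGSITE-style buriedness scanning) and
# "path-of-pockets" adjacency analysis.
#
# A lattice is laid over the structure's bounding box; lattice points
# inside any atom's solvent-expanded sphere (vdW + probe) are protein,
# the rest solvent. A solvent point is kept when it is enclosed by
# protein on both sides along at least `burial_min` of 7 scan axes
# (x, y, z and the four space diagonals). Kept points are clustered by
# 26-connectivity; clusters below `min_points` are discarded.

.extract_plane <- function(a, ax, i) {
  switch(ax, a[i, , ], a[, i, ], a[, , i])
}

.assign_plane <- function(a, ax, i, m) {
  switch(ax, a[i, , ] <- m, a[, i, ] <- m, a[, , i] <- m)
  a
}

.shift_matrix <- function(m, d1, d2) {
  out <- matrix(FALSE, nrow(m), ncol(m))
  r_src <- seq_len(nrow(m)) + d1
  c_src <- seq_len(ncol(m)) + d2
  ok_r <- r_src >= 1L & r_src <= nrow(m)
  ok_c <- c_src >= 1L & c_src <= ncol(m)
  out[ok_r, ok_c] <- m[r_src[ok_r], c_src[ok_c], drop = FALSE]
  out
}

# seen[x] = TRUE if any protein cell lies strictly beyond x along +d
.scan_direction <- function(prot, d) {
  dims <- dim(prot)
  seen <- array(FALSE, dims)
  ax <- which(d != 0L)[1L]
  others <- setdiff(1:3, ax)
  ord <- if (d[ax] > 0L) seq(dims[ax] - 1L, 1L) else seq(2L, dims[ax])
  for (i in ord) {
    src <- i + d[ax]
    comb <- .extract_plane(prot, ax, src) | .extract_plane(seen, ax, src)
    comb <- .shift_matrix(comb, d[others[1L]], d[others[2L]])
    seen <- .assign_plane(seen, ax, i, comb)
  }
  seen
}

.scan_axes <- rbind(c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
                    c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L),
                    c(-1L, 1L, 1L))

#' Detect surface pockets on one conformation
#'
#' Grid/buriedness pocket detection with configurable strictness: larger
#' `burial_min` or `min_points` give fewer, deeper pockets. Pocket volume
#' is the retained point count times the grid-cell volume.
#'
#' @param structure `structure_model` with >= 20 atoms.
#' @param spacing grid spacing in A (default 0.8).
#' @param burial_min minimum number of the 7 scan axes along which a
#'   point must be enclosed (default 5).
#' @param min_points minimum cluster size (default 30).
#' @param probe solvent probe radius added to vdW radii (default 1.4 A).
#' @param merge_dist pocket adjacency distance (default 2 x spacing).
#' @return `pocket_set`: list of pockets (id, points, centroid, volume,
#'   n_points) plus the adjacency edge list; pockets are ordered by
#'   decreasing size.
#' @export
detect_pockets <- function(structure, spacing = 0.8, burial_min = 5L,
                           min_points = 30L, probe = 1.4,
                           merge_dist = 2 * spacing) {
  stopifnot(inherits(structure, "structure_model"))
  if (spacing <= 0) stop("spacing must be > 0")
  xyz <- structure$xyz
  if (nrow(xyz) < 20L) stop("need at least 20 atoms")
  rad <- structure$atoms$vdw_radius + probe
  pad <- max(rad) + 2 * spacing
  lo <- apply(xyz, 2L, min) - pad
  hi <- apply(xyz, 2L, max) + pad
  gx <- seq(lo[1L], hi[1L], by = spacing)
  gy <- seq(lo[2L], hi[2L], by = spacing)
  gz <- seq(lo[3L], hi[3L], by = spacing)
  dims <- c(length(gx), length(gy), length(gz))
  prot <- array(FALSE, dims)
  for (a in seq_len(nrow(xyz))) {
    r <- rad[a]
    ix <- which(abs(gx - xyz[a, 1L]) <= r)
    iy <- which(abs(gy - xyz[a, 2L]) <= r)
    iz <- which(abs(gz - xyz[a, 3L]) <= r)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (gx[ix] - xyz[a, 1L])^2
    dy2 <- (gy[iy] - xyz[a, 2L])^2
    dz2 <- (gz[iz] - xyz[a, 3L])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
    prot[ix, iy, iz] <- prot[ix, iy, iz] | (d2 <= r^2)
  }
  buried <- array(0L, dims)
  for (k in seq_len(nrow(.scan_axes))) {
    d <- .scan_axes[k, ]
    enc <- .scan_direction(prot, d) & .scan_direction(prot, -d)
    buried <- buried + enc
  }
  psp <- which(!prot & buried >= burial_min)
  pockets <- list()
  edges <- matrix(integer(0), ncol = 2L)
  if (length(psp) > 0L) {
    coord <- arrayInd(psp, dims)
    # cluster by 26-connectivity on the lattice
    key <- (coord[, 1L] - 1L) + dims[1L] * ((coord[, 2L] - 1L) +
             dims[2L] * (coord[, 3L] - 1L))
    offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
    offs <- offs[rowSums(abs(offs)) > 0L & (offs[, 1L] > 0L |
             (offs[, 1L] == 0L & (offs[, 2L] > 0L |
             (offs[, 2L] == 0L & offs[, 3L] > 0L)))), , drop = FALSE]
    el <- list()
    for (o in seq_len(nrow(offs))) {
      nk <- (coord[, 1L] - 1L + offs[o, 1L]) + dims[1L] *
            ((coord[, 2L] - 1L + offs[o, 2L]) + dims[2L] *
             (coord[, 3L] - 1L + offs[o, 3L]))
      hit <- match(nk, key)
      ok <- !is.na(hit)
      if (any(ok)) el[[length(el) + 1L]] <- cbind(which(ok), hit[ok])
    }
    g <- igraph::graph_from_edgelist(
      if (length(el)) do.call(rbind, el) else matrix(integer(0), ncol = 2L),
      directed = FALSE)
    g <- igraph::add_vertices(g, max(0L, length(psp) - igraph::vcount(g)))
    cmp <- igraph::components(g)
    keep_ids <- which(cmp$csize >= min_points)
    ord <- keep_ids[order(-cmp$csize[keep_ids])]
    pockets <- lapply(seq_along(ord), function(p) {
      idx <- which(cmp$membership == ord[p])
      pts <- cbind(gx[coord[idx, 1L]], gy[coord[idx, 2L]], gz[coord[idx, 3L]])
      list(id = p, points = pts, centroid = colMeans(pts),
           volume = length(idx) * spacing^3, n_points = length(idx))
    })
    edges <- .pocket_adjacency(pockets, merge_dist)
  }
  structure(list(pockets = pockets, spacing = spacing, probe = probe,
                 burial_min = burial_min, min_points = min_points,
                 merge_dist = merge_dist, adjacency = edges),
            class = "pocket_set")
}

.min_cross_dist <- function(a, b) {
  # min distance between two point sets, with a bounding-box short-circuit
  lo_gap <- pmax(apply(a, 2L, min), apply(b, 2L, min)) -
            pmin(apply(a, 2L, max), apply(b, 2L, max))
  lower <- sqrt(sum(pmax(lo_gap, 0)^2))
  m <- Inf
  for (i in seq_len(nrow(a))) {
    d2 <- colSums((t(b) - a[i, ])^2)
    m <- min(m, min(d2))
  }
  sqrt(m)
}

.pocket_adjacency <- function(pockets, merge_dist) {
  np <- length(pockets)
  el <- list()
  if (np >= 2L) for (i in seq_len(np - 1L)) for (j in (i + 1L):np) {
    if (.min_cross_dist(pockets[[i]]$points, pockets[[j]]$points) <= merge_dist)
      el[[length(el) + 1L]] <- c(i, j)
  }
  if (length(el)) do.call(rbind, el) else matrix(integer(0), ncol = 2L)
}

#' @export
print.pocket_set <- function(x, ...) {
  cat(sprintf("pocket_set: %d pocket(s), spacing %.2f A\n",
              length(x$pockets), x$spacing))
  for (p in x$pockets)
    cat(sprintf("  #%d: %d points, %.1f A^3, centroid (%.1f, %.1f, %.1f)\n",
                p$id, p$n_points, p$volume,
                p$centroid[1L], p$centroid[2L], p$centroid[3L]))
  invisible(x)
}

#' Pocket-path query toward a declared site
#'
#' Labels each pocket by contact (any pocket point within `contact_dist`
#' of any atom of the selection) with a site region and a start region,
#' then asks whether one connected component of the pocket adjacency
#' graph touches both -- the "path-of-pockets" criterion. The reported
#' path is the shortest pocket chain from a start-touching to a
#' site-touching pocket.
#'
#' @param pockets `pocket_set`.
#' @param structure the `structure_model` the pockets were detected on.
#' @param site,start atom index vectors, or region labels/intervals
#'   resolved against `region_map`.
#' @param contact_dist contact distance in A (default 4.5).
#' @param merge_dist optional override of the adjacency distance.
#' @param region_map map for resolving region labels.
#' @return list(path_exists, path (pocket ids in order), table
#'   (per-pocket n_points, volume, touches_site, touches_start)).
#' @export
pocket_path <- function(pockets, structure, site, start, contact_dist = 4.5,
                        merge_dist = NULL,
                        region_map = default_region_map()) {
  stopifnot(inherits(pockets, "pocket_set"))
  resolve <- function(sel) {
    if (is.numeric(sel) && length(sel) > 2L) as.integer(sel)
    else select_atoms(structure, sel, "all", region_map)
  }
  site_idx <- resolve(site)
  start_idx <- resolve(start)
  if (length(site_idx) == 0L) stop("empty site selection")
  np <- length(pockets$pockets)
  if (np == 0L) {
    return(list(path_exists = FALSE, path = integer(0),
                table = data.frame(id = integer(0), n_points = integer(0),
                                   volume = numeric(0),
                                   touches_site = logical(0),
                                   touches_start = logical(0))))
  }
  touches <- function(p, idx)
    .min_cross_dist(p$points, structure$xyz[idx, , drop = FALSE]) < contact_dist
  t_site <- vapply(pockets$pockets, touches, logical(1L), idx = site_idx)
  t_start <- vapply(pockets$pockets, touches, logical(1L), idx = start_idx)
  edges <- if (is.null(merge_dist)) pockets$adjacency
           else .pocket_adjacency(pockets$pockets, merge_dist)
  g <- igraph::make_empty_graph(n = np, directed = FALSE)
  if (nrow(edges) > 0L) g <- igraph::add_edges(g, t(edges))
  cmp <- igraph::components(g)$membership
  path_exists <- FALSE
  path <- integer(0)
  joint <- which(vapply(seq_len(max(cmp)), function(cc)
    any(t_site[cmp == cc]) && any(t_start[cmp == cc]), logical(1L)))
  if (length(joint) > 0L) {
    path_exists <- TRUE
    cc <- joint[1L]
    from <- which(t_start & cmp == cc)[1L]
    to_set <- which(t_site & cmp == cc)
    sp <- igraph::shortest_paths(g, from = from, to = to_set)$vpath
    lens <- vapply(sp, length, integer(1L))
    path <- as.integer(sp[[which.min(lens)]])
  }
  list(path_exists = path_exists, path = path,
       table = data.frame(
         id = vapply(pockets$pockets, `[[`, integer(1L), "id"),
         n_points = vapply(pockets$pockets, `[[`, integer(1L), "n_points"),
         volume = vapply(pockets$pockets, `[[`, numeric(1L), "volume"),
         touches_site = t_site, touches_start = t_start))
}

#' Write pocket grid points as PDB pseudo-atoms
#'
#' HETATM-style dummy atoms (element X as carbon), one residue per
#' pocket, for visual inspection alongside the structure.
#'
#' @param pockets `pocket_set`.
#' @param path output PDB path.
#' @export
write_pockets <- function(pockets, path) {
  lines <- character(0)
  serial <- 0L
  for (p in pockets$pockets) {
    for (i in seq_len(p$n_points)) {
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "HETATM%5d  C   PKT %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f           %1s",
        serial %% 100000L, "P", p$id, p$points[i, 1L], p$points[i, 2L],
        p$points[i, 3L], 1.00, 0.00, "C"))
    }
  }
  writeLines(c(lines, "END"), path)
  invisible(NULL)
}
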