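# Structure and trajectory I/O, atom selection, named residue regions.
#
# A structure_model is a list(atoms, xyz):
#   atoms : data.frame(serial, atom_name, residue_name, residue_number,
#                      chain_id, element, mass, vdw_radius, apolar)
#   xyz   : N x 3 numeric matrix (Angstrom)
# A trajectory is a list(topology, coords, times):
#   coords : N x 3 x F array; times strictly increasing (ps).

# Element-based vdW radii (A) and masses (Da). Radii follow the usual
# Bondi-style values used by geometric surface/contact codes.
.element_table <- data.frame(
  element    = c("H", "C", "N", "O", "S", "P"),
  vdw_radius = c(1.20, 1.70, 1.55, 1.52, 1.80, 1.80),
  mass       = c(1.008, 12.011, 14.007, 15.999, 32.06, 30.974),
  stringsAsFactors = FALSE
)

.infer_element <- function(atom_name) {
  nm <- gsub("[^A-Za-z]", "", atom_name)
  first <- toupper(substr(nm, 1L, 1L))
  # protein heavy atoms start with C/N/O/S/P; hydrogens with H (or a digit,
  # already stripped)
  ifelse(first %in% .element_table$element, first, "C")
}

.element_lookup <- function(element, what = c("vdw_radius", "mass")) {
  what <- match.arg(what)
  idx <- match(element, .element_table$element)
  out <- .element_table[[what]][idx]
  out[is.na(out)] <- if (what == "mass") 12.011 else 1.70
  out
}

# apolar flag: carbon and sulfur atoms; backbone carbonyl C ("C") is bonded
# to O and excluded by name.
.apolar_flag <- function(atom_name, element) {
  (element == "S") | (element == "C" & trimws(atom_name) != "C")
}

#' Construct a structure model
#'
#' Builds the atom-level container used throughout the package: an atom
#' table (names, residues, elements, masses, van der Waals radii, apolar
#' flags) plus an N x 3 coordinate matrix in Angstrom.
#'
#' @param atoms data frame with at least `atom_name`, `residue_name`,
#'   `residue_number`; `serial`, `chain_id`, `element` are filled in when
#'   absent, radii/masses come from a bundled element table.
#' @param xyz numeric N x 3 matrix of coordinates (Angstrom).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(atoms, xyz) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must be an N x 3 matrix")
  n <- nrow(xyz)
  if (n == 0L) stop("empty input: structure has zero atoms")
  if (nrow(atoms) != n) stop("atoms table and xyz disagree on atom count")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  if (is.null(atoms$serial)) atoms$serial <- seq_len(n)
  if (anyDuplicated(atoms$serial)) stop("atom serials must be unique")
  if (is.null(atoms$chain_id)) atoms$chain_id <- "A"
  if (is.null(atoms$element)) atoms$element <- .infer_element(atoms$atom_name)
  if (is.null(atoms$mass)) atoms$mass <- .element_lookup(atoms$element, "mass")
  if (is.null(atoms$vdw_radius))
    atoms$vdw_radius <- .element_lookup(atoms$element, "vdw_radius")
  if (is.null(atoms$apolar))
    atoms$apolar <- .apolar_flag(atoms$atom_name, atoms$element)
  stopifnot(all(atoms$vdw_radius > 0), all(atoms$mass > 0))
  for (ch in unique(atoms$chain_id)) {
    rn <- atoms$residue_number[atoms$chain_id == ch]
    if (is.unsorted(rn)) stop("residue numbers must be nondecreasing within a chain")
  }
  structure(list(atoms = atoms, xyz = xyz), class = "structure_model")
}

#' Construct a trajectory
#'
#' @param topology a `structure_model` giving the fixed atom topology.
#' @param coords N x 3 x F array (or list of N x 3 matrices) of frames.
#' @param times per-frame times in ps, strictly increasing; defaults to
#'   `1:F`.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(topology, coords, times = NULL) {
  stopifnot(inherits(topology, "structure_model"))
  if (is.list(coords))
    coords <- array(unlist(coords), dim = c(nrow(coords[[1L]]), 3L, length(coords)))
  if (length(dim(coords)) != 3L || dim(coords)[2L] != 3L)
    stop("coords must be an N x 3 x F array")
  if (dim(coords)[1L] != nrow(topology$xyz))
    stop("frame atom count does not match topology")
  nf <- dim(coords)[3L]
  if (nf < 1L) stop("trajectory must contain at least one frame")
  if (is.null(times)) times <- as.numeric(seq_len(nf))
  if (length(times) != nf || any(diff(times) <= 0))
    stop("times must be strictly increasing, one per frame")
  structure(list(topology = topology, coords = coords, times = as.numeric(times)),
            class = "trajectory")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model: %d atoms, %d residues, chains: %s\n",
              nrow(x$xyz),
              length(unique(paste(x$atoms$chain_id, x$atoms$residue_number))),
              paste(unique(x$atoms$chain_id), collapse = ",")))
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames x %d atoms, t = %.1f..%.1f ps\n",
              n_frames(x), nrow(x$topology$xyz),
              x$times[1L], x$times[length(x$times)]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `trajectory`.
#' @export
n_frames <- function(traj) dim(traj$coords)[3L]

#' Extract one frame of a trajectory as a coordinate matrix
#' @param traj a `trajectory`.
#' @param i frame index.
#' @export
frame_coords <- function(traj, i) traj$coords[, , i, drop = TRUE]

#' Read a PDB structure or multi-model trajectory
#'
#' Parses ATOM/HETATM records (via bio3d) into the package containers.
#' Elements are inferred from atom names when the element column is absent;
#' van der Waals radii and masses are assigned from a bundled element table.
#' Alternate locations keep the highest-occupancy copy (first on ties);
#' insertion codes are rejected.
#'
#' @param path PDB file path.
#' @param model_policy `"first"` returns a `structure_model` from the first
#'   MODEL; `"all"` returns a `trajectory` built from all MODEL blocks.
#' @return `structure_model` or `trajectory`.
#' @export
read_structure <- function(path, model_policy = c("first", "all")) {
  model_policy <- match.arg(model_policy)
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = (model_policy == "all"),
                                     verbose = FALSE)),
    error = function(e) stop("PDB parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  at <- pdb$atom
  if (is.null(at) || nrow(at) == 0L) stop("empty input: no atoms in ", path)
  ins <- at$insert
  if (!is.null(ins) && any(!is.na(ins) & nzchar(trimws(ins))))
    stop("insertion codes are not supported")
  keep <- .resolve_altloc(at)
  at <- at[keep, , drop = FALSE]
  atoms <- data.frame(
    serial         = at$eleno,
    atom_name      = trimws(at$elety),
    residue_name   = trimws(at$resid),
    residue_number = at$resno,
    chain_id       = ifelse(is.na(at$chain) | !nzchar(at$chain), "A", at$chain),
    stringsAsFactors = FALSE)
  elesy <- trimws(at$elesy)
  atoms$element <- ifelse(!is.na(elesy) & nzchar(elesy), toupper(elesy),
                          .infer_element(atoms$atom_name))
  if (model_policy == "first") {
    xyz <- matrix(pdb$xyz[1L, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
    return(structure_model(atoms, xyz))
  }
  nmod <- nrow(pdb$xyz)
  n <- nrow(atoms)
  coords <- array(NA_real_, dim = c(n, 3L, nmod))
  for (m in seq_len(nmod))
    coords[, , m] <- matrix(pdb$xyz[m, ], ncol = 3L, byrow = TRUE)[keep, , drop = FALSE]
  topo <- structure_model(atoms, coords[, , 1L])
  trajectory(topo, coords)
}

.resolve_altloc <- function(at) {
  alt <- at$alt
  if (is.null(alt)) return(seq_len(nrow(at)))
  alt[is.na(alt)] <- ""
  if (all(alt == "")) return(seq_len(nrow(at)))
  key <- paste(at$chain, at$resno, trimws(at$elety))
  occ <- at$o
  occ[is.na(occ)] <- 1
  keep <- logical(nrow(at))
  for (k in unique(key)) {
    idx <- which(key == k)
    keep[idx[which.max(occ[idx])]] <- TRUE   # highest occupancy, first on tie
  }
  which(keep)
}

#' Write a structure or trajectory as PDB
#'
#' Emits standard fixed-width ATOM records; trajectories are written as
#' MODEL/ENDMDL blocks. Coordinates are rounded to the PDB's 3 decimals.
#'
#' @param model `structure_model` or `trajectory`.
#' @param path output file path.
#' @export
write_structure <- function(model, path) {
  if (inherits(model, "structure_model")) {
    lines <- c(.pdb_atom_lines(model$atoms, model$xyz), "END")
  } else if (inherits(model, "trajectory")) {
    nf <- n_frames(model)
    if (nf == 0L) stop("empty trajectory")
    lines <- unlist(lapply(seq_len(nf), function(m) {
      c(sprintf("MODEL     %4d", m),
        .pdb_atom_lines(model$topology$atoms, model$coords[, , m]),
        "ENDMDL")
    }))
    lines <- c(lines, "END")
  } else stop("model must be a structure_model or trajectory")
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write to path: ", path)
  invisible(NULL)
}

.pdb_atom_lines <- function(atoms, xyz) {
  if (any(atoms$residue_number > 9999L))
    stop("residue number > 9999 cannot be written in PDB format (record ",
         which(atoms$residue_number > 9999L)[1L], ")")
  if (any(atoms$serial > 99999L)) stop("atom serial > 99999 exceeds PDB format")
  nm <- atoms$atom_name
  # names shorter than 4 chars start in column 14
  nm <- ifelse(nchar(nm) < 4L, sprintf(" %-3s", nm), nm)
  sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          atoms$serial, nm, atoms$residue_name, atoms$chain_id,
          atoms$residue_number, xyz[, 1L], xyz[, 2L], xyz[, 3L],
          1.00, 0.00, atoms$element)
}

#' Default KIT residue-region map
#'
#' Named residue intervals of the KIT cytoplasmic region (author numbering,
#' closed 1-based intervals): the four juxta-membrane fragments JM-Proximal
#' (547-552), JM-Buried (553-559), JM-Switch (560-570), JM-Zipper (571-581),
#' their union JMR (547-581), the glycine-rich P-loop (596-601), C-helix
#' (631-647) and the activation loop (810-835).
#'
#' @return A named list of `c(start, end)` integer intervals
#'   (class `region_map`).
#' @export
default_region_map <- function() {
  structure(list(
    "JM-P"    = c(547L, 552L),
    "JM-B"    = c(553L, 559L),
    "JM-S"    = c(560L, 570L),
    "JM-Z"    = c(571L, 581L),
    "JMR"     = c(547L, 581L),
    "P-loop"  = c(596L, 601L),
    "C-helix" = c(631L, 647L),
    "A-loop"  = c(810L, 835L)
  ), class = "region_map")
}

#' Read a region map from a plain-text config
#'
#' One `label = start-end` line per region; blank lines and `#` comments
#' ignored. Labels must be unique and intervals nonempty.
#'
#' @param path config file path.
#' @return A `region_map`.
#' @export
read_region_map <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  out <- list()
  for (l in ln) {
    m <- regmatches(l, regexec("^(.+?)\\s*=\\s*([0-9]+)\\s*-\\s*([0-9]+)$", l))[[1L]]
    if (length(m) != 4L) stop("malformed region line: '", l, "'")
    lab <- trimws(m[2L])
    if (lab %in% names(out)) stop("duplicate region label: ", lab)
    iv <- c(as.integer(m[3L]), as.integer(m[4L]))
    if (iv[2L] < iv[1L]) stop("empty interval for region ", lab)
    out[[lab]] <- iv
  }
  structure(out, class = "region_map")
}

.resolve_region <- function(region, region_map = default_region_map()) {
  if (is.character(region)) {
    if (!region %in% names(region_map))
      stop("unknown region label: ", region)
    region <- region_map[[region]]
  }
  if (is.numeric(region) && length(region) == 2L) region <- list(region)
  if (!is.list(region)) stop("region must be a label or interval(s)")
  region
}

#' Select atoms by residue region and atom filter
#'
#' @param model a `structure_model`.
#' @param region region label (resolved against `region_map`), a
#'   `c(start, end)` interval, or a list of intervals (closed, 1-based,
#'   author numbering).
#' @param atom_filter `"all"`, `"heavy"` (drop hydrogens) or `"calpha"`
#'   (one CA per residue).
#' @param region_map map used to resolve labels; defaults to the KIT map.
#' @return Integer atom indices in topology order.
#' @export
select_atoms <- function(model, region, atom_filter = c("all", "heavy", "calpha"),
                         region_map = default_region_map()) {
  atom_filter <- match.arg(atom_filter)
  intervals <- .resolve_region(region, region_map)
  rn <- model$atoms$residue_number
  in_region <- rep(FALSE, length(rn))
  for (iv in intervals) in_region <- in_region | (rn >= iv[1L] & rn <= iv[2L])
  idx <- which(in_region)
  if (atom_filter == "heavy") {
    idx <- idx[model$atoms$element[idx] != "H"]
  } else if (atom_filter == "calpha") {
    idx <- idx[model$atoms$atom_name[idx] == "CA" & model$atoms$element[idx] != "H"]
  }
  if (length(idx) == 0L) stop("empty selection: region matches no atoms")
  sort(idx)
}
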