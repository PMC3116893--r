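# Pipeline orchestration: run the analysis stages in dependency order from
# a flat key=value config, with one global seed and a reproducibility
# manifest. All randomness flows from the global seed via fixed per-stage
# offsets, so identical config + inputs give identical outputs.

.pipeline_defaults <- function() {
  list(
    out_dir = NULL,
    stages = "synth,rmsd,converge,pca,tensors,contacts,nma,displace,pockets",
    seed = 1L,
    n_residues = 60L,
    n_frames = 80L,
    enm_cutoff = 12,
    enm_scale = 1,
    n_modes = 20L,
    converge_cutoff = 1.5,
    converge_seeds = "1,2,3,4,5",
    contact_threshold = 0.15,
    relaxation_ps = 0,
    displace_mode = 1L,
    displace_max = 2,
    displace_step = 0.5,
    pockets_input = NULL,     # "cavity" or a PDB path; required for pockets
    pocket_spacing = 0.8,
    pocket_burial_min = 5L,
    pocket_min_points = 30L,
    energy_table = NULL       # required for the energetics stage
  )
}

#' Read a flat key=value pipeline config
#'
#' One `key = value` pair per line; `#` comments and blank lines ignored.
#' Unknown keys are rejected.
#'
#' @param path config file path.
#' @return named list merged over the stage defaults.
#' @export
read_pipeline_config <- function(path) {
  ln <- trimws(readLines(path))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  cfg <- list()
  for (l in ln) {
    kv <- regmatches(l, regexec("^([A-Za-z0-9_.]+)\\s*=\\s*(.*)$", l))[[1L]]
    if (length(kv) != 3L) stop("malformed config line: '", l, "'")
    cfg[[kv[2L]]] <- kv[3L]
  }
  resolve_pipeline_config(cfg)
}

#' Resolve and validate a pipeline config
#'
#' Merges user settings over the defaults, coerces numeric fields and
#' validates stage prerequisites (before any computation): the pockets
#' stage needs `pockets_input`, the energetics stage needs `energy_table`.
#'
#' @param config named list (or nothing, for the all-defaults synthetic
#'   run).
#' @return resolved config list.
#' @export
resolve_pipeline_config <- function(config = list()) {
  defaults <- .pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0L)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  num_keys <- c("seed", "n_residues", "n_frames", "enm_cutoff", "enm_scale",
                "n_modes", "converge_cutoff", "contact_threshold",
                "relaxation_ps", "displace_mode", "displace_max",
                "displace_step", "pocket_spacing", "pocket_burial_min",
                "pocket_min_points")
  for (k in num_keys) cfg[[k]] <- as.numeric(cfg[[k]])
  cfg$stages <- trimws(unlist(strsplit(as.character(cfg$stages), ",")))
  cfg$converge_seeds <- as.integer(unlist(strsplit(as.character(cfg$converge_seeds),
                                                   ",")))
  known <- c("synth", "rmsd", "converge", "pca", "tensors", "contacts",
             "nma", "displace", "pockets", "energetics")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0L) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$out_dir)) stop("config must set out_dir")
  needs_ensemble <- intersect(cfg$stages,
                              c("rmsd", "converge", "pca", "tensors",
                                "contacts", "nma", "displace"))
  if (length(needs_ensemble) > 0L && !"synth" %in% cfg$stages)
    stop("stage(s) ", paste(needs_ensemble, collapse = ","),
         " need the synth stage (no external trajectory input configured)")
  if ("pockets" %in% cfg$stages && is.null(cfg$pockets_input))
    stop("pockets stage requested without pockets_input (path or 'cavity')")
  if ("energetics" %in% cfg$stages && is.null(cfg$energy_table))
    stop("energetics stage requested without energy_table")
  if (!is.null(cfg$pockets_input) && cfg$pockets_input != "cavity" &&
      !file.exists(cfg$pockets_input))
    stop("pockets_input file not found: ", cfg$pockets_input)
  if (!is.null(cfg$energy_table) && !file.exists(cfg$energy_table))
    stop("energy_table file not found: ", cfg$energy_table)
  cfg
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order on a synthetic
#' elastic-network ensemble (ensemble statistics, contacts, normal-mode
#' metrics on a representative conformation, mode-following displacement,
#' pocket detection, free-energy bookkeeping), writing one TSV/PDB per
#' stage plus a `manifest.txt` echoing the fully resolved config, the
#' package version, and the checksum of every output. The manifest
#' suffices to reproduce the run.
#'
#' @param config named list or a config file path (see
#'   [read_pipeline_config()]).
#' @return the output directory, invisibly.
#' @export
run_pipeline <- function(config) {
  cfg <- if (is.character(config)) read_pipeline_config(config)
         else resolve_pipeline_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  emit <- function(name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(path)
    outputs <<- c(outputs, name)
    message("stage output: ", name)
  }
  seed0 <- as.integer(cfg$seed)
  traj <- NULL; chain <- NULL; modes0 <- NULL
  if ("synth" %in% cfg$stages) {
    chain <- make_toy_chain(cfg$n_residues, seed = seed0)
    hess <- build_hessian(chain, cutoff = cfg$enm_cutoff)
    n_avail <- 3L * cfg$n_residues - 6L
    modes0 <- compute_modes(hess, n_modes = min(cfg$n_modes, n_avail))
    traj <- sample_enm_ensemble(chain, modes0, scale = cfg$enm_scale,
                                n_frames = cfg$n_frames, seed = seed0 + 1L)
    emit("ensemble.pdb", function(p) write_structure(traj, p))
  }
  conv <- NULL
  if ("rmsd" %in% cfg$stages) {
    rs <- rmsd_series(traj, reference = "first")
    emit("rmsd.tsv", function(p)
      .write_tsv(data.frame(time_ps = traj$times, rmsd = as.numeric(rs)), p))
  }
  if ("converge" %in% cfg$stages) {
    conv <- convergence_analysis(traj, cutoff = cfg$converge_cutoff,
                                 seeds = cfg$converge_seeds)
    emit("convergence.tsv", function(p) .write_tsv(as.data.frame(conv), p))
  }
  if ("pca" %in% cfg$stages) {
    pc <- trajectory_pca(traj)
    emit("pca.tsv", function(p)
      .write_tsv(data.frame(mode = seq_along(pc$eigenvalues),
                            eigenvalue = pc$eigenvalues,
                            cumulative_variance = pc$cumulative_variance), p))
  }
  if ("tensors" %in% cfg$stages) {
    ft <- fluctuation_tensors(traj)
    emit("fluctuations.tsv", function(p)
      .write_tsv(data.frame(atom = ft$selection, msf = ft$msf), p))
  }
  n <- cfg$n_residues
  thirds <- list(c(1, floor(n / 3)), c(n - floor(n / 3) + 1, n))
  if ("contacts" %in% cfg$stages) {
    om <- occupancy_map(traj, thirds[[1L]], thirds[[2L]],
                        type = "hydrophobic",
                        threshold = cfg$contact_threshold,
                        relaxation_ps = cfg$relaxation_ps)
    emit("contacts.tsv", function(p) .write_tsv(om, p))
  }
  rep_modes <- NULL; rep_struct <- NULL
  if ("nma" %in% cfg$stages) {
    # representative conformation: the convergence module's first
    # reference (earliest frame on ties); frame 1 when converge not run
    rep_frame <- 1L
    if (!is.null(conv)) {
      refs <- attr(conv, "references")[[1L]]
      rep_frame <- min(refs)
    }
    rep_struct <- structure_model(traj$topology$atoms, frame_coords(traj, rep_frame))
    rep_modes <- compute_modes(build_hessian(rep_struct, cutoff = cfg$enm_cutoff),
                               n_modes = min(cfg$n_modes, 3L * n - 6L))
    mm <- mode_metrics(list(rep_modes),
                       subset = seq.int(thirds[[2L]][1L], thirds[[2L]][2L]),
                       fragment = seq.int(thirds[[2L]][1L], thirds[[2L]][2L]))
    emit("nma_metrics.tsv", function(p) .write_tsv(mm, p))
  }
  if ("displace" %in% cfg$stages) {
    amps <- seq(-cfg$displace_max, cfg$displace_max, by = cfg$displace_step)
    disp <- displace_along_mode(rep_struct, rep_modes,
                                mode_index = as.integer(cfg$displace_mode),
                                amplitudes = amps)
    emit("displaced.pdb", function(p) write_structure(disp, p))
  }
  if ("pockets" %in% cfg$stages) {
    pstruct <- if (identical(cfg$pockets_input, "cavity"))
      make_cavity_structure(seed = seed0 + 2L)
    else read_structure(cfg$pockets_input, "first")
    ps <- detect_pockets(pstruct, spacing = cfg$pocket_spacing,
                         burial_min = cfg$pocket_burial_min,
                         min_points = cfg$pocket_min_points)
    tab <- if (length(ps$pockets) == 0L)
      data.frame(id = integer(0), n_points = integer(0), volume = numeric(0))
    else data.frame(id = vapply(ps$pockets, `[[`, integer(1L), "id"),
                    n_points = vapply(ps$pockets, `[[`, integer(1L), "n_points"),
                    volume = vapply(ps$pockets, `[[`, numeric(1L), "volume"))
    emit("pockets.tsv", function(p) .write_tsv(tab, p))
  }
  if ("energetics" %in% cfg$stages) {
    es <- parse_energy_table(cfg$energy_table)
    fe <- estimate_free_energy(es)
    rows <- lapply(c("G", "H", "TS"), function(q)
      data.frame(quantity = q, mean = fe[[q]]$mean, error = fe[[q]]$error))
    emit("energetics.tsv", function(p) .write_tsv(do.call(rbind, rows), p))
  }
  manifest <- c(
    paste0("package_version=", as.character(utils::packageVersion("modescope"))),
    vapply(sort(names(cfg)), function(k)
      paste0(k, "=", paste(cfg[[k]], collapse = ",")), character(1L)),
    vapply(sort(outputs), function(f)
      paste0("md5:", f, "=",
             unname(tools::md5sum(file.path(cfg$out_dir, f)))), character(1L)))
  writeLines(manifest, file.path(cfg$out_dir, "manifest.txt"))
  invisible(cfg$out_dir)
}
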