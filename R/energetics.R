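# MM-GBSA-style free-energy bookkeeping.
#
# The package does not evaluate force-field or solvation energies; it
# consumes per-frame component tables (the output of an end-point
# free-energy code) and does the bookkeeping: component summation
# (E_gas = E_int + E_ele + E_vdw; H = E_gas + G_gb + G_sa; G = H - TS),
# autocorrelation-aware standard errors of time-series means (Straatsma),
# stability differences, and binding thermodynamic cycles with mutational
# differences.

.enthalpy_cols <- c("E_int", "E_ele", "E_vdw", "G_gb", "G_sa")
.entropy_cols <- c("TS_trans", "TS_rot", "TS_vib")
.energy_cols <- c("time_ps", .enthalpy_cols, .entropy_cols)

#' Construct an energy component series
#'
#' @param df data frame with a `time_ps` column, all enthalpy columns
#'   (E_int, E_ele, E_vdw, G_gb, G_sa) and optionally sparse entropy
#'   columns (TS_trans, TS_rot, TS_vib; NA allowed).
#' @param label system identifier (e.g. "WT complex").
#' @return `energy_series` data frame.
#' @export
energy_series <- function(df, label = "") {
  df <- as.data.frame(df)
  unknown <- setdiff(names(df), .energy_cols)
  if (length(unknown) > 0L)
    stop("unknown column(s): ", paste(unknown, collapse = ", "),
         "; accepted: ", paste(.energy_cols, collapse = ", "))
  missing_h <- setdiff(c("time_ps", .enthalpy_cols), names(df))
  if (length(missing_h) > 0L)
    stop("missing required column(s): ", paste(missing_h, collapse = ", "))
  if (any(diff(df$time_ps) <= 0)) stop("time_ps must be strictly increasing")
  if (anyNA(df[.enthalpy_cols]))
    stop("missing values are not allowed in enthalpy columns")
  for (cc in .entropy_cols) if (is.null(df[[cc]])) df[[cc]] <- NA_real_
  df <- df[, .energy_cols]
  attr(df, "label") <- label
  class(df) <- c("energy_series", class(df))
  df
}

#' Read an energy component table
#'
#' TSV/CSV with a header naming the time column `time_ps` and any subset
#' of the component columns; the enthalpy components are required, the
#' entropy components may be absent or sparse.
#'
#' @param path file path (.csv comma-separated, otherwise whitespace/tab).
#' @param label system identifier.
#' @return `energy_series`.
#' @export
parse_energy_table <- function(path, label = basename(path)) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else ""
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = TRUE)
  energy_series(df, label)
}

#' Write an energy component table as TSV
#' @param series `energy_series`.
#' @param path output path.
#' @export
write_energy_table <- function(series, path) {
  utils::write.table(series, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

#' Per-frame total free-energy components
#'
#' Row-wise bookkeeping: `E_gas = E_int + E_ele + E_vdw`,
#' `H = E_gas + G_gb + G_sa`, `TS = TS_trans + TS_rot + TS_vib`,
#' `G = H - TS`. TS and G are NA on frames lacking entropy values.
#'
#' @param series `energy_series`.
#' @return data.frame(time_ps, E_gas, H, TS, G).
#' @export
total_free_energy <- function(series) {
  stopifnot(inherits(series, "energy_series"))
  E_gas <- series$E_int + series$E_ele + series$E_vdw
  H <- E_gas + series$G_gb + series$G_sa
  TS <- series$TS_trans + series$TS_rot + series$TS_vib
  data.frame(time_ps = series$time_ps, E_gas = E_gas, H = H,
             TS = TS, G = H - TS)
}

#' Standard error of a correlated time-series mean (Straatsma)
#'
#' error^2 = (var/T) * (1 + 2 * sum_k rho_k), with the autocorrelation sum
#' truncated at the first non-positive ordinate (initial-positive-sequence
#' rule). The truncated sum is reported as the correlation length tau in
#' frames; for uncorrelated data the error reduces to sd/sqrt(T), and for
#' an AR(1) series with lag-1 autocorrelation phi it approaches the
#' closed form (sd/sqrt(T)) * sqrt((1 + phi)/(1 - phi)).
#'
#' @param x numeric series (length >= 10; a constant series gives error 0).
#' @param method only `"straatsma"`.
#' @return `fe_estimate`: list(mean, error, tau, n, var).
#' @export
estimate_with_error <- function(x, method = "straatsma") {
  method <- match.arg(method, "straatsma")
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 10L) stop("series too short (need >= 10 values)")
  v <- stats::var(x)
  if (v < .Machine$double.eps * max(1, mean(x)^2)) {
    return(structure(list(mean = mean(x), error = 0, tau = 0, n = n, var = 0),
                     class = "fe_estimate"))
  }
  lag_max <- min(n - 1L, 256L)
  repeat {
    rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                                 demean = TRUE)$acf)[-1L]
    cut <- which(rho <= 0)[1L]
    if (!is.na(cut) || lag_max >= n - 1L) break
    lag_max <- min(n - 1L, lag_max * 4L)
  }
  s <- if (is.na(cut)) sum(rho) else if (cut == 1L) 0 else sum(rho[seq_len(cut - 1L)])
  err <- sqrt(v / n * (1 + 2 * s))
  structure(list(mean = mean(x), error = err, tau = s, n = n, var = v),
            class = "fe_estimate")
}

#' @export
print.fe_estimate <- function(x, ...) {
  cat(sprintf("%.4f +/- %.4f (n = %d, tau = %.2f frames)\n",
              x$mean, x$error, x$n, x$tau))
  invisible(x)
}

# single-point series (n < 10) get mean with zero error
.estimate_or_point <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0L) return(NULL)
  if (length(x) >= 10L) estimate_with_error(x)
  else structure(list(mean = mean(x), error = 0, tau = 0,
                      n = length(x), var = if (length(x) > 1L) stats::var(x) else 0),
                 class = "fe_estimate")
}

#' Error-bearing averages of a free-energy series
#'
#' Straatsma estimates for every component and for the derived totals
#' E_gas, H, TS and G. Entropy columns are averaged over their own
#' (possibly sparser) frame set; when entropy and enthalpy live on
#' different frame grids the G error combines the H and TS errors in
#' quadrature, otherwise G is estimated directly from its per-frame
#' series. Without any entropy data TS is dropped and G = H.
#'
#' @param series `energy_series`.
#' @return `free_energy_estimate`: list(G, H, TS, components, label).
#' @export
estimate_free_energy <- function(series) {
  stopifnot(inherits(series, "energy_series"))
  tot <- total_free_energy(series)
  comp <- lapply(c(.enthalpy_cols), function(cc) .estimate_or_point(series[[cc]]))
  names(comp) <- .enthalpy_cols
  comp$E_gas <- .estimate_or_point(tot$E_gas)
  H <- .estimate_or_point(tot$H)
  ts_rows <- which(!is.na(tot$TS))
  if (length(ts_rows) == 0L) {
    TS <- structure(list(mean = 0, error = 0, tau = 0, n = 0L, var = 0),
                    class = "fe_estimate")
    G <- H
  } else {
    TS <- .estimate_or_point(tot$TS[ts_rows])
    if (length(ts_rows) == nrow(tot)) {
      G <- .estimate_or_point(tot$G)
    } else {
      G <- structure(list(mean = H$mean - TS$mean,
                          error = sqrt(H$error^2 + TS$error^2),
                          tau = NA_real_, n = H$n, var = NA_real_),
                     class = "fe_estimate")
    }
  }
  structure(list(G = G, H = H, TS = TS, components = comp,
                 label = attr(series, "label")),
            class = "free_energy_estimate")
}

#' Thermodynamic stability difference between two systems
#'
#' Differences mutant - wild-type for G, H and TS, with the two statistical
#' errors combined in quadrature. A more negative delta-G means the mutant
#' is the more stable form.
#'
#' @param estimate_mut,estimate_wt `free_energy_estimate`s.
#' @return data.frame(quantity, delta, error).
#' @export
stability_change <- function(estimate_mut, estimate_wt) {
  stopifnot(inherits(estimate_mut, "free_energy_estimate"),
            inherits(estimate_wt, "free_energy_estimate"))
  qn <- c("G", "H", "TS")
  data.frame(
    quantity = qn,
    delta = vapply(qn, function(q) estimate_mut[[q]]$mean - estimate_wt[[q]]$mean,
                   numeric(1L)),
    error = vapply(qn, function(q) sqrt(estimate_mut[[q]]$error^2 +
                                        estimate_wt[[q]]$error^2),
                   numeric(1L)),
    row.names = NULL)
}

.cycle_quantities <- c("G", "H", "TS", "E_gas", "G_gb", "G_sa")

.leg_value <- function(est, q) {
  if (q %in% c("G", "H", "TS")) est[[q]] else est$components[[q]]
}

#' Binding thermodynamic cycle across two forms
#'
#' For each form (wild-type, mutant) the binding free energy is
#' `delta-G_bind = G_complex - G_receptor - G_ligand` (same bookkeeping
#' for H, TS and the components E_gas, G_gb, G_sa), and the mutational
#' difference is `delta-delta-G = delta-G_bind(mutant) -
#' delta-G_bind(wild-type)`; delta-delta-H decomposes exactly as
#' delta-delta-E_gas + delta-delta-G_gb + delta-delta-G_sa. Errors are
#' propagated in quadrature at every step. Single-point legs (one-frame
#' series) are allowed and carry zero error. A negative delta-delta-G
#' means the ligand is more tightly bound in the wild-type.
#'
#' @param wt,mut named lists with legs `complex`, `receptor`, `ligand`,
#'   each an `energy_series` or `free_energy_estimate`.
#' @return `binding_cycle`: list(binding = per-form data frame,
#'   difference = data.frame(quantity, value, error)).
#' @export
binding_cycle <- function(wt, mut) {
  forms <- list(WT = wt, MU = mut)
  legs <- c("complex", "receptor", "ligand")
  est <- lapply(names(forms), function(fn) {
    f <- forms[[fn]]
    lapply(legs, function(lg) {
      x <- f[[lg]]
      if (is.null(x)) stop("missing leg: ", lg, " (", fn, ")")
      if (inherits(x, "energy_series")) x <- estimate_free_energy(x)
      if (!inherits(x, "free_energy_estimate"))
        stop("leg ", lg, " (", fn, ") is not an energy series or estimate")
      x
    })
  })
  names(est) <- names(forms)
  for (fn in names(est)) names(est[[fn]]) <- legs
  binding <- do.call(rbind, lapply(names(est), function(fn) {
    do.call(rbind, lapply(.cycle_quantities, function(q) {
      vals <- lapply(est[[fn]], .leg_value, q = q)
      data.frame(form = fn, quantity = q,
                 value = vals$complex$mean - vals$receptor$mean - vals$ligand$mean,
                 error = sqrt(vals$complex$error^2 + vals$receptor$error^2 +
                              vals$ligand$error^2))
    }))
  }))
  rownames(binding) <- NULL
  difference <- do.call(rbind, lapply(.cycle_quantities, function(q) {
    w <- binding[binding$form == "WT" & binding$quantity == q, ]
    m <- binding[binding$form == "MU" & binding$quantity == q, ]
    data.frame(quantity = q, value = m$value - w$value,
               error = sqrt(m$error^2 + w$error^2))
  }))
  rownames(difference) <- NULL
  structure(list(binding = binding, difference = difference),
            class = "binding_cycle")
}

#' @export
print.binding_cycle <- function(x, ...) {
  cat("binding cycle (mutant - wild-type differences, kcal/mol):\n")
  print(x$difference, row.names = FALSE)
  invisible(x)
}
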