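#' Builtin conformer predictions for dulcin
#'
#' The MP2/6-311++G(d,p) predictions for the four lowest-energy conformers
#' of the artificial sweetener dulcin (p-ethoxyphenylurea): rotational
#' constants (MHz), electric dipole moment component magnitudes (D), and
#' relative energies (cm^-1): electronic (`dE`), zero-point corrected
#' (`dE_zpe`), and Gibbs at 298 K (`dG`).
#'
#' @return Data frame with one row per conformer (I-IV).
#' @export
dulcin_conformers <- function() {
  data.frame(
    id = c("I", "II", "III", "IV"),
    A = c(2787, 3068, 2832, 2394),
    B = c(312, 304, 311, 339),
    C = c(292, 290, 286, 322),
    mu_a = c(4.9, 5.1, 0.6, 4.6),
    mu_b = c(0.9, 0.8, 1.4, 1.2),
    mu_c = c(0.9, 1.5, 1.9, 1.1),
    dE = c(0, 21, 399, 356),
    dE_zpe = c(0, 6, 374, 414),
    dG = c(9, 0, 399, 489),
    stringsAsFactors = FALSE)
}

#' Experimentally fitted rotamer constants for dulcin
#'
#' The two rotameric species identified in the jet-cooled broadband
#' rotational spectrum of dulcin, with fitted Watson A-reduced constants
#' (MHz), their standard errors, the RMS of each fit (kHz) and the number of
#' fitted transitions. Rotamer 1 was assigned to conformer II and rotamer 2
#' to conformer IV.
#'
#' @return Data frame with one row per rotamer.
#' @export
dulcin_rotamers <- function() {
  data.frame(
    id = c("rotamer1", "rotamer2"),
    A = c(3052.1532, 2413.98), A_se = c(0.0053, 0.76),
    B = c(304.82621, 336.70893), B_se = c(0.00033, 0.00042),
    C = c(292.43629, 319.08422), C_se = c(0.00032, 0.00042),
    DJ = c(0.00589, 0.0116), DJ_se = c(0.00093, 0.0017),
    DJK = c(-0.128, -0.135), DJK_se = c(0.017, 0.084),
    sigma_kHz = c(9.1, 6.3),
    N = c(52L, 16L),
    assigned_conformer = c("II", "IV"),
    stringsAsFactors = FALSE)
}

#' Filter conformers by a relative-energy window
#'
#' @param records Conformer data frame (e.g. [dulcin_conformers()]).
#' @param window Energy window in cm^-1 (exclusive upper bound).
#' @param field Energy column to use: `"dE"`, `"dE_zpe"` or `"dG"`.
#' @return The subset of rows with `field < window`, order preserved.
#' @export
window_filter <- function(records, window, field = "dE_zpe") {
  if (!field %in% names(records)) stop("unknown energy field: ", field)
  records[records[[field]] < window, , drop = FALSE]
}

# Energy-field precedence for population estimates: Gibbs if available,
# else ZPE-corrected, else electronic.
default_energy_field <- function(records) {
  for (f in c("dG", "dE_zpe", "dE")) if (f %in% names(records)) return(f)
  stop("no relative-energy column in conformer records")
}

#' Boltzmann population fractions of conformers
#'
#' `fraction_i = exp(-E_i/kT) / sum_j exp(-E_j/kT)` with
#' k = 0.6950348 cm^-1/K. These are pre-expansion (equilibrium) fractions;
#' collisional relaxation in the jet is modelled separately by
#' [relax_fractions()].
#'
#' @param records Conformer data frame with an `id` column.
#' @param T Temperature in K (> 0).
#' @param field Energy column (cm^-1); default follows the precedence
#'   dG > dE_zpe > dE.
#' @return Named numeric vector of fractions (sums to 1).
#' @export
boltzmann_fractions <- function(records, T = 298, field = NULL) {
  if (T <= 0) stop("temperature must be positive")
  if (is.null(field)) field <- default_energy_field(records)
  if (!field %in% names(records)) stop("unknown energy field: ", field)
  E <- records[[field]]
  w <- exp(-(E - min(E)) / (KB_CM1_PER_K * T))
  stats::setNames(w / sum(w), records$id)
}

#' Relaxation edges between conformers
#'
#' @param from,to Conformer ids: relaxation is directed from the
#'   higher-energy conformer (`from`) to the lower (`to`).
#' @param barrier Forward interconversion barriers in cm^-1 (>= 0).
#' @return Data frame of edges.
#' @export
relaxation_edges <- function(from, to, barrier) {
  if (any(barrier < 0)) stop("barriers must be non-negative")
  data.frame(from = from, to = to, barrier = barrier, stringsAsFactors = FALSE)
}

#' Collisional relaxation of jet populations
#'
#' Applies the barrier-threshold rule for conformational cooling in a
#' supersonic expansion: a higher-energy conformer relaxes completely into a
#' lower-energy one when their interconversion barrier is below the
#' threshold (default 400 cm^-1, the empirical rule for collisional removal
#' in rare-gas jets). Transfers are applied repeatedly until stable, so
#' relaxation chains (III -> I -> II) drain correctly; the total population
#' is conserved exactly and the operation is idempotent.
#'
#' @param fractions Named fractions from [boltzmann_fractions()].
#' @param edges Data frame from [relaxation_edges()].
#' @param threshold Barrier threshold in cm^-1.
#' @return Named fractions after relaxation (same ids, same order).
#' @export
relax_fractions <- function(fractions, edges, threshold = 400) {
  if (!nrow(edges)) return(fractions)
  if (!all(c(edges$from, edges$to) %in% names(fractions)))
    stop("edge references unknown conformer id")
  active <- edges[edges$barrier < threshold, , drop = FALSE]
  out <- fractions
  for (pass in seq_len(nrow(active) + 1L)) {
    moved <- FALSE
    for (i in seq_len(nrow(active))) {
      f <- active$from[i]; t <- active$to[i]
      if (out[f] > 0) {
        out[t] <- out[t] + out[f]
        out[f] <- 0
        moved <- TRUE
      }
    }
    if (!moved) return(out)
  }
  stop("relaxation did not stabilize: cyclic edges?")
}

#' Interconversion barrier from a scanned energy surface
#'
#' Reads the barrier between two minima off a scanned (1D or 2D) torsional
#' energy grid as the minimax path energy: the minimum over all grid paths
#' of the path's maximum energy, minus the start energy. Connectivity is
#' 4-neighbour with periodic wrap in each torsion angle. Exact for the given
#' grid resolution (computed by a widest-path Dijkstra variant).
#'
#' @param grid An `energy_grid`: list with `energy` (numeric vector for 1D
#'   scans or matrix for 2D), optionally `axis1`, `axis2` (angles, degrees).
#'   A bare vector or matrix is accepted. Non-finite entries block paths.
#' @param start,end Node indices: scalar index for 1D, `c(row, col)` for 2D.
#' @param periodic Wrap connectivity (default TRUE; torsions are periodic).
#' @return Barrier in the grid's energy units (cm^-1 for torsional scans).
#' @export
barrier_minimax <- function(grid, start, end, periodic = TRUE) {
  E <- if (is.list(grid)) grid$energy else grid
  if (is.null(dim(E))) E <- matrix(E, nrow = 1)
  nr <- nrow(E); nc <- ncol(E)
  id <- function(r, c) (c - 1L) * nr + r
  if (length(start) == 1) start <- c(1L, start)
  if (length(end) == 1) end <- c(1L, end)
  s <- id(start[1], start[2]); t <- id(end[1], end[2])
  if (!is.finite(E[s]) || !is.finite(E[t])) stop("start/end energy not finite")

  n <- nr * nc
  best <- rep(Inf, n)        # minimal achievable path maximum to each node
  best[s] <- E[s]
  visited <- rep(FALSE, n)
  nbr <- function(r, c) {
    out <- list()
    cand <- rbind(c(r - 1L, c), c(r + 1L, c), c(r, c - 1L), c(r, c + 1L))
    for (k in seq_len(4)) {
      rr <- cand[k, 1]; cc <- cand[k, 2]
      if (periodic) {
        rr <- ((rr - 1L) %% nr) + 1L
        cc <- ((cc - 1L) %% nc) + 1L
      } else if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      out[[length(out) + 1L]] <- c(rr, cc)
    }
    out
  }
  repeat {
    u <- which(!visited & is.finite(best))
    if (!length(u)) break
    u <- u[which.min(best[u])]
    if (u == t) break
    visited[u] <- TRUE
    r <- ((u - 1L) %% nr) + 1L
    c <- ((u - 1L) %/% nr) + 1L
    for (v in nbr(r, c)) {
      j <- id(v[1], v[2])
      if (visited[j] || !is.finite(E[j])) next
      cand <- max(best[u], E[j])
      if (cand < best[j]) best[j] <- cand
    }
  }
  if (!is.finite(best[t]))
    stop("grid disconnected: no finite-energy path between start and end")
  best[t] - E[s]
}

#' Detectability score of conformers in a jet spectrum
#'
#' Expected relative a-type intensity per conformer:
#' `score_i = fraction_i * mu_a_i^2`, normalised to the strongest. A
#' conformer is flagged detectable when its relative score exceeds
#' `noise_floor`. This captures why a weak-dipole conformer can escape
#' detection even at appreciable population.
#'
#' @param records Conformer data frame with `mu_a`.
#' @param fractions Named population fractions (e.g. post-relaxation).
#' @param noise_floor Relative instrument sensitivity threshold.
#' @return Data frame with `id`, `fraction`, `mu_a`, `score`,
#'   `rel_score`, `detectable`.
#' @export
detectability <- function(records, fractions, noise_floor = 0.01) {
  fr <- fractions[records$id]
  score <- fr * records$mu_a^2
  rel <- if (max(score) > 0) score / max(score) else score
  data.frame(id = records$id, fraction = as.numeric(fr), mu_a = records$mu_a,
             score = as.numeric(score), rel_score = as.numeric(rel),
             detectable = as.numeric(rel) > noise_floor,
             stringsAsFactors = FALSE)
}

#' Read / write torsional energy-surface grids
#'
#' CSV with columns `angle1, angle2, energy` (degrees, degrees, cm^-1) for
#' 2D scans, or `angle1, energy` for 1D. Angles must form a regular grid on
#' `[0, 360)`.
#'
#' @param path File path.
#' @return An `energy_grid` list with `axis1`, `axis2` (or `NULL`), `energy`
#'   (vector or matrix indexed `[axis1, axis2]`).
#' @export
read_energy_grid <- function(path) {
  d <- utils::read.csv(path, comment.char = "#")
  if (!"energy" %in% names(d)) stop("energy grid needs an 'energy' column")
  if ("angle2" %in% names(d)) {
    a1 <- sort(unique(d$angle1)); a2 <- sort(unique(d$angle2))
    E <- matrix(NA_real_, length(a1), length(a2))
    E[cbind(match(d$angle1, a1), match(d$angle2, a2))] <- d$energy
    if (anyNA(E)) stop("incomplete 2D grid")
    list(axis1 = a1, axis2 = a2, energy = E)
  } else {
    o <- order(d$angle1)
    list(axis1 = d$angle1[o], axis2 = NULL, energy = d$energy[o])
  }
}
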