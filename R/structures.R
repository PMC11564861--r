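# Most-abundant-isotope masses (amu), sufficient for typical organics.
ATOMIC_MASSES <- c(
  H = 1.00782503, D = 2.01410178, He = 4.00260325,
  Li = 7.01600344, Be = 9.01218307, B = 11.00930536,
  C = 12.0, N = 14.00307401, O = 15.99491462, F = 18.99840316,
  Ne = 19.99244018, Na = 22.98976928, Mg = 23.98504170,
  Al = 26.98153853, Si = 27.97692653, P = 30.97376200,
  S = 31.97207117, Cl = 34.96885268, Ar = 39.96238312,
  K = 38.96370649, Ca = 39.96259086, Br = 78.91833760, I = 126.90447290)

MHZ_AMU_A2 <- 505379.07   # conversion: X(MHz) = 505379.07 / I(amu A^2)

#' Molecular geometry
#'
#' A set of atoms with Cartesian coordinates in Angstrom. Masses default to
#' the most abundant isotope of each element (parent species).
#'
#' @param atoms Character vector of element symbols.
#' @param coordinates Numeric matrix, one row per atom, columns x, y, z (A).
#' @param masses Optional numeric vector of masses (amu); defaults from the
#'   element symbols.
#' @return Object of class `geometry`: list with `atoms`, `masses`,
#'   `coordinates`.
#' @export
geometry <- function(atoms, coordinates, masses = NULL) {
  coordinates <- as.matrix(coordinates)
  if (length(atoms) < 2) stop("a geometry needs at least 2 atoms")
  if (nrow(coordinates) != length(atoms) || ncol(coordinates) != 3)
    stop("coordinates must be an n x 3 matrix matching atoms")
  if (any(!is.finite(coordinates))) stop("coordinates must be finite")
  if (is.null(masses)) {
    masses <- ATOMIC_MASSES[atoms]
    if (anyNA(masses))
      stop("unknown element(s): ",
           paste(unique(atoms[is.na(masses)]), collapse = ", "))
  }
  if (any(masses <= 0)) stop("masses must be positive")
  dimnames(coordinates) <- list(NULL, c("x", "y", "z"))
  structure(list(atoms = atoms, masses = unname(masses),
                 coordinates = coordinates), class = "geometry")
}

#' Read / write XYZ files
#'
#' Standard XYZ dialect: atom count line, comment line, then one
#' `element x y z` row per atom (Angstrom).
#'
#' @param path File path.
#' @return `read_xyz` returns a [geometry()]; `write_xyz` returns `path`
#'   invisibly.
#' @export
read_xyz <- function(path) {
  raw <- readLines(path)
  if (length(raw) < 3) stop("XYZ file too short")
  n <- suppressWarnings(as.integer(trimws(raw[1])))
  if (is.na(n)) stop("line 1: expected atom count")
  rows <- raw[-(1:2)]
  rows <- rows[nzchar(trimws(rows))]
  if (length(rows) < n)
    stop(sprintf("atom count %d but only %d coordinate rows", n, length(rows)))
  rows <- rows[seq_len(n)]
  atoms <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    fields <- strsplit(trimws(rows[i]), "[[:space:]]+")[[1]]
    if (length(fields) < 4)
      stop(sprintf("row %d: expected 'element x y z'", i + 2L))
    atoms[i] <- fields[1]
    v <- suppressWarnings(as.numeric(fields[2:4]))
    if (anyNA(v)) stop(sprintf("row %d: non-numeric coordinate", i + 2L))
    xyz[i, ] <- v
  }
  if (any(!atoms %in% names(ATOMIC_MASSES)))
    stop("unknown element(s): ",
         paste(unique(atoms[!atoms %in% names(ATOMIC_MASSES)]), collapse = ", "))
  geometry(atoms, xyz)
}

#' @rdname read_xyz
#' @param g A [geometry()] to write.
#' @param comment Comment placed on line 2.
#' @export
write_xyz <- function(g, path, comment = "") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(as.character(length(g$atoms)), comment), con)
  writeLines(sprintf("%-3s %14.6f %14.6f %14.6f", g$atoms,
                     g$coordinates[, 1], g$coordinates[, 2],
                     g$coordinates[, 3]), con)
  invisible(path)
}

#' Rotational constants from a Cartesian geometry
#'
#' Translates to the centre of mass, diagonalizes the inertia tensor, and
#' converts principal moments to rotational constants via
#' `X(MHz) = 505379.07 / I(amu A^2)`. For a linear arrangement the moment
#' about the axis vanishes and A is reported as `Inf`.
#'
#' @param g A [geometry()].
#' @return List with `constants` ([rotational_constants()] or, for a linear
#'   molecule, a named vector with `A = Inf`), `moments` (principal moments
#'   Ia <= Ib <= Ic, amu A^2), and `axes` (3x3 rotation matrix whose rows
#'   a, b, c express the principal axes in the input frame).
#' @export
constants_from_geometry <- function(g) {
  m <- g$masses
  xyz <- sweep(g$coordinates, 2, colSums(g$coordinates * m) / sum(m))
  x <- xyz[, 1]; y <- xyz[, 2]; z <- xyz[, 3]
  I <- matrix(c(sum(m * (y^2 + z^2)), -sum(m * x * y), -sum(m * x * z),
                -sum(m * x * y), sum(m * (x^2 + z^2)), -sum(m * y * z),
                -sum(m * x * z), -sum(m * y * z), sum(m * (x^2 + y^2))),
              3, 3)
  e <- eigen(I, symmetric = TRUE)
  mom <- rev(e$values)                    # ascending: Ia <= Ib <= Ic
  axes <- t(e$vectors[, 3:1])             # rows a, b, c
  if (det(axes) < 0) axes[3, ] <- -axes[3, ]   # keep right-handed
  tol <- 1e-10 * max(mom)
  if (mom[1] <= tol) {
    cs <- c(A = Inf, B = MHZ_AMU_A2 / mom[2], C = MHZ_AMU_A2 / mom[3])
  } else {
    cs <- rotational_constants(MHZ_AMU_A2 / mom[1], MHZ_AMU_A2 / mom[2],
                               MHZ_AMU_A2 / mom[3])
  }
  list(constants = cs, moments = c(Ia = mom[1], Ib = mom[2], Ic = mom[3]),
       axes = axes)
}

#' Dipole vector in the principal axis frame
#'
#' Rotates a dipole vector given in the input (e.g. quantum-chemistry
#' output) frame into the principal inertial frame of the geometry and
#' returns component magnitudes — the observable quantities in rotational
#' intensities.
#'
#' @param g A [geometry()].
#' @param dipole_vector Numeric length-3 dipole vector (Debye) in the same
#'   frame as the coordinates.
#' @return A [dipole_moment()] with components |mu_a|, |mu_b|, |mu_c|.
#' @export
dipole_in_principal_axes <- function(g, dipole_vector) {
  ax <- constants_from_geometry(g)$axes
  v <- as.numeric(ax %*% as.numeric(dipole_vector))
  dipole_moment(abs(v[1]), abs(v[2]), abs(v[3]))
}

#' Match experimental rotational constants to predicted conformers
#'
#' For each candidate conformer, computes per-constant scale factors
#' (experimental / theoretical); the best match minimizes the maximum
#' deviation of the three ratios from 1. An advisory dipole-consistency
#' check compares which dipole types were observed against the predicted
#' component magnitudes (threshold `mu_obs` for "should be observable"); it
#' never overrides the constants-based ranking.
#'
#' @param experimental [rotational_constants()] (or coercible).
#' @param table Conformer table: data frame with columns `id, A, B, C` and
#'   optionally `mu_a, mu_b, mu_c` (e.g. [dulcin_conformers()]).
#' @param observed_types Optional character vector among "a","b","c" naming
#'   the dipole types actually observed, for the advisory check.
#' @param mu_obs Dipole magnitude (D) above which a component is expected
#'   observable.
#' @return Object of class `match_report`: list with `best` (id),
#'   `scale_factors` (ratios for the best match), `candidates` (all ids with
#'   ratios and scores), `dipole_check` (data frame, or `NULL`).
#' @export
match_conformers <- function(experimental, table, observed_types = NULL,
                             mu_obs = 0.5) {
  if (!nrow(table)) stop("empty conformer table")
  exp <- as_rotconst(experimental)
  ratios <- cbind(A = exp[["A"]] / table$A, B = exp[["B"]] / table$B,
                  C = exp[["C"]] / table$C)
  score <- apply(abs(ratios - 1), 1, max)
  best <- which.min(score)
  dip <- NULL
  if (!is.null(observed_types) && all(c("mu_a", "mu_b", "mu_c") %in% names(table))) {
    mu <- as.numeric(table[best, c("mu_a", "mu_b", "mu_c")])
    dip <- data.frame(type = c("a", "b", "c"), predicted = mu,
                      expected_observable = mu >= mu_obs,
                      observed = c("a", "b", "c") %in% observed_types)
    dip$consistent <- dip$observed == dip$expected_observable |
      (dip$observed & !dip$expected_observable)  # seeing a weak line is fine
  }
  structure(list(best = table$id[best],
                 scale_factors = ratios[best, ],
                 candidates = data.frame(id = table$id, ratios, score = score),
                 dipole_check = dip),
            class = "match_report")
}

#' @export
print.match_report <- function(x, ...) {
  cat("Best-matching conformer:", x$best, "\n")
  cat("Scale factors (exp/theory): ",
      paste(sprintf("%s = %.4f", names(x$scale_factors), x$scale_factors),
            collapse = ", "), "\n")
  cat("\nAll candidates:\n")
  print(x$candidates, row.names = FALSE)
  if (!is.null(x$dipole_check)) {
    cat("\nDipole consistency (advisory):\n")
    print(x$dipole_check, row.names = FALSE)
  }
  invisible(x)
}

#' Evaluate the glucophore (sweetness triangle) of a geometry
#'
#' Computes the AH/B/gamma three-point contact of the
#' Shallenberger-Acree-Kier sweetness model: the proton-donor heavy atom
#' (AH), the proton acceptor (B) and the hydrophobic site (gamma), with
#' their pairwise distances. Compliance follows the classic criterion that
#' the two electronegative atoms A and B be separated by 2.5 to 4 Angstrom
#' (applied to the heavy-atom A...B distance).
#'
#' @param g A [geometry()].
#' @param AH Integer length-2: indices of the donor heavy atom and its
#'   bonded hydrogen (checked to be within 1.3 A).
#' @param B Integer index of the acceptor atom.
#' @param gamma Integer index, or vector of indices whose centroid is used
#'   (e.g. an aromatic ring).
#' @param window Compliance window for the A...B distance (A).
#' @return Object of class `glucophore`: list with the three distances
#'   (`d_AH_B`, `d_AH_gamma`, `d_B_gamma`, A), the site definitions and the
#'   `compliant` flag.
#' @export
glucophore_triangle <- function(g, AH, B, gamma, window = c(2.5, 4.0)) {
  xyz <- g$coordinates
  n <- nrow(xyz)
  idx <- c(AH, B, gamma)
  if (any(idx < 1 | idx > n | idx != round(idx))) stop("atom index out of range")
  if (length(AH) != 2) stop("AH must be (donor heavy atom, donor hydrogen)")
  dhb <- sqrt(sum((xyz[AH[1], ] - xyz[AH[2], ])^2))
  if (dhb >= 1.3)
    stop(sprintf("donor H is %.2f A from the donor heavy atom (not bonded)", dhb))
  a <- xyz[AH[1], ]
  b <- xyz[B, ]
  gm <- if (length(gamma) > 1) colMeans(xyz[gamma, , drop = FALSE]) else xyz[gamma, ]
  d <- function(p, q) sqrt(sum((p - q)^2))
  d_ab <- d(a, b); d_ag <- d(a, gm); d_bg <- d(b, gm)
  if (min(d_ab, d_ag, d_bg) < 1e-6)
    stop("degenerate glucophore: coincident sites")
  structure(list(AH = AH, B = B, gamma = gamma,
                 d_AH_B = d_ab, d_AH_gamma = d_ag, d_B_gamma = d_bg,
                 window = window,
                 compliant = d_ab >= window[1] & d_ab <= window[2]),
            class = "glucophore")
}

#' @export
print.glucophore <- function(x, ...) {
  cat("Glucophore triangle (distances in Angstrom):\n")
  cat(sprintf("  AH...B     %.3f\n  AH...gamma %.3f\n  B...gamma  %.3f\n",
              x$d_AH_B, x$d_AH_gamma, x$d_B_gamma))
  cat(sprintf("  AH-B within [%.1f, %.1f] A: %s\n", x$window[1], x$window[2],
              if (x$compliant) "compliant" else "NOT compliant"))
  invisible(x)
}

#' Read / write conformer tables
#'
#' Tab- or whitespace-separated table with header columns
#' `id A B C mu_a mu_b mu_c dE dE_zpe dG` (constants MHz, dipoles Debye,
#' energies cm^-1 relative to the global minimum). Missing energy columns
#' are allowed as long as one is present.
#'
#' @param path File path.
#' @return `read_conformer_table` returns a data frame.
#' @export
read_conformer_table <- function(path) {
  d <- utils::read.table(path, header = TRUE, comment.char = "#",
                         stringsAsFactors = FALSE)
  need <- c("id", "A", "B", "C")
  if (!all(need %in% names(d)))
    stop("conformer table must have columns: ", paste(need, collapse = ", "))
  if (!any(c("dE", "dE_zpe", "dG") %in% names(d)))
    warning("conformer table has no relative-energy column")
  d
}

#' @rdname read_conformer_table
#' @param table Data frame to write.
#' @export
write_conformer_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
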