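#' Rotational constants of a (semi-)rigid rotor
#'
#' Constructs a validated set of rotational constants in MHz. The constants
#' are the reciprocal principal moments of inertia in frequency units; by
#' convention `A >= B >= C`, and the constructor reorders its arguments to
#' enforce this.
#'
#' @param A,B,C Rotational constants in MHz. All must be positive and finite.
#' @return An object of class `rotconst`: a named numeric vector with
#'   elements `A`, `B`, `C` satisfying `A >= B >= C > 0`.
#' @examples
#' rotational_constants(3052.1532, 304.82621, 292.43629)
#' @export
rotational_constants <- function(A, B, C) {
  v <- c(A = as.numeric(A), B = as.numeric(B), C = as.numeric(C))
  if (anyNA(v) || any(!is.finite(v))) stop("rotational constants must be finite")
  if (any(v <= 0)) stop("rotational constants must be positive")
  v <- sort(v, decreasing = TRUE)
  names(v) <- c("A", "B", "C")
  structure(v, class = "rotconst")
}

#' Quartic centrifugal-distortion constants (Watson A-reduction)
#'
#' The five quartic distortion constants of the Watson A-reduced semi-rigid
#' rotor Hamiltonian, in MHz. All default to zero (rigid rotor). Five-parameter
#' fits of near-prolate spectra typically float only `DJ` and `DJK` and hold
#' `DK`, `dJ`, `dK` at zero.
#'
#' @param DJ,DJK,DK,dJ,dK Quartic distortion constants in MHz.
#' @param B Optional rotational constant B (MHz) used for a sanity warning:
#'   quartic constants are perturbations and should be tiny relative to B.
#' @return An object of class `quartic`: named numeric vector
#'   `(DJ, DJK, DK, dJ, dK)`.
#' @examples
#' quartic_distortion(DJ = 0.00589, DJK = -0.128)
#' @export
quartic_distortion <- function(DJ = 0, DJK = 0, DK = 0, dJ = 0, dK = 0, B = NULL) {
  v <- c(DJ = as.numeric(DJ), DJK = as.numeric(DJK), DK = as.numeric(DK),
         dJ = as.numeric(dJ), dK = as.numeric(dK))
  if (anyNA(v) || any(!is.finite(v))) stop("distortion constants must be finite")
  if (!is.null(B) && abs(v[["DJ"]]) > 1e-2 * B)
    warning("|DJ| exceeds 1% of B; quartic terms should be small perturbations")
  structure(v, class = "quartic")
}

# Coerce loose inputs (named vectors/lists) to the two constant classes.
as_rotconst <- function(x) {
  if (inherits(x, "rotconst")) return(x)
  rotational_constants(x[["A"]], x[["B"]], x[["C"]])
}

as_quartic <- function(x) {
  if (is.null(x)) return(quartic_distortion())
  if (inherits(x, "quartic")) return(x)
  x <- as.list(x)
  pick <- function(n) if (!is.null(x[[n]])) x[[n]] else 0
  quartic_distortion(pick("DJ"), pick("DJK"), pick("DK"), pick("dJ"), pick("dK"))
}

#' Ray's asymmetry parameter
#'
#' kappa = (2B - A - C) / (A - C), ranging from -1 at the prolate
#' symmetric-top limit (B = C) to +1 at the oblate limit (A = B).
#'
#' @param constants A [rotational_constants()] object (or coercible).
#' @return Dimensionless kappa in `[-1, 1]`.
#' @examples
#' asymmetry_kappa(rotational_constants(3052.1532, 304.82621, 292.43629))
#' @export
asymmetry_kappa <- function(constants) {
  cst <- as_rotconst(constants)
  if (cst[["A"]] - cst[["C"]] <= 0)
    stop("asymmetry parameter undefined for a spherical top (A == C)")
  unname((2 * cst[["B"]] - cst[["A"]] - cst[["C"]]) / (cst[["A"]] - cst[["C"]]))
}

# Watson A-reduced Hamiltonian matrix for one J block, I^r representation
# (z = a axis), in the signed-K symmetric-top basis K = -J..J.
# H is real symmetric with only K +/- 2 off-diagonal elements.
watson_matrix <- function(J, cst, dst) {
  A <- cst[["A"]]; B <- cst[["B"]]; C <- cst[["C"]]
  DJ <- dst[["DJ"]]; DJK <- dst[["DJK"]]; DK <- dst[["DK"]]
  dJ <- dst[["dJ"]]; dK <- dst[["dK"]]
  K <- seq.int(-J, J)
  JJ <- J * (J + 1)
  n <- 2L * J + 1L
  H <- matrix(0, n, n)
  diag(H) <- 0.5 * (B + C) * (JJ - K^2) + A * K^2 -
    DJ * JJ^2 - DJK * JJ * K^2 - DK * K^4
  if (J >= 1) {
    for (i in seq_len(n - 2L)) {
      k <- K[i]
      f <- sqrt((JJ - k * (k + 1)) * (JJ - (k + 1) * (k + 2)))
      off <- (0.25 * (B - C) - dJ * JJ - 0.5 * dK * (k^2 + (k + 2)^2)) * f
      H[i, i + 2L] <- off
      H[i + 2L, i] <- off
    }
  }
  H
}

# Eigen-solve one J block via Wang symmetrization. The signed-K basis is
# transformed to Wang combinations (|K> + g|-K>)/sqrt(2) (g = +/-1), under
# which H splits into four blocks (even/odd K, g = +/-). Diagonalizing per
# block keeps eigenvectors parity-pure even for numerically degenerate
# asymmetry doublets. Within a block, ascending eigenvalues follow the Ka
# ladder of that block, and the Wang sign fixes Kc exactly:
# g = + states have Ka + Kc = J, g = - states have Ka + Kc = J + 1.
# Returns energies ascending with labels and the eigenvector matrix in the
# signed-K basis (column i belongs to state i; basis rows K = -J..J).
solve_block <- function(J, cst, dst) {
  if (J == 0L) {
    return(list(states = data.frame(J = 0L, Ka = 0L, Kc = 0L, energy = 0),
                vectors = matrix(1, 1, 1)))
  }
  B <- cst[["B"]]; C <- cst[["C"]]
  dJ <- dst[["dJ"]]; dK <- dst[["dK"]]
  JJ <- J * (J + 1)
  Hfull <- watson_matrix(J, cst, dst)
  hdiag <- diag(Hfull)[(0:J) + J + 1L]          # diagonal for K = 0..J
  hoff <- function(k)                            # K <-> K+2 coupling, k >= 0
    (0.25 * (B - C) - dJ * JJ - 0.5 * dK * (k^2 + (k + 2)^2)) *
      sqrt((JJ - k * (k + 1)) * (JJ - (k + 1) * (k + 2)))
  h1m1 <- (0.25 * (B - C) - dJ * JJ - dK) * JJ   # <K=1|H|K=-1> element

  n <- 2L * J + 1L
  energies <- numeric(n)
  Ka_lab <- integer(n)
  Kc_lab <- integer(n)
  vectors <- matrix(0, n, n)
  pos <- 0L
  for (par in c(0L, 1L)) {
    Ks <- seq.int(par, J, by = 2L)
    if (!length(Ks)) next
    for (g in c(1, -1)) {
      bK <- if (par == 0L && g == -1) Ks[Ks > 0L] else Ks
      if (!length(bK)) next
      m <- length(bK)
      Hb <- matrix(0, m, m)
      diag(Hb) <- hdiag[bK + 1L]
      if (par == 1L) Hb[1, 1] <- Hb[1, 1] + g * h1m1
      if (m >= 2) {
        for (i in seq_len(m - 1L)) {
          o <- hoff(bK[i])
          if (bK[i] == 0L) o <- o * sqrt(2)      # K=0 couples to both +/-2
          Hb[i, i + 1L] <- o
          Hb[i + 1L, i] <- o
        }
      }
      e <- eigen(Hb, symmetric = TRUE)
      ord <- seq.int(m, 1L)                      # ascending
      val <- e$values[ord]
      vec <- e$vectors[, ord, drop = FALSE]
      for (i in seq_len(m)) {
        pos <- pos + 1L
        energies[pos] <- val[i]
        Ka_lab[pos] <- bK[i]                     # ascending <-> Ka ladder
        Kc_lab[pos] <- J - bK[i] + if (g == 1) 0L else 1L
        w <- vec[, i]
        full <- numeric(n)
        for (q in seq_len(m)) {
          K <- bK[q]
          if (K == 0L) full[J + 1L] <- w[q]
          else {
            full[K + J + 1L] <- w[q] / sqrt(2)
            full[-K + J + 1L] <- g * w[q] / sqrt(2)
          }
        }
        vectors[, pos] <- full
      }
    }
  }
  o <- order(energies, Ka_lab)
  list(states = data.frame(J = J, Ka = Ka_lab[o], Kc = Kc_lab[o],
                           energy = energies[o]),
       vectors = vectors[, o, drop = FALSE])
}

#' Semi-rigid asymmetric-rotor energy levels
#'
#' Energies of all `2J + 1` rotational states of one J block of the Watson
#' A-reduced Hamiltonian (I^r representation, z along the a axis), built in
#' the symmetric-top basis and diagonalized. States carry the standard
#' King-Hainer-Cross labels `J_{Ka,Kc}`, assigned along the prolate-oblate
#' correlation diagram (energies ascending within the block).
#'
#' @param constants A [rotational_constants()] object (or coercible).
#' @param distortion A [quartic_distortion()] object; `NULL` means rigid rotor.
#' @param J Non-negative integer rotational quantum number.
#' @return A data frame with columns `J`, `Ka`, `Kc`, `energy` (MHz), sorted
#'   by increasing energy; `Ka + Kc` is `J` or `J + 1` for every state.
#' @examples
#' cst <- rotational_constants(3052.1532, 304.82621, 292.43629)
#' energy_levels(cst, NULL, 1)  # B+C, A+C, A+B
#' @export
energy_levels <- function(constants, distortion = NULL, J) {
  if (length(J) != 1L || is.na(J) || J < 0 || J != round(J))
    stop("J must be a single non-negative integer")
  cst <- as_rotconst(constants)
  dst <- as_quartic(distortion)
  solve_block(as.integer(J), cst, dst)$states
}
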