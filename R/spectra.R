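# Physical constants used throughout (frequency units).
KB_MHZ_PER_K <- 20836.61912     # Boltzmann constant / Planck constant, MHz/K
KB_CM1_PER_K <- 0.6950348       # Boltzmann constant, cm^-1/K
CM1_TO_MHZ   <- 29979.2458      # 1 cm^-1 in MHz

#' Electric dipole moment components
#'
#' Magnitudes of the permanent dipole moment along the principal inertial
#' axes a, b, c, in Debye. Signs are not observable in rotational line
#' intensities, so magnitudes are stored.
#'
#' @param mu_a,mu_b,mu_c Component magnitudes in Debye (non-negative).
#' @return Object of class `dipole`: named numeric vector.
#' @examples
#' dipole_moment(5.1, 0.8, 1.5)
#' @export
dipole_moment <- function(mu_a = 0, mu_b = 0, mu_c = 0) {
  v <- c(mu_a = as.numeric(mu_a), mu_b = as.numeric(mu_b), mu_c = as.numeric(mu_c))
  if (anyNA(v) || any(!is.finite(v))) stop("dipole components must be finite")
  if (any(v < 0)) stop("dipole component magnitudes must be non-negative")
  structure(v, class = "dipole")
}

as_dipole <- function(x) {
  if (inherits(x, "dipole")) return(x)
  x <- as.list(x)
  pick <- function(n) if (!is.null(x[[n]])) x[[n]] else 0
  dipole_moment(pick("mu_a"), pick("mu_b"), pick("mu_c"))
}

# Wigner 3j symbol by the Racah factorial sum (log-factorials for stability).
# Integer or half-integer angular momenta; exact to double precision for the
# small j used in rotational spectra.
wigner3j <- function(j1, j2, j3, m1, m2, m3) {
  if (m1 + m2 + m3 != 0) return(0)
  if (j3 < abs(j1 - j2) || j3 > j1 + j2) return(0)
  if (abs(m1) > j1 || abs(m2) > j2 || abs(m3) > j3) return(0)
  lf <- function(n) lgamma(n + 1)
  delta <- 0.5 * (lf(j1 + j2 - j3) + lf(j1 - j2 + j3) + lf(-j1 + j2 + j3) -
                    lf(j1 + j2 + j3 + 1))
  pref <- 0.5 * (lf(j1 + m1) + lf(j1 - m1) + lf(j2 + m2) + lf(j2 - m2) +
                   lf(j3 + m3) + lf(j3 - m3))
  kmin <- max(0, j2 - j3 - m1, j1 - j3 + m2)
  kmax <- min(j1 + j2 - j3, j1 - m1, j2 + m2)
  if (kmax < kmin) return(0)
  k <- seq(kmin, kmax)
  terms <- (-1)^k * exp(delta + pref -
                          lf(k) - lf(j1 + j2 - j3 - k) - lf(j1 - m1 - k) -
                          lf(j2 + m2 - k) - lf(j3 - j2 + m1 + k) -
                          lf(j3 - j1 - m2 + k))
  (-1)^(j1 - j2 - m3) * sum(terms)
}

# Direction-cosine amplitude matrices between two J blocks for molecular-frame
# spherical dipole component sigma (-1, 0, +1), in the signed-K basis:
#   M[K'+Ju+1, K+Jl+1] = (-1)^(Ju-K') 3j(Ju 1 Jl; -K' sigma K), K' = K+sigma.
dipole_block <- function(Ju, Jl, sigma) {
  M <- matrix(0, 2 * Ju + 1, 2 * Jl + 1)
  for (K in seq.int(-Jl, Jl)) {
    Kp <- K + sigma
    if (abs(Kp) > Ju) next
    M[Kp + Ju + 1, K + Jl + 1] <-
      (-1)^(Ju - Kp) * wigner3j(Ju, 1, Jl, -Kp, sigma, K)
  }
  M
}

# Line-strength matrices S_g[upper state, lower state] for axes a, b, c
# between two solved J blocks (eigenvector columns ordered as the states).
# S is the usual dimensionless asymmetric-rotor line strength: in the
# symmetric-top limit the a-type values reduce to Hoenl-London factors.
strength_matrices <- function(block_u, block_l, Ju, Jl) {
  M0 <- dipole_block(Ju, Jl, 0L)
  Mm <- dipole_block(Ju, Jl, -1L)
  Mp <- dipole_block(Ju, Jl, 1L)
  Vu <- block_u$vectors; Vl <- block_l$vectors
  amp_a <- crossprod(Vu, M0 %*% Vl)
  amp_b <- crossprod(Vu, (Mm - Mp) %*% Vl) / sqrt(2)
  amp_c <- crossprod(Vu, (Mm + Mp) %*% Vl) / sqrt(2)
  g <- (2 * Ju + 1) * (2 * Jl + 1)
  list(a = g * amp_a^2, b = g * amp_b^2, c = g * amp_c^2)
}

empty_linelist <- function() {
  structure(data.frame(Ju = integer(), Kau = integer(), Kcu = integer(),
                       Jl = integer(), Kal = integer(), Kcl = integer(),
                       frequency = numeric(), uncertainty = numeric(),
                       strength = numeric(), intensity = numeric(),
                       type = character(), stringsAsFactors = FALSE),
            class = c("linelist", "data.frame"))
}

#' Simulate rotational transitions of an asymmetric rotor
#'
#' Enumerates all electric-dipole-allowed transitions (a-, b-, c-type;
#' Delta J in -1, 0, +1) between Watson A-reduced rotor levels with both
#' state J's up to `Jmax`, restricted to a frequency window. Line strengths
#' come from direction-cosine matrix elements between the asymmetric-rotor
#' eigenvectors; intensities use the thermal model
#' `mu_g^2 * S * (exp(-E_l/kT) - exp(-E_u/kT))` on a shared arbitrary scale.
#' Axes with zero dipole magnitude contribute no lines.
#'
#' @param constants [rotational_constants()] (or coercible).
#' @param distortion [quartic_distortion()] or `NULL`.
#' @param dipoles [dipole_moment()] (or coercible).
#' @param T Rotational temperature in K (default 2 K, typical of a neon
#'   supersonic jet).
#' @param window Numeric length-2, frequency window in MHz.
#' @param Jmax Maximum J of either state.
#' @param strength_min Discard lines with line strength below this value
#'   (numerical zero cut for forbidden transitions).
#' @return A `linelist` data frame with upper/lower quantum numbers
#'   (`Ju, Kau, Kcu, Jl, Kal, Kcl`), `frequency` (MHz), `uncertainty` (kHz,
#'   `NA` for simulated lines), `strength`, `intensity`, `type` ("a"/"b"/"c"),
#'   sorted by frequency.
#' @examples
#' cst <- rotational_constants(3052.1532, 304.82621, 292.43629)
#' simulate_lines(cst, NULL, dipole_moment(5.1, 0, 0),
#'                window = c(500, 1000), Jmax = 2)
#' @export
simulate_lines <- function(constants, distortion = NULL, dipoles,
                           T = 2, window, Jmax = 20, strength_min = 1e-10) {
  if (length(window) != 2 || !all(is.finite(window)) || window[1] >= window[2])
    stop("window must be an increasing pair of frequencies (MHz)")
  if (T <= 0) stop("temperature must be positive")
  if (Jmax < 1) stop("Jmax must be at least 1")
  cst <- as_rotconst(constants)
  dst <- as_quartic(distortion)
  mu <- as_dipole(dipoles)
  axes <- c("a", "b", "c")[unclass(mu) > 0]
  if (length(axes) == 0) return(empty_linelist())

  blocks <- lapply(0:Jmax, solve_block, cst = cst, dst = dst)
  kT <- KB_MHZ_PER_K * T
  out <- vector("list", 0)
  for (Jl in 0:Jmax) {
    for (Ju in Jl:min(Jl + 1L, Jmax)) {
      if (Ju == 0L) next
      bl <- blocks[[Jl + 1L]]; bu <- blocks[[Ju + 1L]]
      S <- strength_matrices(bu, bl, Ju, Jl)
      freq <- outer(bu$states$energy, bl$states$energy, `-`)
      for (ax in axes) {
        sel <- which(S[[ax]] > strength_min & freq > 0 &
                       freq >= window[1] & freq <= window[2], arr.ind = TRUE)
        if (Ju == Jl && nrow(sel))   # avoid double listing within one block
          sel <- sel[bu$states$energy[sel[, 1]] >
                       bl$states$energy[sel[, 2]] + 0, , drop = FALSE]
        if (!nrow(sel)) next
        iu <- sel[, 1]; il <- sel[, 2]
        El <- bl$states$energy[il]; Eu <- bu$states$energy[iu]
        s <- S[[ax]][sel]
        out[[length(out) + 1L]] <- data.frame(
          Ju = Ju, Kau = bu$states$Ka[iu], Kcu = bu$states$Kc[iu],
          Jl = Jl, Kal = bl$states$Ka[il], Kcl = bl$states$Kc[il],
          frequency = freq[sel], uncertainty = NA_real_,
          strength = s,
          intensity = mu[[paste0("mu_", ax)]]^2 * s *
            (exp(-El / kT) - exp(-Eu / kT)),
          type = ax, stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_linelist())
  res <- do.call(rbind, out)
  res <- res[order(res$frequency), ]
  rownames(res) <- NULL
  class(res) <- c("linelist", "data.frame")
  res
}

#' Transition type from quantum-number parity
#'
#' Classifies each transition as a-, b- or c-type from the parity changes in
#' `(Ka, Kc)`: a-type has even Delta Ka and odd Delta Kc, b-type odd/odd,
#' c-type odd/even.
#'
#' @param lines A `linelist` data frame with quantum-number columns.
#' @return Character vector of "a", "b", "c".
#' @export
transition_type <- function(lines) {
  dKa <- (lines$Kau - lines$Kal) %% 2
  dKc <- (lines$Kcu - lines$Kcl) %% 2
  ifelse(dKa == 0 & dKc == 1, "a",
         ifelse(dKa == 1 & dKc == 1, "b",
                ifelse(dKa == 1 & dKc == 0, "c", NA_character_)))
}

new_spectrum <- function(frequency, intensity) {
  if (length(frequency) != length(intensity))
    stop("frequency and intensity must have the same length")
  if (length(frequency) >= 2) {
    st <- diff(frequency)
    if (any(st <= 0) || diff(range(st)) > 1e-6 * st[1])
      stop("frequency grid must be strictly increasing and uniform")
  }
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  structure(data.frame(frequency = frequency, intensity = intensity),
            class = c("rotspec", "data.frame"))
}

#' Render a stick list as a convolved broadband spectrum
#'
#' Each transition contributes a Gaussian profile centred at its frequency
#' with the given full width at half maximum and area proportional to its
#' intensity; the spectrum is their sum on a uniform grid. Gaussian profiles
#' are appropriate for Doppler-limited jet spectra.
#'
#' @param lines `linelist` data frame (may be empty).
#' @param grid_step Grid spacing in MHz; must be finer than `fwhm`.
#' @param window Numeric length-2 window in MHz.
#' @param fwhm Full width at half maximum of each line, MHz.
#' @return A `rotspec` data frame with `frequency` (MHz) and `intensity`.
#' @export
stick_to_spectrum <- function(lines, grid_step, window, fwhm) {
  if (fwhm <= 0) stop("fwhm must be positive")
  if (grid_step >= fwhm) stop("grid_step must be smaller than fwhm")
  grid <- seq(window[1], window[2], by = grid_step)
  y <- numeric(length(grid))
  if (nrow(lines)) {
    amp <- lines$intensity / (fwhm * sqrt(pi / (4 * log(2))))
    c4 <- 4 * log(2) / fwhm^2
    for (i in seq_len(nrow(lines))) {
      f0 <- lines$frequency[i]
      lo <- max(1L, ceiling((f0 - 6 * fwhm - grid[1]) / grid_step) + 1L)
      hi <- min(length(grid), floor((f0 + 6 * fwhm - grid[1]) / grid_step) + 1L)
      if (lo > hi) next
      idx <- lo:hi
      y[idx] <- y[idx] + amp[i] * exp(-c4 * (grid[idx] - f0)^2)
    }
  }
  new_spectrum(grid, y)
}

#' Read / write line lists
#'
#' Plain whitespace-separated text, one transition per row:
#' `J' Ka' Kc' J'' Ka'' Kc'' frequency_MHz uncertainty_kHz`
#' (primes = upper state, double primes = lower state). `#` starts a comment;
#' blank lines are ignored. Frequencies are written to 1e-4 MHz so the
#' write/read round trip is lossless at that precision.
#'
#' @param path File path.
#' @return `read_linelist` returns a `linelist` data frame (with `type`
#'   derived from quantum-number parity); `write_linelist` returns `path`
#'   invisibly.
#' @export
read_linelist <- function(path) {
  raw <- readLines(path)
  stripped <- sub("#.*$", "", raw)
  keep <- which(nzchar(trimws(stripped)))
  if (!length(keep)) return(empty_linelist())
  rows <- lapply(keep, function(i) {
    fields <- strsplit(trimws(stripped[i]), "[[:space:]]+")[[1]]
    if (length(fields) < 7)
      stop(sprintf("line %d: expected 8 columns (7th = frequency), got %d",
                   i, length(fields)))
    qn <- suppressWarnings(as.numeric(fields[1:6]))
    if (anyNA(qn) || any(qn != round(qn)))
      stop(sprintf("line %d: quantum numbers must be integers", i))
    freq <- suppressWarnings(as.numeric(fields[7]))
    if (is.na(freq) || freq <= 0)
      stop(sprintf("line %d: frequency must be a positive number", i))
    unc <- if (length(fields) >= 8) suppressWarnings(as.numeric(fields[8])) else NA_real_
    c(qn, freq, unc)
  })
  m <- do.call(rbind, rows)
  res <- data.frame(Ju = as.integer(m[, 1]), Kau = as.integer(m[, 2]),
                    Kcu = as.integer(m[, 3]), Jl = as.integer(m[, 4]),
                    Kal = as.integer(m[, 5]), Kcl = as.integer(m[, 6]),
                    frequency = m[, 7], uncertainty = m[, 8],
                    stringsAsFactors = FALSE)
  res$type <- transition_type(res)
  class(res) <- c("linelist", "data.frame")
  res
}

#' @rdname read_linelist
#' @param lines `linelist` data frame to write.
#' @export
write_linelist <- function(lines, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# J' Ka' Kc' J'' Ka'' Kc'' frequency_MHz uncertainty_kHz", con)
  if (nrow(lines)) {
    unc <- ifelse(is.na(lines$uncertainty), "NA",
                  sprintf("%.3f", lines$uncertainty))
    writeLines(sprintf("%3d %3d %3d %3d %3d %3d %14.4f %s",
                       lines$Ju, lines$Kau, lines$Kcu,
                       lines$Jl, lines$Kal, lines$Kcl,
                       lines$frequency, unc), con)
  }
  invisible(path)
}

#' Read a JPL-format catalog (.cat) line list
#'
#' Parses the fixed-width JPL/SPCAT catalog format (frequency, error, base-10
#' log intensity, lower-state energy, and asymmetric-rotor quantum numbers
#' J Ka Kc for each state). Only the fields relevant to assignment are kept.
#'
#' @param path Path to a `.cat` file.
#' @return A `linelist` data frame; `uncertainty` is converted from MHz (the
#'   catalog unit) to kHz. A `log10_intensity` column carries LGINT.
#' @export
read_jpl_cat <- function(path) {
  raw <- readLines(path)
  raw <- raw[nzchar(trimws(raw))]
  if (!length(raw)) return(empty_linelist())
  num <- function(s) suppressWarnings(as.numeric(trimws(s)))
  int <- function(s) suppressWarnings(as.integer(trimws(s)))
  res <- do.call(rbind, lapply(seq_along(raw), function(i) {
    ln <- raw[i]
    if (nchar(ln) < 67) stop(sprintf("line %d: truncated .cat record", i))
    data.frame(
      Ju = int(substr(ln, 56, 57)), Kau = int(substr(ln, 58, 59)),
      Kcu = int(substr(ln, 60, 61)),
      Jl = int(substr(ln, 68, 69)), Kal = int(substr(ln, 70, 71)),
      Kcl = int(substr(ln, 72, 73)),
      frequency = num(substr(ln, 1, 13)),
      uncertainty = num(substr(ln, 14, 21)) * 1000,
      log10_intensity = num(substr(ln, 22, 29)),
      stringsAsFactors = FALSE)
  }))
  res$type <- transition_type(res)
  class(res) <- c("linelist", "data.frame")
  res
}

#' Read / write two-column spectra
#'
#' Plain text, two whitespace-separated columns: frequency (MHz), intensity.
#' `#` comments allowed.
#'
#' @param path File path.
#' @return `read_spectrum` returns a `rotspec` data frame.
#' @export
read_spectrum <- function(path) {
  d <- utils::read.table(path, comment.char = "#",
                         col.names = c("frequency", "intensity"))
  new_spectrum(d$frequency, d$intensity)
}

#' @rdname read_spectrum
#' @param spectrum `rotspec` data frame to write.
#' @export
write_spectrum <- function(spectrum, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# frequency_MHz intensity", con)
  writeLines(sprintf("%.6f %.8e", spectrum$frequency, spectrum$intensity), con)
  invisible(path)
}
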