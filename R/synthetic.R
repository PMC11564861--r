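#' Generate a synthetic measured line list
#'
#' Simulates the transitions of one species and perturbs each frequency
#' with Gaussian noise of the stated standard deviation — emulating a table
#' of measured lines with their measurement uncertainty. Deterministic for
#' a fixed seed.
#'
#' @param truth List with `constants`, optional `distortion`, `dipoles`
#'   (coercible by the respective constructors).
#' @param noise_kHz Frequency noise standard deviation (kHz).
#' @param window Frequency window in MHz.
#' @param seed RNG seed (optional).
#' @param T Rotational temperature (K).
#' @param Jmax Maximum J.
#' @param types Optional subset of c("a","b","c") to keep.
#' @param n_strongest Optionally keep only the n most intense lines.
#' @return A `linelist` with perturbed frequencies; `uncertainty` is set to
#'   `noise_kHz`.
#' @export
gen_linelist <- function(truth, noise_kHz = 0, window, seed = NULL,
                         T = 2, Jmax = 20, types = NULL, n_strongest = NULL) {
  if (noise_kHz < 0) stop("noise must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  ll <- simulate_lines(truth$constants, truth$distortion, truth$dipoles,
                       T = T, window = window, Jmax = Jmax)
  if (!is.null(types)) ll <- ll[ll$type %in% types, , drop = FALSE]
  if (!is.null(n_strongest) && nrow(ll) > n_strongest)
    ll <- ll[rank(-ll$intensity, ties.method = "first") <= n_strongest, ,
             drop = FALSE]
  if (nrow(ll)) {
    ll$frequency <- ll$frequency + stats::rnorm(nrow(ll), 0, noise_kHz / 1000)
    ll$uncertainty <- noise_kHz
    ll <- ll[order(ll$frequency), ]
    rownames(ll) <- NULL
    class(ll) <- c("linelist", "data.frame")
  }
  ll
}

#' Scenario configuration for broadband-spectrum synthesis
#'
#' Bundles everything [gen_broadband()] needs: the ground-truth conformers,
#' their population fractions, jet temperature, window, and noise levels.
#'
#' @param conformers Data frame like [dulcin_conformers()] (columns `id, A,
#'   B, C, mu_a, mu_b, mu_c`, optionally `DJ, DJK`).
#' @param fractions Named population fractions per id (e.g. post-relaxation);
#'   default equal.
#' @param T Rotational temperature (K).
#' @param window Frequency window (MHz).
#' @param line_noise_kHz Gaussian frequency noise on each line (kHz).
#' @param spectrum_noise Baseline white-noise level, relative to the
#'   strongest line amplitude.
#' @param n_interlopers Number of interloper lines (photofragments, water
#'   clusters) drawn uniformly over the window with intensities on the same
#'   scale as real lines.
#' @param fwhm,grid_step Line width and grid step of the rendered spectrum
#'   (MHz).
#' @param Jmax Maximum J simulated.
#' @param seed RNG seed.
#' @return List of class `scenario`.
#' @export
scenario_config <- function(conformers, fractions = NULL, T = 2,
                            window = c(2000, 8000), line_noise_kHz = 10,
                            spectrum_noise = 0.01, n_interlopers = 20,
                            fwhm = 0.15, grid_step = 0.03, Jmax = 20,
                            seed = 1) {
  if (is.null(fractions))
    fractions <- stats::setNames(rep(1 / nrow(conformers), nrow(conformers)),
                                 conformers$id)
  if (line_noise_kHz < 0 || spectrum_noise < 0) stop("noise must be >= 0")
  structure(list(conformers = conformers, fractions = fractions, T = T,
                 window = window, line_noise_kHz = line_noise_kHz,
                 spectrum_noise = spectrum_noise,
                 n_interlopers = n_interlopers, fwhm = fwhm,
                 grid_step = grid_step, Jmax = Jmax, seed = seed),
            class = "scenario")
}

#' Synthesize a broadband spectrum with ground truth
#'
#' Sums the convolved spectra of all conformers in the scenario (line
#' intensities weighted by population fraction and the dipole-squared
#' thermal model), adds uniformly placed interloper lines with intensities
#' drawn from the real-line intensity scale, and white Gaussian baseline
#' noise. The returned ledger records which line belongs to which conformer
#' (or interloper), for use as a test oracle.
#'
#' @param scenario A [scenario_config()].
#' @return List with `spectrum` (`rotspec`), `lines` (truth ledger: all
#'   stick lines with `species` column), `scenario`.
#' @export
gen_broadband <- function(scenario) {
  sc <- scenario
  set.seed(sc$seed)
  all <- list()
  for (i in seq_len(nrow(sc$conformers))) {
    row <- sc$conformers[i, ]
    truth <- list(
      constants = rotational_constants(row$A, row$B, row$C),
      distortion = quartic_distortion(
        DJ = if (!is.null(row$DJ)) row$DJ else 0,
        DJK = if (!is.null(row$DJK)) row$DJK else 0),
      dipoles = dipole_moment(row$mu_a, row$mu_b, row$mu_c))
    ll <- gen_linelist(truth, noise_kHz = sc$line_noise_kHz,
                       window = sc$window, T = sc$T, Jmax = sc$Jmax)
    if (!nrow(ll)) next
    ll$intensity <- ll$intensity * sc$fractions[[row$id]]
    ll$species <- row$id
    all[[length(all) + 1L]] <- ll
  }
  lines <- if (length(all)) do.call(rbind, all) else empty_linelist()
  if (sc$n_interlopers > 0) {
    ref <- if (nrow(lines)) stats::quantile(lines$intensity, c(0.5, 1)) else c(0.5, 1)
    intr <- data.frame(
      Ju = NA_integer_, Kau = NA_integer_, Kcu = NA_integer_,
      Jl = NA_integer_, Kal = NA_integer_, Kcl = NA_integer_,
      frequency = stats::runif(sc$n_interlopers, sc$window[1], sc$window[2]),
      uncertainty = NA_real_, strength = NA_real_,
      intensity = stats::runif(sc$n_interlopers, ref[1], ref[2]),
      type = NA_character_, species = "interloper",
      stringsAsFactors = FALSE)
    lines <- rbind(lines, intr)
  }
  lines <- lines[order(lines$frequency), ]
  rownames(lines) <- NULL
  spec <- stick_to_spectrum(lines, sc$grid_step, sc$window, sc$fwhm)
  if (sc$spectrum_noise > 0 && nrow(lines)) {
    amp0 <- max(spec$intensity)
    spec$intensity <- spec$intensity +
      stats::rnorm(nrow(spec), 0, sc$spectrum_noise * amp0)
  }
  list(spectrum = spec, lines = lines, scenario = sc)
}

#' Deterministic toy urea-phenyl geometry
#'
#' A small synthetic planar molecule built from standard bond lengths and
#' angles: a six-membered carbon ring (the hydrophobic gamma site) bearing an
#' N-C(=O)-NH2 urea fragment, providing an N-H proton donor and a C=O
#' acceptor. Used as a self-contained fixture for geometry-level operations;
#' it is a constructed surrogate, not an optimized structure of any real
#' molecule.
#'
#' Atom order: C1..C6 (ring), N1, H(N1), C7 (carbonyl), O, N2 (amide),
#' H1(N2), H2(N2).
#'
#' @return A [geometry()].
#' @export
toy_urea_fixture <- function() {
  deg <- pi / 180
  ring <- t(vapply(0:5, function(k)
    c(1.39 * cos(60 * k * deg), 1.39 * sin(60 * k * deg), 0), numeric(3)))
  N1 <- c(1.39 + 1.41, 0, 0)
  HN1 <- N1 + 1.01 * c(cos(120 * deg), sin(120 * deg), 0)
  C7 <- N1 + 1.38 * c(cos(-60 * deg), sin(-60 * deg), 0)
  # sp2 carbon: substituent directions 120 deg apart from the N1 side
  toN1 <- (N1 - C7) / sqrt(sum((N1 - C7)^2))
  rot <- function(v, th) c(v[1] * cos(th) - v[2] * sin(th),
                           v[1] * sin(th) + v[2] * cos(th), 0)
  O <- C7 + 1.22 * rot(toN1, 120 * deg)
  N2 <- C7 + 1.38 * rot(toN1, -120 * deg)
  toC7 <- (C7 - N2) / sqrt(sum((C7 - N2)^2))
  H1 <- N2 + 1.01 * rot(toC7, 120 * deg)
  H2 <- N2 + 1.01 * rot(toC7, -120 * deg)
  xyz <- rbind(ring, N1, HN1, C7, O, N2, H1, H2)
  geometry(c(rep("C", 6), "N", "H", "C", "O", "N", "H", "H"), xyz)
}
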