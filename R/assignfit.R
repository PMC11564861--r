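PARAM_NAMES <- c("A", "B", "C", "DJ", "DJK", "DK", "dJ", "dK")

# Hellmann-Feynman derivative dE/dp = v' (dH/dp) v for one eigenvector of a
# J block. H is linear in every spectroscopic parameter, so these are exact.
# v is in the signed-K basis (K = -J..J).
state_derivatives <- function(v, J) {
  K <- seq.int(-J, J)
  JJ <- J * (J + 1)
  c2 <- v^2
  n <- 2L * J + 1L
  # off-diagonal quadratic forms: sum over K<->K+2 couplings of 2 c_i c_{i+2} g(k)
  offsum <- function(g) {
    if (J < 1) return(0)
    i <- seq_len(n - 2L)
    k <- K[i]
    f <- sqrt((JJ - k * (k + 1)) * (JJ - (k + 1) * (k + 2)))
    sum(2 * v[i] * v[i + 2L] * g(k) * f)
  }
  c(A = sum(c2 * K^2),
    B = sum(c2 * 0.5 * (JJ - K^2)) + offsum(function(k) 0.25),
    C = sum(c2 * 0.5 * (JJ - K^2)) + offsum(function(k) -0.25),
    DJ = -JJ^2,
    DJK = sum(c2 * (-JJ * K^2)),
    DK = sum(c2 * (-K^4)),
    dJ = offsum(function(k) -JJ),
    dK = offsum(function(k) -0.5 * (k^2 + (k + 2)^2)))
}

# Calculated frequencies and the Jacobian (d nu / d p over all 8 parameters)
# for a set of quantum-number-labelled lines at given parameter values.
calc_lines <- function(lines, par) {
  cst <- rotational_constants(par[["A"]], par[["B"]], par[["C"]])
  dst <- quartic_distortion(par[["DJ"]], par[["DJK"]], par[["DK"]],
                            par[["dJ"]], par[["dK"]])
  Js <- sort(unique(c(lines$Ju, lines$Jl)))
  blocks <- lapply(Js, solve_block, cst = cst, dst = dst)
  names(blocks) <- Js
  look <- function(J, Ka, Kc) {
    b <- blocks[[as.character(J)]]
    i <- which(b$states$Ka == Ka & b$states$Kc == Kc)
    if (length(i) != 1)
      stop(sprintf("no state %d_{%d,%d}: invalid quantum numbers", J, Ka, Kc))
    i
  }
  n <- nrow(lines)
  freq <- numeric(n)
  jac <- matrix(0, n, 8, dimnames = list(NULL, PARAM_NAMES))
  for (r in seq_len(n)) {
    bu <- blocks[[as.character(lines$Ju[r])]]
    bl <- blocks[[as.character(lines$Jl[r])]]
    iu <- look(lines$Ju[r], lines$Kau[r], lines$Kcu[r])
    il <- look(lines$Jl[r], lines$Kal[r], lines$Kcl[r])
    freq[r] <- bu$states$energy[iu] - bl$states$energy[il]
    jac[r, ] <- state_derivatives(bu$vectors[, iu], lines$Ju[r]) -
      state_derivatives(bl$vectors[, il], lines$Jl[r])
  }
  list(freq = freq, jac = jac)
}

#' Fit spectroscopic constants to assigned transitions
#'
#' Weighted least-squares fit of Watson A-reduced rotational and quartic
#' centrifugal-distortion constants to a list of measured, quantum-number
#' assigned transition frequencies. Minimizes `sum w_i (nu_obs - nu_calc)^2`
#' by Gauss-Newton iteration; frequency derivatives are exact
#' (Hellmann-Feynman on the parameter-linear Hamiltonian), which keeps the
#' fit stable for tiny distortion constants. Non-floated parameters are held
#' at their starting values.
#'
#' Blended lines are supported through an optional integer `blend` column in
#' `lines`: rows sharing a blend id share one observed frequency, which is
#' compared against the mean of the components' calculated frequencies (the
#' blend counts once in N).
#'
#' @param lines `linelist` data frame with quantum numbers, `frequency`
#'   (MHz), optional `uncertainty` (kHz), optional `blend`.
#' @param start Starting [rotational_constants()] (or coercible). Must be
#'   within the convergence basin; a few percent, as quantum-chemistry
#'   predictions typically are.
#' @param start_distortion Starting [quartic_distortion()] or `NULL`.
#' @param float Character vector of parameters to float, a subset of
#'   `A, B, C, DJ, DJK, DK, dJ, dK`. Default matches the common 5-parameter
#'   near-prolate fit.
#' @param weights `"uniform"` (default) or `"uncertainty"` (w = 1/u^2 from
#'   the `uncertainty` column).
#' @param max_iter,reltol Convergence control: stop when the relative change
#'   in the RMS falls below `reltol` (default 1e-6) or after `max_iter`
#'   iterations (a non-converged fit is flagged, not silently returned).
#' @return An object of class `rotfit` with components `constants`,
#'   `distortion`, `coefficients` (floated parameters), `se`, `vcov`,
#'   `correlation`, `rms` (kHz), `n_lines`, `residuals` (kHz), `fitted`
#'   (MHz), `converged`, `iterations`, `lines`.
#' @seealso [predict.rotfit()], [simulate.rotfit()], [summary.rotfit()]
#' @export
fit_constants <- function(lines, start, start_distortion = NULL,
                          float = c("A", "B", "C", "DJ", "DJK"),
                          weights = c("uniform", "uncertainty"),
                          max_iter = 50, reltol = 1e-6) {
  weights <- match.arg(weights)
  float <- match.arg(float, PARAM_NAMES, several.ok = TRUE)
  if (!nrow(lines)) stop("no lines to fit")
  cst <- as_rotconst(start)
  dst <- as_quartic(start_distortion)
  par <- c(unclass(cst), unclass(dst))

  grp <- if (!is.null(lines$blend) && any(!is.na(lines$blend) & lines$blend > 0)) {
    g <- ifelse(is.na(lines$blend) | lines$blend == 0,
                -seq_len(nrow(lines)), lines$blend)
    match(g, unique(g))
  } else seq_len(nrow(lines))
  ngrp <- max(grp)
  p <- length(float)
  if (ngrp < p)
    stop(sprintf("underdetermined fit: %d observations for %d parameters",
                 ngrp, p))
  obs <- tapply(lines$frequency, grp, mean)          # identical within a blend
  w <- if (weights == "uncertainty") {
    u <- tapply(lines$uncertainty, grp, mean) / 1000  # kHz -> MHz
    if (anyNA(u) || any(u <= 0))
      stop("uncertainty weighting requires positive uncertainties on all lines")
    1 / u^2
  } else rep(1, ngrp)

  rms_mhz <- Inf
  rms_path <- numeric(0)
  converged <- FALSE
  iter <- 0L
  repeat {
    iter <- iter + 1L
    cl <- calc_lines(lines, par)
    calc <- as.numeric(tapply(cl$freq, grp, mean))
    Jg <- apply(cl$jac[, float, drop = FALSE], 2,
                function(col) as.numeric(tapply(col, grp, mean)))
    Jg <- matrix(Jg, nrow = ngrp, dimnames = list(NULL, float))
    r <- as.numeric(obs) - calc
    new_rms <- sqrt(mean(r^2))
    rms_path <- c(rms_path, new_rms * 1000)
    JtWJ <- crossprod(Jg, Jg * w)
    step <- tryCatch(solve(JtWJ, crossprod(Jg, r * w)),
                     error = function(e) stop("singular normal equations: ",
                                              conditionMessage(e)))
    done <- is.finite(rms_mhz) &&
      (new_rms < 1e-9 || abs(rms_mhz - new_rms) <= reltol * max(new_rms, 1e-9))
    rms_mhz <- new_rms
    if (done) { converged <- TRUE; break }
    if (iter >= max_iter) break
    # keep the step inside the physical region (A, B, C > 0 and ordered
    # within reason): halve until valid
    step <- as.numeric(step)
    for (h in 1:20) {
      cand <- par
      cand[float] <- cand[float] + step
      if (cand[["A"]] > 0 && cand[["B"]] > 0 && cand[["C"]] > 0 &&
          cand[["A"]] >= cand[["B"]] && cand[["B"]] >= cand[["C"]]) break
      step <- step / 2
    }
    par[float] <- par[float] + step
  }

  dof <- ngrp - p
  sigma2 <- if (dof > 0) sum(w * r^2) / dof else NA_real_
  vc <- sigma2 * solve(JtWJ)
  dimnames(vc) <- list(float, float)
  se <- sqrt(diag(vc))
  corr <- vc / outer(se, se)

  fit <- list(
    constants = rotational_constants(par[["A"]], par[["B"]], par[["C"]]),
    distortion = quartic_distortion(par[["DJ"]], par[["DJK"]], par[["DK"]],
                                    par[["dJ"]], par[["dK"]]),
    coefficients = par[float], se = se, vcov = vc, correlation = corr,
    rms = rms_mhz * 1000, rms_path = rms_path, n_lines = ngrp,
    residuals = r * 1000, fitted = calc, observed = as.numeric(obs),
    weights = weights, float = float, df = dof,
    converged = converged, iterations = iter, lines = lines)
  class(fit) <- "rotfit"
  if (!converged) warning("fit did not converge in ", max_iter, " iterations")
  fit
}

#' @export
print.rotfit <- function(x, ...) {
  cat("Watson A-reduced rotor fit (", x$n_lines, " lines, sigma = ",
      formatC(x$rms, digits = 3, format = "fg"), " kHz",
      if (!x$converged) ", NOT CONVERGED", ")\n", sep = "")
  est <- formatC(x$coefficients, digits = 10, format = "fg")
  se <- formatC(x$se, digits = 3, format = "fg")
  cat(paste0("  ", format(x$float, width = 4), " = ", est, " (", se, ") MHz",
             collapse = "\n"), "\n")
  invisible(x)
}

#' @export
coef.rotfit <- function(object, ...) object$coefficients

#' @export
vcov.rotfit <- function(object, ...) object$vcov

#' @export
fitted.rotfit <- function(object, ...) object$fitted

#' @export
residuals.rotfit <- function(object, units = c("kHz", "MHz"), ...) {
  units <- match.arg(units)
  if (units == "kHz") object$residuals else object$residuals / 1000
}

#' Predict transition frequencies from a fitted rotor model
#'
#' @param object A `rotfit` object.
#' @param newdata Optional data frame with quantum-number columns
#'   `Ju, Kau, Kcu, Jl, Kal, Kcl`; defaults to the fitted lines.
#' @param ... Unused.
#' @return Numeric vector of calculated frequencies in MHz.
#' @export
predict.rotfit <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  par <- c(unclass(object$constants), unclass(object$distortion))
  calc_lines(newdata, par)$freq
}

#' Simulate measured line lists from a fitted rotor model
#'
#' Draws `nsim` replicate line lists: the fitted frequencies perturbed by
#' Gaussian noise with the fit's RMS.
#'
#' @param object A `rotfit` object.
#' @param nsim Number of replicates.
#' @param seed Optional RNG seed.
#' @param ... Unused.
#' @return A list of `linelist` data frames.
#' @export
simulate.rotfit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  sigma_mhz <- object$rms / 1000
  lapply(seq_len(nsim), function(i) {
    ll <- object$lines
    calc <- predict(object, ll)
    ll$frequency <- calc + stats::rnorm(nrow(ll), 0, sigma_mhz)
    ll$uncertainty <- object$rms
    ll
  })
}

#' @export
summary.rotfit <- function(object, ...) {
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = object$se)
  structure(list(coefficients = tab, correlation = object$correlation,
                 rms = object$rms, n_lines = object$n_lines, df = object$df,
                 converged = object$converged, constants = object$constants,
                 distortion = object$distortion),
            class = "summary.rotfit")
}

#' @export
print.summary.rotfit <- function(x, ...) {
  cat("Weighted least-squares fit of Watson A-reduced constants\n\n")
  print(x$coefficients)
  cat("\nRMS of fit (sigma):", formatC(x$rms, digits = 3, format = "fg"),
      "kHz on", x$n_lines, "lines (", x$df, "degrees of freedom )\n")
  cat("\nParameter correlations:\n")
  print(round(x$correlation, 3))
  invisible(x)
}

#' @export
plot.rotfit <- function(x, ...) {
  graphics::plot(x$observed / 1000, x$residuals,
                 xlab = "Frequency (GHz)", ylab = "Obs - calc (kHz)",
                 main = "Fit residuals", ...)
  graphics::abline(h = 0, lty = 2)
}

#' Pick peaks from a broadband spectrum
#'
#' Local maxima above `snr_threshold` times a robust noise estimate
#' (1.4826 * median absolute deviation of the intensity), with the peak
#' frequency refined by three-point parabolic interpolation.
#'
#' @param spectrum A `rotspec` data frame.
#' @param snr_threshold Signal-to-noise threshold (> 0).
#' @param min_sep Merge maxima closer than this (MHz), keeping the tallest —
#'   suppresses noise-induced satellite maxima on the flanks of strong
#'   lines. Set to about half the linewidth; 0 (default) disables merging.
#' @return Data frame with `frequency` (MHz) and `height`, sorted by
#'   frequency; empty for an all-zero spectrum.
#' @export
peak_pick <- function(spectrum, snr_threshold = 5, min_sep = 0) {
  if (!nrow(spectrum)) stop("empty spectrum")
  if (snr_threshold <= 0) stop("snr_threshold must be positive")
  y <- spectrum$intensity
  f <- spectrum$frequency
  noise <- stats::mad(y)
  thr <- snr_threshold * noise
  n <- length(y)
  if (n < 3) return(data.frame(frequency = numeric(), height = numeric()))
  i <- which(y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n] &
               y[2:(n - 1)] > thr & y[2:(n - 1)] > 0) + 1L
  if (!length(i)) return(data.frame(frequency = numeric(), height = numeric()))
  # three-point parabolic refinement; on log intensity where the flanks are
  # positive (exact for an uncontaminated Gaussian profile)
  yl <- y[i - 1L]; yc <- y[i]; yr <- y[i + 1L]
  uselog <- yl > 0 & yr > 0
  la <- yl; lc <- yc; lr <- yr
  la[uselog] <- log(yl[uselog])
  lc[uselog] <- log(yc[uselog])
  lr[uselog] <- log(yr[uselog])
  denom <- la - 2 * lc + lr
  delta <- ifelse(abs(denom) > 0, 0.5 * (la - lr) / denom, 0)
  delta[abs(delta) > 0.5] <- 0
  step <- f[2] - f[1]
  out <- data.frame(frequency = f[i] + delta * step,
                    height = yc - 0.25 * (yl - yr) * delta)
  if (min_sep > 0 && nrow(out) > 1) {
    keep <- rep(TRUE, nrow(out))
    ord <- order(out$height, decreasing = TRUE)
    taken <- numeric(0)
    for (j in ord) {
      if (length(taken) && min(abs(taken - out$frequency[j])) < min_sep)
        keep[j] <- FALSE
      else taken <- c(taken, out$frequency[j])
    }
    out <- out[keep, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Detect harmonic (R-branch) progressions in a peak list
#'
#' Searches for combs of peaks at frequencies close to integer multiples of a
#' common spacing near `spacing_hint` — the signature of a-type R-branch
#' clusters of a near-prolate rotor, whose spacing is approximately B+C.
#' Detected progressions are disjoint in peaks and returned sorted by member
#' count (descending).
#'
#' @param peaks Data frame from [peak_pick()].
#' @param spacing_hint Expected spacing in MHz (e.g. a predicted B+C).
#' @param rel_tol Comb residual tolerance as a fraction of the spacing.
#' @param min_members Minimum peaks per progression. The default 4 keeps the
#'   chance-comb rate negligible in interloper-rich spectra; 3 is the logical
#'   minimum.
#' @param max_curvature If positive, allow a cubic comb
#'   `freq ~ s*n + b*n^3` with `b` in `[-max_curvature, 0]` (MHz). This is
#'   the signature of centrifugal distortion in an R-branch series
#'   (`b = -4 DJ` for a Ka = 0 progression); the default 0 searches strict
#'   harmonic combs.
#' @return List of progressions, each a list with `peaks` (member rows),
#'   `spacing` (fitted, MHz), `curvature` (fitted b, MHz), `harmonics`
#'   (integer indices n with `freq ~ s*n + b*n^3`).
#' @export
find_progressions <- function(peaks, spacing_hint, rel_tol = 0.005,
                              min_members = 4, max_curvature = 0) {
  if (spacing_hint <= 0) stop("spacing_hint must be positive")
  bgrid <- if (max_curvature > 0)
    seq(-max_curvature, 0, length.out = 16) else 0
  sgrid <- spacing_hint * seq(0.9, 1.1, length.out = 2001)
  members_of <- function(f, s, b) {
    n <- round(f / s)
    n <- round((f - b * n^3) / s)       # refine harmonic index under curvature
    ok <- n >= 1 & abs(f - n * s - b * n^3) <= rel_tol * s
    list(n = n, ok = ok)
  }
  out <- list()
  remaining <- peaks
  while (nrow(remaining) >= min_members) {
    f <- remaining$frequency
    best <- NULL
    for (b in bgrid) {
      for (s in sgrid) {
        m <- members_of(f, s, b)
        cnt <- sum(m$ok)
        if (cnt >= min_members) {
          ss <- sum((f[m$ok] - m$n[m$ok] * s - b * m$n[m$ok]^3)^2)
          if (is.null(best) || cnt > best$cnt ||
              (cnt == best$cnt && ss < best$ss))
            best <- list(s = s, b = b, cnt = cnt, ss = ss)
        }
      }
    }
    if (is.null(best)) break
    # refine (s, b) by least squares on the members, re-collect
    s <- best$s; b <- best$b
    for (k in 1:3) {
      m <- members_of(f, s, b)
      if (sum(m$ok) < min_members) break
      n <- m$n[m$ok]; fm <- f[m$ok]
      if (max_curvature > 0 && length(fm) >= 3) {
        cf <- stats::lm.fit(cbind(n, n^3), fm)$coefficients
        s <- cf[[1]]; b <- min(max(cf[[2]], -max_curvature), 0)
      } else {
        s <- sum(n * fm) / sum(n^2)
      }
    }
    m <- members_of(f, s, b)
    if (sum(m$ok) < min_members) break
    out[[length(out) + 1L]] <- list(peaks = remaining[m$ok, , drop = FALSE],
                                    spacing = s, curvature = b,
                                    harmonics = as.integer(m$n[m$ok]))
    remaining <- remaining[!m$ok, , drop = FALSE]
  }
  out[order(vapply(out, function(p) nrow(p$peaks), 0), decreasing = TRUE)]
}

#' Assign picked peaks to predicted transitions
#'
#' Matches each peak to the nearest predicted transition within `match_tol`.
#' Predicted lines closer together than `blend_tol` (unresolvable asymmetry
#' doublets) are collapsed into one blended prediction at their mean
#' frequency; a peak assigned to a blend yields one row per component,
#' sharing a `blend` id and the measured frequency. A peak with two distinct
#' (non-blended) predictions inside the tolerance is ambiguous: it is left
#' unassigned and reported. A prediction claimed by several peaks keeps the
#' nearest.
#'
#' @param peaks Data frame from [peak_pick()].
#' @param predicted `linelist` of predicted transitions (e.g.
#'   [simulate_lines()] output), sorted by frequency.
#' @param match_tol Matching tolerance in MHz.
#' @param blend_tol Predictions closer than this (MHz) are treated as one
#'   blended line.
#' @param ambiguity `"drop"` (default): a peak with two candidate
#'   predictions inside the tolerance is left unassigned and reported;
#'   `"nearest"`: assign it to the closer prediction (used while
#'   bootstrapping from rough constants, when predictions are still dense
#'   relative to the tolerance).
#' @return List with `lines` (measured-frequency `linelist` with `blend`
#'   column), `ambiguous` (peaks with competing predictions), `unassigned`
#'   (all peaks not assigned).
#' @export
assign_lines <- function(peaks, predicted, match_tol, blend_tol = 0.15,
                         ambiguity = c("drop", "nearest")) {
  ambiguity <- match.arg(ambiguity)
  if (match_tol <= 0) stop("match_tol must be positive")
  if (!nrow(predicted) || !nrow(peaks))
    return(list(lines = empty_linelist(), ambiguous = peaks[0, ],
                unassigned = peaks))
  predicted <- predicted[order(predicted$frequency), ]
  gap <- c(Inf, diff(predicted$frequency))
  grp <- cumsum(gap >= blend_tol)
  gfreq <- as.numeric(tapply(predicted$frequency, grp, mean))

  cand_grp <- integer(nrow(peaks)); cand_d <- numeric(nrow(peaks))
  ambiguous <- logical(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    d <- abs(gfreq - peaks$frequency[i])
    hits <- which(d <= match_tol)
    if (length(hits) == 0) { cand_grp[i] <- NA_integer_; next }
    if (length(hits) > 1 && ambiguity == "drop") {
      cand_grp[i] <- NA_integer_; ambiguous[i] <- TRUE; next
    }
    best <- hits[which.min(d[hits])]
    cand_grp[i] <- best
    cand_d[i] <- d[best]
  }
  # one peak per prediction group: keep the nearest
  for (g in unique(stats::na.omit(cand_grp))) {
    claim <- which(!is.na(cand_grp) & cand_grp == g)
    if (length(claim) > 1) {
      keep <- claim[which.min(cand_d[claim])]
      cand_grp[setdiff(claim, keep)] <- NA_integer_
    }
  }
  rows <- list()
  bid <- 0L
  for (i in which(!is.na(cand_grp))) {
    members <- predicted[grp == cand_grp[i], , drop = FALSE]
    members$frequency <- peaks$frequency[i]
    members$blend <- if (nrow(members) > 1) { bid <- bid + 1L; bid } else NA_integer_
    rows[[length(rows) + 1L]] <- members
  }
  lines <- if (length(rows)) do.call(rbind, rows) else empty_linelist()
  if (nrow(lines)) {
    lines <- lines[order(lines$frequency), ]
    rownames(lines) <- NULL
    class(lines) <- c("linelist", "data.frame")
  }
  list(lines = lines,
       ambiguous = peaks[ambiguous, , drop = FALSE],
       unassigned = peaks[is.na(cand_grp), , drop = FALSE])
}

# Bootstrap the assignment from the a-type R-branch comb structure.
# Detected combs nu ~ s*n + b*n^3 (the cubic term is the centrifugal-
# distortion signature; the Ka = 0 series and both Ka = 1 doublet series
# all form such combs) serve as seeds: members are re-collected from the
# full peak list, read as the Ka = 0 series ((n)_{0,n} <- (n-1)_{0,n-1}),
# fitted with B and DJ floating, trimmed, and polished by re-matching
# peaks against the fitted model's own Ka = 0 predictions. Candidates are
# ranked by cluster symmetry: a genuine Ka = 0 member has Ka = 1 doublet
# satellites at roughly +/- (B-C)/2 per harmonic index on BOTH sides,
# whereas a Ka = 1 or high-Ka pile comb sits at a cluster edge.
ka0_bootstrap <- function(peaks, cst, dst, mu, cfg, window, trim_refit) {
  bc0 <- cst[["B"]] + cst[["C"]]
  strong <- peaks[order(peaks$height, decreasing = TRUE), , drop = FALSE]
  strong <- strong[seq_len(min(60L, nrow(strong))), , drop = FALSE]
  progs <- find_progressions(strong, spacing_hint = bc0,
                             rel_tol = cfg$prog_rel_tol,
                             min_members = 5, max_curvature = 0.15)
  if (!length(progs))
    progs <- find_progressions(strong, spacing_hint = bc0,
                               rel_tol = cfg$prog_rel_tol,
                               min_members = 4, max_curvature = 0.15)
  if (!length(progs)) return(NULL)

  ka0_lines <- function(n, freq) {
    ll <- data.frame(Ju = n, Kau = 0L, Kcu = n, Jl = n - 1L, Kal = 0L,
                     Kcl = n - 1L, frequency = freq, uncertainty = NA_real_)
    class(ll) <- c("linelist", "data.frame")
    ll
  }
  collect <- function(s, b, tol) {
    n <- round(peaks$frequency / s)
    n <- round((peaks$frequency - b * n^3) / s)
    res <- peaks$frequency - n * s - b * n^3
    sel <- which(n >= 2 & n <= cfg$Jmax & abs(res) <= tol)
    if (!length(sel)) return(NULL)
    # one peak per harmonic: keep the closest to the comb
    sel <- sel[order(abs(res[sel]))]
    sel <- sel[!duplicated(n[sel])]
    sel <- sel[order(n[sel])]
    list(n = n[sel], freq = peaks$frequency[sel])
  }
  best <- NULL
  for (pg in progs) {
    mem <- collect(pg$spacing, pg$curvature, 3)
    if (is.null(mem) || length(mem$n) < 4) next
    ll <- ka0_lines(mem$n, mem$freq)
    f0 <- tryCatch(fit_constants(ll, cst, dst, float = c("B", "DJ")),
                   error = function(e) NULL)
    if (is.null(f0)) next
    tr <- trim_refit(ll, f0, c("B", "DJ"))
    f0 <- tr$fit
    lines <- tr$lines
    # polish: re-match peaks against the model's own Ka = 0 predictions
    for (pass in 1:2) {
      nall <- 2:min(cfg$Jmax, ceiling(window[2] / (bc0 * 0.9)))
      pred <- ka0_lines(nall, rep(0, length(nall)))
      pf <- tryCatch(predict(f0, pred), error = function(e) NULL)
      if (is.null(pf)) break
      hit <- lapply(seq_along(nall), function(i) {
        d <- abs(peaks$frequency - pf[i])
        j <- which.min(d)
        if (d[j] <= 0.4 && pf[i] >= window[1] && pf[i] <= window[2])
          c(nall[i], peaks$frequency[j]) else NULL
      })
      hit <- do.call(rbind, hit)
      if (is.null(hit) || nrow(hit) < 4) break
      ll2 <- ka0_lines(as.integer(hit[, 1]), hit[, 2])
      f2 <- tryCatch(fit_constants(ll2, f0$constants, f0$distortion,
                                   float = c("B", "DJ")),
                     error = function(e) NULL)
      if (is.null(f2)) break
      f0 <- f2
      lines <- ll2
    }
    if (f0$rms > 300 || f0$n_lines < 4) next
    d0 <- (cst[["B"]] - cst[["C"]]) / 2
    lo <- 0.6 * d0; hi <- 1.6 * d0
    sc <- 0L
    for (r in seq_len(nrow(lines))) {
      off <- (peaks$frequency - lines$frequency[r]) / lines$Ju[r]
      if (any(off >= lo & off <= hi) && any(off <= -lo & off >= -hi))
        sc <- sc + 1L
    }
    if (is.null(best) || sc > best$score ||
        (sc == best$score && f0$rms < best$fit$rms))
      best <- list(fit = f0, prog = pg, score = sc, lines = lines)
  }
  if (!is.null(best)) {
    # The fit floated only B, so the whole B+C correction sits on B and
    # B-C is distorted. Ka = 0 lines carry no B-C information: split the
    # correction evenly, keeping the starting (theory) B-C, which remains
    # the best estimate until Ka = 1 doublets are assigned.
    delta <- best$fit$constants[["B"]] - cst[["B"]]
    best$constants <- rotational_constants(best$fit$constants[["A"]],
                                           cst[["B"]] + delta / 2,
                                           cst[["C"]] + delta / 2)
    best$distortion <- best$fit$distortion
    # refit under the rebalanced asymmetry so DJ is not biased by the
    # B-heavy parametrization of the comb fit
    f2 <- tryCatch(fit_constants(best$lines, best$constants,
                                 best$distortion, float = c("B", "DJ")),
                   error = function(e) NULL)
    if (!is.null(f2)) {
      best$fit <- f2
      best$constants <- f2$constants
      best$distortion <- f2$distortion
    }
  }
  best
}

# The two a-type Ka = 1 doublet series, (n,1,n)<-(n-1,1,n-1) and
# (n,1,n-1)<-(n-1,1,n-2), run parallel to the Ka = 0 R-branch comb with
# spacings offset by roughly -(B-C)/2 and +(B-C)/2. Each side is detected
# as a whole progression among the peaks: a candidate comb qualifies when
# its spacing sits on the correct side of the Ka = 0 spacing by 0.5-1.7
# times the predicted (B-C)/2 (the window absorbs the starting-constant
# error). Members are returned as assigned Ka = 1 transitions; which
# quantum-number series is the high-frequency one is read off the current
# constants, not assumed.
# Iteratively refine a cubic comb nu = s*n + b*n^3 on a peak list: pick the
# single nearest peak per harmonic, refit, repeat; drop members whose final
# residual is out of scale. Robust against interleaved foreign series (LTS
# flavour: the selection converges to the majority/consistent series).
comb_polish <- function(peaks, s, b, nmin, nmax, window_mhz = 3) {
  for (pass in 1:5) {
    n <- round(peaks$frequency / s)
    n <- round((peaks$frequency - b * n^3) / s)
    res <- peaks$frequency - n * s - b * n^3
    sel <- which(n >= nmin & n <= nmax & abs(res) <= window_mhz)
    if (length(sel) < 4) return(NULL)
    sel <- sel[order(abs(res[sel]))]
    sel <- sel[!duplicated(n[sel])]
    nn <- n[sel]; ff <- peaks$frequency[sel]
    cf <- stats::lm.fit(cbind(nn, nn^3), ff)$coefficients
    s <- cf[[1]]; b <- cf[[2]]
  }
  res <- ff - nn * s - cf[[2]] * nn^3
  cut <- max(0.15, 5 * 1.4826 * stats::median(abs(res)))
  keep <- abs(res) <= cut
  if (sum(keep) < 4) return(NULL)
  list(n = nn[keep], frequency = ff[keep], spacing = s, curvature = b)
}

ka1_series <- function(ka0, cst, dst, peaks, cfg) {
  if (!nrow(ka0)) return(NULL)
  par <- c(unclass(cst), unclass(dst))
  s0 <- cst[["B"]] + cst[["C"]]
  d0 <- (cst[["B"]] - cst[["C"]]) / 2
  if (d0 < 0.5) return(NULL)          # doublets unresolved at comb scale
  nref <- max(3L, min(6L, max(ka0$Ju)))
  qn <- data.frame(Ju = rep(nref, 2), Kau = c(1L, 1L),
                   Kcu = c(nref, nref - 1L), Jl = rep(nref - 1L, 2),
                   Kal = c(1L, 1L), Kcl = c(nref - 1L, nref - 2L),
                   frequency = NA_real_, uncertainty = NA_real_)
  pf <- calc_lines(qn, par)$freq
  hi_first <- pf[1] > pf[2]            # is (n,1,n) the high-frequency series?
  rows <- list()
  side_ok <- function(progs, side) {
    ok <- vapply(progs, function(p) {
      off <- p$spacing - s0
      side * off > 0 && abs(off) >= 0.5 * d0 && abs(off) <= 1.7 * d0
    }, logical(1))
    progs[ok]
  }
  for (side in c(-1, 1)) {
    progs <- side_ok(find_progressions(peaks, spacing_hint = s0 + side * d0,
                                       rel_tol = cfg$prog_rel_tol,
                                       min_members = 5,
                                       max_curvature = 0.15), side)
    if (!length(progs))
      progs <- side_ok(find_progressions(peaks,
                                         spacing_hint = s0 + side * d0,
                                         rel_tol = cfg$prog_rel_tol,
                                         min_members = 4,
                                         max_curvature = 0.15), side)
    if (!length(progs)) next
    pg <- progs[[1]]
    # low harmonics first: above n ~ 8 the Ka = 1 series of a strong
    # species interleaves with its Ka = 2 doublet components and branch
    # identity needs the fitted DJK (the polish stages re-admit the high-n
    # members later). For weak species whose Ka = 2 stacks are below the
    # peak threshold the full range is safe, so fall back to it.
    pol <- comb_polish(peaks, pg$spacing, pg$curvature, 2L,
                       min(8L, cfg$Jmax))
    if (is.null(pol))
      pol <- comb_polish(peaks, pg$spacing, pg$curvature, 2L, cfg$Jmax)
    if (is.null(pol)) next
    n <- pol$n
    upper <- (side == 1) == hi_first   # TRUE -> (n,1,n) series
    rows[[length(rows) + 1L]] <- data.frame(
      Ju = n, Kau = 1L, Kcu = if (upper) n else n - 1L,
      Jl = n - 1L, Kal = 1L, Kcl = if (upper) n - 1L else n - 2L,
      frequency = pol$frequency, uncertainty = NA_real_)
  }
  if (!length(rows)) return(NULL)
  out <- do.call(rbind, rows)
  out <- out[order(out$frequency), ]
  rownames(out) <- NULL
  class(out) <- c("linelist", "data.frame")
  out
}

#' Iterative assignment and fitting against a broadband spectrum
#'
#' Implements the iterative measure-and-fit workflow used to analyse
#' jet-cooled broadband spectra of near-prolate rotors, starting from
#' quantum-chemistry constants good to a few percent. The stages mirror
#' manual practice:
#' \enumerate{
#' \item Bootstrap: a-type R-branch combs `nu ~ s*n + b*n^3` are located
#'   near the predicted B+C spacing (the cubic term is the
#'   centrifugal-distortion signature); the comb best explaining the
#'   cluster symmetry is read directly as the Ka = 0 series, calibrating
#'   B+C and DJ before any tolerance matching.
#' \item The Ka = 0 series is refined by prediction matching.
#' \item The two Ka = 1 doublet satellite series (combs offset by about
#'   +/- (B-C)/2 per harmonic) fix B-C and DJK.
#' \item The Ka <= 1 solution is polished at shrinking tolerance; if b- or
#'   c-type dipoles are present, A is calibrated by a scan that counts
#'   b/c-type prediction-peak matches; finally all predicted lines
#'   (high-Ka blends, b/c-type) are admitted at tight tolerance and A
#'   floats where the data determine it.
#' }
#' Peaks left over afterwards are candidates for a further species (a
#' second rotamer is found by re-running on them).
#'
#' @param spectrum A `rotspec` broadband spectrum.
#' @param initial List with starting `constants` (coercible), optional
#'   `distortion`, and `dipoles` (coercible) — typically one conformer's
#'   quantum-chemistry predictions.
#' @param config Optional list overriding defaults: `snr` (peak threshold,
#'   default 5), `T` (rotational temperature K, default 2), `Jmax` (default
#'   20), `tol_start`/`tol_end` (bracketing match tolerances, MHz, default
#'   2 and 0.05), `blend_tol` (MHz, default 0.08; scale with the
#'   linewidth), `min_intensity` (relative prediction cutoff, default
#'   1e-4), `leftover_tol` (MHz, default 0.15), `prog_rel_tol` (comb
#'   residual tolerance, default 0.005), `verbose` (print stage progress).
#' @return List with `fit` (a `rotfit`), `lines` (assigned `linelist`),
#'   `leftovers` (unassigned peaks away from any fitted-species line),
#'   `peaks` (all picked peaks), `progression` (the comb used to calibrate
#'   B+C).
#' @export
iterate_assign_fit <- function(spectrum, initial, config = list()) {
  cfg <- utils::modifyList(
    list(snr = 5, T = 2, Jmax = 20, tol_start = 2, tol_end = 0.05,
         blend_tol = 0.08, min_intensity = 1e-4,
         leftover_tol = 0.15, prog_rel_tol = 0.005, verbose = FALSE), config)
  window <- range(spectrum$frequency)
  peaks <- peak_pick(spectrum, cfg$snr)
  if (!nrow(peaks)) stop("no peaks above threshold: nothing to assign")
  cst <- as_rotconst(initial$constants)
  dst <- as_quartic(initial$distortion)
  mu <- as_dipole(initial$dipoles)

  trim_refit <- function(asg_lines, fit, float) {
    for (pass in 1:2) {
      res <- fit$residuals
      cut <- max(4 * 1.4826 * stats::median(abs(res - stats::median(res))), 30)
      bad <- abs(res) > cut
      if (!any(bad) || sum(!bad) < length(float) + 2) break
      kept <- asg_lines[asg_lines$frequency %in% fit$observed[!bad], ,
                        drop = FALSE]
      refit <- tryCatch(fit_constants(kept, fit$constants, fit$distortion,
                                      float = float),
                        error = function(e) NULL)
      if (is.null(refit)) break
      asg_lines <- kept
      fit <- refit
    }
    list(lines = asg_lines, fit = fit)
  }

  boot <- ka0_bootstrap(peaks, cst, dst, mu, cfg, window, trim_refit)
  if (is.null(boot))
    stop("no progression found: no peak comb near the predicted B+C = ",
         round(cst[["B"]] + cst[["C"]], 2),
         " MHz could be read as a Ka = 0 R-branch series")
  prog <- boot$prog
  cst <- boot$constants
  dst <- boot$distortion

  # Assignment phases mirror how broadband near-prolate spectra are analysed
  # by hand: (1) the Ka = 0 R-branch series, whose predictions are reliable
  # once B+C is comb-calibrated, pins B+C and DJ; (2) the Ka = 1 doublet
  # series fixes B-C and DJK; (3) the full Ka cluster stacks, now predicted
  # accurately, let A float. The matching tolerance shrinks within each
  # phase; A stays fixed until phase 3 because a-type low-Ka lines leave it
  # nearly unobservable.
  say <- function(...) if (isTRUE(cfg$verbose)) message(sprintf(...))
  fit <- boot$fit
  assigned <- list(lines = boot$lines,
                   ambiguous = peaks[0, , drop = FALSE],
                   unassigned = peaks)

  # Stage A: refine the Ka = 0 series by prediction matching.
  for (tol in c(cfg$tol_start / 2, cfg$tol_start / 4)) {
    pred <- simulate_lines(cst, dst, mu, T = cfg$T, window = window,
                           Jmax = cfg$Jmax)
    pred <- pred[pred$Kau == 0 & pred$Kal == 0, , drop = FALSE]
    asg <- assign_lines(peaks, pred, match_tol = tol,
                        blend_tol = cfg$blend_tol, ambiguity = "nearest")
    nobs <- length(unique(asg$lines$frequency))
    if (nobs < 3) next
    float <- if (nobs >= 6 && max(asg$lines$Jl) >= 8) c("B", "DJ") else "B"
    newfit <- tryCatch(fit_constants(asg$lines, cst, dst, float = float),
                       error = function(e) NULL)
    if (is.null(newfit)) next
    tr <- trim_refit(asg$lines, newfit, float)
    fit <- tr$fit; asg$lines <- tr$lines
    cst <- fit$constants; dst <- fit$distortion
    assigned <- asg
    say("Ka=0 stage (tol %.2f): %d lines, rms %.1f kHz", tol, fit$n_lines,
        fit$rms)
  }
  ka0 <- assigned$lines[assigned$lines$Kau == 0 & assigned$lines$Kal == 0, ,
                        drop = FALSE]

  # Stage B: the two Ka = 1 doublet series run parallel to the Ka = 0 comb
  # with spacings offset by roughly +/- (B-C)/2. Detecting each side as a
  # whole progression (rather than peak by peak) gives series-level
  # consistency; their joint fit with the Ka = 0 lines fixes B-C and DJK.
  sats <- ka1_series(ka0, cst, dst, peaks, cfg)
  if (!is.null(sats) && nrow(sats) >= 4) {
    core <- c("Ju", "Kau", "Kcu", "Jl", "Kal", "Kcl", "frequency",
              "uncertainty")
    lines <- rbind(ka0[, core], sats[, core])
    class(lines) <- c("linelist", "data.frame")
    lines <- lines[order(lines$frequency), ]
    float <- c("B", "C", "DJ")
    if (nrow(sats) >= 6 && max(lines$Jl) >= 8) float <- c(float, "DJK")
    newfit <- tryCatch(fit_constants(lines, cst, dst, float = float),
                       error = function(e) NULL)
    if (!is.null(newfit)) {
      tr <- trim_refit(lines, newfit, float)
      fit <- tr$fit
      cst <- fit$constants; dst <- fit$distortion
      assigned$lines <- tr$lines
      say("Ka=1 stage: %d lines (%d satellites), rms %.1f kHz",
          fit$n_lines, nrow(sats), fit$rms)
    }
  }

  # Stage C: polish the Ka <= 1 solution at shrinking tolerance (DJK must
  # be solid before the dense high-Ka stacks are trusted); calibrate A by
  # a scan against any b/c-type lines (the only transitions with real A
  # sensitivity while the starting A is off by tens of MHz); then admit
  # all predicted lines — Ka >= 2 blends and b/c-type — at tight
  # tolerance, where chance matches are improbable, floating A last.
  run_step <- function(Kacap, tol, allow_bc) {
    pred <- simulate_lines(cst, dst, mu, T = cfg$T, window = window,
                           Jmax = cfg$Jmax)
    pred <- pred[pred$intensity > cfg$min_intensity * max(pred$intensity) &
                   pmax(pred$Kau, pred$Kal) <= Kacap, , drop = FALSE]
    if (!allow_bc) pred <- pred[pred$type == "a", , drop = FALSE]
    asg <- assign_lines(peaks, pred, match_tol = tol,
                        blend_tol = cfg$blend_tol, ambiguity = "nearest")
    nobs <- length(unique(asg$lines$frequency))
    if (nobs < 6) return(NULL)
    maxKa <- max(asg$lines$Kau, asg$lines$Kal)
    has_bc <- any(transition_type(asg$lines) != "a")
    both_ka1 <- any(asg$lines$Kau == 1 & asg$lines$Kcu == asg$lines$Ju) &&
      any(asg$lines$Kau == 1 & asg$lines$Kcu == asg$lines$Ju - 1)
    float <- c("B", "C", "DJ")
    if (nobs >= 8 && max(asg$lines$Jl) >= 8) float <- c(float, "DJK")
    # A is identifiable from Ka >= 2 structure, b/c-type lines, or (weakly,
    # through the asymmetry splitting) both Ka = 1 doublet series together
    if ((maxKa >= 2 || has_bc || both_ka1) && Kacap > 1 && nobs >= 10)
      float <- c("A", float)
    newfit <- NULL
    for (fl in list(float, setdiff(float, "A"),
                    setdiff(float, c("A", "DJK")))) {
      newfit <- tryCatch(fit_constants(asg$lines, cst, dst, float = fl),
                         error = function(e) NULL)
      if (!is.null(newfit)) { float <- fl; break }
    }
    if (is.null(newfit)) return(NULL)
    tr <- trim_refit(asg$lines, newfit, float)
    asg$lines <- tr$lines
    list(fit = tr$fit, asg = asg, float = float)
  }
  for (stp in list(c(1L, 8 * cfg$tol_end), c(1L, 3 * cfg$tol_end))) {
    st <- run_step(stp[1], stp[2], allow_bc = FALSE)
    if (is.null(st)) next
    fit <- st$fit; assigned <- st$asg
    cst <- fit$constants; dst <- fit$distortion
    say("polish stage (Ka<=%d, tol %.2f): %d lines, float {%s}, rms %.1f kHz",
        stp[1], stp[2], fit$n_lines, paste(st$float, collapse = ","), fit$rms)
  }

  # A-scan against b/c-type structure (skipped without b/c dipoles)
  allow_bc <- FALSE
  if (mu[["mu_b"]] > 0 || mu[["mu_c"]] > 0) {
    score_A <- function(Aval, win) {
      cs <- rotational_constants(max(Aval, cst[["B"]] + 1), cst[["B"]],
                                 cst[["C"]])
      pred <- simulate_lines(cs, dst, mu, T = cfg$T, window = window,
                             Jmax = cfg$Jmax)
      pred <- pred[pred$type != "a" &
                     pred$intensity > 1e-3 * max(pred$intensity), ,
                   drop = FALSE]
      if (!nrow(pred)) return(0L)
      sum(vapply(pred$frequency,
                 function(f) any(abs(peaks$frequency - f) <= win),
                 logical(1)))
    }
    grid1 <- cst[["A"]] + seq(-40, 40, by = 2)
    s1 <- vapply(grid1, score_A, integer(1), win = 1.5)
    if (max(s1) >= 3) {
      grid2 <- grid1[which.max(s1)] + seq(-2.5, 2.5, by = 0.25)
      s2 <- vapply(grid2, score_A, integer(1), win = 0.4)
      if (max(s2) >= 3) {
        cst <- rotational_constants(grid2[which.max(s2)], cst[["B"]],
                                    cst[["C"]])
        allow_bc <- TRUE
        say("A scan: A = %.2f MHz (%d b/c-type matches)", cst[["A"]],
            max(s2))
      }
    }
  }

  prev_key <- NULL
  for (stp in list(c(cfg$Jmax, 2 * cfg$tol_end), c(cfg$Jmax, cfg$tol_end),
                   c(cfg$Jmax, cfg$tol_end))) {
    st <- run_step(stp[1], stp[2], allow_bc = allow_bc)
    if (is.null(st)) next
    fit <- st$fit; assigned <- st$asg
    cst <- fit$constants; dst <- fit$distortion
    say("full stage (tol %.2f): %d lines, float {%s}, rms %.1f kHz",
        stp[2], fit$n_lines, paste(st$float, collapse = ","), fit$rms)
    key <- paste(sort(sprintf("%.4f", assigned$lines$frequency)),
                 collapse = ";")
    if (identical(key, prev_key)) break
    prev_key <- key
  }
  pred <- simulate_lines(cst, dst, mu, T = cfg$T, window = window,
                         Jmax = cfg$Jmax)
  pred <- pred[pred$intensity > cfg$min_intensity * max(pred$intensity), ]
  near <- vapply(peaks$frequency,
                 function(f) min(abs(pred$frequency - f)) <= cfg$leftover_tol,
                 logical(1))
  list(fit = fit, lines = assigned$lines, leftovers = peaks[!near, , drop = FALSE],
       peaks = peaks, progression = prog)
}
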