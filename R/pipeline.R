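#' Run the full conformational-analysis workflow
#'
#' Orchestrates the pipeline: synthesize or load a broadband spectrum,
#' discover and fit rotameric species by iterative assignment, match them to
#' predicted conformers by rotational-constant scale factors, model
#' populations with Boltzmann statistics and collisional relaxation, and
#' evaluate the glucophore triangle of a geometry. Any stage may be omitted
#' from the configuration; completed stages are reported even when a later
#' stage fails.
#'
#' @param config A configuration list, or the path to a YAML file holding
#'   one. Recognized top-level keys (all optional unless a stage needs
#'   them):
#' \describe{
#'   \item{seed}{integer seed logged and used by every random stage.}
#'   \item{conformers}{path to a conformer table (TSV), or `"builtin"` for
#'     [dulcin_conformers()]. Needed by generate/discover/match/populations.}
#'   \item{generate}{list(ids, fractions, window, T, line_noise_kHz,
#'     spectrum_noise, n_interlopers, fwhm, grid_step): synthesize the
#'     spectrum from the named conformers.}
#'   \item{spectrum}{path to a two-column spectrum file (alternative to
#'     generate).}
#'   \item{discover}{list(candidates = conformer ids tried in order, each on
#'     the leftovers of the previous fit; plus any [iterate_assign_fit()]
#'     config overrides).}
#'   \item{populations}{list(T, field, threshold, edges = data frame or TSV
#'     path with from/to/barrier).}
#'   \item{glucophore}{list(xyz = path or `"toy"`, donor = c(heavy, H),
#'     acceptor, gamma = index vector).}
#' }
#' @param out Optional output directory: writes `report.md` and
#'   `report.json` there.
#' @return List of stage results (class `rotjet_report`), invisibly when
#'   `out` is given.
#' @export
run_analysis <- function(config, out = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  known <- c("seed", "conformers", "generate", "spectrum", "discover",
             "populations", "glucophore")
  bad <- setdiff(names(config), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  seed <- if (!is.null(config$seed)) as.integer(config$seed) else 1L
  res <- list(seed = seed)

  table <- NULL
  if (!is.null(config$conformers)) {
    table <- if (identical(config$conformers, "builtin")) dulcin_conformers()
    else read_conformer_table(config$conformers)
  }

  spec <- NULL
  truth <- NULL
  if (!is.null(config$generate)) {
    gcfg <- config$generate
    if (is.null(table)) stop("stage generate: needs 'conformers'")
    rows <- if (!is.null(gcfg$ids)) table[table$id %in% gcfg$ids, ] else table
    if (!nrow(rows)) stop("stage generate: no matching conformer ids")
    fr <- if (!is.null(gcfg$fractions))
      stats::setNames(as.numeric(gcfg$fractions), rows$id) else NULL
    sc <- scenario_config(
      rows, fractions = fr,
      T = gcfg$T %||% 2,
      window = if (!is.null(gcfg$window)) as.numeric(gcfg$window) else c(2000, 8000),
      line_noise_kHz = gcfg$line_noise_kHz %||% 10,
      spectrum_noise = gcfg$spectrum_noise %||% 0.01,
      n_interlopers = gcfg$n_interlopers %||% 20,
      fwhm = gcfg$fwhm %||% 0.15, grid_step = gcfg$grid_step %||% 0.03,
      seed = seed)
    gb <- gen_broadband(sc)
    spec <- gb$spectrum
    truth <- gb$lines
    res$generate <- list(n_lines = nrow(gb$lines), scenario = sc)
  } else if (!is.null(config$spectrum)) {
    spec <- read_spectrum(config$spectrum)
  }

  if (!is.null(config$discover)) {
    if (is.null(spec)) stop("stage discover: needs 'generate' or 'spectrum'")
    if (is.null(table)) stop("stage discover: needs 'conformers'")
    dcfg <- config$discover
    cands <- dcfg$candidates %||% table$id
    over <- dcfg[setdiff(names(dcfg), "candidates")]
    fits <- list()
    current <- spec
    for (id in cands) {
      row <- table[table$id == id, ]
      if (!nrow(row)) stop("stage discover: unknown candidate id ", id)
      initial <- list(constants = c(A = row$A, B = row$B, C = row$C),
                      dipoles = c(mu_a = row$mu_a, mu_b = row$mu_b,
                                  mu_c = row$mu_c))
      r <- tryCatch(iterate_assign_fit(current, initial, over),
                    error = function(e) e)
      if (inherits(r, "error")) {
        fits[[id]] <- list(error = conditionMessage(r))
        next
      }
      fits[[id]] <- r
      # later candidates are searched in the leftover peaks only
      left <- r$leftovers
      keep <- rep(TRUE, nrow(current))
      if (nrow(left)) {
        step <- current$frequency[2] - current$frequency[1]
        assigned_f <- setdiff(r$peaks$frequency, left$frequency)
        for (f in assigned_f)
          keep[abs(current$frequency - f) < 3 * (over$fwhm %||% 0.15)] <- FALSE
      }
      current <- new_spectrum(current$frequency,
                              ifelse(keep, current$intensity, 0))
    }
    res$discover <- fits
    # match each successful fit against the table
    res$match <- lapply(Filter(function(f) is.null(f$error), fits),
                        function(f) {
                          obs <- unique(f$lines$type)
                          match_conformers(f$fit$constants, table,
                                           observed_types = obs)
                        })
  }

  if (!is.null(config$populations)) {
    if (is.null(table)) stop("stage populations: needs 'conformers'")
    pcfg <- config$populations
    T <- pcfg$T %||% 298
    field <- pcfg$field %||% default_energy_field(table)
    pre <- boltzmann_fractions(table, T = T, field = field)
    post <- pre
    edges <- NULL
    if (!is.null(pcfg$edges)) {
      edges <- if (is.character(pcfg$edges))
        utils::read.table(pcfg$edges, header = TRUE, stringsAsFactors = FALSE)
      else as.data.frame(pcfg$edges)
      post <- relax_fractions(pre, edges, threshold = pcfg$threshold %||% 400)
    }
    res$populations <- list(T = T, field = field, pre = pre, post = post,
                            edges = edges,
                            detectability = detectability(table, post))
  }

  if (!is.null(config$glucophore)) {
    gcfg <- config$glucophore
    g <- if (identical(gcfg$xyz, "toy")) toy_urea_fixture()
    else read_xyz(gcfg$xyz)
    for (k in c("donor", "acceptor", "gamma"))
      if (is.null(gcfg[[k]])) stop("stage glucophore: missing key '", k, "'")
    res$glucophore <- glucophore_triangle(g, as.integer(gcfg$donor),
                                          as.integer(gcfg$acceptor),
                                          as.integer(gcfg$gamma))
  }

  class(res) <- "rotjet_report"
  if (!is.null(out)) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    writeLines(format_report(res), file.path(out, "report.md"))
    jsonlite::write_json(report_json(res), file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    return(invisible(res))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Markdown rendering of a pipeline report; timestamps confined to the header.
format_report <- function(res) {
  out <- c("# Rotational-spectroscopy conformational analysis",
           paste0("_Generated: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  "; seed ", res$seed, "_"), "")
  if (!is.null(res$discover)) {
    out <- c(out, "## Fitted rotamers", "")
    for (id in names(res$discover)) {
      f <- res$discover[[id]]
      if (!is.null(f$error)) {
        out <- c(out, sprintf("* candidate %s: %s", id, f$error))
        next
      }
      fit <- f$fit
      out <- c(out, sprintf("### Species seeded from %s", id), "",
               sprintf("| parameter | value (MHz) | std. error |"),
               "|---|---|---|",
               sprintf("| %s | %.6f | %.6f |", fit$float, fit$coefficients,
                       fit$se),
               "",
               sprintf("sigma = %.2f kHz, N = %d lines", fit$rms, fit$n_lines),
               "")
      m <- res$match[[id]]
      if (!is.null(m))
        out <- c(out, sprintf("Best match: conformer %s (scale factors %s)",
                              m$best,
                              paste(sprintf("%.4f", m$scale_factors),
                                    collapse = ", ")), "")
    }
  }
  if (!is.null(res$populations)) {
    p <- res$populations
    out <- c(out, "## Conformational populations",
             sprintf("_T = %g K, energy field %s_", p$T, p$field), "",
             "| conformer | pre-jet | post-relaxation |", "|---|---|---|",
             sprintf("| %s | %.4f | %.4f |", names(p$pre), p$pre,
                     p$post[names(p$pre)]), "")
  }
  if (!is.null(res$glucophore)) {
    gl <- res$glucophore
    out <- c(out, "## Glucophore triangle",
             sprintf("AH...B %.3f A, AH...gamma %.3f A, B...gamma %.3f A: %s",
                     gl$d_AH_B, gl$d_AH_gamma, gl$d_B_gamma,
                     if (gl$compliant) "compliant" else "not compliant"), "")
  }
  out
}

report_json <- function(res) {
  j <- list(seed = res$seed)
  if (!is.null(res$discover)) {
    j$rotamers <- lapply(res$discover, function(f) {
      if (!is.null(f$error)) return(list(error = f$error))
      list(parameters = as.list(f$fit$coefficients),
           standard_errors = as.list(stats::setNames(f$fit$se, f$fit$float)),
           sigma_kHz = f$fit$rms, n_lines = f$fit$n_lines)
    })
    j$match <- lapply(res$match, function(m)
      list(best = m$best, scale_factors = as.list(m$scale_factors)))
  }
  if (!is.null(res$populations))
    j$populations <- list(T = res$populations$T,
                          field = res$populations$field,
                          pre = as.list(res$populations$pre),
                          post = as.list(res$populations$post))
  if (!is.null(res$glucophore))
    j$glucophore <- list(d_AH_B = res$glucophore$d_AH_B,
                         d_AH_gamma = res$glucophore$d_AH_gamma,
                         d_B_gamma = res$glucophore$d_B_gamma,
                         compliant = res$glucophore$compliant)
  j
}

#' @export
print.rotjet_report <- function(x, ...) {
  cat(paste(format_report(x), collapse = "\n"), "\n")
  invisible(x)
}
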