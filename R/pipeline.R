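# Run configuration and end-to-end pipeline drivers.

#' Default run configuration
#'
#' Flat list of documented defaults for the glycoprofiling pipeline.
#' Fields: `fasta` (protein FASTA path), `peaklists` (comma-separated
#' peak-list paths), `out_dir`, `protease`, `max_missed`, `tol_ppm`,
#' `combine` (`pooled`/`per_digest`), `carbamidomethyl` (apply fixed Cys
#' modification), `chymo_residues` (comma-separated specificity set),
#' `hexnac_min` .. `neugc_max` (composition bounds), `assoc_end` and
#' `dissoc_end` (BLI phase boundaries in s), `fit_offset`, `seed`.
#'
#' @return Named list of defaults.
#' @export
default_run_config <- function() {
  list(
    fasta = "",
    peaklists = "",
    out_dir = ".",
    protease = "trypsin",
    max_missed = 2L,
    tol_ppm = 10,
    combine = "pooled",
    carbamidomethyl = TRUE,
    chymo_residues = "F,W,Y,L",
    hexnac_min = 2L, hexnac_max = 8L,
    hex_min = 3L, hex_max = 12L,
    fuc_min = 0L, fuc_max = 2L,
    neuac_min = 0L, neuac_max = 4L,
    neugc_min = 0L, neugc_max = 2L,
    assoc_end = 600,
    dissoc_end = 1200,
    fit_offset = TRUE,
    seed = 1L
  )
}

#' Write a run configuration as flat key = value text
#'
#' @param config Named list (as [default_run_config()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  lines <- vapply(names(config), function(nm) {
    sprintf("%s = %s", nm, format(config[[nm]], digits = 15))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a run configuration
#'
#' Parses a flat `key = value` text file (`#` comments allowed). Values are
#' coerced to the type of the corresponding default; unknown keys are
#' rejected.
#'
#' @param path Config file path.
#' @param defaults Defaults to fill unset keys (default
#'   [default_run_config()]).
#' @return Named list.
#' @export
read_run_config <- function(path, defaults = default_run_config()) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  config <- defaults
  for (ln in lines) {
    eq <- regexpr("=", ln, fixed = TRUE)
    key <- if (eq > 0) trimws(substr(ln, 1L, eq - 1L)) else ""
    if (eq < 0 || !nzchar(key)) {
      stop("malformed config line: '", ln, "'", call. = FALSE)
    }
    val <- trimws(substring(ln, eq + 1L))
    if (!key %in% names(defaults)) {
      stop("unknown config key: '", key, "'", call. = FALSE)
    }
    proto <- defaults[[key]]
    config[[key]] <- suppressWarnings(if (is.logical(proto)) {
      as.logical(val)
    } else if (is.integer(proto)) {
      as.integer(val)
    } else if (is.numeric(proto)) {
      as.numeric(val)
    } else {
      val
    })
    if (is.na(config[[key]]) && !is.na(proto)) {
      stop("cannot parse value for config key '", key, "': '", val, "'",
           call. = FALSE)
    }
  }
  config
}

.config_bounds <- function(config) {
  list(hexnac = c(config$hexnac_min, config$hexnac_max),
       hex = c(config$hex_min, config$hex_max),
       fuc = c(config$fuc_min, config$fuc_max),
       neuac = c(config$neuac_min, config$neuac_max),
       neugc = c(config$neugc_min, config$neugc_max))
}

.config_mods <- function(config) {
  if (isTRUE(config$carbamidomethyl)) default_fixed_mods() else numeric()
}

#' Run the glycoprofiling pipeline end to end
#'
#' FASTA -> digest -> theoretical table -> peak matching -> classification
#' -> per-site quantification -> report files. Stage counts are logged via
#' [message()].
#'
#' @param config A config list ([default_run_config()]) or the path of a
#'   config file ([read_run_config()]).
#' @return The [quantify_profiles()] result, invisibly; report files are
#'   written to `config$out_dir`.
#' @export
run_profile <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  if (!nzchar(config$fasta)) {
    stop("profile stage: no FASTA path configured", call. = FALSE)
  }
  proteins <- read_fasta(config$fasta)
  sequence <- proteins[[1]]
  message("profile: protein of ", nchar(sequence), " residues, ",
          nrow(find_sequons(sequence)), " sequon(s)")

  table <- build_glycopeptide_table(
    sequence, protease = config$protease, max_missed = config$max_missed,
    bounds = .config_bounds(config), fixed_mods = .config_mods(config),
    chymo_residues = strsplit(config$chymo_residues, ",")[[1]]
  )
  message("profile: theoretical table of ", nrow(table), " glycopeptides")

  paths <- trimws(strsplit(config$peaklists, ",")[[1]])
  paths <- paths[nzchar(paths)]
  if (!length(paths)) {
    stop("profile stage: no peak lists configured", call. = FALSE)
  }
  pls <- lapply(paths, read_peaklist)
  n_peaks <- sum(vapply(pls, nrow, integer(1)))
  res <- match_peaklists(pls, table, tol_ppm = config$tol_ppm)
  n_matched <- if (is.null(res$matches)) 0L else nrow(res$matches)
  message("profile: ", n_peaks, " peaks, ", n_matched, " matched, ",
          nrow(res$unmatched), " unmatched (tol ", config$tol_ppm, " ppm)")

  profiles <- quantify_profiles(res$matches, combine = config$combine)
  message("profile: ", length(profiles), " site profile(s), ",
          attr(profiles, "excluded_multi_sequon"),
          " multi-sequon bare-peptide match(es) excluded")

  files <- render_report(profiles, res, config$out_dir)
  message("profile: report written to ", config$out_dir)
  invisible(structure(profiles, files = files, match_result = res))
}

#' Run the full synthetic round-trip demo
#'
#' Generates a synthetic glycoprotein with planted sequons, ground-truth
#' glycoform distributions, noisy peak lists and 1:1 binding sensorgrams;
#' runs the matching/quantification pipeline and the global kinetic fit;
#' and reports recovery metrics: the maximal absolute per-site category
#' proportion error, the site-assignment accuracy over signal peaks, and
#' the relative KD error.
#'
#' @param seed Integer seed (default 1).
#' @param proteases Digests to simulate and pool (default trypsin,
#'   chymotrypsin and the double digest).
#' @param tol_ppm Matching tolerance; the default 20 ppm covers four
#'   standard deviations of the simulated 5 ppm mass error.
#' @param kon,koff,rmax True kinetic parameters for the sensorgram arm.
#' @param quiet Suppress the printed summary.
#' @return List with elements `profile_errors` (per site),
#'   `max_proportion_error`, `site_accuracy`, `kd_true`, `kd_fit`,
#'   `kd_rel_error`, `fit` and `profiles`, invisibly.
#' @export
run_demo <- function(seed = 1L,
                     proteases = c("trypsin", "chymotrypsin",
                                   "trypsin+chymotrypsin"),
                     tol_ppm = 20,
                     kon = 2.06e5, koff = 6.57e-4, rmax = 1,
                     quiet = FALSE) {
  truth <- synth_ground_truth(seed = seed)
  sims <- simulate_peaklist(truth, proteases = proteases)
  ## each digest is matched against its own theoretical table
  per_digest <- lapply(proteases, function(p) {
    table <- build_glycopeptide_table(truth$protein$sequence, protease = p,
                                      max_missed = 2L)
    match_peaks(sims[[p]]$peaklist, table, tol_ppm = tol_ppm)
  })
  res <- list(
    matches = do.call(rbind, Filter(Negate(is.null),
                                    lapply(per_digest, `[[`, "matches"))),
    unmatched = do.call(rbind, lapply(per_digest, `[[`, "unmatched"))
  )
  profiles <- quantify_profiles(res$matches, combine = "pooled")

  truth_props <- truth_category_proportions(truth)
  profile_errors <- vapply(names(truth_props), function(site_chr) {
    key <- paste("site", site_chr)
    est <- if (key %in% names(profiles)) profiles[[key]]$proportions else
      stats::setNames(numeric(), character())
    cats <- union(names(truth_props[[site_chr]]), names(est))
    tv <- vapply(cats, function(cc) {
      v <- truth_props[[site_chr]]
      if (cc %in% names(v)) v[[cc]] else 0
    }, numeric(1))
    ev <- vapply(cats, function(cc) if (cc %in% names(est)) est[[cc]] else 0,
                 numeric(1))
    max(abs(tv - ev))
  }, numeric(1))

  site_accuracy <- .site_assignment_accuracy(sims, res$matches)

  sg <- simulate_sensorgrams(kon = kon, koff = koff, rmax = rmax,
                             seed = seed + 10L)
  fit <- bli_global_fit(sg)
  kd_true <- bli_kd(kon, koff)
  kd_rel_error <- abs(fit$kd - kd_true) / kd_true

  if (!quiet) {
    cat("Synthetic round-trip demo (seed ", seed, ")\n", sep = "")
    cat("  per-site max |proportion error|:\n")
    for (nm in names(profile_errors)) {
      cat(sprintf("    site N%-4s %.4f\n", nm, profile_errors[[nm]]))
    }
    cat(sprintf("  site assignment accuracy: %.4f\n", site_accuracy))
    cat(sprintf("  KD true %.3f nM, fitted %.3f nM (rel. error %.2f%%)\n",
                kd_true * 1e9, fit$kd * 1e9, 100 * kd_rel_error))
  }
  invisible(list(
    profile_errors = profile_errors,
    max_proportion_error = max(profile_errors),
    site_accuracy = site_accuracy,
    kd_true = kd_true, kd_fit = fit$kd, kd_rel_error = kd_rel_error,
    fit = fit, profiles = profiles, truth = truth, match_result = res
  ))
}

## fraction of matched signal (non-contaminant) peaks assigned to their
## true sequon site; provenance and matches are joined on (source, mass)
.site_assignment_accuracy <- function(sims, matches) {
  if (is.null(matches) || !nrow(matches)) return(NA_real_)
  prov <- do.call(rbind, lapply(sims, `[[`, "provenance"))
  key_prov <- paste(prov$source, sprintf("%.8f", prov$mass))
  key_match <- paste(matches$source, sprintf("%.8f", matches$peak_mass))
  idx <- match(key_match, key_prov)
  signal <- !is.na(idx) & !prov$contaminant[idx]
  if (!any(signal)) return(NA_real_)
  true_site <- prov$site[idx[signal]]
  assigned <- matches$site[signal]
  mean(!is.na(assigned) & assigned == true_site)
}
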