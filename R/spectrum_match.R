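# Matching deconvoluted peak lists against theoretical glycopeptide tables
# and quantifying per-site glycoform profiles.

#' Read a deconvoluted peak list
#'
#' Parses a delimited text file of neutral monoisotopic masses and
#' intensities. Lines starting with `#` are treated as comments (the
#' synthetic generator embeds its parameters there). Columns are located by
#' name when a header is present, else positionally (mass first, intensity
#' second).
#'
#' @param path Path to the peak-list file.
#' @param sep Field separator; `NULL` (default) infers `,` for `.csv` and
#'   tab otherwise.
#' @param mass_col,intensity_col Column names used when the file has a
#'   header.
#' @param source Label recorded on the peak list (e.g. the digest
#'   identity); defaults to the file name.
#' @return A `peaklist`: data frame with columns `mass` and `intensity` and
#'   attribute `source`.
#' @export
read_peaklist <- function(path, sep = NULL, mass_col = "mass",
                          intensity_col = "intensity",
                          source = basename(path)) {
  if (!file.exists(path)) {
    stop("peak-list file not found: ", path, call. = FALSE)
  }
  if (is.null(sep)) {
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) stop("no parsable rows in ", path, call. = FALSE)

  fields <- strsplit(lines, sep, fixed = TRUE)
  first <- fields[[1]]
  has_header <- suppressWarnings(any(is.na(as.numeric(first))))
  if (has_header) {
    header <- trimws(first)
    mi <- match(mass_col, header)
    ii <- match(intensity_col, header)
    if (is.na(mi) || is.na(ii)) {
      mi <- 1L
      ii <- 2L
    }
    fields <- fields[-1]
    line_no <- line_no[-1]
  } else {
    mi <- 1L
    ii <- 2L
  }
  if (!length(fields)) stop("no parsable rows in ", path, call. = FALSE)

  get_col <- function(j) {
    vapply(fields, function(f) if (length(f) >= j) trimws(f[j]) else NA_character_, "")
  }
  mass <- suppressWarnings(as.numeric(get_col(mi)))
  intensity <- suppressWarnings(as.numeric(get_col(ii)))
  bad <- which(is.na(mass) | is.na(intensity))
  if (length(bad)) {
    stop("non-numeric mass/intensity field(s) in ", path, " at line(s) ",
         paste(line_no[bad], collapse = ", "), call. = FALSE)
  }
  if (any(!is.finite(mass)) || any(mass <= 0)) {
    stop("masses must be finite and > 0 in ", path, call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("intensities must be non-negative in ", path, call. = FALSE)
  }
  peaklist(mass, intensity, source)
}

#' Construct a peak list
#'
#' @param mass Neutral monoisotopic masses in Da (finite, > 0).
#' @param intensity Non-negative intensities.
#' @param source Text label (e.g. digest identity).
#' @return A `peaklist` data frame.
#' @export
peaklist <- function(mass, intensity, source = "peaklist") {
  if (length(mass) != length(intensity)) {
    stop("mass and intensity lengths differ", call. = FALSE)
  }
  if (length(mass) && (any(!is.finite(mass)) || any(mass <= 0))) {
    stop("masses must be finite and > 0", call. = FALSE)
  }
  if (length(intensity) && any(intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  structure(data.frame(mass = as.numeric(mass),
                       intensity = as.numeric(intensity)),
            source = source, class = c("peaklist", "data.frame"))
}

#' Write a peak list as delimited text
#'
#' Parameters passed via `params` are embedded as `# key=value` comment
#' lines, making the file self-describing; [read_peaklist()] skips them.
#'
#' @param pl A [peaklist()].
#' @param path Output path; `.csv` gives comma separation, anything else
#'   tab.
#' @param params Optional named list recorded as comment header lines.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(pl, path, params = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    for (nm in names(params)) {
      writeLines(sprintf("# %s=%s", nm, format(params[[nm]], digits = 15)), con)
    }
  }
  writeLines(paste("mass", "intensity", sep = sep), con)
  writeLines(paste(sprintf("%.8f", pl$mass), format(pl$intensity, digits = 15),
                   sep = sep), con)
  invisible(path)
}

## number of distinct monosaccharide types in each composition row;
## zero when the table carries no composition columns
.n_glycan_types <- function(table) {
  if (!all(COMP_COLS %in% names(table))) return(rep(0L, nrow(table)))
  rowSums(as.matrix(table[COMP_COLS]) > 0)
}

#' Match peaks against a theoretical glycopeptide table
#'
#' A peak matches a table entry when the relative deviation
#' `|observed - theoretical| / theoretical * 1e6` is within `tol_ppm`. Each
#' peak is assigned to the candidate with the smallest absolute ppm error;
#' ties are broken by fewest distinct monosaccharide types, then lower
#' theoretical mass. Peaks with more than one in-tolerance candidate are
#' flagged ambiguous with the candidate count.
#'
#' @param peaks A [peaklist()].
#' @param table Theoretical table from [build_glycopeptide_table()] (any
#'   data frame with a `mass` column and the composition columns works).
#' @param tol_ppm Mass tolerance in parts per million (> 0).
#' @return List with elements `matches` (one row per assigned peak:
#'   `peak_mass`, `intensity`, `source`, `ppm_error`, `n_candidates`,
#'   `ambiguous`, plus all table columns of the chosen candidate) and
#'   `unmatched` (peaks with no in-tolerance candidate).
#' @export
match_peaks <- function(peaks, table, tol_ppm = 10) {
  if (!is.numeric(tol_ppm) || length(tol_ppm) != 1L || tol_ppm <= 0) {
    stop("tol_ppm must be a single positive number", call. = FALSE)
  }
  src <- attr(peaks, "source")
  if (is.null(src)) src <- "peaklist"
  empty_unmatched <- data.frame(mass = numeric(), intensity = numeric(),
                                source = character(), stringsAsFactors = FALSE)
  if (nrow(peaks) == 0L) {
    return(list(matches = NULL, unmatched = empty_unmatched))
  }
  if (is.null(table) || nrow(table) == 0L) {
    return(list(matches = NULL,
                unmatched = data.frame(mass = peaks$mass,
                                       intensity = peaks$intensity,
                                       source = src,
                                       stringsAsFactors = FALSE)))
  }

  ord <- order(table$mass)
  tmass <- table$mass[ord]
  ntypes <- .n_glycan_types(table)[ord]
  tol <- tol_ppm * 1e-6

  chosen <- integer(nrow(peaks))
  ppm_err <- numeric(nrow(peaks))
  n_cand <- integer(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    m <- peaks$mass[i]
    lo <- m / (1 + tol)
    hi <- m / (1 - tol)
    j0 <- findInterval(lo, tmass)          # last index with tmass <= lo
    j1 <- findInterval(hi, tmass)
    cand <- if (j1 > j0) seq.int(j0 + 1L, j1) else integer()
    if (length(cand)) {
      ppm <- (m - tmass[cand]) / tmass[cand] * 1e6
      keep <- abs(ppm) <= tol_ppm
      cand <- cand[keep]
      ppm <- ppm[keep]
    }
    if (!length(cand)) {
      chosen[i] <- NA_integer_
      next
    }
    pick <- order(abs(ppm), ntypes[cand], tmass[cand])[1]
    chosen[i] <- cand[pick]
    ppm_err[i] <- ppm[pick]
    n_cand[i] <- length(cand)
  }

  hit <- !is.na(chosen)
  matches <- if (any(hit)) {
    cbind(
      data.frame(peak_mass = peaks$mass[hit], intensity = peaks$intensity[hit],
                 source = src, ppm_error = ppm_err[hit],
                 n_candidates = n_cand[hit], ambiguous = n_cand[hit] > 1L,
                 stringsAsFactors = FALSE),
      table[ord[chosen[hit]], , drop = FALSE]
    )
  } else {
    NULL
  }
  if (!is.null(matches)) rownames(matches) <- NULL
  unmatched <- if (all(hit)) empty_unmatched else data.frame(
    mass = peaks$mass[!hit], intensity = peaks$intensity[!hit],
    source = src, stringsAsFactors = FALSE
  )
  list(matches = matches, unmatched = unmatched)
}

#' Match several peak lists against one table
#'
#' Convenience wrapper running [match_peaks()] per peak list and binding
#' the results.
#'
#' @param peaklists List of [peaklist()] objects (names override their
#'   `source` attributes).
#' @inheritParams match_peaks
#' @return As [match_peaks()], with `source` distinguishing the inputs.
#' @export
match_peaklists <- function(peaklists, table, tol_ppm = 10) {
  if (!is.null(names(peaklists))) {
    for (nm in names(peaklists)) {
      if (nzchar(nm)) attr(peaklists[[nm]], "source") <- nm
    }
  }
  res <- lapply(peaklists, match_peaks, table = table, tol_ppm = tol_ppm)
  matches <- do.call(rbind, Filter(Negate(is.null),
                                   lapply(res, `[[`, "matches")))
  unmatched <- do.call(rbind, lapply(res, `[[`, "unmatched"))
  rownames(unmatched) <- NULL
  if (!is.null(matches)) rownames(matches) <- NULL
  list(matches = matches, unmatched = unmatched)
}

#' Quantify per-site glycoform profiles from matched peaks
#'
#' Groups matched peaks by sequon site and computes category proportions
#' via [site_profile()]. Unglycosylated matches on peptides spanning more
#' than one sequon cannot be attributed to a single site; they are excluded
#' from normalization and counted in the `excluded_multi_sequon` attribute.
#'
#' @param matches The `matches` element of [match_peaks()] /
#'   [match_peaklists()].
#' @param combine `"pooled"` sums intensities across digests (sources) per
#'   site before normalizing; `"per_digest"` emits one profile per
#'   (site, source) pair.
#' @return Named list of [site_profile()] objects (names `site <pos>` or
#'   `site <pos> | <source>`), with attribute `excluded_multi_sequon`.
#' @export
quantify_profiles <- function(matches, combine = c("pooled", "per_digest")) {
  combine <- match.arg(combine)
  if (is.null(matches) || nrow(matches) == 0L) {
    return(structure(list(), excluded_multi_sequon = 0L))
  }
  multi <- is.na(matches$site)
  excluded <- sum(multi)
  matches <- matches[!multi, , drop = FALSE]
  if (!nrow(matches)) {
    return(structure(list(), excluded_multi_sequon = excluded))
  }
  key <- if (combine == "pooled") {
    matches$site
  } else {
    paste(matches$site, matches$source, sep = " | ")
  }
  groups <- split(matches, key)
  ## order by site position (then source)
  ord <- order(vapply(groups, function(g) g$site[1], numeric(1)),
               names(groups))
  groups <- groups[ord]
  profiles <- lapply(groups, site_profile)
  names(profiles) <- if (combine == "pooled") {
    paste("site", names(groups))
  } else {
    paste("site", names(groups))
  }
  structure(profiles, excluded_multi_sequon = excluded)
}

#' Write the glycoprofiling report files
#'
#' Writes three tab-separated tables: per-site category proportions (with
#' percentages rounded to 0.1), the full glycoform table (composition,
#' theoretical mass, ppm error, intensity, category and flags), and the
#' unmatched-peak table. Output is deterministic for a fixed input.
#'
#' @param profiles Output of [quantify_profiles()].
#' @param match_result Output of [match_peaks()] / [match_peaklists()].
#' @param out_dir Output directory (created if missing).
#' @param prefix File-name prefix (default `"glycoprofile"`).
#' @return Named character vector of the three file paths, invisibly.
#' @export
render_report <- function(profiles, match_result, out_dir,
                          prefix = "glycoprofile") {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) {
      stop("cannot create output directory: ", out_dir, call. = FALSE)
    }
  }
  paths <- c(
    sites = file.path(out_dir, paste0(prefix, "_site_proportions.tsv")),
    glycoforms = file.path(out_dir, paste0(prefix, "_glycoforms.tsv")),
    unmatched = file.path(out_dir, paste0(prefix, "_unmatched.tsv"))
  )

  ## (a) site-by-category proportion table, plus flagged fractions
  site_rows <- list()
  for (nm in names(profiles)) {
    pr <- profiles[[nm]]
    cats <- names(pr$proportions)
    if (length(cats)) {
      site_rows[[length(site_rows) + 1L]] <- data.frame(
        profile = nm, site = pr$site, kind = "category",
        name = cats,
        percent = round(100 * as.numeric(pr$proportions), 1),
        intensity = as.numeric(pr$proportions) * pr$total_intensity,
        stringsAsFactors = FALSE
      )
    }
    site_rows[[length(site_rows) + 1L]] <- data.frame(
      profile = nm, site = pr$site, kind = "flag",
      name = names(pr$flag_fractions),
      percent = round(100 * as.numeric(pr$flag_fractions), 1),
      intensity = as.numeric(pr$flag_fractions) * pr$total_intensity,
      stringsAsFactors = FALSE
    )
  }
  site_tab <- if (length(site_rows)) do.call(rbind, site_rows) else
    data.frame(profile = character(), site = integer(), kind = character(),
               name = character(), percent = numeric(), intensity = numeric())
  utils::write.table(site_tab, paths[["sites"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  ## (b) full glycoform table
  m <- match_result$matches
  if (!is.null(m) && nrow(m)) {
    cls <- classify_glycan(m)
    g <- cbind(m, cls)
    g <- g[order(g$source, g$site, g$mass), , drop = FALSE]
    g$ppm_error <- round(g$ppm_error, 3)
    utils::write.table(g, paths[["glycoforms"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    hdr <- c("peak_mass", "intensity", "source", "ppm_error", "n_candidates",
             "ambiguous", "peptide", "start", "end", "missed_cleavages",
             "site", "n_sequons", COMP_COLS, "mass", "primary", GLYCAN_FLAGS)
    writeLines(paste(hdr, collapse = "\t"), paths[["glycoforms"]])
  }

  ## (c) unmatched peaks
  u <- match_result$unmatched
  u <- u[order(u$source, u$mass), , drop = FALSE]
  utils::write.table(u, paths[["unmatched"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(paths)
}
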