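# Glycan category assignment and per-site glycoform profiles.

## reporting categories, in fixed display order
GLYCAN_CATEGORIES <- c("TerminalSia", "TerminalGal", "TerminalGlcNAc",
                       "HighMannose", "Unglycosylated")
GLYCAN_FLAGS <- c("fucosylated", "contains_neu5gc", "lacnac_repeat")

#' Classify glycan compositions into reporting categories
#'
#' Assigns each composition exactly one primary category, by precedence:
#' all-zero is `Unglycosylated`; HexNAc2 with at least five hexoses is
#' `HighMannose`; any sialic acid (NeuAc or NeuGc) is `TerminalSia`; more
#' than three hexoses (at least one galactose beyond the three core
#' mannoses) is `TerminalGal`; everything else is `TerminalGlcNAc`.
#' Independent flags: `fucosylated` (any fucose), `contains_neu5gc` (any
#' NeuGc), and `lacnac_repeat` for N-acetyllactosamine extensions, i.e.
#' more than six HexNAc and more than four galactoses (hex - 3 > 4).
#'
#' @inheritParams glycan_mass
#' @return Data frame with one row per composition: `primary` (character,
#'   one of `TerminalSia`, `TerminalGal`, `TerminalGlcNAc`, `HighMannose`,
#'   `Unglycosylated`) and logical columns `fucosylated`,
#'   `contains_neu5gc`, `lacnac_repeat`.
#' @examples
#' classify_glycan(glycan_composition(hexnac = 4, hex = 5, fuc = 1, neuac = 2))
#' @export
classify_glycan <- function(comp) {
  comp <- .check_composition(comp)
  if (is.numeric(comp)) comp <- as.data.frame(as.list(comp))
  total <- rowSums(comp[COMP_COLS])
  sia <- comp$neuac + comp$neugc
  primary <- ifelse(total == 0, "Unglycosylated",
             ifelse(comp$hexnac == 2 & comp$hex >= 5, "HighMannose",
             ifelse(sia >= 1, "TerminalSia",
             ifelse(comp$hex > 3, "TerminalGal", "TerminalGlcNAc"))))
  data.frame(
    primary = primary,
    fucosylated = comp$fuc >= 1,
    contains_neu5gc = comp$neugc >= 1,
    lacnac_repeat = comp$hexnac > 6 & (comp$hex - 3) > 4,
    stringsAsFactors = FALSE
  )
}

#' Per-site glycoform profile from matched intensities
#'
#' Aggregates matched glycopeptide intensities at a single sequon site into
#' relative category proportions. Unglycosylated peptide matches count in
#' the denominator.
#'
#' @param matches Data frame with the composition columns (`hexnac`, `hex`,
#'   `fuc`, `neuac`, `neugc`), an `intensity` column (non-negative), and a
#'   `site` column; all rows must share one site.
#' @return Object of class `site_glycoprofile`: a list with elements
#'   `site`, `proportions` (named fractions summing to 1 over categories
#'   with signal), `flag_fractions` (fraction of intensity carrying each
#'   flag) and `total_intensity`. An empty input yields total intensity 0
#'   and empty proportions.
#' @export
site_profile <- function(matches) {
  if (nrow(matches) == 0L) {
    return(structure(
      list(site = NA_integer_, proportions = stats::setNames(numeric(), character()),
           flag_fractions = stats::setNames(numeric(), character()),
           total_intensity = 0),
      class = "site_glycoprofile"
    ))
  }
  if (!"intensity" %in% names(matches)) {
    stop("matches must have an 'intensity' column", call. = FALSE)
  }
  if (any(matches$intensity < 0)) {
    stop("intensities must be non-negative", call. = FALSE)
  }
  sites <- unique(matches$site)
  if (length(sites) != 1L) {
    stop("matches span multiple sites (", paste(sites, collapse = ", "),
         "); profile one site at a time", call. = FALSE)
  }
  cls <- classify_glycan(matches)
  total <- sum(matches$intensity)
  props <- vapply(GLYCAN_CATEGORIES, function(cat) {
    sum(matches$intensity[cls$primary == cat])
  }, numeric(1))
  props <- props[props > 0 | GLYCAN_CATEGORIES %in% cls$primary]
  if (total > 0) props <- props / total
  flags <- vapply(GLYCAN_FLAGS, function(fl) {
    if (total > 0) sum(matches$intensity[cls[[fl]]]) / total else 0
  }, numeric(1))
  structure(
    list(site = sites, proportions = props, flag_fractions = flags,
         total_intensity = total),
    class = "site_glycoprofile"
  )
}

#' @export
print.site_glycoprofile <- function(x, ...) {
  cat("Site glycoprofile (site ", x$site, ", total intensity ",
      format(x$total_intensity, digits = 4), ")\n", sep = "")
  if (length(x$proportions)) {
    for (nm in names(x$proportions)) {
      cat(sprintf("  %-15s %5.1f%%\n", nm, 100 * x$proportions[[nm]]))
    }
  } else {
    cat("  (no matched intensity)\n")
  }
  invisible(x)
}

#' Sialylation summary of a site profile
#'
#' @param profile A [site_profile()] object.
#' @return Named numeric vector: `terminal_sia`, the proportion of
#'   sialylated glycans, and `sia_or_gal`, the combined proportion of
#'   sialylated plus terminal-galactose glycans.
#' @export
sialylation_summary <- function(profile) {
  if (!inherits(profile, "site_glycoprofile")) {
    stop("profile must be a site_glycoprofile", call. = FALSE)
  }
  p <- profile$proportions
  get <- function(nm) if (nm %in% names(p)) p[[nm]] else 0
  c(terminal_sia = get("TerminalSia"),
    sia_or_gal = get("TerminalSia") + get("TerminalGal"))
}
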