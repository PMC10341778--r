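# Seed-deterministic synthetic-data generators: glycoproteins with planted
# sequons, ground-truth glycoform distributions, noisy deconvoluted peak
# lists, 1:1 binding sensorgrams, and perfusion-culture time series.

## residues used for filler: no N (prevents accidental sequons), no K/R
## (cleavage sites are placed explicitly), no P (never blocks cleavage)
.FILLER_AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M",
                "Q", "S", "T", "V", "W", "Y")

.rdirichlet <- function(alpha) {
  x <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(x) == 0) x <- rep(1, length(alpha))
  x / sum(x)
}

## chunk a filler block of a given length into tryptic pieces <= 20 residues
.filler_block <- function(len) {
  if (len <= 0L) return(character(0))
  res <- sample(.FILLER_AA, len, replace = TRUE)
  ## replace some residues with K/R so no tryptic filler peptide is overlong
  if (len > 20L) {
    cut_at <- seq(15L, len - 5L, by = 15L)
    res[cut_at] <- sample(c("K", "R"), length(cut_at), replace = TRUE)
  }
  res
}

#' Generate a random glycoprotein with planted sequons
#'
#' Builds a random amino-acid sequence containing exactly `n_sites`
#' N-X-S/T sequons (X != P) and no accidental extras. Lysine/arginine
#' residues are placed so that each sequon lies on a tryptic
#' (zero-missed-cleavage) peptide of 5-25 residues. The construction is
#' verified against [find_sequons()] and [digest()] and retried with fresh
#' randomness on failure.
#'
#' @param n_sites Number of sequons to plant (default 5).
#' @param length Total sequence length (>= `3 * n_sites`; default 300).
#' @param seed Integer seed; fully determines the output.
#' @param max_tries Bounded number of construction attempts.
#' @return List with elements `id`, `sequence`, `sites` (the
#'   [find_sequons()] data frame) and `seed`.
#' @export
make_glycoprotein <- function(n_sites = 5L, length = 300L, seed = 1L,
                              max_tries = 100L) {
  if (length < 3L * n_sites) {
    stop("length must be at least 3 * n_sites", call. = FALSE)
  }
  withr::with_seed(seed, {
    for (try in seq_len(max_tries)) {
      seq_chr <- .build_glycoprotein_once(n_sites, length)
      if (is.null(seq_chr)) next
      sites <- find_sequons(seq_chr)
      if (nrow(sites) != n_sites) next
      if (n_sites > 0L) {
        peps <- digest(seq_chr, "trypsin", max_missed = 0L)
        cov_len <- vapply(sites$position, function(p) {
          hit <- peps$start <= p & peps$end >= p
          if (!any(hit)) return(0L)
          nchar(peps$sequence[hit][1])
        }, integer(1))
        if (any(cov_len < 5L | cov_len > 25L)) next
      }
      return(list(id = sprintf("synthetic_glycoprotein_%dsites_seed%d",
                               n_sites, seed),
                  sequence = seq_chr, sites = sites, seed = seed))
    }
    stop("could not construct a sequence satisfying the constraints after ",
         max_tries, " tries", call. = FALSE)
  })
}

## one construction attempt; NULL on infeasible length budgeting
.build_glycoprotein_once <- function(n_sites, length) {
  if (n_sites == 0L) {
    return(paste(.filler_block(length), collapse = ""))
  }
  ## sequon-carrying tryptic peptides: pre(>=1) + N X (S|T) + post + K/R
  pep_len <- sample(8:18, n_sites, replace = TRUE)
  n_fill <- n_sites + 1L
  remaining <- length - sum(pep_len)
  if (remaining < n_fill) {
    pep_len <- rep(5L, n_sites)
    remaining <- length - sum(pep_len)
    if (remaining < 0L) return(NULL)
  }
  fill_len <- rep(remaining %/% n_fill, n_fill)
  extra <- remaining - sum(fill_len)
  if (extra > 0L) fill_len[seq_len(extra)] <- fill_len[seq_len(extra)] + 1L

  parts <- character(0)
  for (i in seq_len(n_sites)) {
    fb <- .filler_block(fill_len[i])
    ## filler segments end on K/R so the sequon peptide starts cleanly
    if (length(fb) > 0L) fb[length(fb)] <- sample(c("K", "R"), 1L)
    L <- pep_len[i]
    a <- sample(seq_len(L - 4L), 1L)     # pre-motif length, >= 1
    b <- L - 4L - a
    pep <- c(sample(.FILLER_AA, a, replace = TRUE),
             "N",
             sample(.FILLER_AA, 1L),
             sample(c("S", "T"), 1L),
             if (b > 0L) sample(.FILLER_AA, b, replace = TRUE),
             sample(c("K", "R"), 1L))
    parts <- c(parts, fb, pep)
  }
  parts <- c(parts, .filler_block(fill_len[n_fill]))
  paste(parts, collapse = "")
}

#' Draw ground-truth per-site glycoform distributions
#'
#' For each site, category masses are drawn Dirichlet-style according to
#' `style`, then individual compositions are sampled within each category
#' from the default bounded composition space, with a Dirichlet split of
#' the category mass. `sialylated_heavy` emulates heavily sialylated
#' complex-type profiles (TerminalSia mass drawn in \[0.7, 1.0\]);
#' `mannose_heavy` draws a dominant high-mannose mass; `uniform` draws all
#' five category masses symmetrically.
#'
#' @param n_sites Number of sites.
#' @param style One of `"sialylated_heavy"`, `"mannose_heavy"`,
#'   `"uniform"`.
#' @param n_glycoforms Approximate number of glycoforms per site
#'   (default 10).
#' @param seed Integer seed.
#' @param bounds,constraints Composition space, as
#'   [enumerate_compositions()].
#' @return List of per-site data frames (composition columns plus
#'   `fraction`; fractions sum to 1).
#' @export
sample_profiles <- function(n_sites = 5L,
                            style = c("sialylated_heavy", "mannose_heavy",
                                      "uniform"),
                            n_glycoforms = 10L, seed = 1L,
                            bounds = default_composition_bounds(),
                            constraints = "default") {
  style <- match.arg(style)
  space <- enumerate_compositions(bounds, constraints)
  cls <- classify_glycan(space)$primary
  withr::with_seed(seed, {
    lapply(seq_len(n_sites), function(s) {
      w <- switch(style,
        sialylated_heavy = {
          sia <- stats::runif(1, 0.7, 1.0)
          rest <- (1 - sia) * .rdirichlet(c(4, 1, 0.7, 0.3))
          c(TerminalSia = sia, TerminalGal = rest[1],
            TerminalGlcNAc = rest[2], HighMannose = rest[3],
            Unglycosylated = rest[4])
        },
        mannose_heavy = {
          hm <- stats::runif(1, 0.6, 0.9)
          rest <- (1 - hm) * .rdirichlet(c(1, 1, 1, 0.3))
          c(TerminalSia = rest[1], TerminalGal = rest[2],
            TerminalGlcNAc = rest[3], HighMannose = hm,
            Unglycosylated = rest[4])
        },
        uniform = {
          w <- .rdirichlet(rep(1, 5))
          c(TerminalSia = w[1], TerminalGal = w[2], TerminalGlcNAc = w[3],
            HighMannose = w[4], Unglycosylated = w[5])
        }
      )
      rows <- list()
      for (cat in names(w)) {
        if (w[[cat]] <= 1e-6) next
        if (cat == "Unglycosylated") {
          rows[[cat]] <- cbind(glycan_composition(), fraction = w[[cat]])
          next
        }
        pool <- which(cls == cat)
        if (!length(pool)) next
        m <- min(length(pool), max(1L, round(n_glycoforms * w[[cat]])))
        pick <- if (length(pool) == 1L) pool else sample(pool, m)
        frac <- w[[cat]] * .rdirichlet(rep(2, length(pick)))
        rows[[cat]] <- cbind(space[pick, , drop = FALSE], fraction = frac)
      }
      out <- do.call(rbind, rows)
      out$fraction <- out$fraction / sum(out$fraction)
      rownames(out) <- NULL
      out
    })
  })
}

#' Assemble a synthetic ground truth
#'
#' Convenience constructor bundling a planted-sequon glycoprotein
#' ([make_glycoprotein()]) with per-site glycoform distributions
#' ([sample_profiles()]) and the noise parameters used by
#' [simulate_peaklist()].
#'
#' @inheritParams make_glycoprotein
#' @inheritParams sample_profiles
#' @param mass_error_sd_ppm Gaussian mass-error SD in ppm (default 5).
#' @param intensity_cv Lognormal intensity coefficient of variation
#'   (default 0.01).
#' @param contaminant_fraction Contaminant peaks as a fraction of signal
#'   peaks (default 0.1).
#' @return Object of class `ground_truth`.
#' @export
synth_ground_truth <- function(n_sites = 5L, length = 300L,
                               style = "sialylated_heavy",
                               n_glycoforms = 10L,
                               mass_error_sd_ppm = 5,
                               intensity_cv = 0.01,
                               contaminant_fraction = 0.1,
                               seed = 1L) {
  protein <- make_glycoprotein(n_sites, length, seed = seed)
  profiles <- sample_profiles(n_sites, style, n_glycoforms, seed = seed + 1L)
  names(profiles) <- as.character(protein$sites$position)
  structure(list(
    protein = protein, profiles = profiles,
    mass_error_sd_ppm = mass_error_sd_ppm, intensity_cv = intensity_cv,
    contaminant_fraction = contaminant_fraction, seed = seed
  ), class = "ground_truth")
}

## true per-site category proportions of a ground truth
truth_category_proportions <- function(truth) {
  lapply(truth$profiles, function(pr) {
    cls <- classify_glycan(pr)$primary
    vapply(split(pr$fraction, cls), sum, numeric(1))
  })
}

#' Simulate deconvoluted glycopeptide peak lists
#'
#' For each protease digest, selects the covering peptide of each sequon
#' (fewest missed cleavages, then shortest), emits one peak per
#' ground-truth glycoform at the theoretical glycopeptide mass perturbed by
#' Gaussian ppm error, with intensity proportional to the ground-truth
#' fraction under lognormal noise, and adds low-intensity contaminant peaks
#' at uniform random masses.
#'
#' @param truth A [synth_ground_truth()] object.
#' @param proteases Character vector of digests to simulate.
#' @param base_intensity Total signal intensity per site (arbitrary units).
#' @param fixed_mods Fixed modifications used for theoretical masses.
#' @param out_dir If non-`NULL`, each peak list is written there as a
#'   self-describing TSV via [write_peaklist()].
#' @param seed Integer seed; defaults to `truth$seed + 2`.
#' @return Named list (one element per protease) of lists with `peaklist`,
#'   `provenance` (true site/composition per emitted peak, contaminants
#'   flagged) and `path` (`NA` when not written).
#' @export
simulate_peaklist <- function(truth,
                              proteases = "trypsin",
                              base_intensity = 100,
                              fixed_mods = default_fixed_mods(),
                              out_dir = NULL,
                              seed = truth$seed + 2L) {
  stopifnot(inherits(truth, "ground_truth"))
  sdlog <- sqrt(log(1 + truth$intensity_cv^2))
  withr::with_seed(seed, {
    out <- lapply(proteases, function(protease) {
      peps <- digest(truth$protein$sequence, protease, max_missed = 2L)
      rows <- list()
      for (site_chr in names(truth$profiles)) {
        site <- as.integer(site_chr)
        cov <- peps[peps$start <= site & peps$end >= site, , drop = FALSE]
        if (!nrow(cov)) {
          warning("site ", site, " not covered by any ", protease,
                  " peptide; skipped", call. = FALSE)
          next
        }
        cov <- cov[order(cov$missed_cleavages,
                         nchar(cov$sequence)), , drop = FALSE]
        pep <- cov$sequence[1]
        pr <- truth$profiles[[site_chr]]
        pr <- pr[pr$fraction > 0, , drop = FALSE]
        theo <- glycopeptide_mass(pep, pr, fixed_mods,
                                  require_sequon = FALSE)
        obs <- theo * (1 + stats::rnorm(length(theo), 0,
                                        truth$mass_error_sd_ppm) * 1e-6)
        inten <- base_intensity * pr$fraction *
          stats::rlnorm(length(theo), -0.5 * sdlog^2, sdlog)
        rows[[site_chr]] <- data.frame(
          source = protease, site = site, peptide = pep, pr[COMP_COLS],
          mass_theo = theo, mass = obs, intensity = inten,
          contaminant = FALSE, stringsAsFactors = FALSE
        )
      }
      prov <- do.call(rbind, rows)
      if (is.null(prov)) {
        stop("no site covered for protease ", protease, call. = FALSE)
      }
      n_contam <- round(truth$contaminant_fraction * nrow(prov))
      if (n_contam > 0) {
        cm <- stats::runif(n_contam, 0.9 * min(prov$mass_theo),
                           1.1 * max(prov$mass_theo))
        ci <- stats::runif(n_contam, 0.01, 0.5) * stats::median(prov$intensity)
        prov <- rbind(prov, data.frame(
          source = protease, site = NA_integer_, peptide = NA_character_,
          as.data.frame(stats::setNames(as.list(rep(NA_integer_, 5)),
                                        COMP_COLS)),
          mass_theo = NA_real_, mass = cm, intensity = ci,
          contaminant = TRUE, stringsAsFactors = FALSE
        ))
      }
      prov <- prov[order(prov$mass), , drop = FALSE]
      rownames(prov) <- NULL
      pl <- peaklist(prov$mass, prov$intensity, source = protease)
      path <- NA_character_
      if (!is.null(out_dir)) {
        if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
        path <- file.path(out_dir, paste0("peaks_", gsub("\\+", "_", protease),
                                          ".tsv"))
        write_peaklist(pl, path, params = list(
          protease = protease, seed = seed,
          mass_error_sd_ppm = truth$mass_error_sd_ppm,
          intensity_cv = truth$intensity_cv,
          contaminant_fraction = truth$contaminant_fraction
        ))
      }
      list(peaklist = pl, provenance = prov, path = path)
    })
    names(out) <- proteases
    out
  })
}

#' Simulate 1:1 binding sensorgrams
#'
#' Evaluates the 1:1 model per analyte concentration over an association
#' and a dissociation phase, with continuity at the phase boundary, and
#' adds iid Gaussian noise.
#'
#' @param kon,koff,rmax Model parameters (1/(M s), 1/s, nm).
#' @param concentrations Analyte concentrations in molar.
#' @param t_assoc,t_dissoc Association and dissociation durations in
#'   seconds (defaults 600 each).
#' @param dt Sampling interval in seconds (default 2).
#' @param noise_sd Gaussian noise SD in nm (default `0.01 * rmax`).
#' @param seed Integer seed.
#' @param path If non-`NULL`, the sensorgram table is written there as CSV.
#' @return Data frame with columns `curve_id`, `conc_M`, `time_s`,
#'   `signal_nm`, `phase`.
#' @export
simulate_sensorgrams <- function(kon = 2.06e5, koff = 6.57e-4, rmax = 1,
                                 concentrations = c(10, 50, 100, 300, 600) * 1e-9,
                                 t_assoc = 600, t_dissoc = 600, dt = 2,
                                 noise_sd = 0.01 * rmax, seed = 1L,
                                 path = NULL) {
  withr::with_seed(seed, {
    curves <- lapply(concentrations, function(conc) {
      ta <- seq(0, t_assoc, by = dt)
      td <- t_assoc + seq(dt, t_dissoc, by = dt)
      r_end <- bli_association(t_assoc, conc, kon, koff, rmax)
      sig <- c(bli_association(ta, conc, kon, koff, rmax),
               bli_dissociation(td, r_end, koff, t_start = t_assoc))
      tt <- c(ta, td)
      noise <- if (noise_sd > 0) stats::rnorm(length(tt), 0, noise_sd) else 0
      data.frame(
        curve_id = sprintf("conc_%gnM", conc * 1e9),
        conc_M = conc, time_s = tt, signal_nm = sig + noise,
        phase = rep(c("association", "dissociation"),
                    c(length(ta), length(td))),
        stringsAsFactors = FALSE
      )
    })
    sg <- do.call(rbind, curves)
    rownames(sg) <- NULL
    if (!is.null(path)) {
      utils::write.csv(sg, path, row.names = FALSE, quote = FALSE)
    }
    sg
  })
}

#' Simulate a semi-continuous perfusion culture
#'
#' Logistic viable-cell-density growth, slowed after the temperature-shift
#' day; daily harvest titer equals `qP * VCD` under multiplicative
#' lognormal noise (full daily medium exchange).
#'
#' @param days Number of process days (default 11).
#' @param v0 Seeding VCD in 1e6 cells/mL.
#' @param capacity Logistic carrying capacity in 1e6 cells/mL.
#' @param growth_rate Per-day logistic growth rate before the shift.
#' @param shift_day Temperature-shift day; growth afterwards is slowed by
#'   `post_shift_factor`.
#' @param post_shift_factor Multiplier on the growth rate after the shift.
#' @param qp_before,qp_after Cell-specific productivity in pg/cell/day
#'   before/after the shift.
#' @param viability0 Starting viability fraction.
#' @param noise_cv Coefficient of variation of the multiplicative titer
#'   noise (0 gives exactly `qP * VCD`).
#' @param seed Integer seed.
#' @return `culture_timeseries` data frame with columns `day`, `vcd`,
#'   `viability`, `titer` and attribute `shift_day`.
#' @export
simulate_culture <- function(days = 11L, v0 = 5, capacity = 60,
                             growth_rate = 0.8, shift_day = 3L,
                             post_shift_factor = 0.15,
                             qp_before = 0.1, qp_after = 0.5,
                             viability0 = 0.97, noise_cv = 0.05,
                             seed = 1L) {
  if (growth_rate < 0 || post_shift_factor < 0 || qp_before < 0 ||
      qp_after < 0) {
    stop("rates must be >= 0", call. = FALSE)
  }
  withr::with_seed(seed, {
    day <- seq_len(days)
    vcd <- numeric(days)
    vcd[1] <- v0
    for (d in seq_len(days - 1L)) {
      r <- if (day[d] < shift_day) growth_rate else
        growth_rate * post_shift_factor
      vcd[d + 1L] <- vcd[d] + r * vcd[d] * (1 - vcd[d] / capacity)
    }
    viability <- pmin(1, pmax(0, viability0 - 0.004 * pmax(0, day - shift_day)))
    qp <- ifelse(day <= shift_day, qp_before, qp_after)
    sdlog <- if (noise_cv > 0) sqrt(log(1 + noise_cv^2)) else 0
    noise <- if (sdlog > 0) {
      stats::rlnorm(days, -0.5 * sdlog^2, sdlog)
    } else {
      rep(1, days)
    }
    ts <- data.frame(day = day, vcd = vcd, viability = viability,
                     titer = qp * vcd * noise)
    attr(ts, "shift_day") <- shift_day
    class(ts) <- c("culture_timeseries", "data.frame")
    ts
  })
}
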