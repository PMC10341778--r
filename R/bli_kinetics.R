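# 1:1 Langmuir binding kinetics for biolayer-interferometry sensorgrams:
# closed-form association/dissociation models and a global nonlinear
# least-squares fit sharing kon, koff and Rmax across analyte
# concentrations.

#' 1:1 association-phase model
#'
#' Closed-form solution of `dR/dt = kon*C*(Rmax - R) - koff*R` with
#' `R(0) = 0`:
#' `R(t) = Rmax*C/(C + koff/kon) * (1 - exp(-(kon*C + koff)*t))`.
#'
#' @param t Time since association start, in seconds (>= 0).
#' @param conc Analyte concentration in molar (>= 0).
#' @param kon Association rate constant, 1/(M s) (> 0).
#' @param koff Dissociation rate constant, 1/s (>= 0).
#' @param rmax Maximal response (saturation amplitude), in nm.
#' @return Signal in nm; 0 for all `t` when `conc = 0`.
#' @export
bli_association <- function(t, conc, kon, koff, rmax) {
  if (!is.numeric(kon) || kon <= 0) {
    stop("kon must be > 0", call. = FALSE)
  }
  if (koff < 0) stop("koff must be >= 0", call. = FALSE)
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (any(conc < 0)) stop("conc must be >= 0", call. = FALSE)
  kobs <- kon * conc + koff
  req <- ifelse(conc == 0, 0, rmax * conc / (conc + koff / kon))
  req * (1 - exp(-kobs * t))
}

#' 1:1 dissociation-phase model
#'
#' Single-exponential decay from the response at dissociation start:
#' `R(t) = R0 * exp(-koff * (t - t_start))`.
#'
#' @param t Time in seconds (>= `t_start`).
#' @param r0 Response at dissociation start, in nm.
#' @param koff Dissociation rate constant, 1/s (>= 0).
#' @param t_start Dissociation start time (default 0).
#' @return Signal in nm.
#' @export
bli_dissociation <- function(t, r0, koff, t_start = 0) {
  if (koff < 0) stop("koff must be >= 0", call. = FALSE)
  if (any(t < t_start)) {
    stop("t must be >= dissociation start time", call. = FALSE)
  }
  r0 * exp(-koff * (t - t_start))
}

#' Equilibrium dissociation constant
#'
#' @param kon Association rate constant, 1/(M s) (> 0).
#' @param koff Dissociation rate constant, 1/s (>= 0).
#' @return `KD = koff / kon`, in molar.
#' @examples
#' bli_kd(2.06e5, 6.57e-4) * 1e9 # nM
#' @export
bli_kd <- function(kon, koff) {
  if (any(!is.finite(kon)) || any(kon <= 0)) {
    stop("kon must be finite and > 0", call. = FALSE)
  }
  if (any(koff < 0)) stop("koff must be >= 0", call. = FALSE)
  koff / kon
}

#' Read sensorgrams from CSV
#'
#' Expected columns: `curve_id`, `conc_M`, `time_s`, `signal_nm`, `phase`
#' (one of `baseline`, `association`, `dissociation`).
#'
#' @param path CSV file path.
#' @return Sensorgram data frame.
#' @export
read_sensorgrams <- function(path) {
  if (!file.exists(path)) {
    stop("sensorgram file not found: ", path, call. = FALSE)
  }
  sg <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("curve_id", "conc_M", "time_s", "signal_nm", "phase")
  missing_cols <- setdiff(needed, names(sg))
  if (length(missing_cols)) {
    stop("sensorgram file lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(sg$phase), c("baseline", "association", "dissociation"))
  if (length(bad)) {
    stop("unknown phase label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  sg
}

## per-curve phase geometry: association start/end, dissociation start
.curve_geometry <- function(d) {
  a <- d[d$phase == "association", , drop = FALSE]
  list(
    t_a0 = min(a$time_s),
    t_a1 = max(a$time_s),
    conc = d$conc_M[1]
  )
}

## model signal for one curve at parameters (kon, koff, rmax, offset)
.curve_model <- function(d, geo, kon, koff, rmax, offset) {
  out <- numeric(nrow(d))
  assoc <- d$phase == "association"
  dissoc <- d$phase == "dissociation"
  base <- d$phase == "baseline"
  if (any(assoc)) {
    out[assoc] <- bli_association(d$time_s[assoc] - geo$t_a0, geo$conc,
                                  kon, koff, rmax)
  }
  if (any(dissoc)) {
    ## continuity: decay starts from the model response at association end
    r_end <- bli_association(geo$t_a1 - geo$t_a0, geo$conc, kon, koff, rmax)
    out[dissoc] <- bli_dissociation(d$time_s[dissoc], r_end, koff,
                                    t_start = geo$t_a1)
  }
  if (any(base)) out[base] <- 0
  out + offset
}

## initial koff: log-linear regression on the dissociation decay of each
## curve, pooled by median
.init_koff <- function(curves, geos, bounds) {
  ests <- vapply(seq_along(curves), function(i) {
    d <- curves[[i]]
    dd <- d[d$phase == "dissociation", , drop = FALSE]
    if (nrow(dd) < 5L) return(NA_real_)
    y <- dd$signal_nm - min(dd$signal_nm)
    top <- max(y)
    if (top <= 0) return(NA_real_)
    use <- y > 0.05 * top
    if (sum(use) < 5L) return(NA_real_)
    fit <- stats::lm(log(y[use]) ~ dd$time_s[use])
    -unname(stats::coef(fit)[2])
  }, numeric(1))
  ests <- ests[is.finite(ests) & ests > 0]
  k <- if (length(ests)) stats::median(ests) else 1e-3
  min(max(k, bounds$koff[1]), bounds$koff[2])
}

## initial kon: per-curve observed rate kobs from a log-linear fit of the
## association approach to plateau, then the slope of kobs vs concentration
.init_kon <- function(curves, geos, koff0, bounds) {
  kobs <- conc <- numeric(0)
  for (i in seq_along(curves)) {
    d <- curves[[i]]
    a <- d[d$phase == "association", , drop = FALSE]
    if (nrow(a) < 5L || geos[[i]]$conc <= 0) next
    sig <- a$signal_nm - min(a$signal_nm)
    plateau <- 1.02 * max(sig)
    if (plateau <= 0) next
    y <- plateau - sig
    use <- y > 0.02 * plateau & sig < 0.95 * plateau
    if (sum(use) < 5L) next
    fit <- stats::lm(log(y[use]) ~ a$time_s[use])
    k <- -unname(stats::coef(fit)[2])
    if (is.finite(k) && k > 0) {
      kobs <- c(kobs, k)
      conc <- c(conc, geos[[i]]$conc)
    }
  }
  if (length(kobs) >= 2L) {
    slope <- unname(stats::coef(stats::lm(kobs ~ conc))[2])
  } else if (length(kobs) == 1L) {
    slope <- max(kobs - koff0, kobs * 0.5) / conc
  } else {
    slope <- 1e5
  }
  if (!is.finite(slope) || slope <= 0) slope <- 1e5
  min(max(slope, bounds$kon[1]), bounds$kon[2])
}

#' Global 1:1 fit of multi-concentration sensorgrams
#'
#' Fits all curves jointly by nonlinear least squares
#' ([minpack.lm::nls.lm()]), sharing `kon`, `koff` and `rmax` across
#' concentrations, with an optional per-curve additive offset absorbing
#' residual baseline after reference subtraction. The dissociation phase is
#' tied to the model response at association end, so both phases constrain
#' the shared parameters. Rate constants are optimized on a log10 scale
#' within `bounds`. Initialization: `koff` from a log-linear regression on
#' the dissociation decay; per-curve `kobs` from the association approach to
#' plateau, then `kon` from the slope of `kobs` versus concentration.
#'
#' @param sensorgrams Data frame with columns `curve_id`, `conc_M`,
#'   `time_s`, `signal_nm`, `phase` (`baseline`/`association`/
#'   `dissociation`); typically [read_sensorgrams()] or
#'   [simulate_sensorgrams()] output.
#' @param fit_offset Fit a per-curve additive offset (default `TRUE`).
#' @param bounds List with elements `kon` and `koff`, each `c(lower,
#'   upper)`; defaults `kon` in `[1e2, 1e8]` 1/(M s) and `koff` in
#'   `[1e-7, 1]` 1/s.
#' @param init Optional named list overriding the automatic initialization
#'   (`kon`, `koff`, `rmax`).
#' @param no_binding_factor Declare "no specific binding" when the fitted
#'   `rmax` is below this multiple of the residual noise SD (default 3).
#' @return Object of class `kinetic_fit`: list with `kon`, `koff`, `rmax`,
#'   `kd` (`= koff/kon`), `offsets` (per curve), `residual_sse`,
#'   `noise_sd`, `converged`, `no_binding`, `n_points` and `message`.
#' @export
bli_global_fit <- function(sensorgrams, fit_offset = TRUE,
                           bounds = list(kon = c(1e2, 1e8),
                                         koff = c(1e-7, 1)),
                           init = NULL, no_binding_factor = 3) {
  needed <- c("curve_id", "conc_M", "time_s", "signal_nm", "phase")
  missing_cols <- setdiff(needed, names(sensorgrams))
  if (length(missing_cols)) {
    stop("sensorgrams lack column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (ph in c("association", "dissociation")) {
    if (!any(sensorgrams$phase == ph)) {
      stop("sensorgrams contain no '", ph, "' phase; a 1:1 global fit ",
           "needs both association and dissociation data", call. = FALSE)
    }
  }
  curves <- split(sensorgrams, sensorgrams$curve_id)
  curves <- curves[order(vapply(curves, function(d) d$conc_M[1], numeric(1)))]
  geos <- lapply(curves, .curve_geometry)
  ncur <- length(curves)

  koff0 <- .init_koff(curves, geos, bounds)
  kon0 <- .init_kon(curves, geos, koff0, bounds)
  kd0 <- koff0 / kon0
  top <- which.max(vapply(geos, `[[`, numeric(1), "conc"))
  top_amp <- diff(range(curves[[top]]$signal_nm))
  top_conc <- geos[[top]]$conc
  rmax0 <- if (top_conc > 0) top_amp * (top_conc + kd0) / top_conc else 1
  if (!is.finite(rmax0) || rmax0 <= 0) rmax0 <- 1
  if (!is.null(init)) {
    if (!is.null(init$kon)) kon0 <- init$kon
    if (!is.null(init$koff)) koff0 <- max(init$koff, bounds$koff[1])
    if (!is.null(init$rmax)) rmax0 <- init$rmax
  }

  par0 <- c(log10(kon0), log10(koff0), rmax0,
            if (fit_offset) rep(0, ncur))
  lower <- c(log10(bounds$kon[1]), log10(bounds$koff[1]), 0,
             if (fit_offset) rep(-Inf, ncur))
  upper <- c(log10(bounds$kon[2]), log10(bounds$koff[2]), Inf,
             if (fit_offset) rep(Inf, ncur))

  residual_fn <- function(par) {
    kon <- 10^par[1]
    koff <- 10^par[2]
    rmax <- par[3]
    unlist(lapply(seq_len(ncur), function(i) {
      off <- if (fit_offset) par[3 + i] else 0
      .curve_model(curves[[i]], geos[[i]], kon, koff, rmax, off) -
        curves[[i]]$signal_nm
    }), use.names = FALSE)
  }

  fit <- minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = residual_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12)
  )
  converged <- fit$info %in% 1:4
  if (!converged) {
    warning("global fit did not converge (", fit$message,
            "); best-found parameters returned", call. = FALSE)
  }
  kon <- 10^fit$par[1]
  koff <- 10^fit$par[2]
  rmax <- fit$par[3]
  offsets <- if (fit_offset) {
    stats::setNames(fit$par[3 + seq_len(ncur)], names(curves))
  } else {
    stats::setNames(rep(0, ncur), names(curves))
  }
  resid <- residual_fn(fit$par)
  sse <- sum(resid^2)
  noise_sd <- stats::sd(resid)

  structure(list(
    kon = kon, koff = koff, rmax = rmax, kd = koff / kon,
    offsets = offsets, residual_sse = sse, noise_sd = noise_sd,
    converged = converged,
    no_binding = !converged || rmax < no_binding_factor * noise_sd,
    n_points = length(resid), n_curves = ncur,
    initial_sse = sum(residual_fn(par0)^2),
    message = fit$message
  ), class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Global 1:1 kinetic fit (", x$n_curves, " curves, ", x$n_points,
      " points)\n", sep = "")
  cat(sprintf("  kon  = %.4g 1/(M s)\n", x$kon))
  cat(sprintf("  koff = %.4g 1/s\n", x$koff))
  cat(sprintf("  Rmax = %.4g nm\n", x$rmax))
  cat(sprintf("  KD   = %.4g M (%.2f nM)\n", x$kd, x$kd * 1e9))
  cat(sprintf("  residual SSE = %.4g, converged: %s\n",
              x$residual_sse, x$converged))
  if (x$no_binding) cat("  NOTE: no specific binding detected\n")
  invisible(x)
}
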