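#' Fit Michaelis-Menten kinetics to an initial-rate series
#'
#' Nonlinear least squares of v = Vmax S / (Km + S), unweighted. The
#' turnover number is derived from the mass-specific Vmax through the
#' monomer molar mass: kcat (s-1) = Vmax (umol min-1 mg-1) * M (g/mol)
#' * 1e-6 / 60, and catalytic efficiency as kcat/Km (mM-1 s-1).
#'
#' @param s_conc substrate concentrations in mM (>= 5 values recommended,
#'   spanning Km; a warning is issued otherwise).
#' @param rate initial rates in umol min-1 mg-1.
#' @param molar_mass monomer molar mass in g/mol (default 69400, rat PCK1;
#'   configurable since affinity tags change the mass).
#' @return list of class \code{mm_fit}: \code{Vmax}, \code{Km},
#'   \code{kcat}, \code{kcat_over_Km}, \code{se} (Vmax, Km),
#'   \code{degenerate}, \code{molar_mass}.
#' @examples
#' S <- c(0.02, 0.05, 0.1, 0.2, 0.5, 1, 2)
#' fit_mm(S, 32 * S / (0.1 + S))
#' @export
fit_mm <- function(s_conc, rate, molar_mass = 69400) {
  if (length(s_conc) != length(rate)) {
    stop("s_conc and rate must have equal length", call. = FALSE)
  }
  if (any(s_conc < 0) || any(!is.finite(rate))) {
    stop("substrate concentrations must be >= 0 and rates finite",
         call. = FALSE)
  }
  if (all(rate == 0)) {
    return(structure(list(Vmax = 0, Km = NA_real_, kcat = 0,
                          kcat_over_Km = NA_real_,
                          se = c(Vmax = NA_real_, Km = NA_real_),
                          degenerate = TRUE, molar_mass = molar_mass),
                     class = "mm_fit"))
  }
  if (length(unique(s_conc)) < 5) {
    warning("fewer than 5 substrate concentrations: Km poorly constrained")
  }
  vmax0 <- max(rate)
  km0 <- s_conc[which.min(abs(rate - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(s_conc[s_conc > 0])
  d <- data.frame(S = s_conc, v = rate)
  fit <- minpack.lm::nlsLM(v ~ Vmax * S / (Km + S), data = d,
                           start = list(Vmax = vmax0, Km = km0),
                           lower = c(1e-12, 1e-12),
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-15, ptol = 1e-15))
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(Vmax = NA_real_, Km = NA_real_))
  Vmax <- unname(cf[["Vmax"]]); Km <- unname(cf[["Km"]])
  if (max(s_conc) < 5 * Km) {
    warning("plateau not reached (max S < 5 Km): Vmax extrapolated, wide se")
  }
  kcat <- Vmax * molar_mass * 1e-6 / 60
  structure(list(Vmax = Vmax, Km = Km, kcat = kcat,
                 kcat_over_Km = kcat / Km,
                 se = c(Vmax = unname(se[["Vmax"]]), Km = unname(se[["Km"]])),
                 degenerate = FALSE, molar_mass = molar_mass),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Michaelis-Menten fit: degenerate (all rates zero)\n")
    return(invisible(x))
  }
  cat(sprintf("Michaelis-Menten fit: Vmax = %.3g umol/min/mg (se %.2g), Km = %.3g mM (se %.2g)\n",
              x$Vmax, x$se[["Vmax"]], x$Km, x$se[["Km"]]))
  cat(sprintf("  kcat = %.3g s-1 (M = %g g/mol), kcat/Km = %.3g mM-1 s-1\n",
              x$kcat, x$molar_mass, x$kcat_over_Km))
  invisible(x)
}

#' Fit every enzyme/substrate/direction series in a rate table
#'
#' @param rates data frame in the [simulate_mm_rates()] schema.
#' @param molar_mass passed to [fit_mm()].
#' @return data frame with one row per series: \code{enzyme},
#'   \code{substrate}, \code{direction}, \code{Vmax}, \code{Vmax_se},
#'   \code{Km}, \code{Km_se}, \code{kcat}, \code{kcat_over_Km}.
#' @export
fit_mm_table <- function(rates, molar_mass = 69400) {
  key <- interaction(rates$enzyme, rates$substrate, rates$direction,
                     drop = TRUE)
  rows <- lapply(split(rates, key), function(d) {
    f <- fit_mm(d$s_conc_mM, d$rate_umol_min_mg, molar_mass = molar_mass)
    data.frame(enzyme = d$enzyme[1], substrate = d$substrate[1],
               direction = d$direction[1], Vmax = f$Vmax,
               Vmax_se = f$se[["Vmax"]], Km = f$Km, Km_se = f$se[["Km"]],
               kcat = f$kcat, kcat_over_Km = f$kcat_over_Km,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare enzyme variants against a reference
#'
#' Per substrate/direction, fold-changes of Vmax (= kcat), Km and
#' catalytic efficiency of each variant relative to the reference enzyme,
#' and residual activity as a percentage of the reference Vmax. Swapping
#' the reference inverts every fold.
#'
#' @param fits data frame from [fit_mm_table()].
#' @param reference name of the reference enzyme (must be present).
#' @return data frame with \code{enzyme}, \code{substrate},
#'   \code{direction}, \code{fold_Vmax}, \code{fold_Km},
#'   \code{fold_kcat_over_Km}, \code{residual_activity_pct}.
#' @export
compare_variants <- function(fits, reference) {
  if (!reference %in% fits$enzyme) {
    stop("reference enzyme '", reference, "' absent from fits", call. = FALSE)
  }
  key <- interaction(fits$substrate, fits$direction, drop = TRUE)
  rows <- lapply(split(fits, key), function(d) {
    ref <- d[d$enzyme == reference, , drop = FALSE]
    if (nrow(ref) != 1) return(NULL)
    data.frame(enzyme = d$enzyme, substrate = d$substrate,
               direction = d$direction,
               fold_Vmax = d$Vmax / ref$Vmax,
               fold_Km = d$Km / ref$Km,
               fold_kcat_over_Km = d$kcat_over_Km / ref$kcat_over_Km,
               residual_activity_pct = 100 * d$Vmax / ref$Vmax,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Specific activity at saturating substrate
#'
#' Mean and sample sd of replicate rates measured at saturating substrate
#' concentration (S >= 10 Km, or assert saturation explicitly).
#'
#' @param rate replicate rates in umol min-1 mg-1.
#' @param s_conc substrate concentration(s) in mM (optional, for the
#'   saturation check).
#' @param Km Km in mM (optional, for the saturation check).
#' @param saturating set \code{TRUE} to assert saturation when s_conc/Km
#'   are not supplied.
#' @return list with \code{mean}, \code{sd}, \code{n}.
#' @examples
#' specific_activity(c(31, 32, 33), saturating = TRUE)
#' @export
specific_activity <- function(rate, s_conc = NULL, Km = NULL,
                              saturating = FALSE) {
  if (!saturating) {
    if (is.null(s_conc) || is.null(Km)) {
      warning("saturation not verifiable without s_conc and Km")
    } else if (any(s_conc < 10 * Km)) {
      warning("substrate below 10 x Km: reported activity underestimates Vmax")
    }
  }
  list(mean = mean(rate),
       sd = if (length(rate) > 1) stats::sd(rate) else NA_real_,
       n = length(rate))
}

#' Eadie-Hofstee transform of a rate series
#'
#' Returns (v, v/S) pairs; on data that follow Michaelis-Menten kinetics
#' exactly these are collinear with slope -Km and intercept Vmax, which
#' the test suite uses as an internal consistency check on the nonlinear
#' fitter.
#'
#' @param s_conc substrate concentrations in mM (> 0).
#' @param rate rates.
#' @return data frame with columns \code{v} and \code{v_over_S}.
#' @export
eadie_hofstee <- function(s_conc, rate) {
  stopifnot_positive(s_conc, "substrate concentrations")
  data.frame(v = rate, v_over_S = rate / s_conc)
}

#' Rate from NADH absorbance change in a coupled assay
#'
#' Optional helper converting a spectrophotometric slope (A340/min) into a
#' specific activity via the NADH extinction coefficient
#' (6220 M-1 cm-1).
#'
#' @param dA340_per_min absorbance change per minute.
#' @param path_cm optical path length, cm.
#' @param enzyme_mg_per_mL enzyme concentration in the cuvette, mg/mL.
#' @param volume_mL assay volume, mL (cancels with enzyme mass; kept for
#'   explicitness).
#' @return specific activity in umol min-1 mg-1.
#' @export
nadh_rate <- function(dA340_per_min, path_cm = 1, enzyme_mg_per_mL,
                      volume_mL = 1) {
  stopifnot_positive(c(path_cm, enzyme_mg_per_mL, volume_mL),
                     "path, enzyme concentration and volume")
  # dA/min / (eps * l) = M/min; * volume = mol scale; per mg enzyme
  mol_per_min_per_L <- dA340_per_min / (6220 * path_cm)
  umol_per_min <- mol_per_min_per_L * 1e6 * (volume_mL / 1000)
  umol_per_min / (enzyme_mg_per_mL * volume_mL / 1000 * 1000)
}
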