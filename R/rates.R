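#' Pseudo-first-order rate from a single-timepoint stoichiometry
#'
#' Inverts the saturating labelling kinetics S = 1 - exp(-k_obs t) at a
#' fixed acetyl-CoA concentration: k_obs = -ln(1 - S) / t. This is the
#' estimator for the standard one-hour, multi-concentration design.
#'
#' @param S stoichiometry in [0, 1).
#' @param t incubation time in seconds (> 0).
#' @return k_obs in s-1.
#' @examples
#' kobs_single_timepoint(1 - exp(-1), 1)  # 1
#' @export
kobs_single_timepoint <- function(S, t) {
  if (any(t <= 0)) stop("time must be positive", call. = FALSE)
  if (any(S < 0)) stop("stoichiometry must be non-negative", call. = FALSE)
  if (any(S >= 1)) {
    stop("saturated stoichiometry (S >= 1) is uninformative for k_obs",
         call. = FALSE)
  }
  -log(1 - S) / t
}

#' Pseudo-first-order rate from a stoichiometry time series
#'
#' Least-squares fit of S(t) = S_inf (1 - exp(-k_obs t)) to a
#' multi-timepoint series at one acetyl-CoA concentration. By default the
#' plateau S_inf is fixed at 1 (the complete-modification limit implied by
#' pseudo-first-order labelling); a free plateau is unidentifiable at the
#' low stoichiometries typical of chemical acetylation, but can be enabled
#' for diagnostics.
#'
#' @param t timepoints in seconds (>= 3 distinct values).
#' @param S stoichiometries aligned with \code{t}.
#' @param fix_plateau fix S_inf = 1 (default) or fit it freely.
#' @return list with \code{kobs} (s-1), \code{se}, \code{S_inf},
#'   \code{converged}.
#' @export
kobs_exponential_fit <- function(t, S, fix_plateau = TRUE) {
  if (length(unique(t)) < 3) {
    stop("at least 3 distinct timepoints required", call. = FALSE)
  }
  if (all(S == 0)) {
    return(list(kobs = 0, se = 0, S_inf = if (fix_plateau) 1 else NA_real_,
                converged = TRUE))
  }
  d <- data.frame(t = t, S = S)
  # moment start: invert the largest observed stoichiometry
  k0 <- max(-log(1 - min(max(S), 0.99)) / max(t), 1e-12)
  fit <- tryCatch({
    if (fix_plateau) {
      minpack.lm::nlsLM(S ~ 1 - exp(-k * t), data = d,
                        start = list(k = k0), lower = 0,
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    } else {
      minpack.lm::nlsLM(S ~ Sinf * (1 - exp(-k * t)), data = d,
                        start = list(Sinf = min(max(S) * 1.05, 1), k = k0),
                        lower = c(0, 0), upper = c(1, Inf),
                        control = minpack.lm::nls.lm.control(
                          maxiter = 200, ftol = 1e-15, ptol = 1e-15))
    }
  }, error = function(e) NULL)
  if (is.null(fit)) {
    warning("exponential fit did not converge; site should be excluded")
    return(list(kobs = NA_real_, se = NA_real_, S_inf = NA_real_,
                converged = FALSE))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) rep(NA_real_, length(cf)))
  list(kobs = unname(cf[["k"]]),
       se = unname(if ("k" %in% names(se)) se[["k"]] else se[length(se)]),
       S_inf = if (fix_plateau) 1 else unname(cf[["Sinf"]]),
       converged = TRUE)
}

#' Second-order acetylation rate constant from k_obs vs concentration
#'
#' Linear regression of the pseudo-first-order rates on acetyl-CoA
#' concentration, k_obs = k2 c, through the origin by default (no acetyl
#' donor, no acetylation); a free intercept is available as a diagnostic
#' for concentration-independent background. Weights are inverse-variance
#' when standard errors are supplied, otherwise unweighted.
#'
#' @param conc acetyl-CoA concentrations in M (>= 2 values; a warning is
#'   issued below 3).
#' @param kobs pseudo-first-order rates in s-1.
#' @param se optional standard errors on \code{kobs} for weighting.
#' @param through_origin regression through the origin (default) or with a
#'   free intercept.
#' @return list of class \code{site_rate_fit}: \code{k2} (M-1 s-1),
#'   \code{k2_se}, \code{intercept}, \code{r_squared}, \code{n_points}.
#' @examples
#' conc <- c(0.5, 1, 2, 4, 8) * 1e-3
#' second_order_fit(conc, 14.7e-5 * conc)$k2  # 14.7e-5
#' @export
second_order_fit <- function(conc, kobs, se = NULL, through_origin = TRUE) {
  if (length(conc) < 2) {
    stop("at least 2 concentrations required for a second-order fit",
         call. = FALSE)
  }
  if (length(conc) < 3) {
    warning("fewer than 3 concentrations: k2 poorly constrained")
  }
  neg <- kobs < 0
  if (any(neg)) {
    warning(sum(neg), " negative k_obs value(s) clamped to 0")
    kobs[neg] <- 0
  }
  w <- if (!is.null(se) && all(is.finite(se)) && all(se > 0)) 1 / se^2 else NULL
  d <- data.frame(conc = conc, kobs = kobs)
  if (all(kobs == 0)) {
    fit <- NULL
    k2 <- 0; k2_se <- 0; icpt <- if (through_origin) NA_real_ else 0
    r2 <- NA_real_
  } else {
    fml <- if (through_origin) kobs ~ 0 + conc else kobs ~ conc
    fit <- stats::lm(fml, data = d, weights = w)
    # summary.lm warns on an exactly collinear fit; noiseless designs hit it
    sm <- suppressWarnings(summary(fit))
    cf <- sm$coefficients
    k2 <- unname(cf["conc", "Estimate"])
    k2_se <- unname(cf["conc", "Std. Error"])
    icpt <- if (through_origin) NA_real_ else unname(cf["(Intercept)", "Estimate"])
    r2 <- sm$r.squared
  }
  if (is.finite(k2) && k2 < 0) {
    warning("negative fitted k2 clamped to 0")
    k2 <- 0
  }
  structure(list(k2 = k2, k2_se = k2_se, intercept = icpt, r_squared = r2,
                 n_points = length(conc),
                 through_origin = through_origin, fit = fit),
            class = "site_rate_fit")
}

#' @export
print.site_rate_fit <- function(x, ...) {
  cat(sprintf("Second-order acetylation rate: k2 = %.3g M-1 s-1 (%.2f x 10-5), se = %.2g, r2 = %.4f, n = %d\n",
              x$k2, x$k2 * 1e5, x$k2_se, x$r_squared, x$n_points))
  invisible(x)
}

#' Per-site rate constants from a stoichiometry table
#'
#' Drives the stoichiometry -> k_obs -> k2 chain for every peptide in an
#' aggregated stoichiometry table. With one timepoint per concentration the
#' single-timepoint inversion is used; with a time series per concentration
#' the exponential fit is used.
#'
#' @param stoich aggregated stoichiometry table from
#'   [compute_stoichiometry()].
#' @param method "single_timepoint" or "exponential_fit"; default picks
#'   single_timepoint when each (peptide, concentration) has one timepoint.
#' @param through_origin passed to [second_order_fit()].
#' @param fix_plateau passed to [kobs_exponential_fit()].
#' @return data frame with one row per peptide: \code{peptide_id},
#'   \code{site_ids}, \code{k2_Msinv}, \code{k2_se}, \code{r2},
#'   \code{n_points}, \code{method}.
#' @export
fit_site_rates <- function(stoich, method = c("auto", "single_timepoint",
                                              "exponential_fit"),
                           through_origin = TRUE, fix_plateau = TRUE) {
  method <- match.arg(method)
  parts <- split(stoich, stoich$peptide_id)
  rows <- lapply(parts, function(d) {
    per_conc <- split(d, d$accoa_conc_M)
    use_exp <- switch(method,
      auto = any(vapply(per_conc, nrow, 1L) >= 3),
      single_timepoint = FALSE, exponential_fit = TRUE)
    kobs_tab <- do.call(rbind, lapply(per_conc, function(dc) {
      if (use_exp) {
        f <- kobs_exponential_fit(dc$time_s, dc$stoichiometry,
                                  fix_plateau = fix_plateau)
        data.frame(conc = dc$accoa_conc_M[1], kobs = f$kobs, se = f$se)
      } else {
        data.frame(conc = dc$accoa_conc_M[1],
                   kobs = kobs_single_timepoint(dc$stoichiometry[1],
                                                dc$time_s[1]),
                   se = NA_real_)
      }
    }))
    kobs_tab <- kobs_tab[is.finite(kobs_tab$kobs), , drop = FALSE]
    f2 <- second_order_fit(kobs_tab$conc, kobs_tab$kobs,
                           through_origin = through_origin)
    data.frame(peptide_id = d$peptide_id[1], site_ids = d$site_ids[1],
               k2_Msinv = f2$k2, k2_se = f2$k2_se, r2 = f2$r_squared,
               n_points = f2$n_points,
               method = if (use_exp) "exponential_fit" else "single_timepoint",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Lysine annotation table for rat PCK1
#'
#' Residue-level annotation of the quantifiable acetylation sites, with an
#' active-site flag for the catalytic lysines K244 (Mn2+ coordination) and
#' K290 (phosphate contact) and a note on the surrounding structural
#' context (R87 loop, nucleotide groove).
#'
#' @return data frame with columns \code{residue}, \code{active_site},
#'   \code{note}.
#' @export
pck1_lysine_annotation <- function() {
  data.frame(
    residue = c(70, 71, 91, 107, 135, 204, 243, 244, 278, 290, 316, 342,
                349, 353),
    active_site = c(rep(FALSE, 7), TRUE, FALSE, TRUE, rep(FALSE, 4)),
    note = c("", "", "near nucleotide groove", "", "", "", "adjacent to K244",
             "active site; coordinates Mn2+, H-bonds R87-loop when acetylated",
             "", "active site; contacts nucleotide phosphate", "", "", "", ""),
    stringsAsFactors = FALSE
  )
}

#' Rank sites by acetylation reactivity
#'
#' Sorts site-rate fits by decreasing k2 and joins the packaged active-site
#' annotation (a multi-lysine peptide is flagged when any of its lysines is
#' an active-site residue). Rates at or above \code{lower_bound} (default
#' 20e-5 M-1 s-1, the regime where the one-hour design begins to saturate)
#' are flagged as lower bounds rather than point estimates.
#'
#' @param fits data frame from [fit_site_rates()].
#' @param lower_bound threshold in M-1 s-1 above which k2 is reported as a
#'   lower bound.
#' @return the fits table sorted by k2 with added \code{active_site},
#'   \code{k2_x1e5} (display scale) and \code{lower_bound_flag} columns.
#' @export
rank_sites <- function(fits, lower_bound = 20e-5) {
  if (nrow(fits) == 0) {
    return(cbind(fits, active_site = logical(0), k2_x1e5 = numeric(0),
                 lower_bound_flag = logical(0)))
  }
  ann <- pck1_lysine_annotation()
  site_active <- vapply(fits$site_ids, function(s) {
    res <- as.integer(gsub("K", "", strsplit(s, ";", fixed = TRUE)[[1]]))
    any(res %in% ann$residue[ann$active_site])
  }, logical(1))
  out <- fits
  out$active_site <- unname(site_active)
  out$k2_x1e5 <- out$k2_Msinv * 1e5
  out$lower_bound_flag <- out$k2_Msinv >= lower_bound
  out <- out[order(-out$k2_Msinv), , drop = FALSE]
  rownames(out) <- NULL
  out
}
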