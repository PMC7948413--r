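#' Isothermal titration calorimetry titration container
#'
#' Holds one titration: instrument geometry (overfill perfusion cell),
#' injection schedule and integrated per-injection heats. All volumes are
#' litres, concentrations molar, heats calories.
#'
#' @param cell_conc protein concentration in the cell, M.
#' @param syringe_conc ligand concentration in the syringe, M.
#' @param cell_volume active cell volume V0, L.
#' @param injection_volumes per-injection volumes, L.
#' @param heats integrated heats per injection, cal.
#' @param temperature K (default 298.15, i.e. 25 C).
#' @param label condition string (e.g. "0.1 mM Mn2+").
#' @return object of class \code{itc_titration}.
#' @export
itc_titration <- function(cell_conc, syringe_conc, cell_volume,
                          injection_volumes, heats,
                          temperature = 298.15, label = "") {
  stopifnot_positive(c(cell_conc, syringe_conc, cell_volume), "concentrations and cell volume")
  stopifnot_positive(injection_volumes, "injection volumes")
  if (length(heats) != length(injection_volumes)) {
    stop("heats and injection_volumes must have equal length", call. = FALSE)
  }
  structure(list(cell_conc = cell_conc, syringe_conc = syringe_conc,
                 cell_volume = cell_volume,
                 injection_volumes = injection_volumes, heats = heats,
                 temperature = temperature, label = label),
            class = "itc_titration")
}

#' @export
print.itc_titration <- function(x, ...) {
  cat(sprintf("ITC titration [%s]: %d injections, cell %.3g uM / syringe %.3g uM, V0 = %.0f uL, T = %.2f K\n",
              x$label, length(x$heats), M_to_uM(x$cell_conc),
              M_to_uM(x$syringe_conc), x$cell_volume * 1e6, x$temperature))
  invisible(x)
}

#' Cell concentrations after the i-th injection
#'
#' Displacement-dilution bookkeeping for an overfill perfusion cell: each
#' injection of volume dV displaces cell content, so after a cumulative
#' injected volume DV the protein concentration is
#' Mt = M0 (1 - DV/2V0) / (1 + DV/2V0) and the total ligand concentration
#' is Xt = X0 (DV/V0) / (1 + DV/2V0).
#'
#' @param i injection index (1-based); \code{i = 0} returns the pre-titration
#'   state (M0, 0).
#' @param titr an [itc_titration()].
#' @return list with \code{Mt} and \code{Xt} in M.
#' @export
concentrations_after_injection <- function(i, titr) {
  if (i < 0 || i > length(titr$injection_volumes)) {
    stop("injection index out of range", call. = FALSE)
  }
  DV <- if (i == 0) 0 else sum(titr$injection_volumes[seq_len(i)])
  V0 <- titr$cell_volume
  if (DV >= 2 * V0) {
    stop("cumulative injected volume exceeds cell capacity", call. = FALSE)
  }
  denom <- 1 + DV / (2 * V0)
  list(Mt = titr$cell_conc * (1 - DV / (2 * V0)) / denom,
       Xt = titr$syringe_conc * (DV / V0) / denom)
}

#' Fraction of protein sites occupied at a titration point
#'
#' Closed-form solution of the single-site binding equilibrium at total
#' concentrations Mt (protein) and Xt (ligand) for binding-competent
#' fraction n and association constant K:
#' Theta = (A - sqrt(A^2 - 4 Xt/(n Mt))) / 2 with
#' A = 1 + Xt/(n Mt) + 1/(n K Mt). Equivalent to the mass-balance root for
#' free ligand (checked against a brute-force solver in the test suite).
#'
#' @param Mt total protein concentration, M.
#' @param Xt total ligand concentration, M.
#' @param n binding-competent fraction.
#' @param K association constant, M-1.
#' @return occupancy Theta in [0, 1].
#' @export
bound_fraction <- function(Mt, Xt, n, K) {
  stopifnot_positive(c(Mt, n, K), "Mt, n and K")
  if (any(Xt < 0)) stop("Xt must be non-negative", call. = FALSE)
  A <- 1 + Xt / (n * Mt) + 1 / (n * K * Mt)
  disc <- A^2 - 4 * Xt / (n * Mt)
  if (any(disc < 0)) {
    warning("negative discriminant clipped to 0 (numerical)")
    disc <- pmax(disc, 0)
  }
  (A - sqrt(disc)) / 2
}

#' Predicted per-injection heats of a single-site titration
#'
#' Forward (Wiseman) model shared by the simulator and the fitter. The
#' cumulative heat after injection i is Q_i = n Theta_i Mt_i dH V0; the
#' per-injection heat applies the displaced-volume correction
#' q_i = Q_i - Q_{i-1} + (dV_i/V0) (Q_i + Q_{i-1}) / 2, with Q_0 = 0.
#'
#' @param params list with \code{n}, \code{K} (M-1), \code{dH} (cal/mol).
#' @param titr an [itc_titration()].
#' @return numeric vector of per-injection heats, cal.
#' @export
predict_heats <- function(params, titr) {
  n_inj <- length(titr$injection_volumes)
  V0 <- titr$cell_volume
  Q <- numeric(n_inj + 1)  # Q[1] = Q_0 = 0
  for (i in seq_len(n_inj)) {
    conc <- concentrations_after_injection(i, titr)
    theta <- bound_fraction(conc$Mt, conc$Xt, params$n, params$K)
    Q[i + 1] <- params$n * theta * conc$Mt * params$dH * V0
  }
  dV <- titr$injection_volumes
  q <- Q[-1] - Q[-(n_inj + 1)] +
    (dV / V0) * (Q[-1] + Q[-(n_inj + 1)]) / 2
  q
}

#' Fit the single-site binding isotherm to a titration
#'
#' Nonlinear least squares of [predict_heats()] over (n, K, dH), with K
#' handled on the log scale to enforce positivity and a small grid of
#' affinity starts to avoid local minima on low-c isotherms. Reports the
#' dissociation constant Kd = 1/K and the thermodynamic decomposition
#' dG = -RT ln K, TdS = dH - dG at the experiment temperature. Standard
#' errors are asymptotic fit errors from the least-squares covariance.
#'
#' A c-value (n K M0) outside [0.1, 1000] triggers a warning: such
#' isotherms constrain the parameters poorly.
#'
#' @param titr an [itc_titration()].
#' @param drop_first discard the first injection (common practice for the
#'   diffusion-compromised first aliquot); default \code{FALSE}.
#' @param n_start starting value for n.
#' @return list of class \code{binding_fit}: \code{n}, \code{K},
#'   \code{Kd}, \code{dH}, \code{dG}, \code{TdS}, per-parameter \code{se},
#'   \code{rss}, \code{residuals}, \code{c_value}, \code{converged},
#'   \code{degenerate}.
#' @examples
#' truth <- ground_truth(noise = noise_free())
#' fit <- fit_isotherm(simulate_itc(truth))
#' M_to_uM(fit$Kd)  # 110
#' @export
fit_isotherm <- function(titr, drop_first = FALSE, n_start = 1) {
  keep <- seq_along(titr$heats)
  if (drop_first) keep <- keep[-1]
  if (length(keep) < 6) {
    stop("at least 6 informative injections required", call. = FALSE)
  }
  q_obs <- titr$heats
  if (all(q_obs == 0)) {
    warning("all heats zero: dH -> 0, K unidentifiable")
    return(structure(list(n = NA_real_, K = NA_real_, Kd = NA_real_, dH = 0,
                          dG = NA_real_, TdS = NA_real_,
                          se = c(n = NA, K = NA, dH = NA), rss = 0,
                          residuals = q_obs, c_value = NA_real_,
                          converged = FALSE, degenerate = TRUE,
                          temperature = titr$temperature),
                     class = "binding_fit"))
  }

  model_resid <- function(par) {
    q_hat <- predict_heats(list(n = par[1], K = exp(par[2]), dH = par[3]),
                           titr)
    (q_hat - q_obs)[keep]
  }
  # crude dH scale from total observed heat assuming near-complete binding
  dH0 <- sum(q_obs[keep]) / (n_start * titr$cell_conc * titr$cell_volume)
  if (!is.finite(dH0) || dH0 == 0) dH0 <- sign(sum(q_obs)) * 1e3
  kd_starts <- c(1e-3, 1e-4, 1e-5, 1e-6)
  best <- NULL
  for (kd0 in kd_starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = c(n = n_start, lK = log(1 / kd0), dH = dH0),
        fn = model_resid,
        lower = c(1e-3, log(1e-2), -Inf), upper = c(3, log(1e12), Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                             ptol = 1e-15)),
      error = function(e) NULL)
    if (!is.null(res) &&
        (is.null(best) || res$deviance < best$deviance)) best <- res
  }
  if (is.null(best)) {
    stop("isotherm fit did not converge; residuals unavailable", call. = FALSE)
  }
  par <- best$par
  K <- exp(par[["lK"]])
  vc <- tryCatch(vcov(best), error = function(e) matrix(NA, 3, 3))
  se <- sqrt(diag(vc))
  se_K <- K * se[2]  # delta method from log scale
  T <- titr$temperature
  dG <- -.R_CAL * T * log(K)
  fit <- structure(list(
    n = par[["n"]], K = K, Kd = 1 / K, dH = par[["dH"]],
    dG = dG, TdS = par[["dH"]] - dG,
    se = c(n = unname(se[1]), K = unname(se_K), dH = unname(se[3])),
    rss = best$deviance, residuals = model_resid(par),
    c_value = par[["n"]] * K * titr$cell_conc,
    converged = best$info %in% 1:4, degenerate = FALSE,
    temperature = T
  ), class = "binding_fit")
  if (is.finite(fit$c_value) &&
      (fit$c_value < 0.1 || fit$c_value > 1000)) {
    warning(sprintf("c-value %.3g outside [0.1, 1000]: isotherm poorly determined",
                    fit$c_value))
  }
  fit
}

#' @export
print.binding_fit <- function(x, ...) {
  if (x$degenerate) {
    cat("Binding fit: degenerate (all heats zero)\n")
    return(invisible(x))
  }
  cat(sprintf("Single-site binding fit (T = %.2f K)\n", x$temperature))
  cat(sprintf("  n  = %.3f +/- %.3f\n", x$n, x$se[["n"]]))
  cat(sprintf("  Kd = %.3g uM (K = %.3g M-1 +/- %.2g)\n",
              M_to_uM(x$Kd), x$K, x$se[["K"]]))
  cat(sprintf("  dH = %.0f cal/mol, dG = %.0f cal/mol, TdS = %.0f cal/mol\n",
              x$dH, x$dG, x$TdS))
  cat(sprintf("  c-value = %.3g, rss = %.3g\n", x$c_value, x$rss))
  invisible(x)
}

#' Read an ITC titration from CSV
#'
#' Expects a two-part file: a key,value header block (keys
#' \code{cell_conc_uM}, \code{syringe_conc_uM}, \code{cell_volume_uL},
#' \code{temperature_K}, \code{label}) followed by an
#' \code{injection,volume_uL,heat_ucal} table; the two parts are separated
#' by a blank line. Units are converted to M / L / cal on read.
#'
#' @param path file path.
#' @return an [itc_titration()].
#' @export
read_itc_csv <- function(path) {
  lines <- readLines(path)
  sep <- which(lines == "")[1]
  if (is.na(sep)) stop("ITC CSV must contain a blank line between header and table",
                       call. = FALSE)
  hdr <- utils::read.csv(text = lines[seq_len(sep - 1)], header = FALSE,
                         stringsAsFactors = FALSE)
  kv <- stats::setNames(hdr$V2, hdr$V1)
  tab <- utils::read.csv(text = lines[(sep + 1):length(lines)])
  itc_titration(
    cell_conc = as.numeric(kv[["cell_conc_uM"]]) * 1e-6,
    syringe_conc = as.numeric(kv[["syringe_conc_uM"]]) * 1e-6,
    cell_volume = as.numeric(kv[["cell_volume_uL"]]) * 1e-6,
    injection_volumes = tab$volume_uL * 1e-6,
    heats = tab$heat_ucal * 1e-6,
    temperature = as.numeric(kv[["temperature_K"]]),
    label = if ("label" %in% names(kv)) kv[["label"]] else ""
  )
}

#' @rdname read_itc_csv
#' @param titr titration to write.
#' @export
write_itc_csv <- function(titr, path) {
  hdr <- c(
    sprintf("cell_conc_uM,%.10g", M_to_uM(titr$cell_conc)),
    sprintf("syringe_conc_uM,%.10g", M_to_uM(titr$syringe_conc)),
    sprintf("cell_volume_uL,%.10g", titr$cell_volume * 1e6),
    sprintf("temperature_K,%.10g", titr$temperature),
    sprintf("label,%s", titr$label), ""
  )
  tab <- data.frame(injection = seq_along(titr$heats),
                    volume_uL = titr$injection_volumes * 1e6,
                    heat_ucal = titr$heats * 1e6)
  writeLines(c(hdr, "injection,volume_uL,heat_ucal",
               apply(tab, 1, function(r) paste(format(r, trim = TRUE,
                                                      digits = 15),
                                               collapse = ","))), path)
  invisible(path)
}
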