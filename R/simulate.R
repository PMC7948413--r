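#' Simulate isotope-labelled peptide intensity tables
#'
#' Emulates the light/heavy chemical-acetylation labelling experiment: the
#' protein is incubated with acetyl-CoA so that each lysine acquires an
#' endogenous ("light", +42.0106 Da) acetyl group with pseudo-first-order
#' kinetics, then all remaining free lysines are exhaustively labelled with a
#' heavy D3-acetyl group (+45.0294 Da). For a site with second-order rate
#' constant k2 at acetyl-CoA concentration c and time t, the true
#' stoichiometry is S = 1 - exp(-k2 c t). For a peptide with m lysines the
#' sites react independently, so the intensity of the channel carrying l
#' light acetyls is A * C(m, l) S^l (1-S)^(m-l), with A the (arbitrary)
#' peptide abundance. Multiplicative log-normal noise with coefficient of
#' variation \code{noise$ms_cv} is applied per channel; with
#' \code{ms_cv = 0} channel intensities are exact and sum to A.
#'
#' @param truth a [ground_truth()] object.
#' @return data frame with columns \code{peptide_id}, \code{site_ids}
#'   (semicolon-separated residues), \code{n_lysines}, \code{light_acetyls},
#'   \code{intensity}, \code{accoa_conc_M}, \code{time_s}, \code{replicate}
#'   -- the same schema [read_peptide_table()] consumes.
#' @seealso [compute_stoichiometry()], [fit_site_rates()]
#' @export
simulate_labeled_peptides <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(truth$seed)
  rows <- list()
  base_abundance <- 1e6
  for (p in seq_along(truth$site_rates)) {
    pid <- names(truth$site_rates)[p]
    k2 <- truth$site_rates[[p]]
    m <- length(strsplit(pid, ";", fixed = TRUE)[[1]])
    A <- base_abundance * p  # distinct, arbitrary abundances
    for (conc in truth$acCoA_concs) {
      for (t in truth$timepoints) {
        S <- 1 - exp(-k2 * conc * t)
        for (rep_i in seq_len(truth$n_replicates)) {
          l <- 0:m
          channel <- A * stats::dbinom(l, size = m, prob = S)
          channel <- channel * lognormal_noise(m + 1, truth$noise$ms_cv)
          rows[[length(rows) + 1]] <- data.frame(
            peptide_id = pid, site_ids = pid, n_lysines = m,
            light_acetyls = l, intensity = channel,
            accoa_conc_M = conc, time_s = t, replicate = rep_i,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a single-site calorimetric titration
#'
#' Generates per-injection heats for a titration of ligand into protein
#' through the same single-site (Wiseman) forward model used by
#' [fit_isotherm()] -- [predict_heats()] -- plus additive Gaussian noise
#' with sd \code{noise$itc_sd} (cal). With zero noise the heats are exactly
#' those of the forward model, so fitting recovers the generating
#' parameters.
#'
#' @param truth a [ground_truth()] object; \code{truth$itc_params} holds the
#'   true (n, Kd, dH) and the instrument geometry.
#' @param label condition string carried on the titration (e.g. the Mn2+
#'   level).
#' @return an [itc_titration()] object.
#' @export
simulate_itc <- function(truth, label = "default") {
  stopifnot(inherits(truth, "ground_truth"))
  ip <- truth$itc_params
  stopifnot_positive(ip$Kd, "Kd")
  set.seed(truth$seed + 1L)
  titr <- itc_titration(
    cell_conc = ip$cell_conc, syringe_conc = ip$syringe_conc,
    cell_volume = ip$cell_volume, injection_volumes = ip$injection_volumes,
    heats = rep(0, length(ip$injection_volumes)),
    temperature = ip$temperature, label = label
  )
  q <- predict_heats(list(n = ip$n, K = 1 / ip$Kd, dH = ip$dH), titr)
  if (truth$noise$itc_sd > 0) {
    q <- q + stats::rnorm(length(q), sd = truth$noise$itc_sd)
  }
  titr$heats <- q
  titr
}

#' Simulate STD NMR build-up curves
#'
#' Mono-exponential saturation-transfer build-up per ligand proton:
#' STD(t_sat) = STD_max (1 - exp(-k_sat t_sat)), evaluated on the saturation
#' time grid, with additive Gaussian noise sd \code{noise$std_sd}. At
#' t_sat = 0 the STD intensity is 0 by construction.
#'
#' @param truth a [ground_truth()] object.
#' @param t_sat saturation times in seconds (default 0.5 to 5 s).
#' @param ligand ligand label carried on the curves.
#' @param irradiation on-resonance irradiation regime, "aliphatic"
#'   (-1 ppm) or "aromatic" (7.19 ppm).
#' @param std_params optional override of \code{truth$std_params}, e.g. to
#'   simulate a second irradiation frequency for DEEP-STD analysis.
#' @return data frame with columns \code{ligand}, \code{irradiation},
#'   \code{proton_id}, \code{t_sat_s}, \code{std_intensity}.
#' @export
simulate_std_buildup <- function(truth,
                                 t_sat = c(0.5, 1, 1.5, 2, 3, 4, 5),
                                 ligand = "acetyl-CoA",
                                 irradiation = c("aliphatic", "aromatic"),
                                 std_params = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  irradiation <- match.arg(irradiation)
  if (any(t_sat < 0)) stop("saturation times must be >= 0", call. = FALSE)
  pars <- if (is.null(std_params)) truth$std_params else std_params
  set.seed(truth$seed + 2L)
  out <- do.call(rbind, lapply(seq_len(nrow(pars)), function(i) {
    y <- pars$STD_max[i] * (1 - exp(-pars$k_sat[i] * t_sat))
    if (truth$noise$std_sd > 0) {
      y <- y + stats::rnorm(length(y), sd = truth$noise$std_sd)
    }
    data.frame(ligand = ligand, irradiation = irradiation,
               proton_id = pars$proton_id[i], t_sat_s = t_sat,
               std_intensity = y, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Simulate initial-rate Michaelis-Menten data
#'
#' For each enzyme/substrate/direction in \code{truth$mm_params}, evaluates
#' v = Vmax S / (Km + S) on a substrate grid spanning 0.2x to 20x Km
#' (log-spaced) and applies multiplicative Gaussian noise with CV
#' \code{noise$rate_cv}. Noiseless tables are fitted back exactly by
#' [fit_mm()].
#'
#' @param truth a [ground_truth()] object.
#' @param n_conc number of substrate concentrations (default 8).
#' @param replicates replicate measurements per concentration.
#' @return data frame with columns \code{enzyme}, \code{substrate},
#'   \code{direction}, \code{s_conc_mM}, \code{rate_umol_min_mg},
#'   \code{replicate}.
#' @export
simulate_mm_rates <- function(truth, n_conc = 8, replicates = 1) {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(truth$seed + 3L)
  mm <- truth$mm_params
  out <- do.call(rbind, lapply(seq_len(nrow(mm)), function(i) {
    S <- exp(seq(log(0.2 * mm$Km[i]), log(20 * mm$Km[i]), length.out = n_conc))
    do.call(rbind, lapply(seq_len(replicates), function(r) {
      v <- mm$Vmax[i] * S / (mm$Km[i] + S)
      if (truth$noise$rate_cv > 0) {
        v <- v * (1 + stats::rnorm(length(v), sd = truth$noise$rate_cv))
      }
      data.frame(enzyme = mm$enzyme[i], substrate = mm$substrate[i],
                 direction = mm$direction[i], s_conc_mM = S,
                 rate_umol_min_mg = v, replicate = r,
                 stringsAsFactors = FALSE)
    }))
  }))
  rownames(out) <- NULL
  out
}

#' Simulate a Western-blot densitometry time course
#'
#' Band intensities for the acetyl-lysine signal follow the same saturating
#' exponential as the site kinetics, normalised against a constant total
#' protein signal, with multiplicative log-normal noise (CV
#' \code{noise$ms_cv}).
#'
#' @param truth a [ground_truth()] object.
#' @param times_h sampling times in hours.
#' @param kobs pseudo-first-order rate (s-1) of the bulk acetylation signal.
#' @param condition condition label for the lanes.
#' @return data frame with columns \code{lane_label}, \code{ack_signal},
#'   \code{pck1_signal}, \code{time_h}, \code{condition}.
#' @export
simulate_densitometry <- function(truth, times_h = c(0, 1, 2, 4, 6, 8, 12, 18),
                                  kobs = 5e-5, condition = "AcCoA") {
  stopifnot(inherits(truth, "ground_truth"))
  set.seed(truth$seed + 4L)
  sat <- 1 - exp(-kobs * times_h * 3600)
  n <- length(times_h)
  data.frame(
    lane_label = sprintf("%s_t%gh", condition, times_h),
    ack_signal = 100 * sat * lognormal_noise(n, truth$noise$ms_cv),
    pck1_signal = 100 * lognormal_noise(n, truth$noise$ms_cv),
    time_h = times_h, condition = condition, stringsAsFactors = FALSE
  )
}
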