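#' Fit a mono-exponential STD build-up curve
#'
#' Saturation-transfer difference intensities grow with saturation time as
#' STD(t_sat) = STD_max (1 - exp(-k_sat t_sat)). Fitting the full build-up
#' rather than a single saturation time and mapping the initial growth rate
#' STD0 = STD_max * k_sat minimises the T1 relaxation bias across protons.
#'
#' @param t_sat saturation times in s (>= 4 values).
#' @param std_intensity STD intensities (fractional amplification), >= 0.
#' @return list with \code{STD_max}, \code{k_sat}, \code{STD0}, standard
#'   errors, and \code{measurable} (FALSE for flat/zero curves or
#'   non-convergent fits, which downstream maps skip).
#' @examples
#' t <- c(0.5, 1, 2, 3, 5)
#' fit_buildup(t, 2 * (1 - exp(-0.5 * t)))
#' @export
fit_buildup <- function(t_sat, std_intensity) {
  if (length(t_sat) < 4) {
    stop("at least 4 saturation times required", call. = FALSE)
  }
  if (is.unsorted(t_sat, strictly = TRUE)) {
    stop("saturation times must be strictly increasing", call. = FALSE)
  }
  not_measurable <- list(STD_max = NA_real_, k_sat = NA_real_,
                         STD0 = NA_real_, se = c(STD_max = NA_real_,
                                                 k_sat = NA_real_),
                         measurable = FALSE)
  if (all(std_intensity <= 0) || stats::sd(std_intensity) == 0) {
    return(not_measurable)
  }
  d <- data.frame(t = t_sat, y = std_intensity)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ smax * (1 - exp(-k * t)), data = d,
                      start = list(smax = max(std_intensity),
                                   k = 1 / stats::median(t_sat)),
                      lower = c(1e-12, 1e-12),
                      control = minpack.lm::nls.lm.control(
                        maxiter = 200, ftol = 1e-15, ptol = 1e-15)),
    error = function(e) NULL)
  if (is.null(fit)) return(not_measurable)
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(smax = NA_real_, k = NA_real_))
  list(STD_max = unname(cf[["smax"]]), k_sat = unname(cf[["k"]]),
       STD0 = unname(cf[["smax"]] * cf[["k"]]),
       se = c(STD_max = unname(se[["smax"]]), k_sat = unname(se[["k"]])),
       measurable = TRUE)
}

#' Binding-epitope map from STD build-up fits
#'
#' Fits every proton's build-up curve, computes the initial growth rate
#' STD0 = STD_max k_sat, and normalises STD0 values to the largest proton
#' (= 100%). Protons whose curves cannot be fit are reported with
#' \code{measurable = FALSE} and NA values -- never imputed. Ties at the
#' maximum all map to 100%.
#'
#' @param curves data frame with columns \code{proton_id}, \code{t_sat_s},
#'   \code{std_intensity} (and optionally \code{ligand},
#'   \code{irradiation}, carried through).
#' @return data frame of class \code{epitope_map}: one row per proton with
#'   \code{STD_max}, \code{k_sat}, \code{STD0}, \code{normalized_STD0}
#'   (percent of the maximum), \code{measurable}.
#' @export
epitope_map <- function(curves) {
  parts <- split(curves, curves$proton_id)
  rows <- lapply(parts, function(d) {
    d <- d[order(d$t_sat_s), , drop = FALSE]
    f <- fit_buildup(d$t_sat_s, d$std_intensity)
    data.frame(proton_id = d$proton_id[1],
               ligand = if ("ligand" %in% names(d)) d$ligand[1] else NA,
               irradiation = if ("irradiation" %in% names(d)) d$irradiation[1] else NA,
               STD_max = f$STD_max, k_sat = f$k_sat, STD0 = f$STD0,
               measurable = f$measurable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!any(out$measurable)) {
    stop("no measurable proton in the curve set", call. = FALSE)
  }
  out$normalized_STD0 <- 100 * out$STD0 / max(out$STD0, na.rm = TRUE)
  out <- out[order(-replace(out$normalized_STD0,
                            is.na(out$normalized_STD0), -Inf)), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("epitope_map", class(out))
  out
}

#' DEEP-STD differential factors between two irradiation regimes
#'
#' Differential epitope mapping compares per-proton STD responses under
#' alternate on-resonance irradiation (aliphatic, -1 ppm, vs aromatic,
#' 7.19 ppm protein resonances). Each map's STD0 values are first
#' referenced to their mean over the common proton set, then differenced:
#' Delta_i = STD0_i(f1)/mean(STD0(f1)) - STD0_i(f2)/mean(STD0(f2)).
#' The mean-referencing makes the factors invariant to a global scaling of
#' either map; identical maps give all-zero factors. A nonzero factor
#' indicates that proton i receives relatively more saturation from one
#' residue type, i.e. it reports the kind of side chains contacted.
#'
#' @param map_f1,map_f2 [epitope_map()]s acquired at the two irradiation
#'   frequencies.
#' @return data frame with \code{proton_id} and \code{deep_std_factor} for
#'   the common measurable protons.
#' @export
deep_std_factors <- function(map_f1, map_f2) {
  m1 <- map_f1[map_f1$measurable, c("proton_id", "STD0")]
  m2 <- map_f2[map_f2$measurable, c("proton_id", "STD0")]
  common <- intersect(m1$proton_id, m2$proton_id)
  if (length(common) == 0) {
    stop("no common measurable protons between the two maps", call. = FALSE)
  }
  s1 <- m1$STD0[match(common, m1$proton_id)]
  s2 <- m2$STD0[match(common, m2$proton_id)]
  data.frame(proton_id = common,
             deep_std_factor = s1 / mean(s1) - s2 / mean(s2),
             stringsAsFactors = FALSE)
}

#' Compare the binding epitopes of two ligands
#'
#' Quantifies how similar two epitope maps are (e.g. acetyl-CoA vs CoA):
#' Spearman rank correlation of normalised STD0 over the common protons,
#' plus per-proton differences in normalised STD0.
#'
#' @param map_a,map_b [epitope_map()]s for the two ligands.
#' @return list with \code{rank_correlation}, \code{n_common} and a
#'   \code{deltas} data frame (\code{proton_id},
#'   \code{normalized_STD0_a}, \code{normalized_STD0_b}, \code{delta}).
#' @export
compare_ligands <- function(map_a, map_b) {
  a <- map_a[map_a$measurable, c("proton_id", "normalized_STD0")]
  b <- map_b[map_b$measurable, c("proton_id", "normalized_STD0")]
  common <- intersect(a$proton_id, b$proton_id)
  if (length(common) == 0) {
    stop("no common measurable protons between ligands", call. = FALSE)
  }
  na <- a$normalized_STD0[match(common, a$proton_id)]
  nb <- b$normalized_STD0[match(common, b$proton_id)]
  rho <- if (length(common) > 1) {
    suppressWarnings(stats::cor(na, nb, method = "spearman"))
  } else NA_real_
  list(rank_correlation = rho, n_common = length(common),
       deltas = data.frame(proton_id = common, normalized_STD0_a = na,
                           normalized_STD0_b = nb, delta = na - nb,
                           stringsAsFactors = FALSE))
}
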