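#' Acetylation stoichiometry from a light/heavy channel pair
#'
#' The fraction of a lysine carrying an endogenous (light) acetyl group,
#' measured against the exhaustive heavy D3-acetyl label of the remaining
#' free amine: S = I_L / (I_L + I_H). The ratio is scale invariant, so
#' intensities can be in any common arbitrary unit.
#'
#' @param I_light intensity of the light-acetyl channel (>= 0).
#' @param I_heavy intensity of the heavy-acetyl channel (>= 0).
#' @return stoichiometry in [0, 1], or \code{NA} with an "undetected"
#'   attribute when both channels are zero (such conditions are excluded
#'   from kinetic fits, not imputed as zero).
#' @examples
#' stoichiometry_single(25, 75)  # 0.25
#' @export
stoichiometry_single <- function(I_light, I_heavy) {
  if (I_light < 0 || I_heavy < 0) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  if (I_light + I_heavy == 0) {
    return(structure(NA_real_, undetected = TRUE))
  }
  I_light / (I_light + I_heavy)
}

#' Peptide-level acetylation stoichiometry for multi-lysine peptides
#'
#' Peptides containing m lysines are observed as m + 1 isotopologue
#' channels, indexed by the number l of light acetyls they carry. The
#' fractional occupancy of lysine positions by light acetyl is
#' S = sum(l * I_l) / (m * sum(I_l)). With m = 1 this reduces to
#' [stoichiometry_single()]. Site-level deconvolution within a peptide is
#' not attempted; multi-lysine peptides are reported jointly (e.g.
#' "K278;K290").
#'
#' @param light_acetyls integer vector of light-acetyl counts l (subset of
#'   0..m).
#' @param intensity channel intensities aligned with \code{light_acetyls}.
#' @param n_lysines number of lysines m in the peptide.
#' @return fractional occupancy in [0, 1], or undetected \code{NA} as in
#'   [stoichiometry_single()].
#' @examples
#' stoichiometry_multisite(c(0, 1, 2), c(50, 50, 0), 2)  # 0.25
#' @export
stoichiometry_multisite <- function(light_acetyls, intensity, n_lysines) {
  m <- n_lysines
  if (m < 1) stop("peptide must contain at least one lysine", call. = FALSE)
  if (any(light_acetyls < 0) || any(light_acetyls > m)) {
    stop("light-acetyl counts must lie in 0..n_lysines", call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("channel intensities must be non-negative", call. = FALSE)
  }
  total <- sum(intensity)
  if (total == 0) return(structure(NA_real_, undetected = TRUE))
  sum(light_acetyls * intensity) / (m * total)
}

#' Per-condition stoichiometry table from a labelled-peptide table
#'
#' Collapses channel-level intensities into one stoichiometry per
#' (peptide, acetyl-CoA concentration, time, replicate), then optionally
#' aggregates replicates into mean and sample sd.
#'
#' @param peptides data frame in the [simulate_labeled_peptides()] /
#'   [read_peptide_table()] schema.
#' @param aggregate if \code{TRUE} (default), replicates are averaged; set
#'   \code{FALSE} to keep one row per replicate.
#' @return data frame with columns \code{peptide_id}, \code{site_ids},
#'   \code{n_lysines}, \code{accoa_conc_M}, \code{time_s},
#'   \code{stoichiometry}, \code{sd}, \code{n}. Undetected conditions
#'   (all channels zero) are dropped with a message.
#' @export
compute_stoichiometry <- function(peptides, aggregate = TRUE) {
  req <- c("peptide_id", "site_ids", "n_lysines", "light_acetyls",
           "intensity", "accoa_conc_M", "time_s", "replicate")
  missing_cols <- setdiff(req, names(peptides))
  if (length(missing_cols) > 0) {
    stop("peptide table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  key <- interaction(peptides$peptide_id, peptides$accoa_conc_M,
                     peptides$time_s, peptides$replicate, drop = TRUE)
  parts <- split(peptides, key)
  rows <- lapply(parts, function(d) {
    S <- stoichiometry_multisite(d$light_acetyls, d$intensity, d$n_lysines[1])
    data.frame(peptide_id = d$peptide_id[1], site_ids = d$site_ids[1],
               n_lysines = d$n_lysines[1], accoa_conc_M = d$accoa_conc_M[1],
               time_s = d$time_s[1], replicate = d$replicate[1],
               stoichiometry = as.numeric(S), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  n_undetected <- sum(is.na(out$stoichiometry))
  if (n_undetected > 0) {
    message(n_undetected, " undetected (all-zero) peptide condition(s) excluded")
    out <- out[!is.na(out$stoichiometry), , drop = FALSE]
  }
  if (!aggregate) return(out)
  aggregate_replicates(out)
}

#' Aggregate replicate stoichiometries
#'
#' Mean and sample standard deviation over replicates of the same peptide
#' and condition. A single replicate yields \code{sd = NA}.
#'
#' @param stoich data frame with per-replicate rows as produced by
#'   \code{compute_stoichiometry(aggregate = FALSE)}.
#' @return one row per (peptide, condition) with \code{stoichiometry},
#'   \code{sd}, \code{n}.
#' @export
aggregate_replicates <- function(stoich) {
  if (nrow(stoich) == 0) stop("no stoichiometry rows to aggregate", call. = FALSE)
  key <- interaction(stoich$peptide_id, stoich$accoa_conc_M, stoich$time_s,
                     drop = TRUE)
  parts <- split(stoich, key)
  rows <- lapply(parts, function(d) {
    data.frame(peptide_id = d$peptide_id[1], site_ids = d$site_ids[1],
               n_lysines = d$n_lysines[1], accoa_conc_M = d$accoa_conc_M[1],
               time_s = d$time_s[1],
               stoichiometry = mean(d$stoichiometry),
               sd = if (nrow(d) > 1) stats::sd(d$stoichiometry) else NA_real_,
               n = nrow(d), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$peptide_id, out$accoa_conc_M, out$time_s), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read / write labelled-peptide and stoichiometry CSV tables
#'
#' Flat CSV schemas shared between the simulator and the analysis stages:
#' the peptide table has columns \code{peptide_id, site_ids, n_lysines,
#' light_acetyls, intensity, accoa_conc_M, time_s, replicate}.
#'
#' @param path file path.
#' @return data frame (readers); invisibly the path (writers).
#' @export
read_peptide_table <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(site_ids = "character"))
}

#' @rdname read_peptide_table
#' @param x table to write.
#' @export
write_peptide_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}
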