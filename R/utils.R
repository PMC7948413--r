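#' Convert millimolar to molar
#'
#' Concentration unit helper. All internal rate arithmetic is done in molar
#' units (M, s); bench data are typically recorded in mM, so conversions go
#' through this helper rather than ad hoc factors.
#'
#' @param x numeric vector of concentrations in mM.
#' @return concentrations in M.
#' @export
mM_to_M <- function(x) x * 1e-3

#' Convert molar to micromolar
#' @param x numeric vector of concentrations in M.
#' @return concentrations in uM.
#' @export
M_to_uM <- function(x) x * 1e6

#' Gas constant in cal mol-1 K-1
#' @keywords internal
.R_CAL <- 1.98720425

stopifnot_positive <- function(x, what) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop(what, " must be strictly positive and finite", call. = FALSE)
  }
  invisible(x)
}

# multiplicative log-normal noise factors with mean 1 and coefficient of
# variation cv; cv = 0 returns exact ones
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}
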