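# Independent oracles, deliberately on different code paths from the package.

# Brute-force single-site binding occupancy: root-find the free-ligand
# mass balance F + n*Mt*K*F/(1+K*F) = Xt, then Theta = K*F/(1+K*F).
oracle_bound_fraction <- function(Mt, Xt, n, K) {
  if (Xt == 0) return(0)
  g <- function(F) F + n * Mt * K * F / (1 + K * F) - Xt
  lo <- 0; hi <- Xt
  for (i in 1:200) {  # bisection to double-precision resolution
    mid <- (lo + hi) / 2
    if (g(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < .Machine$double.eps * hi) break
  }
  F <- (lo + hi) / 2
  K * F / (1 + K * F)
}

# noiseless truth with the study's default conditions
noiseless_truth <- function(...) {
  ground_truth(noise = noise_free(), ...)
}
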