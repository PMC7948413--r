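# ackinetics

Quantitative analysis of **nonenzymatic (chemical) lysine acetylation** of
cytosolic phosphoenolpyruvate carboxykinase (PCK1) and its functional
consequences. PCK1 can transfer the acetyl group of acetyl-CoA onto its own
lysines — including the catalytic residues K244 and K290 inside the active
site — without any acetyltransferase. This package is for biochemists and
proteomics analysts who need to turn the raw tabular outputs of that kind of
study into site reactivities, binding constants, epitope maps and kinetic
comparisons:

* **Acetylation stoichiometry** from light (endogenous, +42.0106 Da) vs
  heavy (D3-acetyl, +45.0294 Da) peptide channel intensities:
  `S = I_L/(I_L + I_H)`, with peptide-level fractional occupancy
  `S = Σ ℓ·I_ℓ / (m Σ I_ℓ)` for m-lysine peptides.
* **Site reactivity**: pseudo-first-order rates `k_obs = −ln(1−S)/t` per
  acetyl-CoA concentration and the second-order constant `k₂` as the slope
  of `k_obs` vs concentration (through the origin), reported on the
  conventional ×10⁻⁵ M⁻¹s⁻¹ scale.
* **Single-site (Wiseman) ITC isotherm fitting** over (n, K, ΔH) with
  overfill-cell dilution bookkeeping, returning K_d = 1/K,
  ΔG = −RT ln K and TΔS = ΔH − ΔG — used for the metal dependence of
  acetyl-CoA binding.
* **STD NMR build-up fitting**, `STD(t_sat) = STD_max(1 − e^(−k_sat t_sat))`,
  initial growth rates STD₀ = STD_max·k_sat, normalised binding-epitope
  maps and DEEP-STD differential factors between irradiation frequencies.
* **Michaelis–Menten comparison** of control vs acetylated enzyme variants:
  V_max, K_m, k_cat, k_cat/K_m, fold-changes and residual activity.
* **Densitometry utilities** (relative acetylation, substrate protection %)
  and a deterministic `run_pipeline()` orchestrator.
* A **synthetic-data generator** (`ground_truth()` + `simulate_*()`) with
  known true parameters and switchable noise, so every estimator is
  validated by parameter recovery.

## Worked example

Simulate the standard labelling design (acetyl-CoA at 0.5–8 mM, 1 h) at the
published site rate constants with zero noise, and recover them through the
stoichiometry → k_obs → k₂ chain:

```r
library(ackinetics)

truth <- ground_truth(noise = noise_free())
stoich <- compute_stoichiometry(simulate_labeled_peptides(truth))
rank_sites(fit_site_rates(stoich))[, c("peptide_id", "k2_x1e5", "r2", "active_site")]
#>   peptide_id k2_x1e5 r2 active_site
#> 1       K204    14.7  1       FALSE
#> 2        K71    14.6  1       FALSE
#> 3  K278;K290     5.9  1        TRUE
#> 4       K135     4.8  1       FALSE
#> 5       K316     3.8  1       FALSE
```

`k2_x1e5` is the second-order rate constant in 10⁻⁵ M⁻¹s⁻¹: K204 and K71
are the most reactive single-lysine sites, and the K278/K290 peptide is
flagged because K290 lines the active site. Fit a calorimetric titration
generated at the high-affinity metal condition (K_d = 0.9 μM, 10 μM protein,
100 μM ligand):

```r
truth$itc_params$Kd <- 0.9e-6
fit_isotherm(simulate_itc(truth))
#> Single-site binding fit (T = 298.15 K)
#>   n  = 1.000 +/- 0.000
#>   Kd = 0.9 uM (K = 1.11e+06 M-1 +/- 1.1e-08)
#>   dH = -8000 cal/mol, dG = -8248 cal/mol, TdS = 248 cal/mol
#>   c-value = 11.1, rss = 1.61e-40
```

Compare the acetylated variants against wild type:

```r
fits <- fit_mm_table(simulate_mm_rates(truth))
cmp <- compare_variants(fits, "WT")
cmp[cmp$enzyme == "K244AcK", c("enzyme", "direction", "residual_activity_pct")]
#>    enzyme     direction residual_activity_pct
#> 1 K244AcK gluconeogenic             1.4375000
#> 4 K244AcK       reverse             0.8823529
```

Acetylation of the active-site lysine K244 leaves ~1% residual activity in
either reaction direction — an inactive enzyme.

See the vignette (`vignettes/acetylation-analysis.Rmd`) for the models,
assumptions, noise structure and design decisions.

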