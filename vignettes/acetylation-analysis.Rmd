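---
title: "Quantifying nonenzymatic PCK1 self-acetylation: models, fitting and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying nonenzymatic PCK1 self-acetylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ackinetics)
```

Cytosolic phosphoenolpyruvate carboxykinase (PCK1) can transfer the acetyl
group of acetyl-CoA onto its own lysine residues without an
acetyltransferase. This package implements the quantitative workflow around
that observation: measuring per-site acetylation stoichiometry, converting
stoichiometry into site reactivity (rate constants), characterising the
acetyl-CoA/PCK1 interaction calorimetrically and by saturation-transfer
difference (STD) NMR, and quantifying the catalytic consequences on the
enzyme. Because the underlying wet-lab measurements cannot be re-run, every
stage is paired with a synthetic-data generator carrying known ground truth,
and correctness is established by parameter recovery.

This vignette documents the models, their assumptions, the tunable
parameters, and the design decisions taken where the methodology left
choices open.

## 1. Acetylation stoichiometry from isotope labelling

After incubation with acetyl-CoA, the protein is denatured and all
*remaining free* lysines are exhaustively acetylated with a heavy
D3-acetyl group (from D6-acetic anhydride). Each lysine is then carrying
either a light (+42.0106 Da, endogenous) or heavy (+45.0294 Da, chemical)
acetyl, and tryptic peptides appear as isotopologue channels. For a peptide
with one lysine the stoichiometry is the light fraction

$$S = \frac{I_L}{I_L + I_H},$$

which is invariant to the (arbitrary) intensity scale. Peptides with $m$
lysines are observed as $m+1$ channels indexed by the number $\ell$ of
light acetyls; we quantify them at peptide level as fractional occupancy

$$S = \frac{\sum_\ell \ell\, I_\ell}{m \sum_\ell I_\ell},$$

which reduces to the single-site formula at $m = 1$. Site-level
deconvolution within a peptide is deliberately not attempted: the channel
intensities alone cannot attribute occupancy to individual positions, and
the experimental reports for multi-lysine peptides (e.g. K278/K290) are
joint. Conditions where every channel is zero are flagged *undetected* and
excluded from kinetic fits rather than imputed as zero, which would bias
rates downward.

```{r stoich}
stoichiometry_single(25, 75)
stoichiometry_multisite(c(0, 1, 2), c(50, 50, 0), n_lysines = 2)
```

## 2. Site reactivity: pseudo-first-order and second-order rate constants

At a fixed acetyl-CoA concentration $c$ the labelling of a site follows
pseudo-first-order kinetics, $S(t) = 1 - e^{-k_{obs} t}$. Two estimators
are provided:

* **single-timepoint inversion**, $k_{obs} = -\ln(1-S)/t$, matching the
  standard design (five concentrations, 0.5–8 mM, one hour);
* **exponential fit** over a time series, with the plateau $S_\infty$
  fixed at 1 by default. A free plateau is unidentifiable at the low
  stoichiometries chemical acetylation reaches (a few tenths of a percent
  per hour at millimolar acetyl-CoA), and the pseudo-first-order framing
  implies complete modification in the long-time limit; `fix_plateau =
  FALSE` is available for diagnostics.

The second-order constant is the slope of $k_{obs}$ against $c$,
$k_{obs} = k_2 c$, fitted through the origin by default — with no acetyl
donor there is no acetylation. A free intercept can be requested to probe
concentration-independent background. Weights are inverse-variance when
replicate standard errors exist, otherwise unweighted. Negative fitted
rates (possible under noise) are clamped to zero with a warning rather
than propagated into the concentration fit.

All internal rates are in s⁻¹ and M⁻¹s⁻¹; the reporting layer prints
$k_2 \times 10^{-5}$ M⁻¹s⁻¹, the conventional scale for lysine reactivity.
Constants at or above $20 \times 10^{-5}$ M⁻¹s⁻¹ are flagged as lower
bounds: on a one-hour design such sites approach saturation and the point
estimate degrades.

```{r rates}
truth <- ground_truth(noise = noise_free())
stoich <- compute_stoichiometry(simulate_labeled_peptides(truth))
rank_sites(fit_site_rates(stoich))[, c("peptide_id", "k2_x1e5", "r2", "active_site")]
```

The `rank_sites()` output joins a packaged annotation of the quantifiable
rat PCK1 lysines (1-based residue numbering) flagging the two active-site
lysines, K244 (Mn²⁺ coordination) and K290 (nucleotide phosphate contact).

## 3. Single-site calorimetric isotherm

Titrations of ligand into protein in an overfill perfusion cell are
modelled with the standard displacement-dilution bookkeeping: after a
cumulative injected volume $\Delta V$ into a cell of volume $V_0$,

$$M_t = M_0\,\frac{1 - \Delta V/2V_0}{1 + \Delta V/2V_0}, \qquad
  X_t = X_0\,\frac{\Delta V/V_0}{1 + \Delta V/2V_0}.$$

The occupancy of a single binding site with association constant $K$ and
binding-competent fraction $n$ is the closed-form root of the binding
equilibrium,

$$\Theta = \tfrac12\!\left[A - \sqrt{A^2 - 4X_t/(nM_t)}\right],\quad
  A = 1 + \frac{X_t}{nM_t} + \frac{1}{nKM_t},$$

verified in the test suite against a brute-force mass-balance root finder
to 10⁻¹⁰ across a random parameter sweep, so the fitter and the simulator
are not checked against themselves alone. Cumulative heat is
$Q_i = n\,\Theta_i M_{t,i}\,\Delta H\, V_0$ and per-injection heats carry
the displaced-volume correction
$q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2$.

`fit_isotherm()` runs Levenberg–Marquardt least squares over
$(n, \log K, \Delta H)$ — the log parameterisation keeps $K$ positive —
from a small grid of affinity starts, and reports $K_d = 1/K$,
$\Delta G = -RT\ln K$ ($R = 1.98720425$ cal mol⁻¹ K⁻¹, $T$ default
298.15 K) and $T\Delta S = \Delta H - \Delta G$. Parameter uncertainties
are asymptotic least-squares errors only; experiment-to-experiment
repeatability is a separate (larger) error source. A Wiseman c-value
$nKM_0$ outside $[0.1, 1000]$ triggers a warning — the metal-free
condition ($K_d \approx 110$ μM at 10 μM protein, $c \approx 0.09$) sits
just below it, which is why that isotherm is featureless and its
parameters are fragile under noise even though noiseless recovery is
exact. The first injection is included by default; `drop_first = TRUE`
implements the common practice of discarding the diffusion-compromised
first aliquot. No separate dilution-heat term is fitted by default.
Ternary (premixed second ligand) titrations are fitted independently with
the same single-site model; explicit cooperative models are out of scope.

```{r itc}
truth$itc_params$Kd <- 0.9e-6   # the 0.1 mM Mn2+ condition
fit <- fit_isotherm(simulate_itc(truth))
fit
```

## 4. STD NMR build-up and DEEP-STD epitope mapping

Per-proton saturation-transfer intensities build up mono-exponentially
with saturation time,

$$STD(t_{sat}) = STD_{max}\,(1 - e^{-k_{sat} t_{sat}}),$$

and the mapped quantity is the initial growth rate
$STD_0 = STD_{max} \cdot k_{sat}$, which minimises the T₁ relaxation bias
that a single-saturation-time comparison would carry. Epitope maps
normalise $STD_0$ to the strongest proton (= 100%); normalisation is
per-ligand by default (a global-maximum option exists, since the
convention is not fixed by the methodology). Exactly one proton sits at
100% barring ties; ties all map to 100%. Protons whose curves are flat or
do not converge are flagged *not measurable* and propagate as explicit
missing values, never imputed.

DEEP-STD factors compare responses under alternate on-resonance
irradiation (aliphatic, −1 ppm, vs aromatic, 7.19 ppm protein
resonances). The published workflow prints no formula, so this package
adopts the mean-referenced difference from the originating DEEP-STD
methodology:

$$\Delta_i = \frac{STD_{0,i}(f_1)}{\langle STD_0(f_1)\rangle}
           - \frac{STD_{0,i}(f_2)}{\langle STD_0(f_2)\rangle},$$

with means over the common proton set. This makes the factors invariant
to global scaling of either map and zero for identical maps. **This
formula choice is the one place the implementation goes beyond what the
workflow states explicitly**; it is flagged here deliberately.

```{r std}
emap <- epitope_map(simulate_std_buildup(truth))
emap[, c("proton_id", "STD0", "normalized_STD0")]
```

## 5. Enzyme kinetics of control vs acetylated variants

Initial rates are fitted to $v = V_{max} S/(K_m + S)$ by unweighted
nonlinear least squares (the assay protocol states no weighting scheme).
$k_{cat}$ is derived from the mass-specific $V_{max}$ through a
configurable monomer molar mass (default 69.4 kDa for rat PCK1; affinity
tags change it), and catalytic efficiency as $k_{cat}/K_m$.
`compare_variants()` produces fold-changes and residual activity
percentages against a reference enzyme and is exactly anti-symmetric
under swapping the reference. An Eadie–Hofstee linearisation is provided
as an internal consistency check (collinear on noiseless data), not as an
estimator. CO₂ is treated as a substrate axis like any other;
bi-substrate ternary-complex rate laws and inhibitor modelling are out of
scope.

```{r mm}
mm_fits <- fit_mm_table(simulate_mm_rates(truth))
compare_variants(mm_fits, reference = "WT")
```

## 6. Densitometry-derived quantities

Western-blot band quantities enter as numbers (image processing is out of
scope). `relative_acetylation()` normalises the acetyl-lysine signal to
total protein within each lane and expresses lanes relative to a
reference; `protection_percent()` is the defining arithmetic
$100(1 - \text{with}/\text{control})$ for substrate protection, capped at
100 with negative values indicating enhancement.

## 7. The synthetic-data generator

`ground_truth()` holds the true parameters and `simulate_*()` draw the
five dataset types. The defaults *are* the study conditions: the
0.5–8 mM / 1 h labelling grid (an extended 0–18 h time grid is available
for time-course designs); 10 μM cell protein and 100 μM syringe ligand
with 19 × 2 μL injections into a 200 μL cell at 298.15 K; saturation
times 0.5–5 s; and the published specific activities for WT, K244AcK and
K290AcK in both directions. Values the study does not print were fixed
once at field-typical magnitudes and are not tuned: binding enthalpy
−8000 cal/mol with $n = 1$; $K_m$ 0.1 mM (OAA) and 0.5 mM (PEP); replicate
count 1 (exposed as `n_replicates`, since the labelling experiment's
replication is unstated).

Noise models follow typical instrument error structure, each switchable
to zero: multiplicative log-normal (CV `ms_cv`, default 10%) for MS
intensities; additive Gaussian (`itc_sd`, default 0.1 μcal) for injection
heats; additive Gaussian (`std_sd`, default 2%) for STD intensities;
multiplicative Gaussian (CV `rate_cv`, default 5%) for initial rates.

The simulators share their forward models with the fitters
(`predict_heats()` is literally the same code path), which makes
noiseless round-trips exact *by construction*; that is why the test suite
additionally checks the binding model against an independent brute-force
equilibrium solver, and the Michaelis–Menten fitter against the
Eadie–Hofstee linearisation.

What the generator does **not** emulate: raw spectra, chromatographic
peak shapes, retention time, isotope-envelope overlap, baseline drift in
the calorimeter, or spectral processing artefacts. Passing parameter
recovery therefore demonstrates the correctness of the estimators given
correctly integrated upstream signals, not robustness to upstream
processing errors.

## 8. Numerical choices and problem sizes

* All nonlinear fits use Levenberg–Marquardt (`minpack.lm`) with tight
  convergence tolerances (`ftol = ptol = 1e-15`) so that noiseless
  recovery is limited by machine precision, not the optimiser.
* The isotherm fit multi-starts over $K_d \in \{10^{-3} \ldots 10^{-6}\}$ M
  and keeps the lowest residual sum of squares, which removes the local
  minima low-c isotherms otherwise produce.
* Degenerate inputs (all-zero heats, flat build-up curves, zero-rate
  series) short-circuit to flagged results instead of entering the
  optimiser.
* The test suite and examples run at the study's own problem sizes
  (5 concentrations × 5 peptides, 19 injections, 7 protons × 7 saturation
  times, 6 enzyme series × 8 concentrations) plus a 10⁴-draw random sweep
  for the equilibrium-solver equivalence; the whole suite completes in
  well under a minute.

## 9. Known limitations

* Peptide-level occupancy cannot distinguish which lysine in a
  multi-lysine peptide carries the modification.
* The reported ITC uncertainties are asymptotic; for the low-c metal-free
  condition they understate the true parameter fragility.
* The DEEP-STD factor formula is adopted from the cited methodology, not
  from the workflow itself (see §4).
* Mechanistic modelling of the Mn²⁺ enhancement of the acetylation rate
  is out of scope; metal conditions enter only as separate titrations and
  condition labels.
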