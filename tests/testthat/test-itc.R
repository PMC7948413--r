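default_titr <- function(heats = rep(0, 19)) {
  itc_titration(cell_conc = 10e-6, syringe_conc = 100e-6,
                cell_volume = 200e-6, injection_volumes = rep(2e-6, 19),
                heats = heats)
}

test_that("displacement-dilution bookkeeping matches hand evaluation", {
  titr <- default_titr()
  c0 <- concentrations_after_injection(0, titr)
  expect_equal(c0$Mt, 10e-6)
  expect_equal(c0$Xt, 0)
  # cumulative 40 uL into a 200 uL cell: Mt = M0 * 0.9 / 1.1
  titr40 <- itc_titration(10e-6, 100e-6, 200e-6, rep(2e-6, 20),
                          heats = rep(0, 20))
  c20 <- concentrations_after_injection(20, titr40)
  expect_equal(c20$Mt, 10e-6 * 0.9 / 1.1, tolerance = 1e-12)  # 8.1818 uM
  # ligand concentration strictly increases with injections
  Xt <- vapply(1:19, function(i) concentrations_after_injection(i, titr)$Xt,
               numeric(1))
  expect_true(all(diff(Xt) > 0))
  big <- itc_titration(10e-6, 100e-6, 200e-6, rep(300e-6, 2), rep(0, 2))
  expect_error(concentrations_after_injection(2, big), "capacity")
})

test_that("closed-form occupancy equals the brute-force mass-balance root", {
  expect_equal(bound_fraction(10e-6, 0, 1, 1e4), 0)
  # stoichiometric limit: K -> inf, half an equivalent of ligand
  expect_equal(bound_fraction(10e-6, 5e-6, 1, 1e15), 0.5, tolerance = 1e-6)
  # recorded oracle value at the study concentrations, Kd = 110 uM
  theta_oracle <- oracle_bound_fraction(10e-6, 10e-6, 1, 1 / 110e-6)
  expect_lt(abs(bound_fraction(10e-6, 10e-6, 1, 1 / 110e-6) - theta_oracle),
            1e-10)
  # random sweep over the physically plausible parameter space
  set.seed(20)
  for (i in 1:300) {
    Mt <- 10^runif(1, -6, -4); Xt <- 10^runif(1, -7, -3)
    n <- runif(1, 0.3, 2); K <- 10^runif(1, 2, 8)
    expect_lt(abs(bound_fraction(Mt, Xt, n, K) -
                    oracle_bound_fraction(Mt, Xt, n, K)), 1e-10)
  }
})

test_that("predicted heats behave at the physical limits", {
  titr <- default_titr()
  expect_true(all(predict_heats(list(n = 1, K = 1e4, dH = 0), titr) == 0))
  # one huge injection at K -> inf releases the full site enthalpy
  one <- itc_titration(10e-6, 10e-3, 200e-6, 100e-6, heats = 0)
  q <- predict_heats(list(n = 1, K = 1e15, dH = -8000), one)
  expect_equal(sum(q), 1 * 10e-6 * 200e-6 * -8000, tolerance = 1e-3)
})

test_that("isotherm fits recover the three metal-condition dissociation constants", {
  for (kd_uM in c(110, 0.9, 13)) {
    truth <- noiseless_truth()
    truth$itc_params$Kd <- kd_uM * 1e-6
    fit <- suppressWarnings(fit_isotherm(simulate_itc(truth)))
    expect_equal(M_to_uM(fit$Kd), kd_uM, tolerance = 1e-3)
    expect_equal(fit$n, 1, tolerance = 1e-3)
    expect_equal(fit$dH, -8000, tolerance = 1e-3)
    # thermodynamic identities
    expect_equal(fit$Kd, 1 / fit$K, tolerance = 1e-12)
    expect_equal(fit$dG, fit$dH - fit$TdS, tolerance = 1e-9 * abs(fit$dG))
    expect_equal(fit$dG, -1.98720425 * 298.15 * log(fit$K),
                 tolerance = 1e-9 * abs(fit$dG))
  }
})

test_that("the low-c titration warns and the sigmoidal one has an inflection near n", {
  truth <- noiseless_truth()
  expect_warning(fit_isotherm(simulate_itc(truth)), "c-value")
  # at Kd = 0.9 uM (c ~ 11) the isotherm is sigmoidal: steepest heat change
  # near molar ratio Xt/Mt = n = 1
  truth$itc_params$Kd <- 0.9e-6
  titr <- simulate_itc(truth)
  ratio <- vapply(seq_along(titr$heats), function(i) {
    cc <- concentrations_after_injection(i, titr); cc$Xt / cc$Mt
  }, numeric(1))
  steepest <- which.max(abs(diff(titr$heats)))
  expect_lt(abs(ratio[steepest] - 1), 0.35)
})

test_that("fit is scale consistent between cal and ucal heat units", {
  truth <- noiseless_truth()
  truth$itc_params$Kd <- 13e-6
  titr <- simulate_itc(truth)
  fit_cal <- fit_isotherm(titr)
  titr_u <- titr
  titr_u$heats <- titr$heats * 1e6
  fit_ucal <- fit_isotherm(titr_u)
  expect_equal(fit_ucal$dH, fit_cal$dH * 1e6, tolerance = 1e-6)
  expect_equal(fit_ucal$Kd, fit_cal$Kd, tolerance = 1e-6)
  expect_equal(fit_ucal$n, fit_cal$n, tolerance = 1e-6)
})

test_that("degenerate and short titrations are rejected or flagged", {
  zero <- default_titr()
  expect_warning(f <- fit_isotherm(zero), "unidentifiable")
  expect_true(f$degenerate)
  expect_equal(f$dH, 0)
  short <- itc_titration(10e-6, 100e-6, 200e-6, rep(2e-6, 5), rep(1e-6, 5))
  expect_error(fit_isotherm(short), "at least 6")
  expect_error(itc_titration(10e-6, 100e-6, 200e-6, rep(2e-6, 3), rep(0, 2)),
               "equal length")
})

test_that("Kd recovery tolerates 1% heat noise within 15% (seeded)", {
  for (kd_uM in c(0.9, 13)) {
    truth <- ground_truth(seed = 55L)
    truth$itc_params$Kd <- kd_uM * 1e-6
    clean <- simulate_itc(ground_truth(
      seed = 55L, noise = noise_free(),
      itc_params = truth$itc_params))
    truth$noise$itc_sd <- 0.01 * max(abs(clean$heats))
    fit <- suppressWarnings(fit_isotherm(simulate_itc(truth)))
    expect_lt(abs(M_to_uM(fit$Kd) - kd_uM) / kd_uM, 0.15)
  }
})

test_that("titrations survive the CSV round trip with header block intact", {
  truth <- noiseless_truth()
  titr <- simulate_itc(truth, label = "0.1 mM Mn2+")
  path <- withr::local_tempfile(fileext = ".csv")
  write_itc_csv(titr, path)
  back <- read_itc_csv(path)
  expect_equal(back$heats, titr$heats, tolerance = 1e-9)
  expect_equal(back$cell_conc, titr$cell_conc, tolerance = 1e-12)
  expect_identical(back$label, titr$label)
  fit <- suppressWarnings(fit_isotherm(back))
  expect_equal(M_to_uM(fit$Kd), 110, tolerance = 1e-3)
})
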