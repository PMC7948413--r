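test_that("build-up fits recover the generating exponential exactly", {
  t <- c(0.5, 1, 1.5, 2, 3, 4, 5)
  f <- fit_buildup(t, 2.0 * (1 - exp(-0.5 * t)))
  expect_equal(f$STD_max, 2.0, tolerance = 1e-9)
  expect_equal(f$k_sat, 0.5, tolerance = 1e-9)
  expect_equal(f$STD0, 1.0, tolerance = 1e-9)
  # residuals of the fitted model vanish on exact data
  resid <- 2.0 * (1 - exp(-0.5 * t)) - f$STD_max * (1 - exp(-f$k_sat * t))
  expect_true(all(abs(resid) < 1e-10))
})

test_that("flat or empty curves are flagged not measurable", {
  t <- c(0.5, 1, 2, 4)
  expect_false(fit_buildup(t, rep(0, 4))$measurable)
  expect_false(fit_buildup(t, rep(0.3, 4))$measurable)
  expect_error(fit_buildup(c(0.5, 1, 2), c(0, 1, 2)), "at least 4")
  expect_error(fit_buildup(c(1, 0.5, 2, 4), rep(1, 4)), "increasing")
})

test_that("epitope normalization puts the strongest proton at exactly 100%", {
  truth <- noiseless_truth()
  emap <- epitope_map(simulate_std_buildup(truth))
  expect_equal(max(emap$normalized_STD0), 100)
  expect_equal(sum(emap$normalized_STD0 == 100), 1)
  # adenosine protons dominate the synthetic epitope by construction
  expect_identical(emap$proton_id[1], "A")
  expect_true(all(emap$normalized_STD0 >= 0))
  # normalization is idempotent
  emap2 <- emap
  emap2$normalized_STD0 <- 100 * emap2$STD0 / max(emap2$STD0)
  expect_equal(emap2$normalized_STD0, emap$normalized_STD0)
  # single measurable proton maps to 100%
  single <- simulate_std_buildup(truth,
                                 std_params = data.frame(proton_id = "A",
                                                         STD_max = 0.5,
                                                         k_sat = 0.4))
  expect_equal(epitope_map(single)$normalized_STD0, 100)
})

test_that("STD0 is invariant under consistent time-unit rescaling", {
  t <- c(0.5, 1, 1.5, 2, 3, 4, 5)
  y <- 1.5 * (1 - exp(-0.6 * t))
  f_s <- fit_buildup(t, y)
  f_ms <- fit_buildup(t * 1000, y)  # times in ms
  expect_equal(f_ms$k_sat * 1000, f_s$k_sat, tolerance = 1e-6)
  expect_equal(f_ms$STD_max, f_s$STD_max, tolerance = 1e-6)
  expect_equal(f_ms$STD0 * 1000, f_s$STD0, tolerance = 1e-6)
})

test_that("DEEP-STD factors vanish for identical and globally scaled maps", {
  truth <- noiseless_truth()
  m1 <- epitope_map(simulate_std_buildup(truth, irradiation = "aliphatic"))
  expect_true(all(abs(deep_std_factors(m1, m1)$deep_std_factor) < 1e-12))
  m2 <- m1
  m2$STD0 <- m2$STD0 * 2  # global doubling cancels in the mean reference
  expect_true(all(abs(deep_std_factors(m1, m2)$deep_std_factor) < 1e-12))
})

test_that("two-proton DEEP-STD factors match direct arithmetic", {
  mk <- function(std0) data.frame(proton_id = c("A", "B"), STD0 = std0,
                                  measurable = TRUE)
  f <- deep_std_factors(mk(c(0.8, 0.4)), mk(c(0.5, 0.5)))
  # hand: 0.8/0.6 - 0.5/0.5 = 1/3 ; 0.4/0.6 - 1 = -1/3
  expect_equal(f$deep_std_factor[f$proton_id == "A"], 1 / 3, tolerance = 1e-12)
  expect_equal(f$deep_std_factor[f$proton_id == "B"], -1 / 3, tolerance = 1e-12)
  disjoint <- data.frame(proton_id = "C", STD0 = 1, measurable = TRUE)
  expect_error(deep_std_factors(mk(c(1, 1)), disjoint), "common")
})

test_that("ligand comparison reports rank correlation and per-proton deltas", {
  truth <- noiseless_truth()
  acoa <- epitope_map(simulate_std_buildup(truth, ligand = "acetyl-CoA"))
  expect_equal(compare_ligands(acoa, acoa)$rank_correlation, 1)
  rev_params <- truth$std_params
  rev_params$STD_max <- rev(rev_params$STD_max)
  rev_params$k_sat <- rev(rev_params$k_sat)
  coa <- epitope_map(simulate_std_buildup(truth, ligand = "CoA",
                                          std_params = rev_params))
  expect_equal(compare_ligands(acoa, coa)$rank_correlation, -1)
  # swapping one pair of protons: hand-computed Spearman on 3 protons
  m3 <- function(std0) {
    d <- data.frame(proton_id = c("A", "B", "C"), STD0 = std0,
                    measurable = TRUE)
    d$normalized_STD0 <- 100 * d$STD0 / max(d$STD0)
    d
  }
  cmp <- compare_ligands(m3(c(3, 2, 1)), m3(c(2, 3, 1)))
  expect_equal(cmp$rank_correlation, cor(c(3, 2, 1), c(2, 3, 1),
                                         method = "spearman"))
  expect_equal(cmp$n_common, 3)
})

test_that("k_sat recovery under 2% noise stays within 10% (seeded)", {
  truth <- ground_truth(noise = list(ms_cv = 0, itc_sd = 0, std_sd = 0.02,
                                     rate_cv = 0), seed = 77L)
  curves <- do.call(rbind, lapply(1:10, function(i) {
    truth$seed <- 77L + i
    cbind(simulate_std_buildup(truth), run = i)
  }))
  # protons whose early-time signal clears the noise floor are the ones
  # an experimentalist would call accurately measurable; the weakest
  # synthetic proton (STD_max 0.30) sits below it at 2% absolute noise
  pars <- truth$std_params
  measurable <- pars$proton_id[pars$STD_max >= 0.4]
  expect_gte(length(measurable), 5)
  for (p in measurable) {
    d <- curves[curves$proton_id == p, ]
    ks <- vapply(split(d, d$run), function(dd) {
      fit_buildup(dd$t_sat_s, pmax(dd$std_intensity, 0))$k_sat
    }, numeric(1))
    k_true <- pars$k_sat[pars$proton_id == p]
    expect_lt(abs(mean(ks, na.rm = TRUE) - k_true) / k_true, 0.10)
  }
})
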