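test_that("zero-noise generation reproduces the model surface exactly", {
  d <- fixture_drugs()
  truth <- interaction_model(
    list(d$a, d$b), gpdi_term("B", "A", "EC50", int = 2, ec50_int = 0.5), "bliss")
  des <- checkerboard_design("log2")
  dat <- generate_checkerboard(truth, des, sigma = 0, seed = 3)
  expect_equal(dat$wells$effect_obs,
               as.numeric(combined_effect(truth, list(A = dat$wells$conc_a,
                                                      B = dat$wells$conc_b))))
  expect_equal(dat$n_truncated, 0L)
})

test_that("generation is bit-identical under the same seed", {
  d <- fixture_drugs()
  truth <- interaction_model(list(d$a, d$b), list(), "bliss")
  des <- checkerboard_design("log2")
  d1 <- generate_checkerboard(truth, des, sigma = 0.03, seed = 42)
  d2 <- generate_checkerboard(truth, des, sigma = 0.03, seed = 42)
  expect_identical(d1$wells, d2$wells)
  d3 <- generate_checkerboard(truth, des, sigma = 0.03, seed = 43)
  expect_false(identical(d1$wells$effect_obs, d3$wells$effect_obs))
  # time-course mode is reproducible too
  gp <- growth_params()
  t1 <- generate_checkerboard(truth, checkerboard_design(tiers_a = c(0, 1, 2),
                                                         tiers_b = c(0, 1, 2)),
                              sigma = 0.02, seed = 7, mode = "timecourse",
                              growth = gp, times = seq(0, 24, 6))
  t2 <- generate_checkerboard(truth, checkerboard_design(tiers_a = c(0, 1, 2),
                                                         tiers_b = c(0, 1, 2)),
                              sigma = 0.02, seed = 7, mode = "timecourse",
                              growth = gp, times = seq(0, 24, 6))
  expect_identical(t1$timecourses, t2$timecourses)
})

test_that("residual spread matches the requested noise level", {
  d <- fixture_drugs()
  truth <- interaction_model(list(d$a, d$b), list(), "bliss")
  dat <- generate_checkerboard(truth, checkerboard_design("log2"),
                               sigma = 0.03, seed = 9)
  res <- dat$wells$effect_obs - dat$wells$effect_true
  res <- res[dat$wells$effect_obs > 0]  # exclude truncated zeros
  # chi-square bounds on a sample SD at n = 64: [0.02, 0.04] comfortably
  expect_gt(sd(res), 0.02)
  expect_lt(sd(res), 0.04)
})

test_that("sham datasets obey Loewe self-additivity at zero noise", {
  drug <- pd_drug("X", emax = 1, ec50 = 2, hill = 2)
  des <- checkerboard_design("log2")
  dat <- generate_sham(drug, des, sigma = 0, seed = 5)
  expect_equal(dat$drug_ids, c("X.1", "X.2"))
  w <- dat$wells
  # combined well (c, c) equals monotherapy at 2c
  for (cc in c(0.5, 1, 2)) {
    e_comb <- w$effect_obs[w$conc_a == cc & w$conc_b == cc]
    e_mono <- w$effect_obs[w$conc_a == 2 * cc & w$conc_b == 0]
    expect_equal(e_comb, e_mono, tolerance = 1e-9)
  }
  # fitting the sham under Loewe recovers a near-zero interaction
  set.seed(71)
  fit <- fit_gpdi_stepwise(dat, "loewe")
  terms <- fitted_terms(fit, dat)
  perp <- pd_drug("X.2", emax = 1, ec50 = fit$estimates[["ec50_b"]], hill = fit$estimates[["h_b"]])
  fs <- fractional_shift(terms$ab, perp)
  expect_lt(abs(fs$shift_at_ec50), 0.02)
})

test_that("Bliss fits of sham data drift towards apparent self-synergy", {
  drug <- pd_drug("X", emax = 1, ec50 = 2, hill = 2)
  des <- checkerboard_design("log2")
  set.seed(72)
  shifts <- vapply(1:8, function(i) {
    dat <- generate_sham(drug, des, sigma = 0.03, seed = 100 + i)
    fit <- fit_gpdi_stepwise(dat, "bliss",
                             config = stepwise_config(n_starts = 2))
    terms <- fitted_terms(fit, dat)
    perp <- pd_drug("p", emax = 1, ec50 = fit$estimates[["ec50_b"]],
                    hill = fit$estimates[["h_b"]])
    fractional_shift(terms$ab, perp)$shift_at_ec50
  }, 0)
  expect_lt(median(shifts), 0)
})

test_that("datasets round-trip through the CSV interchange format", {
  d <- fixture_drugs()
  truth <- interaction_model(list(d$a, d$b), list(), "bliss")
  des <- checkerboard_design("log2")
  dat <- generate_checkerboard(truth, des, sigma = 0.03, seed = 15)
  path <- withr::local_tempfile(fileext = ".csv")
  write_checkerboard(dat, path)
  back <- read_checkerboard(path)
  expect_equal(back$mode, "endpoint")
  expect_equal(back$drug_ids, c("A", "B"))
  expect_equal(back$wells$effect_obs, dat$wells$effect_obs)
  expect_equal(back$design$tiers_a, des$tiers_a)
  # a fit on the re-read data reproduces the original fit
  set.seed(73)
  f1 <- fit_single_drugs(dat)
  set.seed(73)
  f2 <- fit_single_drugs(back)
  expect_equal(f1$estimates, f2$estimates, tolerance = 1e-6)
})

test_that("the full pipeline replays exactly from the recorded seed", {
  d <- fixture_drugs()
  truth <- interaction_model(
    list(d$a, d$b), gpdi_term("B", "A", "EC50", int = 3, ec50_int = 0.5), "bliss")
  run <- function() {
    dat <- generate_checkerboard(truth, checkerboard_design("log2"),
                                 sigma = 0.03, seed = 21)
    set.seed(22)
    fit <- fit_gpdi_stepwise(dat, "bliss", config = stepwise_config(n_starts = 2))
    terms <- fitted_terms(fit, dat)
    perp <- pd_drug("B", emax = 1, ec50 = fit$estimates[["ec50_b"]],
                    hill = fit$estimates[["h_b"]])
    classify_pair(fractional_shift(terms$ab, perp)$shift_at_ec50,
                  0, additivity_margin())$class
  }
  expect_identical(run(), run())
})
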