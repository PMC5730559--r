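test_that("the objective function is the Gaussian -2 log-likelihood", {
  set.seed(41)
  obs <- runif(30); pred <- obs + rnorm(30, 0, 0.05)
  direct <- -2 * sum(dnorm(obs, pred, 0.05, log = TRUE))
  expect_equal(gaussian_ofv(obs, pred, 0.05)$ofv, direct, tolerance = 1e-8)
  # profiled sigma equals the ML residual SD
  prof <- gaussian_ofv(obs, pred)
  expect_equal(prof$sigma, sqrt(mean((obs - pred)^2)))
  expect_equal(prof$ofv, -2 * sum(dnorm(obs, pred, prof$sigma, log = TRUE)),
               tolerance = 1e-8)
})

test_that("the optimized endpoint surface equals the model-object path", {
  des <- checkerboard_design("log2")
  w <- gpdi:::design_wells(des)
  p <- gpdi:::full_param_vector(c(ec50_a = 1, h_a = 2, ec50_b = 2, h_b = 3,
                                  int_ab = 3, int_ba = -0.7,
                                  ec50_int_ab = 0.5, ec50_int_ba = 1.2))
  for (crit in c("bliss", "loewe")) {
    m <- gpdi:::params_to_model(p, c("A", "B"), crit)
    expect_equal(gpdi:::endpoint_surface(p, w$conc_a, w$conc_b, crit),
                 as.numeric(combined_effect(m, list(A = w$conc_a, B = w$conc_b))),
                 tolerance = 1e-10, info = crit)
  }
})

test_that("noise-free monotherapy data recover the generating parameters", {
  d <- fixture_drugs()
  des <- checkerboard_design("log2")
  truth <- interaction_model(list(d$a, d$b), list(), "bliss")
  dat <- generate_checkerboard(truth, des, sigma = 0, seed = 1)
  set.seed(42)
  fit <- fit_single_drugs(dat)
  expect_true(fit$converged)
  expect_equal(unname(fit$estimates["ec50_a"]), 1, tolerance = 1e-4)
  expect_equal(unname(fit$estimates["h_a"]), 2, tolerance = 1e-4)
  expect_equal(unname(fit$estimates["ec50_b"]), 2, tolerance = 1e-4)
  expect_equal(unname(fit$estimates["h_b"]), 3, tolerance = 1e-4)
})

test_that("monotherapy fitting requires enough distinct concentrations", {
  d <- fixture_drugs()
  des <- checkerboard_design(tiers_a = c(0, 1, 2), tiers_b = c(0, 1, 2, 4, 8))
  truth <- interaction_model(list(d$a, d$b), list(), "bliss")
  dat <- generate_checkerboard(truth, des, sigma = 0, seed = 1)
  expect_error(fit_single_drugs(dat), "drug A")
  # combination-only data: no monotherapy wells at all
  dat2 <- generate_checkerboard(truth, checkerboard_design("log2"), sigma = 0,
                                seed = 1)
  dat2$wells <- dat2$wells[dat2$wells$conc_a > 0 & dat2$wells$conc_b > 0, ]
  expect_error(fit_single_drugs(dat2), "monotherapy")
})

test_that("stepwise building recovers an asymmetric interaction exactly at zero noise", {
  d <- fixture_drugs()
  truth <- interaction_model(
    list(d$a, d$b),
    gpdi_term("B", "A", "EC50", int = 3, ec50_int = 0.5), "bliss")
  dat <- generate_checkerboard(truth, checkerboard_design("log2"), sigma = 0,
                               seed = 7)
  set.seed(43)
  fit <- fit_gpdi_stepwise(dat, "bliss")
  expect_true(fit$converged)
  expect_true("int_ab" %in% names(fit$estimates))  # directional split retained
  expect_equal(unname(fit$estimates["int_ab"]), 3, tolerance = 1e-3)
  expect_equal(unname(fit$estimates["ec50_int_ab"]), 0.5, tolerance = 1e-3)
  if ("int_ba" %in% names(fit$estimates))
    expect_lt(abs(fit$estimates[["int_ba"]]), 0.05)
  # nesting: every accepted expansion lowered the objective
  h <- fit$history
  expect_true(all(h$delta_ofv[h$accepted & h$step == "2"] >= 0, na.rm = TRUE))
})

test_that("stepwise stays at the reduced model on null-interaction data", {
  d <- fixture_drugs()
  truth <- interaction_model(list(d$a, d$b), list(), "bliss")
  dat <- generate_checkerboard(truth, checkerboard_design("log2"),
                               sigma = 0.03, seed = 11)
  set.seed(44)
  fit <- fit_gpdi_stepwise(dat, "bliss")
  # whatever structure the LRT retains on null data, the implied shifts must
  # stay inside the additivity margin (no false interaction call)
  terms <- fitted_terms(fit, dat)
  perp_b <- pd_drug("B", emax = 1, ec50 = fit$estimates[["ec50_b"]],
                    hill = fit$estimates[["h_b"]])
  perp_a <- pd_drug("A", emax = 1, ec50 = fit$estimates[["ec50_a"]],
                    hill = fit$estimates[["h_a"]])
  cl <- classify_pair(fractional_shift(terms$ab, perp_b)$shift_at_ec50,
                      fractional_shift(terms$ba, perp_a)$shift_at_ec50)
  expect_equal(cl$class, "additive")
})

test_that("interaction parameters carry usable standard errors after step 4", {
  d <- fixture_drugs()
  truth <- interaction_model(
    list(d$a, d$b),
    gpdi_term("B", "A", "EC50", int = 3, ec50_int = 0.5), "bliss")
  dat <- generate_checkerboard(truth, checkerboard_design("log2"),
                               sigma = 0.03, seed = 13)
  set.seed(45)
  fit <- fit_gpdi_stepwise(dat, "bliss")
  expect_false(is.null(fit$se))
  sig <- intersect(names(fit$estimates), c("int_ab", "int"))
  expect_true(all(is.finite(fit$se[sig])))
  tab <- fit_parameter_table(fit)
  expect_true(all(c("parameter", "estimate", "se", "rse_pct", "fixed") %in%
                  names(tab)))
})

test_that("profiled sigma is consistent with the generating noise", {
  d <- fixture_drugs()
  truth <- interaction_model(list(d$a, d$b), list(), "bliss")
  des <- checkerboard_design("log2", n_tiers = 16)
  dat <- generate_checkerboard(truth, des, sigma = 0.03, seed = 17)
  set.seed(46)
  fit <- fit_single_drugs(dat)
  expect_equal(fit$sigma, 0.03, tolerance = 0.1)
})

test_that("AIC ranking penalizes parameters and validates comparability", {
  mk <- function(ofv, k, n = 64)
    gpdi:::new_fit_result(stats::setNames(rep(1, k), paste0("p", seq_len(k))),
                          fixed = numeric(), ofv = ofv, n_obs = n, sigma = 0.03,
                          sigma_estimated = FALSE, label = paste0("m", k))
  cmp <- compare_models(list(mk(-100, 3), mk(-100, 4)))
  expect_equal(cmp$model[1], "m3")
  expect_equal(cmp$delta_aic[2], 2)
  tie <- compare_models(list(first = mk(-100, 3), second = mk(-100, 3)))
  expect_equal(tie$model, c("first", "second"))  # stable input order on ties
  expect_error(compare_models(list(mk(-100, 3), mk(-100, 3, n = 32))),
               "identical data")
})

test_that("comparator fits recover their interaction indices at zero noise", {
  da <- pd_drug("A", emax = 1, ec50 = 1, hill = 2)
  db <- pd_drug("B", emax = 1, ec50 = 2, hill = 1.5)
  des <- checkerboard_design("log2")
  w <- gpdi:::design_wells(des)
  # Greco truth with alpha = 2
  surf <- as.numeric(greco_effect(da, db, 2, w$conc_a, w$conc_b))
  dat <- make_endpoint_dataset(des, surf)
  set.seed(47)
  fit <- fit_conventional(dat, "greco")
  expect_equal(unname(fit$estimates["alpha"]), 2, tolerance = 1e-3)
  # empiric Bliss truth with beta = 1.8
  surf2 <- as.numeric(empiric_bliss_effect(da, db, 1.8, w$conc_a, w$conc_b))
  dat2 <- make_endpoint_dataset(des, surf2)
  set.seed(48)
  fit2 <- fit_conventional(dat2, "empiric_bliss")
  expect_equal(unname(fit2$estimates["beta"]), 1.8, tolerance = 1e-3)
  # the GPDI model out-ranks Greco on asymmetric GPDI-generated data
  truth <- interaction_model(
    list(da, db), gpdi_term("B", "A", "EC50", int = 5, ec50_int = 0.3), "bliss")
  dat3 <- generate_checkerboard(truth, des, sigma = 0.03, seed = 19)
  set.seed(49)
  sf <- fit_single_drugs(dat3)
  gfit <- fit_gpdi_stepwise(dat3, "bliss", single_fit = sf)
  cfit <- fit_conventional(dat3, "greco", single_fit = sf)
  cmp <- compare_models(list(gpdi = gfit, greco = cfit))
  expect_equal(cmp$model[1], "gpdi")
})
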