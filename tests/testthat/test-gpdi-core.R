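test_that("interaction shift factor evaluates the saturable term", {
  tm0 <- gpdi_term("B", "A", "EC50", int = 0, ec50_int = 5)
  expect_equal(gpdi_shift(tm0, c(0, 1, 100)), rep(1, 3))
  tm <- gpdi_term("B", "A", "EC50", int = 2, ec50_int = 10, h_int = 1)
  expect_equal(gpdi_shift(tm, 10), 2)          # half-maximal interaction
  expect_equal(gpdi_shift(tm, 0), 1)
  tm2 <- gpdi_term("B", "A", "EC50", int = 3.32, ec50_int = 1, h_int = 1)
  expect_equal(gpdi_shift(tm2, 1e12), 4.32, tolerance = 1e-9)  # saturation
  expect_error(gpdi_term("B", "A", "EC50", int = -1.5, ec50_int = 1), ">= -1")
  expect_error(gpdi_term("B", "A", "EC50", int = 1, ec50_int = 0), "ec50_int")
})

test_that("perturbed effect shifts the victim EC50 before exponentiation", {
  d <- fixture_drugs()
  # saturated INT = 1 doubles EC50_A; at C_A = 2 * EC50_A the effect is half-maximal
  m <- interaction_model(
    list(pd_drug("A", emax = 1, ec50 = 1, hill = 1), d$b),
    gpdi_term("B", "A", "EC50", int = 1, ec50_int = 0.001, h_int = 4))
  expect_equal(perturbed_effect(m, "A", list(A = 2, B = 1e6)), 0.5,
               tolerance = 1e-9)
  # with H_A > 1 the factor must sit inside the power: (EC50 * f)^H
  m2 <- interaction_model(
    list(pd_drug("A", emax = 1, ec50 = 1, hill = 3), d$b),
    gpdi_term("B", "A", "EC50", int = 1, ec50_int = 0.001, h_int = 4))
  ca <- 1.7
  expect_equal(perturbed_effect(m2, "A", list(A = ca, B = 1e6)),
               ca^3 / ((1 * 2)^3 + ca^3), tolerance = 1e-9)
  # no terms: reduces to the single-drug model
  m0 <- interaction_model(list(d$a, d$b), list(), "bliss")
  cc <- c(0, 0.5, 1, 4)
  expect_identical(perturbed_effect(m0, "A", list(A = cc, B = 8)),
                   pd_effect(d$a, cc))
})

test_that("Emax-target terms suppress the victim effect in the limit", {
  d <- fixture_drugs()
  m <- interaction_model(
    list(d$a, d$b),
    gpdi_term("B", "A", "Emax", int = -1, ec50_int = 0.01))
  expect_equal(perturbed_effect(m, "A", list(A = 10, B = 1e8)), 0,
               tolerance = 1e-7)
})

test_that("null interaction reduces exactly to single-drug effects", {
  d <- fixture_drugs()
  m <- interaction_model(
    list(d$a, d$b),
    list(gpdi_term("B", "A", "EC50", int = 0, ec50_int = 1),
         gpdi_term("A", "B", "EC50", int = 0, ec50_int = 1)), "bliss")
  grid <- expand.grid(a = c(0, 2^(-3:3)), b = c(0, 2^(-3:3)))
  expect_identical(perturbed_effect(m, "A", list(A = grid$a, B = grid$b)),
                   pd_effect(d$a, grid$a))
  expect_identical(perturbed_effect(m, "B", list(A = grid$a, B = grid$b)),
                   pd_effect(d$b, grid$b))
})

test_that("INT polarity on EC50 moves the whole surface as synergy/antagonism", {
  d <- fixture_drugs()
  grid <- expand.grid(a = seq(0, 8, length.out = 20),
                      b = seq(0, 8, length.out = 20))
  cm <- list(A = grid$a, B = grid$b)
  null <- interaction_model(list(d$a, d$b), list(), "bliss")
  e0 <- combined_effect(null, cm)
  mk <- function(int) interaction_model(
    list(d$a, d$b),
    list(gpdi_term("B", "A", "EC50", int = int, ec50_int = 0.5),
         gpdi_term("A", "B", "EC50", int = int, ec50_int = 0.5)), "bliss")
  expect_true(all(combined_effect(mk(-0.8), cm) >= e0 - 1e-12))  # synergy
  expect_true(all(combined_effect(mk(5), cm) <= e0 + 1e-12))     # antagonism
})

test_that("equal-sign INT on Emax moves the surface the opposite way", {
  d <- fixture_drugs()
  grid <- expand.grid(a = seq(0.5, 8, length.out = 10),
                      b = seq(0.5, 8, length.out = 10))
  cm <- list(A = grid$a, B = grid$b)
  on_ec50 <- interaction_model(
    list(d$a, d$b), gpdi_term("B", "A", "EC50", int = 2, ec50_int = 0.5))
  on_emax <- interaction_model(
    list(d$a, d$b), gpdi_term("B", "A", "Emax", int = 2, ec50_int = 0.5))
  base <- pd_effect(d$a, grid$a)
  expect_true(all(perturbed_effect(on_ec50, "A", cm) < base))
  expect_true(all(perturbed_effect(on_emax, "A", cm) > base))
})

test_that("multiple perpetrators compose as a product on the victim EC50", {
  drugs <- list(pd_drug("A", emax = 1, ec50 = 1, hill = 2),
                pd_drug("B", emax = 1, ec50 = 2, hill = 1),
                pd_drug("C", emax = 1, ec50 = 3, hill = 1))
  t1 <- gpdi_term("B", "A", "EC50", int = 1.5, ec50_int = 0.7)
  t2 <- gpdi_term("C", "A", "EC50", int = -0.6, ec50_int = 1.3)
  m <- interaction_model(drugs, list(t1, t2))
  cb <- 1.1; cc <- 2.3; ca <- 0.9
  f <- gpdi_shift(t1, cb) * gpdi_shift(t2, cc)
  expect_equal(perturbed_effect(m, "A", list(A = ca, B = cb, C = cc)),
               ca^2 / ((1 * f)^2 + ca^2), tolerance = 1e-12)
})

test_that("modulation terms rescale INT and vanish at zero modulator dose", {
  drugs <- list(pd_drug("A", emax = 1, ec50 = 1, hill = 2),
                pd_drug("B", emax = 1, ec50 = 2, hill = 1),
                pd_drug("C", emax = 1, ec50 = 3, hill = 1))
  pair_ab <- gpdi_term("B", "A", "EC50", int = 2, ec50_int = 0.7)
  mod <- gpdi_term("C", "A", "INT", int = -1, ec50_int = 1,
                   modulates = c("A", "B"))
  m <- interaction_model(drugs, list(pair_ab, mod))
  pairwise <- interaction_model(drugs, list(pair_ab))
  cm0 <- list(A = c(0.4, 1, 2.5), B = c(0.8, 1.6, 3), C = 0)
  expect_equal(modulated_effect(m, "A", cm0),
               perturbed_effect(pairwise, "A", cm0))
  # INT_AB|C = -1 at saturating modulator abolishes the interaction
  cm_inf <- list(A = c(0.4, 1, 2.5), B = c(0.8, 1.6, 3), C = 1e9)
  expect_equal(modulated_effect(m, "A", cm_inf),
               pd_effect(drugs[[1]], cm_inf$A), tolerance = 1e-8)
})

test_that("nested modulation reproduces hand-substituted factors", {
  drugs <- list(pd_drug("A", emax = 1, ec50 = 1, hill = 1),
                pd_drug("B", emax = 1, ec50 = 2, hill = 1),
                pd_drug("C", emax = 1, ec50 = 3, hill = 1))
  pair_ab <- gpdi_term("B", "A", "EC50", int = 1, ec50_int = 0.5)
  mod <- gpdi_term("C", "A", "INT", int = 1, ec50_int = 5,
                   modulates = c("A", "B"))
  m <- interaction_model(drugs, list(pair_ab, mod))
  # C_C = 5 gives modulation factor 1.5, effective INT_AB = 1.5; saturating
  # C_B then yields an EC50 factor of 1 + 1.5 = 2.5
  ca <- 1.3
  expect_equal(modulated_effect(m, "A", list(A = ca, B = 1e9, C = 5)),
               ca / (1 * 2.5 + ca), tolerance = 1e-8)
  expect_error(
    interaction_model(drugs, list(gpdi_term("C", "A", "INT", int = 1,
                                            ec50_int = 1,
                                            modulates = c("A", "Z")))),
    "non-existent")
})

test_that("slope-model placement divides or multiplies by the shift factor", {
  s <- pd_drug("S", form = "slope", slope = 0.1)
  perp <- gpdi_term("B", "S", "EC50", int = 1, ec50_int = 0.001, h_int = 4)
  cm <- list(S = 5, B = 1e6)  # saturated factor 2
  num <- slope_model_shift(s, perp, "numerator", cm)
  den <- slope_model_shift(s, perp, "denominator", cm)
  expect_equal(as.numeric(num), 1.0, tolerance = 1e-9)
  expect_equal(as.numeric(den), 0.25, tolerance = 1e-9)
  expect_match(attr(den, "interpretation"), "EC50")
  expect_match(attr(num, "interpretation"), "Emax")
  none <- gpdi_term("B", "S", "EC50", int = 0, ec50_int = 1)
  expect_equal(as.numeric(slope_model_shift(s, none, "denominator", cm)), 0.5)
  expect_error(slope_model_shift(fixture_drugs()$a, perp, "numerator", cm),
               "sigmoid_emax")
})

test_that("Loewe criterion rejects Emax-level terms", {
  d <- fixture_drugs()
  expect_error(
    interaction_model(list(d$a, d$b),
                      gpdi_term("B", "A", "Emax", int = 1, ec50_int = 1),
                      criterion = "loewe"),
    "competitive")
})

test_that("model specifications round-trip through YAML", {
  d <- fixture_drugs()
  m <- interaction_model(
    list(d$a, d$b),
    list(gpdi_term("B", "A", "EC50", int = 3.3, ec50_int = 0.4, h_int = 2),
         gpdi_term("A", "B", "EC50", int = -0.7, ec50_int = 1.1)),
    criterion = "loewe")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_spec(m, path)
  back <- read_model_spec(path)
  expect_equal(back$criterion, "loewe")
  expect_equal(names(back$terms), names(m$terms))
  grid <- list(A = c(0.3, 1, 2), B = c(0.1, 0.8, 3))
  expect_equal(combined_effect(back, grid), combined_effect(m, grid))
})
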