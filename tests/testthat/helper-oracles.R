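# Independent oracles and fixture builders used across the suite.

# Plain bisection solver for the implicit Loewe dose-substitution equation,
# written directly from the equation (no shared code with combine_loewe).
bisect_loewe <- function(ca, cb, ec50_a, ec50_b, h_a, h_b,
                         emax_a = 1, emax_b = 1, iters = 80) {
  lhs <- function(e) {
    ca / (ec50_a * (e / (emax_a - e))^(1 / h_a)) +
      cb / (ec50_b * (e / (emax_b - e))^(1 / h_b))
  }
  lo <- 1e-12; hi <- min(emax_a, emax_b) * (1 - 1e-12)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (lhs(mid) > 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Bisection solver for the Greco response-surface equation.
bisect_greco <- function(ca, cb, alpha, ec50_a, ec50_b, h_a, h_b,
                         emax_a = 1, emax_b = 1, iters = 80) {
  emax <- min(emax_a, emax_b)
  lhs <- function(e) {
    ca / (ec50_a * (e / (emax_a - e))^(1 / h_a)) +
      cb / (ec50_b * (e / (emax_b - e))^(1 / h_b)) +
      alpha * ca * cb / (ec50_a * ec50_b *
        (e / (emax - e))^(1 / (2 * h_a) + 1 / (2 * h_b)))
  }
  lo <- 1e-12; hi <- emax * (1 - 1e-12)
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (lhs(mid) > 1) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Endpoint dataset wrapper around an arbitrary effect surface (used to feed
# fitters with exactly known observations).
make_endpoint_dataset <- function(design, effect, ids = c("A", "B")) {
  wells <- gpdi:::design_wells(design)
  wells$effect_obs <- effect
  structure(list(design = design, wells = wells, timecourses = NULL,
                 truth = NULL, growth = NULL, sigma = 0, seed = NA_integer_,
                 mode = "endpoint", drug_ids = ids, n_truncated = 0L),
            class = "checkerboard_dataset")
}

# Frequently used two-drug fixtures
fixture_drugs <- function() {
  list(a = pd_drug("A", emax = 1, ec50 = 1, hill = 2),
       b = pd_drug("B", emax = 1, ec50 = 2, hill = 3))
}
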