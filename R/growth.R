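#' Lag-plus-logistic growth model parameters
#'
#' Two-state growth model for longitudinal optical-density (OD) read-outs:
#' inoculum starts in a lag state `S1` and transfers with first-order rate
#' `k_lag` into the growing state `S2`, which grows logistically with rate
#' `k_growth` towards the carrying capacity `b_max`, inhibited by the combined
#' drug effect:
#' \deqn{dS_1/dt = -k_{lag} S_1}
#' \deqn{dS_2/dt = k_{lag} S_1 + k_{growth} S_2 (1 - S_2/B_{max})(1 - E_{comb})}
#' with `OD = S1 + S2`.
#'
#' @param k_lag first-order lag-to-growth transfer rate (1/h).
#' @param k_growth logistic growth rate constant (1/h).
#' @param b_max carrying capacity (OD units).
#' @param s1_0 initial lag-state OD; default places the whole inoculum here,
#'   modeling delayed growth onset.
#' @param s2_0 initial growing-state OD.
#' @return An object of class `growth_params`.
#' @export
growth_params <- function(k_lag = 0.5, k_growth = 0.7, b_max = 1,
                          s1_0 = 0.02, s2_0 = 0) {
  if (any(!is.finite(c(k_lag, k_growth, b_max, s1_0, s2_0))))
    stop("growth parameters must be finite", call. = FALSE)
  if (k_lag <= 0 || k_growth <= 0 || b_max <= 0)
    stop("rates and carrying capacity must be positive", call. = FALSE)
  if (s1_0 < 0 || s2_0 < 0 || s1_0 + s2_0 <= 0)
    stop("initial states must be non-negative with positive total", call. = FALSE)
  if (s2_0 > b_max) stop("s2_0 must not exceed b_max", call. = FALSE)
  structure(list(k_lag = k_lag, k_growth = k_growth, b_max = b_max,
                 s1_0 = s1_0, s2_0 = s2_0),
            class = "growth_params")
}

#' Simulate an optical-density time-course under drug inhibition
#'
#' Integrates the lag-plus-logistic system with the growth term scaled by
#' `(1 - E_comb)`. `e_comb` may be a single number (static concentrations give
#' a constant combined effect) or a function of time. Integration uses a
#' non-stiff solver with relative tolerance `1e-10`, falling back to a stiff
#' method if it fails.
#'
#' @param gp a [growth_params()].
#' @param e_comb combined fractional effect in `[0, 1]`, or `function(t)`.
#' @param times numeric vector of time points (h), first `>= 0`.
#' @return data frame with columns `time`, `s1`, `s2`, `od`.
#' @export
simulate_growth <- function(gp, e_comb, times) {
  stopifnot(inherits(gp, "growth_params"))
  if (is.unsorted(times, strictly = TRUE) || times[1] < 0)
    stop("'times' must be strictly increasing and non-negative", call. = FALSE)
  efun <- if (is.function(e_comb)) e_comb else {
    if (!is.finite(e_comb) || e_comb < 0 || e_comb > 1)
      stop("'e_comb' must lie in [0, 1]", call. = FALSE)
    function(t) e_comb
  }
  rhs <- function(t, y, parms) {
    growth <- y[2] * gp$k_growth * (1 - y[2] / gp$b_max) * (1 - efun(t))
    list(c(-y[1] * gp$k_lag, y[1] * gp$k_lag + growth))
  }
  t0 <- times[1]
  tt <- if (t0 > 0) c(0, times) else times
  y0 <- c(s1 = gp$s1_0, s2 = gp$s2_0)
  sol <- tryCatch(
    deSolve::ode(y0, tt, rhs, parms = NULL, method = "lsoda",
                 rtol = 1e-10, atol = 1e-12),
    warning = function(w) NULL, error = function(e) NULL)
  if (is.null(sol) || nrow(sol) < length(tt))
    sol <- tryCatch(
      deSolve::ode(y0, tt, rhs, parms = NULL, method = "bdf",
                   rtol = 1e-10, atol = 1e-12),
      error = function(e)
        stop(sprintf("growth ODE integration failed (k_lag=%g, k_growth=%g, b_max=%g)",
                     gp$k_lag, gp$k_growth, gp$b_max), call. = FALSE))
  sol <- as.data.frame(sol)
  sol <- sol[sol$time %in% times, , drop = FALSE]
  data.frame(time = sol$time, s1 = sol$s1, s2 = sol$s2,
             od = sol$s1 + sol$s2, row.names = NULL)
}

#' Simulate growth time-courses over a checkerboard design
#'
#' For every well of the design the combined drug effect is computed once from
#' the constant well concentrations ([combined_effect()]) and the growth model
#' is integrated under that inhibition.
#'
#' @param gp a [growth_params()].
#' @param model a two-drug [interaction_model()].
#' @param design a [checkerboard_design()].
#' @param times time points (h).
#' @return long data frame with columns `well_id`, `drug_a`, `conc_a`,
#'   `drug_b`, `conc_b`, `time_h`, `od`.
#' @export
predict_checkerboard <- function(gp, model, design, times) {
  ids <- names(model$drugs)
  stopifnot(length(ids) == 2)
  wells <- design_wells(design)
  e <- combined_effect(model, stats::setNames(
    list(wells$conc_a, wells$conc_b), ids))
  e <- pmin(pmax(as.numeric(e), 0), 1)
  out <- lapply(seq_len(nrow(wells)), function(i) {
    tc <- simulate_growth(gp, e[i], times)
    data.frame(well_id = wells$well_id[i], drug_a = ids[1],
               conc_a = wells$conc_a[i], drug_b = ids[2],
               conc_b = wells$conc_b[i], time_h = tc$time, od = tc$od)
  })
  do.call(rbind, out)
}
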