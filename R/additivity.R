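#' Combine single-drug effects under Bliss Independence
#'
#' n-drug generalization `E_comb = 1 - prod(1 - E_i)`; for two drugs this is
#' the familiar `E_A + E_B - E_A * E_B`. Effects must lie on the probability
#' scale `[0, 1]`.
#'
#' @param effects numeric vector (or list of equal-length vectors, combined
#'   elementwise) of fractional effects in `[0, 1]`.
#' @return combined effect in `[0, 1]`.
#' @export
combine_bliss <- function(effects) {
  m <- effects_matrix(effects)
  if (any(m < 0 | m > 1))
    stop("Bliss Independence requires effects in [0, 1]", call. = FALSE)
  1 - apply(1 - m, 1, prod)
}

#' Combine single-drug effects by simple addition or highest single agent
#'
#' `combine_effect_addition()` sums the effects (clipped at `ceiling` unless
#' `clip = FALSE`); `combine_hsa()` takes the maximum.
#'
#' @inheritParams combine_bliss
#' @param clip clip the sum at `ceiling`? Default `TRUE`.
#' @param ceiling upper clip for effect addition (default 1, the full
#'   inhibition bound on the fractional effect scale).
#' @export
combine_effect_addition <- function(effects, clip = TRUE, ceiling = 1) {
  m <- effects_matrix(effects)
  if (any(m < 0)) stop("effects must be non-negative", call. = FALSE)
  s <- rowSums(m)
  if (clip) pmin(s, ceiling) else s
}

#' @rdname combine_effect_addition
#' @export
combine_hsa <- function(effects) {
  m <- effects_matrix(effects)
  if (any(m < 0)) stop("effects must be non-negative", call. = FALSE)
  apply(m, 1, max)
}

effects_matrix <- function(effects) {
  if (is.list(effects)) {
    n <- max(vapply(effects, length, 0L))
    m <- vapply(effects, rep_len, numeric(n), length.out = n)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1)
  } else {
    m <- matrix(effects, nrow = 1)
  }
  if (anyNA(m) || any(!is.finite(m)))
    stop("effects must be finite", call. = FALSE)
  m
}

#' Combined effect under Loewe Additivity (implicit dose substitution)
#'
#' Loewe Additivity states that fractions of equieffective doses sum to one:
#' \deqn{1 = \sum_i \frac{C_i}{\mathrm{EC50}_i\, f_i\,
#'   (E/(\mathrm{Emax}_i - E))^{1/H_i}},}
#' where `f_i` is the product of interaction shift factors on drug *i*'s EC50.
#' The equation is implicit in the combined effect `E` and is solved by
#' bracketed (Brent-type) root finding on `(0, min Emax)`; the left-hand side
#' minus 1 is monotone decreasing in `E` on that interval so the root is
#' unique. When only one concentration is positive the equation degenerates
#' and the perturbed single-drug effect is returned directly; with all
#' concentrations zero the combined effect is 0.
#'
#' Unequal Emax values are permitted (a warning is issued when they differ by
#' more than 1%, since dose substitution presumes a mutual maximum effect);
#' the solution is then capped just below the smaller Emax and flagged via the
#' `"boundary"` attribute.
#'
#' @param model a [interaction_model()] with criterion `"loewe"` (all
#'   interaction terms on EC50).
#' @param conc_map named list of drug concentrations (vectors recycled).
#' @param tol absolute residual tolerance of the root (default `1e-12`).
#' @return numeric vector of combined effects; attribute `"boundary"` is a
#'   logical vector marking entries capped at the smaller Emax.
#' @export
combine_loewe <- function(model, conc_map, tol = 1e-12) {
  stopifnot(inherits(model, "gpdi_model"))
  for (tm in model$terms)
    if (tm$target == "Emax")
      stop("Loewe Additivity supports only EC50-level interaction terms",
           call. = FALSE)
  cm <- normalize_conc_map(model, conc_map)
  ids <- names(model$drugs)
  emax <- vapply(model$drugs, `[[`, 0, "emax")
  if (any(emax <= 0))
    stop("Loewe Additivity requires Emax > 0 for every drug", call. = FALSE)
  if (max(emax) / min(emax) > 1.01)
    warning("Emax values differ by > 1%; Loewe dose substitution presumes a mutual maximum effect")
  n <- length(cm[[1]])
  # per-drug shifted EC50 at each grid point
  ec50_eff <- vapply(ids, function(id) {
    d <- model$drugs[[id]]
    f <- rep(1, n)
    for (tm in model$terms)
      if (tm$target == "EC50" && tm$victim == id)
        f <- f * term_shift_factor(model, tm, cm)
    d$ec50 * f
  }, numeric(n))
  if (is.null(dim(ec50_eff))) ec50_eff <- matrix(ec50_eff, nrow = 1)
  conc <- vapply(ids, function(id) cm[[id]], numeric(n))
  if (is.null(dim(conc))) conc <- matrix(conc, nrow = 1)
  hills <- vapply(model$drugs, `[[`, 0, "hill")
  e_cap <- min(emax)
  eps <- 1e-12
  out <- numeric(n)
  boundary <- logical(n)
  for (i in seq_len(n)) {
    ci <- conc[i, ]
    active <- ci > 0
    if (!any(active)) { out[i] <- 0; next }
    if (sum(active) == 1) {
      id <- ids[active]
      d <- model$drugs[[id]]
      out[i] <- d$emax * hill_fraction(ci[active], ec50_eff[i, active], d$hill)
      next
    }
    g <- function(e) {
      v <- sum(ci[active] / (ec50_eff[i, active] *
                 (e / (emax[active] - e)) ^ (1 / hills[active]))) - 1
      if (is.finite(v)) v else 1e300  # dose-fraction overflow near E = 0
    }
    lo <- e_cap * eps; hi <- e_cap * (1 - eps)
    if (g(hi) > 0) {           # effect pinned against the smaller Emax
      out[i] <- hi; boundary[i] <- TRUE; next
    }
    if (g(lo) < 0) {
      stop(sprintf(
        "no sign change for Loewe root in bracket [%g, %g] at grid point %d",
        lo, hi, i), call. = FALSE)
    }
    r <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.9)
    # polish by bisection until the residual meets tol
    e <- r$root
    if (abs(g(e)) > tol) {
      a <- lo; b <- hi
      for (k in 1:200) {
        m <- (a + b) / 2
        if (g(m) > 0) a <- m else b <- m
        if (abs(g(m)) < tol || (b - a) < .Machine$double.eps * e_cap) break
      }
      e <- (a + b) / 2
    }
    out[i] <- e
  }
  attr(out, "boundary") <- boundary
  out
}

#' Combined effect of an interaction model at given concentrations
#'
#' Dispatches on the model's additivity criterion: Bliss Independence, Loewe
#' Additivity (implicit, root-found), simple effect addition, or highest
#' single agent. For the explicit criteria each drug's perturbed effect is
#' evaluated first ([modulated_effect()]) and then combined.
#'
#' @inheritParams combine_loewe
#' @param ... passed to the criterion-specific combiner.
#' @return numeric vector of combined fractional effects.
#' @export
combined_effect <- function(model, conc_map, ...) {
  stopifnot(inherits(model, "gpdi_model"))
  if (model$criterion == "loewe") return(combine_loewe(model, conc_map, ...))
  cm <- normalize_conc_map(model, conc_map)
  eff <- lapply(names(model$drugs), function(id) modulated_effect(model, id, cm))
  switch(model$criterion,
         bliss = combine_bliss(eff),
         effect_addition = combine_effect_addition(eff, ...),
         hsa = combine_hsa(eff))
}

#' Combined-effect surface over a two-drug concentration grid
#'
#' Convenience export of the response surface as a long data frame
#' (`conc_a`, `conc_b`, `e_comb`), suitable for plotting signature surfaces
#' or writing to CSV.
#'
#' @param model a two-drug [interaction_model()].
#' @param conc_a,conc_b concentration vectors spanning the grid.
#' @param path optional CSV path; when given, the grid is also written there.
#' @return data frame with one row per grid point.
#' @export
surface_grid <- function(model, conc_a, conc_b, path = NULL) {
  ids <- names(model$drugs)
  stopifnot(length(ids) == 2)
  g <- expand.grid(conc_a = conc_a, conc_b = conc_b)
  cm <- stats::setNames(list(g$conc_a, g$conc_b), ids)
  g$e_comb <- as.numeric(combined_effect(model, cm))
  if (!is.null(path)) utils::write.csv(g, path, row.names = FALSE)
  g
}
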