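#' Combined effect under the Greco response-surface model
#'
#' Loewe-based comparator model with a single empirical interaction index
#' `alpha`:
#' \deqn{1 = \frac{C_A}{EC50_A (E/(Emax_A - E))^{1/H_A}}
#'         + \frac{C_B}{EC50_B (E/(Emax_B - E))^{1/H_B}}
#'         + \frac{\alpha\, C_A C_B}{EC50_A EC50_B
#'           (E/(Emax - E))^{1/(2H_A) + 1/(2H_B)}}.}
#' `alpha = 0` reproduces Loewe Additivity exactly; `alpha > 0` indicates
#' synergy and `alpha < 0` antagonism. The equation is implicit in `E` and is
#' solved by the same bracketed root finding as [combine_loewe()]. For
#' strongly negative `alpha` the equation can lose its root inside the
#' bracket; the boundary value is then returned and flagged via the
#' `"boundary"` attribute rather than raising, so batch fits proceed.
#'
#' The unsubscripted `Emax` of the interaction denominator is taken as the
#' smaller of the two Emax values (the models coincide when they are equal).
#'
#' @param drug_a,drug_b sigmoidal [pd_drug()] models.
#' @param alpha interaction index.
#' @param c_a,c_b concentration vectors (recycled to a common length).
#' @param tol absolute residual tolerance of the root.
#' @return numeric vector of combined effects with attribute `"boundary"`.
#' @export
greco_effect <- function(drug_a, drug_b, alpha, c_a, c_b, tol = 1e-12) {
  stopifnot(inherits(drug_a, "pd_drug"), inherits(drug_b, "pd_drug"),
            is.finite(alpha))
  check_conc(c_a); check_conc(c_b)
  n <- max(length(c_a), length(c_b))
  c_a <- rep_len(c_a, n); c_b <- rep_len(c_b, n)
  e_cap <- min(drug_a$emax, drug_b$emax)
  eps <- 1e-12
  out <- numeric(n); boundary <- logical(n)
  for (i in seq_len(n)) {
    ca <- c_a[i]; cb <- c_b[i]
    if (ca == 0 && cb == 0) { out[i] <- 0; next }
    if (cb == 0) { out[i] <- pd_effect(drug_a, ca); next }
    if (ca == 0) { out[i] <- pd_effect(drug_b, cb); next }
    g <- function(e) {
      v <- ca / (drug_a$ec50 * (e / (drug_a$emax - e)) ^ (1 / drug_a$hill)) +
        cb / (drug_b$ec50 * (e / (drug_b$emax - e)) ^ (1 / drug_b$hill)) +
        alpha * ca * cb / (drug_a$ec50 * drug_b$ec50 *
          (e / (e_cap - e)) ^ (1 / (2 * drug_a$hill) + 1 / (2 * drug_b$hill))) - 1
      # near E = 0 the single-agent dose fractions dominate any overflow of
      # the interaction term, so a non-finite residual is positive
      if (is.finite(v)) v else 1e300
    }
    lo <- e_cap * eps; hi <- e_cap * (1 - eps)
    glo <- g(lo); ghi <- g(hi)
    if (is.na(glo) || is.na(ghi) || glo * ghi > 0) {
      out[i] <- if (!is.na(ghi) && ghi > 0) hi else lo
      boundary[i] <- TRUE
      next
    }
    r <- stats::uniroot(g, c(lo, hi), tol = .Machine$double.eps^0.9)
    e <- r$root
    if (abs(g(e)) > tol) {
      a <- lo; b <- hi
      for (k in 1:200) {
        m <- (a + b) / 2
        if (g(m) * g(b) <= 0) a <- m else b <- m
        if (abs(g(m)) < tol) break
      }
      e <- (a + b) / 2
    }
    out[i] <- e
  }
  attr(out, "boundary") <- boundary
  out
}

#' Combined effect under the empiric Bliss interaction model
#'
#' `E = E_A + E_B - beta * E_A * E_B`. `beta = 1` reproduces Bliss
#' Independence, `beta > 1` indicates antagonism and `beta < 1` synergy.
#' Output is clipped to `[0, 1]`; clipped entries are flagged via the
#' `"clipped"` attribute.
#'
#' @param drug_a,drug_b sigmoidal [pd_drug()] models.
#' @param beta interaction index.
#' @param c_a,c_b concentration vectors.
#' @export
empiric_bliss_effect <- function(drug_a, drug_b, beta, c_a, c_b) {
  stopifnot(is.finite(beta))
  ea <- pd_effect(drug_a, c_a); eb <- pd_effect(drug_b, c_b)
  if (any(ea < 0 | ea > 1 | eb < 0 | eb > 1))
    stop("component effects must lie in [0, 1]", call. = FALSE)
  e <- ea + eb - beta * ea * eb
  clipped <- e < 0 | e > 1
  out <- pmin(pmax(e, 0), 1)
  attr(out, "clipped") <- clipped
  out
}

#' Isobole curvature score
#'
#' For a point `(x, y)` on an equi-effect contour (isobole), with both
#' coordinates normalized by the respective drug's MIC, the curvature score is
#' \deqn{\gamma = \log\frac{x}{1-x} - \log\frac{y}{1-y}.}
#' `gamma = 0` indicates a linear isobole (Loewe Additivity); negative values
#' indicate synergy (isobole bent towards the origin) and positive values
#' antagonism. The score is antisymmetric under swapping `x` and `y`.
#' The logarithm base only rescales the score and does not change the sign
#' conclusion; the natural log is the default.
#'
#' @param x,y MIC-normalized concentrations, strictly inside `(0, 1)`.
#' @param base logarithm base (default `exp(1)`).
#' @return numeric vector of scores.
#' @export
isobole_gamma <- function(x, y, base = exp(1)) {
  if (any(x <= 0 | x >= 1 | y <= 0 | y >= 1))
    stop("isobole coordinates must lie strictly inside (0, 1)", call. = FALSE)
  (log(x / (1 - x)) - log(y / (1 - y))) / log(base)
}

#' Extract an equi-effect contour from a response surface
#'
#' Convenience helper locating, for each concentration of drug A, the drug-B
#' concentration at which the combined effect crosses `level` (linear
#' interpolation on a dense grid). Points are returned normalized by each
#' drug's single-agent crossing concentration ("MIC" at that level), ready for
#' [isobole_gamma()].
#'
#' @param model a two-drug [interaction_model()].
#' @param level effect level of the contour (e.g. 0.5).
#' @param c_max upper concentration bound searched for both drugs.
#' @param n grid resolution per axis.
#' @return data frame with columns `conc_a`, `conc_b`, `x`, `y` (normalized).
#' @export
equieffect_contour <- function(model, level, c_max, n = 201) {
  ids <- names(model$drugs)
  stopifnot(length(ids) == 2, level > 0)
  grid <- seq(0, c_max, length.out = n)
  cross <- function(conc, eff) {
    idx <- which(eff[-1] >= level & eff[-length(eff)] < level)
    if (!length(idx)) return(NA_real_)
    i <- idx[1]
    conc[i] + (level - eff[i]) * (conc[i + 1] - conc[i]) / (eff[i + 1] - eff[i])
  }
  mic_a <- cross(grid, as.numeric(combined_effect(
    model, stats::setNames(list(grid, 0), ids))))
  mic_b <- cross(grid, as.numeric(combined_effect(
    model, stats::setNames(list(0, grid), ids))))
  rows <- lapply(grid[grid > 0], function(ca) {
    eff <- as.numeric(combined_effect(model, stats::setNames(list(ca, grid), ids)))
    cb <- cross(grid, eff)
    if (is.na(cb)) return(NULL)
    data.frame(conc_a = ca, conc_b = cb, x = ca / mic_a, y = cb / mic_b)
  })
  out <- do.call(rbind, rows)
  out[is.finite(out$x) & is.finite(out$y), , drop = FALSE]
}
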