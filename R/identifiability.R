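#' Expected Fisher information of a design
#'
#' For an additive Gaussian error model with SD `sigma`, the expected Fisher
#' information is `FIM = (1/sigma^2) * (J' J)` where `J` is the Jacobian of
#' the predicted observations with respect to the free parameters, assembled
#' here by central finite differences (relative step `1e-6`). Anticipated
#' standard errors are the square roots of the diagonal of the inverse FIM,
#' and anticipated relative standard errors normalize them by the parameter
#' values.
#'
#' @param predict_fn `function(theta)` returning the predicted observation
#'   vector for a named parameter vector.
#' @param theta named numeric vector of free parameter values.
#' @param sigma residual SD (> 0).
#' @param rel_step relative finite-difference step.
#' @return An object of class `fim_result`: list with `fim`, `se`, `rse_pct`,
#'   `singular`.
#' @export
expected_fim <- function(predict_fn, theta, sigma, rel_step = 1e-6) {
  stopifnot(sigma > 0, all(is.finite(theta)))
  p <- length(theta)
  n <- length(predict_fn(theta))
  J <- matrix(NA_real_, n, p)
  for (j in seq_len(p)) {
    h <- rel_step * max(abs(theta[j]), 1e-8)
    tp <- theta; tp[j] <- theta[j] + h
    tm <- theta; tm[j] <- theta[j] - h
    J[, j] <- (predict_fn(tp) - predict_fn(tm)) / (2 * h)
  }
  fim <- crossprod(J) / sigma^2
  dimnames(fim) <- list(names(theta), names(theta))
  cov <- tryCatch(solve(fim), error = function(e) NULL)
  if (is.null(cov) || any(!is.finite(diag(cov))) || any(diag(cov) < 0)) {
    se <- rse <- stats::setNames(rep(Inf, p), names(theta))
    singular <- TRUE
  } else {
    se <- stats::setNames(sqrt(diag(cov)), names(theta))
    rse <- 100 * se / abs(theta)
    singular <- FALSE
  }
  structure(list(fim = fim, se = se, rse_pct = rse, singular = singular),
            class = "fim_result")
}

#' @export
print.fim_result <- function(x, ...) {
  cat("<fim_result>", nrow(x$fim), "free parameter(s)",
      if (x$singular) "(SINGULAR)\n" else "\n")
  print(round(x$rse_pct, 2))
  invisible(x)
}

#' Expected FIM of a symmetric two-drug interaction model on a checkerboard
#'
#' Builds the endpoint-effect prediction function of a symmetric two-drug
#' interaction model — both partners share the single-drug parameters `emax`,
#' `ec50`, `h`, and a symmetric bidirectional interaction shares `int` and
#' `ec50_int` — over all wells of the design, and computes the expected FIM
#' over the five-parameter free vector.
#'
#' @param theta named vector with entries `emax`, `ec50`, `h`, `int`,
#'   `ec50_int` (and optionally `h_int`, fixed at 1 otherwise).
#' @param design a [checkerboard_design()].
#' @param sigma residual SD on the effect scale.
#' @param criterion additivity criterion (default `"bliss"`).
#' @param free names of the parameters to include in the FIM (default: all of
#'   `theta`); the rest are held fixed.
#' @return a `fim_result`.
#' @export
expected_fim_checkerboard <- function(theta, design, sigma = 0.03,
                                      criterion = "bliss",
                                      free = names(theta)) {
  wells <- design_wells(design)
  h_int <- if ("h_int" %in% names(theta)) theta[["h_int"]] else 1
  predict_fn <- function(th) {
    full <- theta; full[names(th)] <- th
    m <- symmetric_model(full, criterion, h_int)
    as.numeric(combined_effect(m, list(A = wells$conc_a, B = wells$conc_b)))
  }
  expected_fim(predict_fn, theta[free], sigma)
}

symmetric_model <- function(th, criterion, h_int = 1) {
  drugs <- list(pd_drug("A", emax = th[["emax"]], ec50 = th[["ec50"]],
                        hill = th[["h"]]),
                pd_drug("B", emax = th[["emax"]], ec50 = th[["ec50"]],
                        hill = th[["h"]]))
  terms <- list(
    gpdi_term("B", "A", "EC50", int = th[["int"]],
              ec50_int = th[["ec50_int"]], h_int = h_int),
    gpdi_term("A", "B", "EC50", int = th[["int"]],
              ec50_int = th[["ec50_int"]], h_int = h_int))
  interaction_model(drugs, terms, criterion = criterion)
}

#' Design identifiability study over random interaction scenarios
#'
#' Monte-Carlo assessment of how precisely a checkerboard design can estimate
#' the interaction parameters before any data are collected. Each simulation
#' draws a scenario of the Bliss-based symmetric interaction model from
#' uniform ranges — `Emax ~ U(0.5, 1)`, `EC50 ~ U(0.5, 2)`, `H ~ U(1, 4)`,
#' `INT ~ U(-0.9, -0.5)` or `U(0.5, 20)` (fair coin between the synergy and
#' antagonism sub-ranges), `EC50_INT ~ U(0.1, 1)` — computes the expected FIM
#' of the design at residual SD `sigma`, and records the anticipated relative
#' standard errors. Summaries are the median and the 10th/90th percentiles
#' per parameter; singular FIMs are tallied and excluded.
#'
#' In the linear-dilution variant the potency parameters are placed in the
#' 40-60% range of the highest studied concentration: both `EC50` and
#' `EC50_INT` are drawn from `U(0.4, 0.6) * c_max`.
#'
#' @param n_sims number of simulated scenarios (the reference study uses 1000).
#' @param scheme `"log2"` or `"linear"` dilution design.
#' @param seed RNG seed.
#' @param sigma residual SD on the effect scale (default 0.03).
#' @param design optional [checkerboard_design()] overriding the default
#'   8-by-8, 0-to-8 grid.
#' @param summary_params parameters summarized in the returned table
#'   (default `c("int", "ec50_int")`, the interaction parameters; all RSEs
#'   are kept in the `draws` attribute).
#' @return data frame with columns `parameter, median_rse_pct, p10_rse_pct,
#'   p90_rse_pct, n_singular`; attribute `"draws"` holds the full RSE matrix.
#' @export
identifiability_study <- function(n_sims = 1000, scheme = c("log2", "linear"),
                                  seed = 1L, sigma = 0.03, design = NULL,
                                  summary_params = c("int", "ec50_int")) {
  scheme <- match.arg(scheme)
  stopifnot(n_sims >= 1)
  design <- design %||% checkerboard_design(scheme = scheme)
  set.seed(as.integer(seed))
  par_names <- c("emax", "ec50", "h", "int", "ec50_int")
  draws <- matrix(NA_real_, n_sims, length(par_names),
                  dimnames = list(NULL, par_names))
  n_singular <- 0L
  for (s in seq_len(n_sims)) {
    int <- if (stats::runif(1) < 0.5) stats::runif(1, -0.9, -0.5)
           else stats::runif(1, 0.5, 20)
    if (scheme == "log2") {
      ec50 <- stats::runif(1, 0.5, 2)
      ec50_int <- stats::runif(1, 0.1, 1)
    } else {
      ec50 <- stats::runif(1, 0.4, 0.6) * design$c_max
      ec50_int <- stats::runif(1, 0.4, 0.6) * design$c_max
    }
    theta <- c(emax = stats::runif(1, 0.5, 1), ec50 = ec50,
               h = stats::runif(1, 1, 4), int = int, ec50_int = ec50_int)
    fr <- expected_fim_checkerboard(theta, design, sigma = sigma)
    if (fr$singular) { n_singular <- n_singular + 1L; next }
    draws[s, ] <- fr$rse_pct[par_names]
  }
  out <- do.call(rbind, lapply(summary_params, function(p) {
    v <- draws[, p]
    v <- v[is.finite(v)]
    data.frame(parameter = p,
               median_rse_pct = stats::median(v),
               p10_rse_pct = unname(stats::quantile(v, 0.10)),
               p90_rse_pct = unname(stats::quantile(v, 0.90)),
               n_singular = n_singular)
  }))
  attr(out, "draws") <- draws
  attr(out, "scheme") <- scheme
  out
}
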