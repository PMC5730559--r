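#' Single-drug pharmacodynamic model
#'
#' Constructs the exposure-response model of one drug. The default form is the
#' sigmoidal maximum-effect (Hill) model
#' \deqn{E(C) = \mathrm{Emax}\, C^H / (\mathrm{EC50}^H + C^H),}
#' parameterized by the maximal fractional effect `emax`, the potency `ec50`
#' (concentration at half-maximal effect, in the units of the input
#' concentrations) and the Hill factor `hill` controlling sigmoidicity.
#' When the highest studied concentration lies well below the EC50, the
#' linear slope model (`E = slope * C`) or the power model
#' (`E = slope * C^hill`) can be used instead.
#'
#' The effect scale convention is 1 = full growth inhibition, 0 = no effect.
#'
#' @param drug_id character identifier.
#' @param emax maximal fractional effect (dimensionless, typically in `[0, 1]`
#'   for growth inhibition). Ignored for slope/power forms.
#' @param ec50 concentration at half-maximal effect; must be positive.
#' @param hill Hill factor; must be positive. Fixed at 1 for the slope form.
#' @param form one of `"sigmoid_emax"`, `"slope"`, `"power"`.
#' @param slope effect per concentration unit (slope/power forms only).
#' @return An object of class `pd_drug`.
#' @seealso [pd_effect()]
#' @export
pd_drug <- function(drug_id, emax = 1, ec50 = NULL, hill = 1,
                    form = c("sigmoid_emax", "slope", "power"),
                    slope = NULL) {
  form <- match.arg(form)
  if (form == "slope") hill <- 1
  x <- structure(
    list(drug_id = as.character(drug_id), emax = emax, ec50 = ec50,
         hill = hill, form = form, slope = slope),
    class = "pd_drug")
  validate_pd_drug(x)
  x
}

validate_pd_drug <- function(x) {
  if (x$form == "sigmoid_emax") {
    if (is.null(x$ec50) || !is.finite(x$ec50) || x$ec50 <= 0)
      stop("'ec50' must be a finite positive number", call. = FALSE)
    if (!is.finite(x$emax) || x$emax < 0)
      stop("'emax' must be finite and >= 0", call. = FALSE)
  } else {
    if (is.null(x$slope) || !is.finite(x$slope) || x$slope < 0)
      stop("'slope' must be a finite non-negative number", call. = FALSE)
  }
  if (!is.finite(x$hill) || x$hill <= 0)
    stop("'hill' must be a finite positive number", call. = FALSE)
  invisible(x)
}

#' @export
print.pd_drug <- function(x, ...) {
  cat("<pd_drug>", x$drug_id, "form =", x$form, "\n")
  if (x$form == "sigmoid_emax")
    cat(sprintf("  emax = %g, ec50 = %g, hill = %g\n", x$emax, x$ec50, x$hill))
  else
    cat(sprintf("  slope = %g, hill = %g\n", x$slope, x$hill))
  invisible(x)
}

#' Fractional effect of a single drug
#'
#' Evaluates the drug's exposure-response model at one or more concentrations.
#' For the sigmoidal form the ratio `C^H / (EC50^H + C^H)` is computed in log
#' space when `C/EC50` is large, so extreme concentrations do not overflow.
#' Zero concentration returns exactly 0 for every form (the `0^0` ambiguity of
#' `hill < 1` at `C = 0` is resolved by the limit).
#'
#' @param drug a [pd_drug()].
#' @param conc numeric vector of non-negative concentrations.
#' @return numeric vector of fractional effects.
#' @examples
#' d <- pd_drug("A", emax = 1, ec50 = 50, hill = 4)
#' pd_effect(d, c(0, 50, 100))
#' @export
pd_effect <- function(drug, conc) {
  stopifnot(inherits(drug, "pd_drug"))
  check_conc(conc)
  if (drug$form == "sigmoid_emax")
    drug$emax * hill_fraction(conc, drug$ec50, drug$hill)
  else
    slope_or_power_effect(drug, conc)
}

#' Effect under the linear slope or power model
#'
#' `E = slope * C` (slope form) or `E = slope * C^hill` (power form); unbounded
#' above, unlike the sigmoidal form.
#'
#' @inheritParams pd_effect
#' @export
slope_or_power_effect <- function(drug, conc) {
  stopifnot(inherits(drug, "pd_drug"))
  if (drug$form == "sigmoid_emax")
    stop("drug has form 'sigmoid_emax'; use pd_effect()", call. = FALSE)
  check_conc(conc)
  if (drug$form == "slope") drug$slope * conc
  else drug$slope * ifelse(conc == 0, 0, conc ^ drug$hill)
}

# C^H / (EC50^H + C^H), stable for extreme C/EC50; exact 0 at C = 0
hill_fraction <- function(conc, ec50, hill) {
  r <- conc / ec50
  out <- numeric(length(r))
  pos <- r > 0
  # 1 / (1 + exp(-H * log r)) == r^H / (1 + r^H)
  out[pos] <- stats::plogis(hill * log(r[pos]))
  out
}

check_conc <- function(conc) {
  if (!is.numeric(conc) || anyNA(conc) || any(!is.finite(conc)))
    stop("concentrations must be finite numeric values", call. = FALSE)
  if (any(conc < 0))
    stop("concentrations must be non-negative", call. = FALSE)
  invisible(conc)
}

#' Read or write single-drug parameter tables
#'
#' Flat CSV interchange with columns `drug_id, form, emax, ec50, hill, slope`.
#'
#' @param drugs list of [pd_drug()] objects.
#' @param path CSV file path.
#' @return `read_drug_params()` returns a named list of `pd_drug` objects.
#' @export
write_drug_params <- function(drugs, path) {
  df <- do.call(rbind, lapply(drugs, function(d) {
    data.frame(drug_id = d$drug_id, form = d$form,
               emax = d$emax %||% NA_real_, ec50 = d$ec50 %||% NA_real_,
               hill = d$hill, slope = d$slope %||% NA_real_)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_drug_params
#' @export
read_drug_params <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  drugs <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    pd_drug(r$drug_id,
            emax = if (is.na(r$emax)) 1 else r$emax,
            ec50 = if (is.na(r$ec50)) NULL else r$ec50,
            hill = r$hill, form = r$form,
            slope = if (is.na(r$slope)) NULL else r$slope)
  })
  stats::setNames(drugs, vapply(drugs, `[[`, "", "drug_id"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
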