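#' Pharmacodynamic interaction term
#'
#' A saturable (Emax-type) function of a perpetrator drug's concentration that
#' multiplicatively shifts one pharmacodynamic parameter of a victim drug:
#' \deqn{\theta \times \left(1 + \frac{\mathrm{INT}\, C^{H_{INT}}}
#'   {\mathrm{EC50}_{INT}^{H_{INT}} + C^{H_{INT}}}\right).}
#' `INT` is the maximum fractional change of the victim parameter
#' (`INT >= -1`, zero meaning no interaction), `EC50_INT` the interaction
#' potency of the perpetrator, and `H_INT` the interaction sigmoidicity
#' (default 1, the usual choice when `H_INT` is not estimated).
#'
#' Terms targeting `"EC50"` describe competitive-type interactions; terms
#' targeting `"Emax"` describe allosteric-type interactions (the polarity of
#' `INT` is opposite on Emax compared to EC50). A term targeting `"INT"` is a
#' modulation term: it shifts the `INT` of another (pairwise or modulation)
#' term, identified by `modulates`, capturing emergent third-drug effects.
#'
#' @param perpetrator drug id whose concentration drives the shift.
#' @param victim drug id whose parameter is shifted (for modulation terms, the
#'   victim of the modulated term).
#' @param target one of `"EC50"`, `"Emax"`, `"INT"`.
#' @param int maximum fractional change; must be `>= -1`.
#' @param ec50_int interaction potency (concentration units); positive.
#' @param h_int interaction sigmoidicity; positive, default 1.
#' @param modulates for `target = "INT"`: the key of the modulated term, either
#'   `c(victim, perpetrator)` of a pairwise term or the full key string
#'   returned by [term_key()] for deeper nesting.
#' @return An object of class `gpdi_term`.
#' @export
gpdi_term <- function(perpetrator, victim, target = c("EC50", "Emax", "INT"),
                      int, ec50_int, h_int = 1, modulates = NULL) {
  target <- match.arg(target)
  if (!is.finite(int) || int < -1)
    stop("'int' must be finite and >= -1 (the shift factor must stay positive)",
         call. = FALSE)
  if (!is.finite(ec50_int) || ec50_int <= 0)
    stop("'ec50_int' must be a finite positive number", call. = FALSE)
  if (!is.finite(h_int) || h_int <= 0)
    stop("'h_int' must be a finite positive number", call. = FALSE)
  if (target == "INT") {
    if (is.null(modulates))
      stop("modulation terms (target = 'INT') require 'modulates'", call. = FALSE)
    if (length(modulates) == 2)
      modulates <- sprintf("%s<%s:EC50", modulates[1], modulates[2])
  } else if (!is.null(modulates)) {
    stop("'modulates' is only meaningful for target = 'INT'", call. = FALSE)
  }
  structure(
    list(perpetrator = as.character(perpetrator), victim = as.character(victim),
         target = target, int = int, ec50_int = ec50_int, h_int = h_int,
         modulates = modulates),
    class = "gpdi_term")
}

#' Key identifying a term within a model
#'
#' Pairwise terms are keyed `victim<perpetrator:target`; modulation terms
#' append `|perpetrator` to the key of the term they modulate.
#'
#' @param term a [gpdi_term()].
#' @return character key.
#' @export
term_key <- function(term) {
  if (term$target == "INT") paste0(term$modulates, "|", term$perpetrator)
  else sprintf("%s<%s:%s", term$victim, term$perpetrator, term$target)
}

#' Multiplicative shift factor of an interaction term
#'
#' Evaluates `1 + INT * C^H_INT / (EC50_INT^H_INT + C^H_INT)` at the
#' perpetrator concentration `perp_conc`. The factor is 1 at zero
#' concentration and approaches `1 + INT` at saturation, so it lies in
#' `(0, 1 + INT]` for positive `INT` and `[1 + INT, 1)` for negative `INT`.
#'
#' @param term a [gpdi_term()].
#' @param perp_conc numeric vector of non-negative perpetrator concentrations.
#' @param int optional override of the term's `int` (used internally when a
#'   modulator rescales it).
#' @return numeric vector of multiplicative factors on the target parameter.
#' @examples
#' tm <- gpdi_term("B", "A", "EC50", int = 2, ec50_int = 10)
#' gpdi_shift(tm, 10)  # half-maximal interaction: 1 + 2 * 0.5 = 2
#' @export
gpdi_shift <- function(term, perp_conc, int = term$int) {
  stopifnot(inherits(term, "gpdi_term"))
  check_conc(perp_conc)
  1 + int * hill_fraction(perp_conc, term$ec50_int, term$h_int)
}

#' Interaction model: drugs plus interaction terms under an additivity criterion
#'
#' Bundles single-drug models and GPDI terms and fixes the additivity
#' criterion used to form the combined effect. At most one term may exist per
#' (perpetrator, victim, target, modulated-term) tuple. The Loewe criterion is
#' compatible only with competitive-type interactions, so it requires all
#' non-modulation terms to target `EC50`.
#'
#' @param drugs list of [pd_drug()] objects (names taken from their ids).
#' @param terms list of [gpdi_term()] objects (may be empty).
#' @param criterion one of `"loewe"`, `"bliss"`, `"effect_addition"`, `"hsa"`.
#' @return An object of class `gpdi_model`.
#' @export
interaction_model <- function(drugs, terms = list(),
                              criterion = c("bliss", "loewe",
                                            "effect_addition", "hsa")) {
  criterion <- match.arg(criterion)
  if (inherits(drugs, "pd_drug")) drugs <- list(drugs)
  if (inherits(terms, "gpdi_term")) terms <- list(terms)
  stopifnot(all(vapply(drugs, inherits, TRUE, "pd_drug")),
            all(vapply(terms, inherits, TRUE, "gpdi_term")))
  ids <- vapply(drugs, `[[`, "", "drug_id")
  if (anyDuplicated(ids)) stop("duplicate drug ids", call. = FALSE)
  drugs <- stats::setNames(drugs, ids)
  keys <- vapply(terms, term_key, "")
  if (anyDuplicated(keys))
    stop("duplicate interaction terms: ", keys[duplicated(keys)][1], call. = FALSE)
  for (tm in terms) {
    for (id in c(tm$perpetrator, tm$victim))
      if (!id %in% ids) stop("term references unknown drug '", id, "'", call. = FALSE)
    if (criterion == "loewe" && tm$target == "Emax")
      stop("the Loewe criterion supports only competitive-type (EC50) terms",
           call. = FALSE)
    if (tm$target == "INT") {
      parent <- sub("\\|[^|]*$", "", term_key(tm))
      if (!parent %in% keys)
        stop("modulation term references non-existent term '", parent, "'",
             call. = FALSE)
    }
  }
  structure(list(drugs = drugs, terms = stats::setNames(terms, keys),
                 criterion = criterion),
            class = "gpdi_model")
}

#' @export
print.gpdi_model <- function(x, ...) {
  cat("<gpdi_model>", length(x$drugs), "drug(s),", length(x$terms),
      "interaction term(s), criterion =", x$criterion, "\n")
  for (tm in x$terms)
    cat(sprintf("  %s: INT = %g, EC50_INT = %g, H_INT = %g\n",
                term_key(tm), tm$int, tm$ec50_int, tm$h_int))
  invisible(x)
}

# Effective INT of a term after applying its modulators (recursive, Eqs. of
# the modulation level); shift factor of a term given all concentrations.
term_shift_factor <- function(model, term, conc_map) {
  eff_int <- term$int
  key <- term_key(term)
  for (m in model$terms) {
    if (m$target == "INT" && identical(sub("\\|[^|]*$", "", term_key(m)), key))
      eff_int <- eff_int * term_shift_factor(model, m, conc_map)
  }
  gpdi_shift(term, conc_map[[term$perpetrator]], int = eff_int)
}

# conc_map normalization: named list of equal-length numeric vectors covering
# every drug in the model (missing drugs default to 0).
normalize_conc_map <- function(model, conc_map) {
  ids <- names(model$drugs)
  conc_map <- as.list(conc_map)
  for (id in ids) if (is.null(conc_map[[id]])) conc_map[[id]] <- 0
  n <- max(vapply(conc_map, length, 0L))
  out <- lapply(conc_map[ids], function(v) {
    check_conc(v)
    rep_len(v, n)
  })
  stats::setNames(out, ids)
}

#' Effect of a victim drug with interaction shifts applied
#'
#' Evaluates the victim drug's sigmoidal effect with its EC50 (and/or Emax)
#' multiplied by the product of all applicable interaction shift factors at
#' the given perpetrator concentrations; the shifted EC50 enters before
#' exponentiation by the victim's Hill factor, i.e. `(EC50 * f)^H`. With all
#' perpetrator concentrations zero this reduces exactly to [pd_effect()].
#'
#' `perturbed_effect()` accepts only pairwise (EC50/Emax) terms;
#' [modulated_effect()] additionally resolves modulation terms and is the
#' general entry point.
#'
#' @param model a [interaction_model()].
#' @param victim_id drug id whose effect is evaluated.
#' @param conc_map named list (or vector) mapping drug ids to concentrations;
#'   vectors are recycled to a common length.
#' @return numeric vector of fractional effects of the victim drug.
#' @export
perturbed_effect <- function(model, victim_id, conc_map) {
  if (any(vapply(model$terms, `[[`, "", "target") == "INT"))
    stop("model contains modulation terms; use modulated_effect()", call. = FALSE)
  modulated_effect(model, victim_id, conc_map)
}

#' @rdname perturbed_effect
#' @export
modulated_effect <- function(model, victim_id, conc_map) {
  stopifnot(inherits(model, "gpdi_model"))
  if (!victim_id %in% names(model$drugs))
    stop("unknown victim drug '", victim_id, "'", call. = FALSE)
  cm <- normalize_conc_map(model, conc_map)
  d <- model$drugs[[victim_id]]
  n <- length(cm[[1]])
  f_ec50 <- rep(1, n); f_emax <- rep(1, n)
  for (tm in model$terms) {
    if (tm$target == "INT" || tm$victim != victim_id) next
    f <- term_shift_factor(model, tm, cm)
    if (tm$target == "EC50") f_ec50 <- f_ec50 * f else f_emax <- f_emax * f
  }
  conc <- cm[[victim_id]]
  if (d$form == "sigmoid_emax")
    d$emax * f_emax * hill_fraction(conc, d$ec50 * f_ec50, d$hill)
  else
    stop("use slope_model_shift() for slope/power-form drugs", call. = FALSE)
}

#' Interaction shift applied to a slope or power model
#'
#' For drugs described by a linear slope or power model the interaction factor
#' can be placed in the numerator (multiplying the effect; interpreted as a
#' fractional change of Emax) or in the denominator (dividing the slope;
#' interpreted as a fractional change of EC50 — exactly for the slope model,
#' approximately for the power model, whose slope represents `Emax/EC50^H`).
#'
#' @param drug a [pd_drug()] with form `"slope"` or `"power"`.
#' @param term a [gpdi_term()] whose perpetrator concentration is taken from
#'   `conc_map`.
#' @param placement `"numerator"` or `"denominator"`.
#' @param conc_map named list with the victim's and perpetrator's concentrations.
#' @return numeric vector of effects, with attributes `placement` and
#'   `interpretation` recording how `INT` is to be read.
#' @export
slope_model_shift <- function(drug, term, placement = c("denominator", "numerator"),
                              conc_map) {
  placement <- match.arg(placement)
  if (drug$form == "sigmoid_emax")
    stop("drug has form 'sigmoid_emax'; use perturbed_effect()", call. = FALSE)
  f <- gpdi_shift(term, conc_map[[term$perpetrator]])
  base <- slope_or_power_effect(drug, conc_map[[drug$drug_id]])
  out <- if (placement == "numerator") base * f else base / f
  attr(out, "placement") <- placement
  attr(out, "interpretation") <-
    if (placement == "numerator") "fractional change of Emax"
    else if (drug$form == "slope") "fractional change of EC50"
    else "approximate fractional change of EC50"
  out
}
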