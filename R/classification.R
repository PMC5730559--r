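#' Fractional EC50 shift at the perpetrator's EC50
#'
#' For intuitive reporting, a fitted interaction term is summarized as the
#' fractional change of the victim's EC50 evaluated at the perpetrator's own
#' EC50:
#' \deqn{\mathrm{shift} = \mathrm{INT}\,
#'   \frac{\mathrm{EC50}_{perp}^{H_{INT}}}
#'        {\mathrm{EC50}_{INT}^{H_{INT}} + \mathrm{EC50}_{perp}^{H_{INT}}},}
#' with `pct_of_baseline = (1 + shift) * 100` the victim EC50 as a percentage
#' of its no-interaction value. In the reduced model, where the interaction
#' potency is fixed at the perpetrator EC50, the formula evaluates to exactly
#' `INT / 2` (with `H_INT = 1`).
#'
#' @param term a fitted [gpdi_term()].
#' @param perpetrator the perpetrator's [pd_drug()] (its EC50 is the
#'   evaluation concentration).
#' @return An object of class `fractional_shift`: list with `perpetrator_id`,
#'   `victim_id`, `shift_at_ec50`, `pct_of_baseline`.
#' @export
fractional_shift <- function(term, perpetrator) {
  stopifnot(inherits(term, "gpdi_term"), inherits(perpetrator, "pd_drug"))
  if (is.null(perpetrator$ec50) || !is.finite(perpetrator$ec50))
    stop("perpetrator EC50 is missing", call. = FALSE)
  shift <- term$int * hill_fraction(perpetrator$ec50, term$ec50_int, term$h_int)
  structure(list(perpetrator_id = term$perpetrator, victim_id = term$victim,
                 shift_at_ec50 = shift,
                 pct_of_baseline = (1 + shift) * 100),
            class = "fractional_shift")
}

#' @export
print.fractional_shift <- function(x, ...) {
  cat(sprintf("<fractional_shift> %s -> %s: %.3f (victim EC50 at %.1f%% of baseline)\n",
              x$perpetrator_id, x$victim_id, x$shift_at_ec50, x$pct_of_baseline))
  invisible(x)
}

#' Additivity margin for interaction calling
#'
#' Interval of the fractional EC50 shift within which an interaction is
#' called additive. The pragmatic fixed default is `(-0.5, 0.5)` — a 50-150%
#' change of the victim EC50 at the perpetrator EC50. Alternatively the
#' margin is derived empirically as the 10th-90th percentile of shifts fitted
#' to sham (drug-versus-itself) combinations, which by construction carry no
#' true interaction.
#'
#' @param lower,upper margin bounds (`lower < 0 < upper`).
#' @param source `"fixed"` or `"sham_percentiles"`.
#' @return An object of class `additivity_margin`.
#' @export
additivity_margin <- function(lower = -0.5, upper = 0.5,
                              source = "fixed") {
  if (!(lower < 0 && upper > 0))
    stop("margin must satisfy lower < 0 < upper", call. = FALSE)
  structure(list(lower = lower, upper = upper, source = source),
            class = "additivity_margin")
}

#' @rdname additivity_margin
#' @param sham_shifts numeric vector of fractional shifts fitted to sham
#'   combinations (both directions pooled).
#' @param probs percentile pair defining the empirical margin.
#' @export
derive_margin <- function(sham_shifts, probs = c(0.10, 0.90)) {
  sham_shifts <- sham_shifts[is.finite(sham_shifts)]
  if (length(sham_shifts) < 2) {
    warning("fewer than 2 sham shifts; falling back to the fixed (-0.5, 0.5) margin")
    return(additivity_margin())
  }
  q <- stats::quantile(sham_shifts, probs, names = FALSE)
  if (!(q[1] < 0 && q[2] > 0)) {
    warning("sham percentile margin does not bracket 0; falling back to the fixed (-0.5, 0.5) margin")
    return(additivity_margin())
  }
  additivity_margin(q[1], q[2], source = "sham_percentiles")
}

#' Six-way classification of a bidirectional interaction
#'
#' Classifies a drug pair from its two directional fractional EC50 shifts
#' relative to an additivity margin. Shifts on the margin boundary count as
#' within it (conservative calling). The six classes:
#' * `additive` — both shifts within the margin;
#' * `bidirectional_synergy` — both below the lower bound;
#' * `bidirectional_antagonism` — both above the upper bound;
#' * `monodirectional_synergy` / `monodirectional_antagonism` — exactly one
#'   shift outside (below / above), the other within;
#' * `bidirectional_asymmetric` — both outside with opposite polarity, giving
#'   concentration-dependent synergy or antagonism.
#'
#' @param shift_ab fractional shift of drug A's EC50 caused by perpetrator B.
#' @param shift_ba fractional shift of drug B's EC50 caused by perpetrator A.
#' @param margin an [additivity_margin()].
#' @param pair optional character pair of drug ids `c(a, b)`.
#' @param criterion optional criterion label carried along.
#' @return An object of class `interaction_call`.
#' @export
classify_pair <- function(shift_ab, shift_ba, margin = additivity_margin(),
                          pair = c("A", "B"), criterion = NA_character_) {
  stopifnot(is.finite(shift_ab), is.finite(shift_ba))
  zone <- function(s) {
    if (s < margin$lower) "syn" else if (s > margin$upper) "ant" else "add"
  }
  za <- zone(shift_ab); zb <- zone(shift_ba)
  class <- if (za == "add" && zb == "add") "additive"
    else if (za == "syn" && zb == "syn") "bidirectional_synergy"
    else if (za == "ant" && zb == "ant") "bidirectional_antagonism"
    else if (xor(za == "add", zb == "add")) {
      out <- setdiff(c(za, zb), "add")
      if (out == "syn") "monodirectional_synergy" else "monodirectional_antagonism"
    } else "bidirectional_asymmetric"
  structure(list(pair = pair, shift_ab = shift_ab, shift_ba = shift_ba,
                 class = class, margin = margin, criterion = criterion),
            class = "interaction_call")
}

#' @export
print.interaction_call <- function(x, ...) {
  cat(sprintf("<interaction_call> %s-%s: %s (shifts %.3f / %.3f)\n",
              x$pair[1], x$pair[2], x$class, x$shift_ab, x$shift_ba))
  invisible(x)
}

#' Three-way classification of conventional interaction indices
#'
#' Maps a fitted conventional interaction parameter onto
#' synergy/additive/antagonism using each model's sign convention and an
#' additivity margin (sham-derived or user-supplied interval around the
#' null value):
#' * Greco `alpha` — null 0; above the margin: synergy; below: antagonism.
#' * empiric Bliss `beta` — null 1; above the margin: antagonism; below:
#'   synergy.
#' * isobole `gamma` — null 0; below the margin: synergy; above: antagonism.
#'
#' @param value fitted interaction parameter.
#' @param model `"greco"`, `"empiric_bliss"`, or `"isobole_gamma"`.
#' @param margin numeric length-2 interval within which the call is
#'   `additive`; defaults to the model's conventional null point (a zero-width
#'   margin at 0 or 1).
#' @return `"synergy"`, `"additive"`, or `"antagonism"`.
#' @export
classify_conventional <- function(value,
                                  model = c("greco", "empiric_bliss",
                                            "isobole_gamma"),
                                  margin = NULL) {
  model <- match.arg(model)
  stopifnot(is.finite(value))
  null_pt <- if (model == "empiric_bliss") 1 else 0
  margin <- margin %||% c(null_pt, null_pt)
  stopifnot(length(margin) == 2, margin[1] <= margin[2])
  if (value >= margin[1] && value <= margin[2]) return("additive")
  above <- value > margin[2]
  switch(model,
         greco = if (above) "synergy" else "antagonism",
         empiric_bliss = if (above) "antagonism" else "synergy",
         isobole_gamma = if (above) "antagonism" else "synergy")
}

#' Classification table for a set of fitted pairs
#'
#' Builds the plotting-ready table of directional shifts, percent-of-baseline
#' values and six-way classes, one row per drug pair.
#'
#' @param calls list of `interaction_call` objects.
#' @param path optional CSV path.
#' @return data frame with columns `drug_a, drug_b, criterion, shift_ab,
#'   shift_ba, pct_ab, pct_ba, class`.
#' @export
classification_table <- function(calls, path = NULL) {
  df <- do.call(rbind, lapply(calls, function(cl) {
    data.frame(drug_a = cl$pair[1], drug_b = cl$pair[2],
               criterion = cl$criterion, shift_ab = cl$shift_ab,
               shift_ba = cl$shift_ba, pct_ab = (1 + cl$shift_ab) * 100,
               pct_ba = (1 + cl$shift_ba) * 100, class = cl$class)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}
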