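#' Read or write an interaction model as a YAML specification
#'
#' Round-trips an [interaction_model()] through a structured text file with a
#' `criterion` field, a `drugs` block (one entry per drug with `form`, `emax`,
#' `ec50`, `hill`, `slope`) and a `terms` block (one entry per interaction
#' term with `perpetrator`, `victim`, `target`, `int`, `ec50_int`, `h_int`,
#' and `modulates` for modulation terms).
#'
#' @param model a [interaction_model()].
#' @param path YAML file path.
#' @return `read_model_spec()` returns the reconstructed `gpdi_model`.
#' @export
write_model_spec <- function(model, path) {
  stopifnot(inherits(model, "gpdi_model"))
  spec <- list(
    criterion = model$criterion,
    drugs = lapply(unname(model$drugs), function(d) {
      out <- list(drug_id = d$drug_id, form = d$form, hill = d$hill)
      if (d$form == "sigmoid_emax") { out$emax <- d$emax; out$ec50 <- d$ec50 }
      else out$slope <- d$slope
      out
    }),
    terms = lapply(unname(model$terms), function(tm) {
      out <- list(perpetrator = tm$perpetrator, victim = tm$victim,
                  target = tm$target, int = tm$int, ec50_int = tm$ec50_int,
                  h_int = tm$h_int)
      if (!is.null(tm$modulates)) out$modulates <- tm$modulates
      out
    }))
  yaml::write_yaml(spec, path)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  spec <- yaml::read_yaml(path)
  drugs <- lapply(spec$drugs, function(d)
    pd_drug(d$drug_id, emax = d$emax %||% 1, ec50 = d$ec50,
            hill = d$hill %||% 1, form = d$form %||% "sigmoid_emax",
            slope = d$slope))
  terms <- lapply(spec$terms, function(tm)
    gpdi_term(tm$perpetrator, tm$victim, tm$target %||% "EC50",
              int = tm$int, ec50_int = tm$ec50_int,
              h_int = tm$h_int %||% 1, modulates = tm$modulates))
  interaction_model(drugs, terms, criterion = spec$criterion %||% "bliss")
}
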