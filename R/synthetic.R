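#' Generate a synthetic checkerboard dataset
#'
#' Emulates a two-drug checkerboard combination experiment: per well the
#' combined effect of the truth model is computed and observed either directly
#' on the effect scale (`mode = "endpoint"`) or through the lag-plus-logistic
#' growth model as an optical-density time-course (`mode = "timecourse"`),
#' with additive Gaussian noise (default SD 0.03 on the observation scale,
#' the variability typical of in vitro interaction read-outs). Negative noisy
#' observations are truncated at 0; the number of truncation events is
#' recorded. The RNG seed is stored so a dataset can be regenerated
#' bit-identically.
#'
#' @param model truth [interaction_model()] (two drugs).
#' @param design a [checkerboard_design()].
#' @param sigma additive Gaussian noise SD; `>= 0`.
#' @param seed integer RNG seed.
#' @param mode `"endpoint"` (effect-scale observation per well) or
#'   `"timecourse"` (OD observations over `times`).
#' @param growth a [growth_params()]; required for time-course mode.
#' @param times observation times (h) for time-course mode; default 20 points
#'   over 24 h.
#' @return An object of class `checkerboard_dataset` with elements `design`,
#'   `wells` (well table with per-well concentrations and, in endpoint mode,
#'   `effect_obs`), `timecourses` (long OD table or `NULL`), `truth`,
#'   `growth`, `sigma`, `seed`, `mode`, `drug_ids`, `n_truncated`.
#' @export
generate_checkerboard <- function(model, design, sigma = 0.03, seed = 1L,
                                  mode = c("endpoint", "timecourse"),
                                  growth = NULL,
                                  times = seq(0, 24, length.out = 20)) {
  mode <- match.arg(mode)
  stopifnot(inherits(model, "gpdi_model"), sigma >= 0)
  ids <- names(model$drugs)
  stopifnot(length(ids) == 2)
  wells <- design_wells(design)
  set.seed(as.integer(seed))
  n_trunc <- 0L
  timecourses <- NULL
  e_true <- as.numeric(combined_effect(model, stats::setNames(
    list(wells$conc_a, wells$conc_b), ids)))
  if (mode == "endpoint") {
    obs <- e_true + stats::rnorm(length(e_true), 0, sigma)
    n_trunc <- sum(obs < 0)
    wells$effect_true <- e_true
    wells$effect_obs <- pmax(obs, 0)
  } else {
    if (is.null(growth))
      stop("time-course mode requires 'growth' parameters", call. = FALSE)
    tc <- predict_checkerboard(growth, model, design, times)
    obs <- tc$od + stats::rnorm(nrow(tc), 0, sigma)
    n_trunc <- sum(obs < 0)
    tc$od_true <- tc$od
    tc$od <- pmax(obs, 0)
    timecourses <- tc
    wells$effect_true <- e_true
  }
  structure(list(design = design, wells = wells, timecourses = timecourses,
                 truth = model, growth = growth, sigma = sigma,
                 seed = as.integer(seed), mode = mode, drug_ids = ids,
                 n_truncated = n_trunc),
            class = "checkerboard_dataset")
}

#' @export
print.checkerboard_dataset <- function(x, ...) {
  cat("<checkerboard_dataset>", nrow(x$wells), "wells,", x$mode, "mode,",
      "drugs:", paste(x$drug_ids, collapse = " + "),
      sprintf("(sigma = %g, seed = %d)\n", x$sigma, x$seed))
  invisible(x)
}

#' Generate a sham (drug-versus-itself) checkerboard dataset
#'
#' Both axes of the checkerboard carry the same drug. Under Loewe Additivity
#' the truth surface is exactly `effect(C_A + C_B)` (dose substitution), so a
#' downstream interaction fit against Loewe should recover a shift near zero;
#' the spread of fitted shifts across sham replicates is what
#' [derive_margin()] turns into an empirical additivity margin. Under Bliss
#' Independence a drug cannot be independent of itself, so sham fits are
#' expected to drift towards apparent synergy.
#'
#' @param drug a sigmoidal [pd_drug()].
#' @param design a [checkerboard_design()].
#' @inheritParams generate_checkerboard
#' @param criterion additivity criterion generating the truth surface
#'   (default `"loewe"`, the dose-substitution sham truth).
#' @return a `checkerboard_dataset`; the two axis drugs are labeled
#'   `<id>.1` and `<id>.2`.
#' @export
generate_sham <- function(drug, design, sigma = 0.03, seed = 1L,
                          criterion = "loewe", mode = "endpoint",
                          growth = NULL, times = seq(0, 24, length.out = 20)) {
  stopifnot(inherits(drug, "pd_drug"))
  d1 <- drug; d1$drug_id <- paste0(drug$drug_id, ".1")
  d2 <- drug; d2$drug_id <- paste0(drug$drug_id, ".2")
  model <- interaction_model(list(d1, d2), list(), criterion = criterion)
  generate_checkerboard(model, design, sigma = sigma, seed = seed,
                        mode = mode, growth = growth, times = times)
}

#' Read or write checkerboard datasets as CSV
#'
#' Endpoint tables use columns
#' `well_id, drug_a, conc_a, drug_b, conc_b, effect`; time-course tables use
#' `well_id, drug_a, conc_a, drug_b, conc_b, time_h, od`.
#'
#' @param data a `checkerboard_dataset`.
#' @param path CSV file path.
#' @return `read_checkerboard()` returns a `checkerboard_dataset` (without
#'   truth attached).
#' @export
write_checkerboard <- function(data, path) {
  stopifnot(inherits(data, "checkerboard_dataset"))
  if (data$mode == "endpoint") {
    df <- data.frame(well_id = data$wells$well_id,
                     drug_a = data$drug_ids[1], conc_a = data$wells$conc_a,
                     drug_b = data$drug_ids[2], conc_b = data$wells$conc_b,
                     effect = data$wells$effect_obs)
  } else {
    df <- data$timecourses[, c("well_id", "drug_a", "conc_a", "drug_b",
                               "conc_b", "time_h", "od")]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_checkerboard
#' @export
read_checkerboard <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  mode <- if ("time_h" %in% names(df)) "timecourse" else "endpoint"
  ids <- c(df$drug_a[1], df$drug_b[1])
  if (mode == "endpoint") {
    wells <- data.frame(well_id = df$well_id, conc_a = df$conc_a,
                        conc_b = df$conc_b, effect_obs = df$effect)
    tc <- NULL
  } else {
    wells <- unique(df[, c("well_id", "conc_a", "conc_b")])
    tc <- df
  }
  tiers_a <- sort(unique(wells$conc_a)); tiers_b <- sort(unique(wells$conc_b))
  design <- checkerboard_design(tiers_a = tiers_a, tiers_b = tiers_b)
  structure(list(design = design, wells = wells, timecourses = tc,
                 truth = NULL, growth = NULL, sigma = NA_real_,
                 seed = NA_integer_, mode = mode, drug_ids = ids,
                 n_truncated = NA_integer_),
            class = "checkerboard_dataset")
}
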