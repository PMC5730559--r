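#' Checkerboard concentration design
#'
#' Factorial concentration grid of two drugs across dilution tiers including
#' zero. The canonical anti-infective screening layout is an 8-by-8 grid with
#' tiers from 0 to `c_max` in base-2 logarithmic steps, i.e. zero plus seven
#' two-fold dilutions ending at `c_max`; the linear alternative spaces the
#' tiers evenly from 0 to `c_max`.
#'
#' @param scheme `"log2"` or `"linear"` tier spacing (ignored when explicit
#'   tiers are supplied).
#' @param c_max highest concentration (default 8, arbitrary units).
#' @param n_tiers number of tiers per drug including zero (default 8).
#' @param tiers_a,tiers_b explicit tier vectors (must be sorted ascending and
#'   contain 0); override `scheme`/`c_max`/`n_tiers`.
#' @return An object of class `checkerboard_design`.
#' @export
checkerboard_design <- function(scheme = c("log2", "linear"), c_max = 8,
                                n_tiers = 8, tiers_a = NULL, tiers_b = NULL) {
  scheme <- match.arg(scheme)
  default_tiers <- function() {
    if (scheme == "log2") c(0, c_max / 2 ^ ((n_tiers - 2):0))
    else seq(0, c_max, length.out = n_tiers)
  }
  tiers_a <- tiers_a %||% default_tiers()
  tiers_b <- tiers_b %||% default_tiers()
  for (tiers in list(tiers_a, tiers_b)) {
    if (is.unsorted(tiers, strictly = TRUE) || tiers[1] != 0)
      stop("tiers must be strictly ascending and start at 0", call. = FALSE)
  }
  structure(list(tiers_a = tiers_a, tiers_b = tiers_b, scheme = scheme,
                 c_max = max(tiers_a, tiers_b)),
            class = "checkerboard_design")
}

#' @export
print.checkerboard_design <- function(x, ...) {
  cat("<checkerboard_design>", length(x$tiers_a), "x", length(x$tiers_b),
      "wells,", x$scheme, "spacing, c_max =", x$c_max, "\n")
  invisible(x)
}

# full factorial well table
design_wells <- function(design) {
  stopifnot(inherits(design, "checkerboard_design"))
  g <- expand.grid(conc_a = design$tiers_a, conc_b = design$tiers_b,
                   KEEP.OUT.ATTRS = FALSE)
  g$well_id <- sprintf("w%02d", seq_len(nrow(g)))
  g[, c("well_id", "conc_a", "conc_b")]
}
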