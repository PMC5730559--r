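# Directional shift table from interaction calls: one row per direction
# (perpetrator -> victim), with the outside-margin flag and polarity.
directional_shifts <- function(calls) {
  do.call(rbind, lapply(calls, function(cl) {
    m <- cl$margin
    data.frame(
      perpetrator = c(cl$pair[2], cl$pair[1]),
      victim = c(cl$pair[1], cl$pair[2]),
      shift = c(cl$shift_ab, cl$shift_ba),
      outside = c(cl$shift_ab < m$lower | cl$shift_ab > m$upper,
                  cl$shift_ba < m$lower | cl$shift_ba > m$upper),
      polarity = ifelse(c(cl$shift_ab, cl$shift_ba) < 0,
                        "synergistic", "antagonistic"),
      stringsAsFactors = FALSE)
  }))
}

#' Exclusive join of interaction calls across additivity criteria
#'
#' To avoid biasing conclusions towards a single additivity criterion, only
#' interactions that stick out under both the Loewe- and the Bliss-based
#' analyses are retained: a directed shift survives when it lies outside the
#' additivity margin under both criteria with the same polarity. The surviving
#' edge carries the Loewe-fitted shift as its primary value and the Bliss
#' shift as a secondary attribute. Directions whose polarity conflicts across
#' criteria are dropped and reported in the `"conflicts"` attribute.
#'
#' @param calls_loewe,calls_bliss lists of `interaction_call` objects covering
#'   the same drug pairs (Loewe- and Bliss-based fits of the same data).
#' @return data frame of surviving directed shifts with columns
#'   `perpetrator, victim, polarity, shift_loewe, shift_bliss`.
#' @export
join_exclusive <- function(calls_loewe, calls_bliss) {
  dl <- directional_shifts(calls_loewe)
  db <- directional_shifts(calls_bliss)
  key <- function(d) paste(d$perpetrator, d$victim, sep = "->")
  kl <- key(dl); kb <- key(db)
  if (!setequal(kl, kb)) {
    orphans <- c(setdiff(kl, kb), setdiff(kb, kl))
    stop("call sets cover different drug pairs: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  db <- db[match(kl, kb), , drop = FALSE]
  keep <- dl$outside & db$outside & dl$polarity == db$polarity
  conflict <- dl$outside & db$outside & dl$polarity != db$polarity
  out <- data.frame(perpetrator = dl$perpetrator[keep],
                    victim = dl$victim[keep],
                    polarity = dl$polarity[keep],
                    shift_loewe = dl$shift[keep],
                    shift_bliss = db$shift[keep],
                    stringsAsFactors = FALSE)
  attr(out, "conflicts") <- data.frame(
    perpetrator = dl$perpetrator[conflict], victim = dl$victim[conflict],
    shift_loewe = dl$shift[conflict], shift_bliss = db$shift[conflict])
  out
}

#' Build the directed perpetrator-victim interaction network
#'
#' Each surviving directed shift becomes one edge from the perpetrator to the
#' victim drug, synergistic when the victim EC50 is decreased (negative
#' shift) and antagonistic when increased. Per-drug profiles tally
#' perpetrator (out) and victim (in) edges by polarity and flag drugs that
#' act solely as perpetrators or solely as victims.
#'
#' @param edges data frame from [join_exclusive()] (or any table with columns
#'   `perpetrator, victim, polarity` and a shift column).
#' @param drugs optional character vector of all drug ids (so never-connected
#'   drugs appear in the profiles).
#' @return list with `edges` (the input), `profiles` (one row per drug) and
#'   `graph` (an [igraph::graph] with edge attributes).
#' @export
build_network <- function(edges, drugs = NULL) {
  drugs <- drugs %||% sort(unique(c(edges$perpetrator, edges$victim)))
  profiles <- do.call(rbind, lapply(drugs, function(d) {
    out <- edges[edges$perpetrator == d, , drop = FALSE]
    inn <- edges[edges$victim == d, , drop = FALSE]
    data.frame(drug_id = d,
               n_perpetrator_edges = nrow(out),
               n_victim_edges = nrow(inn),
               n_synergy_out = sum(out$polarity == "synergistic"),
               n_antagonism_out = sum(out$polarity == "antagonistic"),
               n_synergy_in = sum(inn$polarity == "synergistic"),
               n_antagonism_in = sum(inn$polarity == "antagonistic"),
               sole_perpetrator = nrow(out) > 0 && nrow(inn) == 0,
               sole_victim = nrow(inn) > 0 && nrow(out) == 0,
               stringsAsFactors = FALSE)
  }))
  g <- igraph::graph_from_data_frame(
    edges[, c("perpetrator", "victim",
              setdiff(names(edges), c("perpetrator", "victim")))],
    directed = TRUE, vertices = data.frame(name = drugs))
  structure(list(edges = edges, profiles = profiles, graph = g),
            class = "gpdi_network")
}

#' @export
print.gpdi_network <- function(x, ...) {
  cat("<gpdi_network>", nrow(x$profiles), "drugs,", nrow(x$edges), "edges\n")
  invisible(x)
}

#' Export a network in text formats
#'
#' Writes the edge list and drug profiles as CSV, or the graph itself as
#' GraphML/DOT via igraph.
#'
#' @param network a `gpdi_network` from [build_network()].
#' @param edges_path,profiles_path,graph_path output paths (each optional).
#' @param graph_format `"graphml"` or `"dot"`.
#' @export
write_network <- function(network, edges_path = NULL, profiles_path = NULL,
                          graph_path = NULL,
                          graph_format = c("graphml", "dot")) {
  graph_format <- match.arg(graph_format)
  if (!is.null(edges_path))
    utils::write.csv(network$edges, edges_path, row.names = FALSE)
  if (!is.null(profiles_path))
    utils::write.csv(network$profiles, profiles_path, row.names = FALSE)
  if (!is.null(graph_path))
    igraph::write_graph(network$graph, graph_path, format = graph_format)
  invisible(network)
}
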