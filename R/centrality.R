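# Centrality prioritization: degree, betweenness and closeness on each
# entity subnetwork, strict above-average selection, and assembly of the
# Boolean entity-by-gene membership matrices.

#' Centrality scores of a subnetwork
#'
#' Degree is the number of incident edges. Betweenness is unnormalized
#' shortest-path betweenness (each unordered pair of distinct endpoints
#' counted once, fractional credit for tied shortest paths). Closeness is
#' computed within connected components: for a node in a component of size
#' `c >= 2` it is `(c - 1)` divided by the sum of its distances to the rest
#' of the component; isolated nodes score 0. The downstream strict-mean
#' selection rule is invariant to any uniform rescaling of a measure, so
#' these conventions only need to be fixed, not universal.
#'
#' @param s A [induce_subnetwork()] result.
#' @param measure `"degree"`, `"betweenness"` or `"closeness"`.
#' @return Named numeric vector of class `"centrality_vector"` with
#'   attributes `measure` and `entity`.
#' @export
centrality_scores <- function(s, measure = c("degree", "betweenness", "closeness")) {
  measure <- match.arg(measure)
  stopifnot(inherits(s, "subnetwork"))
  g <- subnetwork_graph(s)
  scores <- switch(measure,
    degree = igraph::degree(g, loops = FALSE),
    betweenness = igraph::betweenness(g, directed = FALSE, normalized = FALSE),
    closeness = component_closeness(g))
  scores <- scores[names(s$nodes)]
  structure(as.numeric(scores), names = names(s$nodes),
            class = "centrality_vector", measure = measure, entity = s$entity)
}

# Closeness within components; isolated nodes get 0.
component_closeness <- function(g) {
  comp <- igraph::components(g)
  out <- numeric(igraph::vcount(g))
  names(out) <- igraph::V(g)$name
  for (ci in seq_len(comp$no)) {
    members <- which(comp$membership == ci)
    if (length(members) < 2L) next
    d <- igraph::distances(g, v = members, to = members)
    out[members] <- (length(members) - 1) / rowSums(d)
  }
  out
}

#' Convenience wrappers for the three measures
#' @param s A [induce_subnetwork()] result.
#' @return A `"centrality_vector"`.
#' @export
degree_centrality <- function(s) centrality_scores(s, "degree")

#' @rdname degree_centrality
#' @export
betweenness_centrality <- function(s) centrality_scores(s, "betweenness")

#' @rdname degree_centrality
#' @export
closeness_centrality <- function(s) centrality_scores(s, "closeness")

#' Select genes with above-average centrality
#'
#' Keeps nodes whose score strictly exceeds the mean score of the
#' subnetwork. Comparing against the mean of all genes or against the mean
#' of all *other* genes is algebraically the same selection
#' (`x > (S - x)/(n - 1)` iff `x > S/n`), so both readings of the rule
#' coincide. The result may be empty (e.g. a regular graph, where every
#' score equals the mean); empty selections propagate as all-zero membership
#' rows.
#'
#' @param scores A [centrality_scores()] result (or any named numeric
#'   vector).
#' @return Character vector of selected gene ids.
#' @export
select_above_average <- function(scores) {
  if (length(scores) == 0L) stop("empty centrality vector", call. = FALSE)
  names(scores)[scores > mean(scores)]
}

#' Assemble per-entity gene selections into a Boolean membership matrix
#'
#' @param selections Named list (entity -> character vector of selected
#'   genes).
#' @param universe A [gene_universe()].
#' @param source,measure Provenance labels, see [membership_matrix()].
#' @return A [membership_matrix()].
#' @export
build_membership_matrix <- function(selections, universe,
                                    source = c("text", "expression", "combined"),
                                    measure = c("degree", "betweenness",
                                                "closeness", "none")) {
  genes <- as.character(universe)
  unknown <- setdiff(unique(unlist(selections, use.names = FALSE)), genes)
  if (length(unknown)) {
    stop("selected gene(s) outside the universe: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  values <- matrix(FALSE, nrow = length(selections), ncol = length(genes),
                   dimnames = list(names(selections), genes))
  for (ent in names(selections)) values[ent, selections[[ent]]] <- TRUE
  membership_matrix(values, universe, match.arg(source), match.arg(measure))
}

#' Build one membership matrix from signatures and a reference network
#'
#' The per-source prioritization stage in one call: for every entity, induce
#' the signature subnetwork from the reference, score it with the chosen
#' centrality measure, apply the strict above-average rule, and collect the
#' selections into a Boolean matrix. Restricts selected genes to the
#' universe (neighbor nodes outside it cannot become members). Entities with
#' empty signatures yield all-zero rows.
#'
#' @param signatures Named list (entity -> character vector of signature
#'   genes; empty vectors allowed).
#' @param reference An [interaction_network()].
#' @param universe A [gene_universe()].
#' @param source Provenance label for the matrix.
#' @param measure Centrality measure.
#' @return A [membership_matrix()].
#' @export
prioritize_entities <- function(signatures, reference, universe,
                                source = c("text", "expression", "combined"),
                                measure = c("degree", "betweenness", "closeness")) {
  measure <- match.arg(measure)
  genes <- as.character(universe)
  selections <- lapply(names(signatures), function(ent) {
    sig <- signatures[[ent]]
    if (length(sig) == 0L) return(character())
    s <- induce_subnetwork(sig, reference, entity = ent)
    intersect(select_above_average(centrality_scores(s, measure)), genes)
  })
  names(selections) <- names(signatures)
  build_membership_matrix(selections, universe, match.arg(source), measure)
}
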