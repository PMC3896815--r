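# Entity-specific subnetworks: an entity's signature genes plus their direct
# neighbors, with all edges induced from a source-specific reference network.

#' Merge several reference networks into one
#'
#' Edge-set union of networks over the same universe (e.g. a functional
#' protein-interaction network unioned with a signaling network).
#'
#' @param nets List of [interaction_network()] objects.
#' @return An [interaction_network()] whose source label concatenates the
#'   inputs'.
#' @export
merge_reference_networks <- function(nets) {
  stopifnot(length(nets) >= 1L)
  genes <- as.character(nets[[1L]]$universe)
  for (nw in nets) {
    if (!inherits(nw, "interaction_network") ||
        !identical(as.character(nw$universe), genes)) {
      stop("all networks must share one universe", call. = FALSE)
    }
  }
  edges <- do.call(rbind, lapply(nets, `[[`, "edges"))
  interaction_network(edges[, 1L], edges[, 2L], nets[[1L]]$universe,
                      source = paste(vapply(nets, `[[`, "", "source"),
                                     collapse = "+"))
}

#' Induce an entity-specific subnetwork around a gene signature
#'
#' Nodes are the signature genes plus their direct neighbors in the reference
#' network; edges are every reference edge with both endpoints among those
#' nodes (the full induced subgraph, so neighbor-neighbor edges are kept and
#' centrality reflects the complete local topology). Signature genes absent
#' from the reference survive as isolated nodes so downstream centrality sees
#' them with score 0.
#'
#' @param signature Non-empty character vector of gene ids.
#' @param reference An [interaction_network()].
#' @param entity Entity identifier.
#' @return A list of class `"subnetwork"`: `nodes` (named flag vector,
#'   `"signature"`/`"neighbor"`), `edges` (two-column matrix), `entity`,
#'   `source`.
#' @export
induce_subnetwork <- function(signature, reference, entity = "entity") {
  stopifnot(inherits(reference, "interaction_network"))
  signature <- unique(as.character(signature))
  if (length(signature) == 0L) stop("empty signature", call. = FALSE)
  unknown <- setdiff(signature, as.character(reference$universe))
  if (length(unknown)) {
    stop("signature gene(s) outside the universe: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  e <- reference$edges
  touches <- e[, 1L] %in% signature | e[, 2L] %in% signature
  nbrs <- setdiff(unique(c(e[touches, 1L], e[touches, 2L])), signature)
  nodes <- c(signature, nbrs)
  keep <- e[, 1L] %in% nodes & e[, 2L] %in% nodes
  flags <- c(rep("signature", length(signature)), rep("neighbor", length(nbrs)))
  names(flags) <- nodes
  structure(list(nodes = flags, edges = e[keep, , drop = FALSE],
                 entity = entity, source = reference$source),
            class = "subnetwork")
}

#' @export
print.subnetwork <- function(x, ...) {
  cat("Subnetwork [", x$entity, "]: ", sum(x$nodes == "signature"),
      " signature + ", sum(x$nodes == "neighbor"), " neighbor nodes, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

# igraph view of a subnetwork, keeping isolated nodes.
subnetwork_graph <- function(s) {
  igraph::graph_from_data_frame(
    as.data.frame(s$edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = names(s$nodes), stringsAsFactors = FALSE))
}
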