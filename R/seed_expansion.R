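# Seed expansion: extended gene lists (DrugExt / DiseaseExt) built by adding
# the direct interaction-network neighbors of each entity's seed genes.
# Expansion is exactly one hop, never a transitive closure.

#' Expand entity seed sets by one network hop
#'
#' For every entity, the extended set is the seed genes plus every gene that
#' shares at least one edge with a seed. Seeds absent from the network are
#' kept with no neighbors: curated seed genes are retained regardless of
#' interactome coverage.
#'
#' @param seeds A [seed_map()].
#' @param network An [interaction_network()] over the same universe.
#' @return A named list of class `"extended_seed_map"`; per entity, a named
#'   character vector mapping gene id to flag `"seed"` or `"neighbor"`.
#' @export
expand_seeds <- function(seeds, network) {
  stopifnot(inherits(seeds, "seed_map"), inherits(network, "interaction_network"))
  adj <- adjacency_list(network)
  out <- lapply(seeds, function(sg) {
    nb <- setdiff(unique(unlist(adj[sg], use.names = FALSE)), sg)
    flags <- c(rep("seed", length(sg)), rep("neighbor", length(nb)))
    names(flags) <- c(sg, nb)
    flags
  })
  rn_info("expanded %d entit(ies): %d seed genes -> %d extended genes",
          length(seeds), length(unique(unlist(seeds, use.names = FALSE))),
          length(unique(unlist(lapply(out, names), use.names = FALSE))))
  structure(out, class = "extended_seed_map", kind = attr(seeds, "kind"))
}

adjacency_list <- function(network) {
  e <- network$edges
  if (nrow(e) == 0L) return(list())
  split(c(e[, 2L], e[, 1L]), c(e[, 1L], e[, 2L]))
}

#' Drop expansion flags, returning a plain seed map
#' @param extended An [expand_seeds()] result.
#' @param universe A [gene_universe()] containing all extended genes.
#' @return A [seed_map()].
#' @export
as_seed_map <- function(extended, universe) {
  stopifnot(inherits(extended, "extended_seed_map"))
  seed_map(lapply(extended, names), universe,
           kind = attr(extended, "kind") %||% "drug")
}

#' Build the shared gene universe from both expanded seed maps
#'
#' The universe over which the whole pipeline is indexed: the union of the
#' one-hop expansions of every drug and every disease, ordered
#' lexicographically for reproducibility.
#'
#' @param drug_seeds,disease_seeds [seed_map()] objects.
#' @param network The [interaction_network()] used for expansion.
#' @return A [gene_universe()].
#' @export
union_universe <- function(drug_seeds, disease_seeds, network) {
  ext_drug <- expand_seeds(drug_seeds, network)
  ext_dis <- expand_seeds(disease_seeds, network)
  genes <- unique(c(unlist(lapply(ext_drug, names), use.names = FALSE),
                    unlist(lapply(ext_dis, names), use.names = FALSE)))
  if (length(genes) == 0L) stop("union of expanded seed sets is empty", call. = FALSE)
  gene_universe(sort(genes, method = "radix"))
}

#' Write an extended seed map as TSV (entity, gene, flag)
#' @param extended An [expand_seeds()] result.
#' @param path Output path.
#' @export
write_extended_seed_map <- function(extended, path) {
  df <- data.frame(entity = rep(names(extended), lengths(extended)),
                   gene = unlist(lapply(extended, names), use.names = FALSE),
                   flag = unlist(extended, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
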