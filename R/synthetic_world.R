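# Synthetic world: a complete, internally consistent input bundle with
# planted drug-disease associations, emulating the real pipeline inputs
# (seed maps, interaction networks, literature co-occurrence counts, ranked
# drug profiles, case/control disease expression, gold standard) so every
# stage is testable end-to-end without database access.

#' Configuration of the synthetic world
#'
#' Defaults mirror the study conditions where those are stated (a 2343-gene
#' universe; rank-1 = most up-regulated profiles; top/bottom-25 signatures
#' downstream) and otherwise use values a desk-scale benchmark would call
#' realistic: 50 drugs, 8 diseases, 10 planted pairs sharing 30-gene
#' modules, scale-free reference networks via preferential attachment,
#' overdispersed (negative-binomial) literature counts whose planted cells
#' have their mean scaled by `enrichment`, and unit-variance Gaussian
#' expression noise with a `shift`-sized mean offset on planted module
#' genes.
#'
#' @param n_genes Universe size.
#' @param n_drugs,n_diseases Entity counts.
#' @param n_planted Number of planted (disease, drug) pairs; at most
#'   `n_drugs * n_diseases`.
#' @param module_size Genes shared by each planted pair.
#' @param attachment Edges added per node in the preferential-attachment
#'   reference networks.
#' @param hub_bias Probability that a module gene is drawn from the
#'   high-degree pool (top degree quintile) rather than uniformly; planted
#'   modules overlapping the hub region give centrality selection signal to
#'   find.
#' @param base_rate Mean of the background negative-binomial co-mention
#'   count.
#' @param dispersion Negative-binomial size parameter for all counts.
#' @param enrichment Multiplier on `base_rate` for planted entity-module
#'   cells; 1 plants no literature signal.
#' @param shift Expression offset (in `noise_sd` units) on planted module
#'   genes; 0 plants no expression signal.
#' @param noise_sd Expression noise standard deviation.
#' @param n_case,n_control Disease samples per group.
#' @param n_replicates Replicate ranked lists per drug.
#' @param seed_size Seed genes per entity in the curated-style seed maps.
#' @param signal `"both"`: every planted pair carries literature and
#'   expression signal; `"complementary"`: pairs alternate between
#'   literature-only and expression-only, so the combined source must
#'   outperform either single source.
#' @param seed Integer RNG seed; the whole world is a deterministic function
#'   of the config.
#' @return A list of class `"world_config"`.
#' @export
world_config <- function(n_genes = 2343L, n_drugs = 50L, n_diseases = 8L,
                         n_planted = 10L, module_size = 30L,
                         attachment = 3L, hub_bias = 0.7,
                         base_rate = 0.5, dispersion = 1, enrichment = 40,
                         shift = 3, noise_sd = 1,
                         n_case = 4L, n_control = 4L, n_replicates = 3L,
                         seed_size = 10L,
                         signal = c("both", "complementary"),
                         seed = 1L) {
  signal <- match.arg(signal)
  cfg <- list(n_genes = as.integer(n_genes), n_drugs = as.integer(n_drugs),
              n_diseases = as.integer(n_diseases),
              n_planted = as.integer(n_planted),
              module_size = as.integer(module_size),
              attachment = as.integer(attachment), hub_bias = hub_bias,
              base_rate = base_rate, dispersion = dispersion,
              enrichment = enrichment, shift = shift, noise_sd = noise_sd,
              n_case = as.integer(n_case), n_control = as.integer(n_control),
              n_replicates = as.integer(n_replicates),
              seed_size = as.integer(seed_size), signal = signal,
              seed = as.integer(seed))
  if (cfg$n_planted > cfg$n_drugs * cfg$n_diseases) {
    stop("more planted pairs than drug-disease pairs", call. = FALSE)
  }
  if (cfg$n_planted > cfg$n_drugs) {
    stop("planted pairs must use distinct drugs: n_planted <= n_drugs", call. = FALSE)
  }
  if (cfg$module_size > cfg$n_genes) stop("module larger than universe", call. = FALSE)
  if (cfg$hub_bias < 0 || cfg$hub_bias > 1) stop("hub_bias must be in [0,1]", call. = FALSE)
  if (cfg$enrichment < 1) stop("enrichment must be >= 1", call. = FALSE)
  if (cfg$shift < 0 || cfg$noise_sd <= 0 || cfg$base_rate <= 0 || cfg$dispersion <= 0) {
    stop("rates, noise and dispersion must be positive; shift non-negative",
         call. = FALSE)
  }
  if (cfg$n_case < 2L || cfg$n_control < 2L) {
    stop("need at least 2 samples per expression group", call. = FALSE)
  }
  structure(cfg, class = "world_config")
}

#' Generate a synthetic world
#'
#' Deterministic given the config: two scale-free reference networks (one
#' per evidence source), curated-style seed maps, a co-occurrence table with
#' consistent marginals, replicate ranked drug profiles, case/control
#' disease expression, and the planted-pair ground truth that doubles as
#' the gold-standard positives.
#'
#' @param config A [world_config()].
#' @return A list of class `"synthetic_world"`.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  local_seed(config$seed, generate_world_impl(config))
}

generate_world_impl <- function(cfg) {
  genes <- sprintf("g%04d", seq_len(cfg$n_genes))
  universe <- gene_universe(genes)
  drugs <- sprintf("drug%03d", seq_len(cfg$n_drugs))
  diseases <- sprintf("disease%02d", seq_len(cfg$n_diseases))

  text_net <- pa_network(genes, cfg$attachment, universe, "text-mining")
  expr_net <- pa_network(genes, cfg$attachment, universe, "functional-ppi")

  deg <- table(factor(c(text_net$edges, expr_net$edges), levels = genes))
  hub_pool <- genes[rank(-as.numeric(deg), ties.method = "first") <=
                      ceiling(cfg$n_genes / 5)]

  # planted pairs: distinct drugs, diseases cycled in random order
  p_drugs <- sample(drugs, cfg$n_planted)
  p_dis <- rep(sample(diseases), length.out = cfg$n_planted)
  src <- if (cfg$signal == "both") rep("both", cfg$n_planted) else
    rep(c("text", "expression"), length.out = cfg$n_planted)
  modules <- lapply(seq_len(cfg$n_planted), function(i) {
    n_hub <- min(round(cfg$hub_bias * cfg$module_size), length(hub_pool))
    m <- c(sample(hub_pool, n_hub),
           sample(setdiff(genes, hub_pool), cfg$module_size - n_hub))
    sample(m)  # direction assignment below uses module order
  })
  truth <- data.frame(disease = p_dis, drug = p_drugs, source = src,
                      stringsAsFactors = FALSE)

  # curated-style seed maps: planted entities seed from their modules
  seed_genes <- function(ids, planted_ids) {
    out <- lapply(ids, function(id) {
      hit <- which(planted_ids == id)
      if (length(hit)) {
        mods <- unique(unlist(modules[hit], use.names = FALSE))
        sample(mods, min(cfg$seed_size, length(mods)))
      } else {
        sample(genes, cfg$seed_size)
      }
    })
    names(out) <- ids
    out
  }
  drug_seeds <- seed_map(seed_genes(drugs, p_drugs), universe, "drug")
  disease_seeds <- seed_map(seed_genes(diseases, p_dis), universe, "disease")

  # co-occurrence counts for all entities over the universe
  entities <- c(drugs, diseases)
  counts <- matrix(stats::rnbinom(length(entities) * cfg$n_genes,
                                  size = cfg$dispersion, mu = cfg$base_rate),
                   nrow = length(entities),
                   dimnames = list(entities, genes))
  for (i in seq_len(cfg$n_planted)) {
    if (src[i] == "expression") next
    mu <- cfg$base_rate * cfg$enrichment
    for (ent in c(p_drugs[i], p_dis[i])) {
      counts[ent, modules[[i]]] <-
        stats::rnbinom(cfg$module_size, size = cfg$dispersion, mu = mu)
    }
  }
  entity_extra <- stats::rnbinom(length(entities), size = 10, mu = 200)
  gene_extra <- stats::rnbinom(cfg$n_genes, size = 10, mu = 100)
  entity_abs <- rowSums(counts) + entity_extra
  gene_abs <- colSums(counts) + gene_extra
  names(entity_abs) <- entities
  names(gene_abs) <- genes
  n_total <- sum(counts) + sum(entity_extra) + sum(gene_extra) + 10000
  cooccurrence <- list(
    drugs = cooccurrence_table(counts[drugs, , drop = FALSE],
                               entity_abs[drugs], gene_abs, n_total, universe),
    diseases = cooccurrence_table(counts[diseases, , drop = FALSE],
                                  entity_abs[diseases], gene_abs, n_total,
                                  universe))

  # expression direction per module gene: first half up, second half down
  module_effect <- function(hits) {
    eff <- stats::setNames(numeric(cfg$n_genes), genes)
    for (i in hits) {
      if (src[i] == "text") next
      m <- modules[[i]]
      half <- ceiling(length(m) / 2)
      eff[m[seq_len(half)]] <- cfg$shift
      eff[m[-seq_len(half)]] <- -cfg$shift
    }
    eff
  }
  drug_profiles <- lapply(drugs, function(dr) {
    eff <- module_effect(which(p_drugs == dr))
    lapply(seq_len(cfg$n_replicates), function(r) {
      rank_from_scores(eff + stats::rnorm(cfg$n_genes, 0, cfg$noise_sd),
                       entity = dr)
    })
  })
  names(drug_profiles) <- drugs
  disease_expression <- lapply(diseases, function(ds) {
    eff <- module_effect(which(p_dis == ds))
    n_s <- cfg$n_case + cfg$n_control
    vals <- matrix(stats::rnorm(cfg$n_genes * n_s, 0, cfg$noise_sd),
                   nrow = cfg$n_genes,
                   dimnames = list(genes, sprintf("%s_s%02d", ds, seq_len(n_s))))
    vals[, seq_len(cfg$n_case)] <- vals[, seq_len(cfg$n_case)] + eff
    expression_matrix(vals, rep(c("case", "control"),
                                c(cfg$n_case, cfg$n_control)))
  })
  names(disease_expression) <- diseases

  # every pair not planted has no shared module: negative candidate pool
  all_pairs <- expand.grid(disease = diseases, drug = drugs,
                           stringsAsFactors = FALSE)[, c("disease", "drug")]
  candidates <- all_pairs[!(pair_key(all_pairs) %in% pair_key(truth)), ,
                          drop = FALSE]

  structure(list(config = cfg, universe = universe,
                 drug_seeds = drug_seeds, disease_seeds = disease_seeds,
                 text_network = text_net, expr_network = expr_net,
                 cooccurrence = cooccurrence,
                 drug_profiles = drug_profiles,
                 disease_expression = disease_expression,
                 truth = truth, modules = modules,
                 negative_candidates = candidates),
            class = "synthetic_world")
}

# scale-free-like undirected network over gene ids, vertex order shuffled so
# hubness is independent of lexicographic order
pa_network <- function(genes, attachment, universe, source) {
  g <- igraph::sample_pa(length(genes), m = attachment, directed = FALSE)
  perm <- sample(genes)
  e <- igraph::as_edgelist(g, names = FALSE)
  interaction_network(perm[e[, 1L]], perm[e[, 2L]], universe, source)
}

#' @export
print.synthetic_world <- function(x, ...) {
  print(world_report(x))
  invisible(x)
}

#' Summary report of a synthetic world
#'
#' @param world A [generate_world()] result.
#' @return A data frame of counts (genes, entities, edges per network,
#'   planted pairs, mean module size).
#' @export
world_report <- function(world) {
  stopifnot(inherits(world, "synthetic_world"))
  data.frame(
    quantity = c("genes", "drugs", "diseases", "text_edges", "expr_edges",
                 "planted_pairs", "mean_module_size"),
    value = c(length(world$universe), length(world$drug_seeds),
              length(world$disease_seeds), nrow(world$text_network$edges),
              nrow(world$expr_network$edges), nrow(world$truth),
              if (length(world$modules)) mean(lengths(world$modules)) else 0),
    stringsAsFactors = FALSE)
}

#' Write all files of a synthetic world to a directory
#'
#' Emits every pipeline input in its TSV format plus `truth.tsv` (the
#' planted pairs and their signal source).
#'
#' @param world A [generate_world()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_world <- function(world, dir) {
  stopifnot(inherits(world, "synthetic_world"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  write_gene_universe(world$universe, p("universe.txt"))
  write_seed_map(world$drug_seeds, p("drug_seeds.tsv"))
  write_seed_map(world$disease_seeds, p("disease_seeds.tsv"))
  write_edge_list(world$text_network, p("text_network.tsv"))
  write_edge_list(world$expr_network, p("expr_network.tsv"))
  for (kind in names(world$cooccurrence)) {
    tab <- world$cooccurrence[[kind]]
    utils::write.table(data.frame(entity = rownames(tab$counts), tab$counts,
                                  check.names = FALSE),
                       p(paste0("cooccurrence_", kind, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(entity = names(tab$entity_abs),
                                  abstracts = as.integer(tab$entity_abs)),
                       p(paste0("entity_abstracts_", kind, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(data.frame(gene = names(world$cooccurrence$drugs$gene_abs),
                                abstracts = as.integer(world$cooccurrence$drugs$gene_abs)),
                     p("gene_abstracts.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  writeLines(as.character(world$cooccurrence$drugs$n_total), p("corpus_size.txt"))
  for (dr in names(world$drug_profiles)) {
    reps <- world$drug_profiles[[dr]]
    for (r in seq_along(reps)) {
      utils::write.table(data.frame(gene = names(reps[[r]]),
                                    rank = as.integer(reps[[r]])),
                         p(sprintf("ranks_%s_rep%d.tsv", dr, r)),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  for (ds in names(world$disease_expression)) {
    m <- world$disease_expression[[ds]]
    utils::write.table(data.frame(gene = rownames(m$values), m$values,
                                  check.names = FALSE),
                       p(sprintf("expression_%s.tsv", ds)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(data.frame(sample = colnames(m$values), label = m$labels),
                       p(sprintf("labels_%s.tsv", ds)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(world$truth, p("truth.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(dir)
}
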