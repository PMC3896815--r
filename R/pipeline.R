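# End-to-end orchestration: signatures -> subnetworks -> centrality
# membership matrices -> per-disease lasso-logistic association -> ROC
# against the gold standard.

#' Literature-based signatures for one entity kind
#'
#' Filter low co-occurrence counts, score with the connectivity measure, and
#' keep the strictly positive genes per entity.
#'
#' @param cooccur A [cooccurrence_table()].
#' @param config A [pipeline_config()].
#' @return Named list (entity -> character vector of genes).
#' @export
text_signatures <- function(cooccur, config = pipeline_config()) {
  tab <- filter_cooccurrence(cooccur, config$min_cooccurrence)
  suppressWarnings(select_positive(score_table(tab, config)))
}

#' Expression-based signatures for drugs (replicate rank lists)
#'
#' Merges each drug's replicate ranked profiles and takes the top/bottom-k
#' tails.
#'
#' @param profiles Named list (drug -> list of [ranked_profile()]).
#' @param config A [pipeline_config()].
#' @return Named list (drug -> character vector of genes).
#' @export
drug_expression_signatures <- function(profiles, config = pipeline_config()) {
  out <- lapply(names(profiles), function(dr) {
    select_signature(merge_ranked_lists(profiles[[dr]], entity = dr),
                     k = config$tail_k)
  })
  names(out) <- names(profiles)
  out
}

#' Expression-based signatures for diseases (case/control matrices)
#'
#' Scores each disease matrix with the SAM-style statistic, ranks the genes,
#' and takes the top/bottom-k tails.
#'
#' @param expr Named list (disease -> [expression_matrix()]).
#' @param config A [pipeline_config()].
#' @return Named list (disease -> character vector of genes).
#' @export
disease_expression_signatures <- function(expr, config = pipeline_config()) {
  out <- lapply(names(expr), function(ds) {
    d <- sam_score(expr[[ds]], s0 = config$s0)
    select_signature(rank_from_scores(d, entity = ds), k = config$tail_k)
  })
  names(out) <- names(expr)
  out
}

#' Run the full pipeline on a synthetic world
#'
#' Builds, for every requested evidence source and centrality measure, the
#' drug and disease Boolean membership matrices, fits the per-disease
#' association model, and evaluates each configuration against the world's
#' gold standard (planted pairs as positives, sampled non-planted pairs as
#' negatives).
#'
#' @param world A [generate_world()] result.
#' @param config A [pipeline_config()].
#' @param measures Centrality measures to run.
#' @param sources Evidence sources to run; `"combined"` requires both
#'   `"text"` and `"expression"`.
#' @param n_negatives Negative pairs to sample for the gold standard
#'   (truncated to the candidate pool size; 400 echoes the published
#'   protocol).
#' @return A list of class `"pipeline_result"`: `memberships` (nested
#'   source -> measure -> list(drugs, diseases)), `associations` (per
#'   source/measure label), `gold`, `evaluation` (label/AUC table,
#'   best-first).
#' @export
run_pipeline <- function(world, config = pipeline_config(),
                         measures = config$centrality,
                         sources = c("text", "expression", "combined"),
                         n_negatives = 400L) {
  stopifnot(inherits(world, "synthetic_world"))
  sources <- match.arg(sources, c("text", "expression", "combined"),
                       several.ok = TRUE)
  measures <- match.arg(measures, c("degree", "betweenness", "closeness"),
                        several.ok = TRUE)
  need <- unique(c(sources, if ("combined" %in% sources) c("text", "expression")))

  sigs <- list()
  if ("text" %in% need) {
    sigs$text <- list(
      drugs = text_signatures(world$cooccurrence$drugs, config),
      diseases = text_signatures(world$cooccurrence$diseases, config))
  }
  if ("expression" %in% need) {
    sigs$expression <- list(
      drugs = drug_expression_signatures(world$drug_profiles, config),
      diseases = disease_expression_signatures(world$disease_expression, config))
  }
  refs <- list(text = world$text_network, expression = world$expr_network)

  memberships <- list()
  for (src in intersect(c("text", "expression"), need)) {
    for (ms in measures) {
      memberships[[src]][[ms]] <- list(
        drugs = prioritize_entities(sigs[[src]]$drugs, refs[[src]],
                                    world$universe, src, ms),
        diseases = prioritize_entities(sigs[[src]]$diseases, refs[[src]],
                                       world$universe, src, ms))
    }
  }
  if ("combined" %in% sources) {
    for (ms in measures) {
      memberships$combined[[ms]] <- list(
        drugs = combine_sources(memberships$text[[ms]]$drugs,
                                memberships$expression[[ms]]$drugs),
        diseases = combine_sources(memberships$text[[ms]]$diseases,
                                   memberships$expression[[ms]]$diseases))
    }
  }

  associations <- list()
  for (src in sources) {
    for (ms in measures) {
      m <- memberships[[src]][[ms]]
      associations[[paste(src, ms, sep = "_")]] <-
        suppressWarnings(build_association_matrix(m$diseases, m$drugs, config))
    }
  }

  n_neg <- min(n_negatives, nrow(world$negative_candidates))
  gold <- gold_standard(world$truth[, c("disease", "drug")],
                        sample_negatives(world$negative_candidates, n_neg,
                                         seed = config$seed))
  structure(list(memberships = memberships, associations = associations,
                 gold = gold,
                 evaluation = compare_configurations(associations, gold)),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Pipeline run:", length(x$associations), "configuration(s)\n")
  print(x$evaluation, row.names = FALSE)
  invisible(x)
}
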