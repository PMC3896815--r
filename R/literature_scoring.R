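# Literature co-occurrence scoring: the regularized log-odds connectivity
# score turns abstract co-mention counts into per-entity gene sets
# (Txt-DrugExt / Txt-DiseaseExt).

#' Construct an abstract co-occurrence table
#'
#' Holds, for one entity kind, the number of abstracts co-mentioning each
#' entity with each gene (`counts`), the per-entity and per-gene abstract
#' totals, and the corpus size. Consistency requires every cell to be at most
#' the smaller of its two marginals and the corpus size to dominate every
#' marginal.
#'
#' @param counts Non-negative integer matrix, entities in rows, genes in
#'   columns following the universe order.
#' @param entity_abs Named non-negative vector of per-entity abstract counts.
#' @param gene_abs Named non-negative vector of per-gene abstract counts, in
#'   universe order.
#' @param n_total Total number of abstracts in the corpus.
#' @param universe A [gene_universe()].
#' @param on_inconsistent `"error"` (used for generated data) or `"warn"`
#'   (tolerant mode for user-supplied literature extractions, which can be
#'   internally inconsistent).
#' @return A list of class `"cooccurrence_table"`.
#' @export
cooccurrence_table <- function(counts, entity_abs, gene_abs, n_total, universe,
                               on_inconsistent = c("error", "warn")) {
  on_inconsistent <- match.arg(on_inconsistent)
  stopifnot(is.matrix(counts))
  genes <- as.character(universe)
  if (is.null(colnames(counts))) colnames(counts) <- genes
  check_universe_columns(counts, universe, "co-occurrence counts")
  if (is.null(rownames(counts))) stop("counts need entity row names", call. = FALSE)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  entity_abs <- entity_abs[rownames(counts)]
  gene_abs <- gene_abs[genes]
  if (anyNA(entity_abs) || anyNA(gene_abs)) {
    stop("marginals must cover every entity and gene", call. = FALSE)
  }
  cap <- outer(as.numeric(entity_abs), as.numeric(gene_abs), pmin)
  bad <- counts > cap
  if (any(bad) || n_total < max(entity_abs, gene_abs, 0)) {
    msg <- sprintf("inconsistent co-occurrence table: %d cell(s) exceed a marginal%s",
                   sum(bad),
                   if (n_total < max(entity_abs, gene_abs, 0)) "; corpus size below a marginal" else "")
    if (on_inconsistent == "error") stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  structure(list(counts = counts, entity_abs = entity_abs, gene_abs = gene_abs,
                 n_total = n_total, universe = universe),
            class = "cooccurrence_table")
}

#' @export
print.cooccurrence_table <- function(x, ...) {
  cat("Co-occurrence table: ", nrow(x$counts), " entities x ", ncol(x$counts),
      " genes, corpus size ", x$n_total, "\n", sep = "")
  invisible(x)
}

#' Zero out low co-occurrence counts
#'
#' Co-mention counts are vulnerable to false positives, so any entity-gene
#' cell strictly below `min_count` is set to zero before scoring (default
#' threshold 5). Marginals and the corpus size are left untouched.
#'
#' @param table A [cooccurrence_table()].
#' @param min_count Non-negative integer threshold; 0 is the identity.
#' @return The filtered [cooccurrence_table()].
#' @export
filter_cooccurrence <- function(table, min_count = 5L) {
  stopifnot(inherits(table, "cooccurrence_table"), min_count >= 0)
  zeroed <- table$counts > 0 & table$counts < min_count
  table$counts[zeroed] <- 0L
  rn_info("co-occurrence filter (<%d): zeroed %d of %d nonzero cell(s)",
          min_count, sum(zeroed), sum(zeroed) + sum(table$counts > 0))
  table
}

#' Regularized log-odds connectivity score between an entity and a gene
#'
#' Two variants are available. The original form contrasts the co-mention
#' count against the product of the marginals, scaled by the corpus size:
#' `ln(abs_dg * n + lambda) - ln(abs_d * abs_g + lambda)`. The modified form
#' (the default downstream) drops the corpus-size term, replacing it with the
#' larger marginal and the product with the sum:
#' `ln(abs_dg * max(abs_d, abs_g) + lambda) - ln(abs_d + abs_g + lambda)`.
#' Positive values mark enriched entity-gene pairs, negative values
#' under-represented ones. All arguments are vectorized.
#'
#' @param abs_dg Abstracts co-mentioning entity and gene.
#' @param abs_d Abstracts mentioning the entity.
#' @param abs_g Abstracts mentioning the gene.
#' @param n Corpus size (required by the original variant, ignored by the
#'   modified one).
#' @param lambda Positive regularizer keeping both logarithms finite.
#' @param variant `"modified"` or `"original"`.
#' @return Numeric vector of scores.
#' @export
connect_score <- function(abs_dg, abs_d, abs_g, n = NULL, lambda = 1,
                          variant = c("modified", "original")) {
  variant <- match.arg(variant)
  if (!is.numeric(lambda) || length(lambda) != 1L || lambda <= 0) {
    stop("lambda must be a positive number", call. = FALSE)
  }
  if (any(abs_dg < 0) || any(abs_d < 0) || any(abs_g < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (variant == "original") {
    if (is.null(n)) stop("the original variant requires the corpus size n", call. = FALSE)
    if (any(n < 0)) stop("counts must be non-negative", call. = FALSE)
    log(abs_dg * n + lambda) - log(abs_d * abs_g + lambda)
  } else {
    log(abs_dg * pmax(abs_d, abs_g) + lambda) - log(abs_d + abs_g + lambda)
  }
}

#' Score every cell of a co-occurrence table
#'
#' Element-wise application of [connect_score()] using the configuration's
#' regularizer and variant. The table is expected to have passed through
#' [filter_cooccurrence()] first; that order (filter, then score) is fixed.
#'
#' @param table A [cooccurrence_table()].
#' @param config A [pipeline_config()].
#' @return A numeric matrix of class `"connect_score_matrix"` with attributes
#'   `variant` and `lambda`.
#' @export
score_table <- function(table, config = pipeline_config()) {
  stopifnot(inherits(table, "cooccurrence_table"))
  cnt <- table$counts
  d <- as.numeric(table$entity_abs)
  g <- as.numeric(table$gene_abs)
  if (config$variant == "original") {
    scores <- log(cnt * table$n_total + config$lambda) -
      log(outer(d, g) + config$lambda)
  } else {
    scores <- log(cnt * outer(d, g, pmax) + config$lambda) -
      log(outer(d, g, `+`) + config$lambda)
  }
  dimnames(scores) <- dimnames(cnt)
  if (any(!is.finite(scores))) stop("non-finite connectivity score", call. = FALSE)
  structure(scores, class = c("connect_score_matrix", "matrix", "array"),
            variant = config$variant, lambda = config$lambda,
            universe = table$universe)
}

#' Select the positively connected genes of each entity
#'
#' Keeps, per entity, every gene whose connectivity score is strictly
#' positive (zero is the no-information point under the default regularizer
#' and is excluded). Entities whose positive set is empty are retained as
#' empty entries with a warning so downstream stages see an all-zero row
#' rather than a missing entity.
#'
#' @param scores A [score_table()] result.
#' @return Named list (entity -> character vector of genes); class
#'   `"positive_selection"`.
#' @export
select_positive <- function(scores) {
  stopifnot(inherits(scores, "connect_score_matrix"))
  out <- apply(scores, 1L, function(row) names(row)[row > 0], simplify = FALSE)
  empty <- names(out)[lengths(out) == 0L]
  if (length(empty)) {
    warning("entit(ies) with no positively connected gene: ",
            paste(utils::head(empty, 5L), collapse = ", "), call. = FALSE)
  }
  rn_info("positive-score selection: %d/%d entities non-empty, median set size %d",
          length(out) - length(empty), length(out),
          as.integer(stats::median(lengths(out))))
  out
}
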