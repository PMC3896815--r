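# Evaluation against a gold standard: positive disease-drug pairs plus
# sampled zero-co-occurrence negatives, scored by ROC/AUC.

#' Construct a gold standard
#'
#' @param positives,negatives Data frames with columns `disease` and `drug`.
#'   The two sets must be disjoint.
#' @return A list of class `"gold_standard"`.
#' @export
gold_standard <- function(positives, negatives) {
  positives <- normalize_pairs(positives)
  negatives <- normalize_pairs(negatives)
  if (nrow(positives) == 0L || nrow(negatives) == 0L) {
    stop("gold standard needs at least one positive and one negative pair",
         call. = FALSE)
  }
  if (length(intersect(pair_key(positives), pair_key(negatives)))) {
    stop("positive and negative pairs overlap", call. = FALSE)
  }
  structure(list(positives = positives, negatives = negatives),
            class = "gold_standard")
}

normalize_pairs <- function(pairs) {
  stopifnot(is.data.frame(pairs), all(c("disease", "drug") %in% names(pairs)))
  out <- data.frame(disease = as.character(pairs$disease),
                    drug = as.character(pairs$drug),
                    stringsAsFactors = FALSE)
  out[!duplicated(pair_key(out)), , drop = FALSE]
}

pair_key <- function(pairs) paste(pairs$disease, pairs$drug, sep = "\r")

#' Read a gold standard from a two-column TSV (disease, drug)
#' @param path Path to the positives TSV.
#' @param negatives_path Optional TSV of negative pairs.
#' @return A data frame, or a [gold_standard()] when negatives are given.
#' @export
read_pairs <- function(path, negatives_path = NULL) {
  pos <- read_tsv_cols(path, 2L, c("disease", "drug"))
  if (is.null(negatives_path)) return(normalize_pairs(pos))
  gold_standard(pos, read_tsv_cols(negatives_path, 2L, c("disease", "drug")))
}

#' Sample negative disease-drug pairs
#'
#' Draws a uniform random subset of candidate pairs (pairs with zero
#' literature co-occurrence, so that negatives are unlikely to hide true
#' associations). Reproducible given the seed; the global random stream is
#' left untouched.
#'
#' @param candidates Data frame of candidate pairs (`disease`, `drug`).
#' @param n Number of negatives to draw (0 allowed).
#' @param seed Integer seed.
#' @return A data frame of `n` pairs.
#' @export
sample_negatives <- function(candidates, n, seed = 1L) {
  candidates <- normalize_pairs(candidates)
  if (n < 0) stop("n must be non-negative", call. = FALSE)
  if (n > nrow(candidates)) {
    stop("requested ", n, " negatives but only ", nrow(candidates),
         " candidate pairs", call. = FALSE)
  }
  idx <- local_seed(seed, sample.int(nrow(candidates), size = n))
  candidates[sort(idx), , drop = FALSE]
}

#' Look up association scores for a set of pairs
#'
#' @param assoc An [build_association_matrix()] result.
#' @param pairs Data frame with `disease` and `drug` columns.
#' @return Numeric vector of scores, one per pair.
#' @export
pair_scores <- function(assoc, pairs) {
  stopifnot(inherits(assoc, "association_matrix"))
  pairs <- normalize_pairs(pairs)
  miss_d <- setdiff(unique(pairs$disease), colnames(assoc$scores))
  miss_g <- setdiff(unique(pairs$drug), rownames(assoc$scores))
  if (length(miss_d) || length(miss_g)) {
    stop("pair identifiers unknown to the association matrix: ",
         paste(utils::head(c(miss_d, miss_g), 5L), collapse = ", "), call. = FALSE)
  }
  assoc$scores[cbind(pairs$drug, pairs$disease)]
}

#' ROC curve and AUC for scored positives and negatives
#'
#' AUC is computed as the probability that a random positive outscores a
#' random negative, ties counted 1/2 (the Mann-Whitney convention), which
#' equals the trapezoidal area under the ROC curve. The returned curve
#' sweeps a descending score threshold.
#'
#' @param positive_scores,negative_scores Numeric score vectors.
#' @return A list of class `"roc_result"`: `thresholds`, `tpr`, `fpr`,
#'   `auc`.
#' @export
roc_curve <- function(positive_scores, negative_scores) {
  np <- length(positive_scores); nn <- length(negative_scores)
  if (np == 0L || nn == 0L) {
    stop("need at least one positive and one negative score", call. = FALSE)
  }
  if (anyNA(positive_scores) || anyNA(negative_scores)) {
    stop("scores must not be missing", call. = FALSE)
  }
  r <- rank(c(positive_scores, negative_scores), ties.method = "average")
  auc <- (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
  thr <- sort(unique(c(positive_scores, negative_scores)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(positive_scores >= t), 0)
  fpr <- vapply(thr, function(t) mean(negative_scores >= t), 0)
  structure(list(thresholds = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr),
                 auc = auc),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.4f over %d threshold(s)\n", x$auc,
              length(x$thresholds)))
  invisible(x)
}

#' Evaluate an association matrix against a gold standard
#'
#' @param assoc An [build_association_matrix()] result.
#' @param gold A [gold_standard()]; every pair must be scoreable.
#' @return A `"roc_result"`.
#' @export
roc_auc <- function(assoc, gold) {
  stopifnot(inherits(gold, "gold_standard"))
  roc_curve(pair_scores(assoc, gold$positives),
            pair_scores(assoc, gold$negatives))
}

#' Compare configurations by AUC
#'
#' One AUC per labelled association matrix against a shared gold standard,
#' sorted best-first.
#'
#' @param assoc_list Named list of association matrices.
#' @param gold A [gold_standard()].
#' @return Data frame with columns `label` and `auc`, descending by `auc`.
#' @export
compare_configurations <- function(assoc_list, gold) {
  stopifnot(length(assoc_list) >= 1L, !is.null(names(assoc_list)))
  auc <- vapply(assoc_list, function(a) roc_auc(a, gold)$auc, 0)
  out <- data.frame(label = names(assoc_list), auc = as.numeric(auc),
                    stringsAsFactors = FALSE)
  out[order(-out$auc, out$label), , drop = FALSE]
}
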