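# Expression-based signatures: merged rank lists for drugs (treated vs
# untreated profiles, rank 1 = most up-regulated), a SAM-style moderated
# statistic for disease case/control matrices, and top/bottom-k selection
# (Mir-DrugExt / Mir-DiseaseExt).

#' Construct a ranked expression profile
#'
#' Ranks are a permutation of `1..n` over the gene universe: rank 1 is the
#' most positively (up-) regulated gene, rank `n` the most negatively (down-)
#' regulated.
#'
#' @param ranks Named integer vector (gene -> rank), a permutation of `1..n`.
#' @param entity Entity identifier.
#' @return A named integer vector of class `"ranked_profile"`.
#' @export
ranked_profile <- function(ranks, entity = "entity") {
  genes <- names(ranks)
  if (is.null(genes) || anyDuplicated(genes)) {
    stop("ranks must be named by unique gene ids", call. = FALSE)
  }
  ranks <- as.integer(round(as.numeric(ranks)))
  if (!identical(sort(ranks), seq_along(ranks))) {
    stop("ranks must be a permutation of 1..n", call. = FALSE)
  }
  structure(ranks, names = genes, class = "ranked_profile", entity = entity)
}

#' Merge replicate rank lists into one representative profile
#'
#' Replicate profiles of the same drug are aggregated by mean rank (a Borda
#' count): genes are re-ranked by the average of their input ranks, ties
#' broken by lexicographic gene id. The merge is invariant to the order of
#' its inputs and returns a single replicate unchanged.
#'
#' @param profiles List of [ranked_profile()] objects over the same universe.
#' @param entity Identifier for the merged profile.
#' @return A [ranked_profile()].
#' @export
merge_ranked_lists <- function(profiles, entity = attr(profiles[[1L]], "entity")) {
  stopifnot(length(profiles) >= 1L)
  genes <- sort(names(profiles[[1L]]), method = "radix")
  for (p in profiles) {
    if (!inherits(p, "ranked_profile") ||
        !identical(sort(names(p), method = "radix"), genes)) {
      stop("all profiles must be ranked profiles over the same universe", call. = FALSE)
    }
  }
  mean_rank <- rowMeans(vapply(profiles, function(p) as.numeric(p[genes]),
                               numeric(length(genes))))
  ord <- order(mean_rank, genes, method = "radix")
  ranks <- integer(length(genes))
  ranks[ord] <- seq_along(genes)
  names(ranks) <- genes
  ranked_profile(ranks, entity)
}

#' Normalize ranks to the unit interval
#'
#' Maps rank `r` of an `n`-gene profile to `(r - 1) / (n - 1)`: the most
#' up-regulated gene scores 0, the most down-regulated 1. A single-gene
#' profile maps to 0.
#'
#' @param profile A [ranked_profile()].
#' @return Named numeric vector in `[0, 1]`.
#' @export
normalize_ranks <- function(profile) {
  stopifnot(inherits(profile, "ranked_profile"))
  n <- length(profile)
  out <- if (n == 1L) 0 else (as.numeric(profile) - 1) / (n - 1)
  names(out) <- names(profile)
  out
}

#' Construct a case/control expression matrix
#'
#' @param values Numeric gene-by-sample matrix with gene row names and sample
#'   column names.
#' @param labels Character vector (`"case"`/`"control"`) per sample; at least
#'   two samples per label.
#' @return A list of class `"expression_matrix"`.
#' @export
expression_matrix <- function(values, labels) {
  stopifnot(is.matrix(values), is.numeric(values))
  labels <- match.arg(labels, c("case", "control"), several.ok = TRUE)
  if (length(labels) != ncol(values)) {
    stop("one label per sample required", call. = FALSE)
  }
  if (any(table(factor(labels, levels = c("case", "control"))) < 2L)) {
    stop("each of case and control needs at least 2 samples", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("expression values must be finite", call. = FALSE)
  if (is.null(rownames(values))) stop("gene row names required", call. = FALSE)
  structure(list(values = values, labels = labels), class = "expression_matrix")
}

#' SAM-style moderated differential-expression statistic
#'
#' Per gene, `d = (mean_case - mean_control) / (s + s0)` where `s` is the
#' pooled two-sample standard error
#' `sqrt((1/n1 + 1/n2) * SS_within / (n1 + n2 - 2))` and `s0` is the
#' exchangeability constant damping the statistic for genes with tiny
#' variance. Positive `d` means up-regulated in cases.
#'
#' @param m An [expression_matrix()].
#' @param s0 Non-negative number, or `"auto"` to use the median of `s` over
#'   genes.
#' @return Numeric vector of class `"sam_scores"` (named by gene) with
#'   attribute `s0`.
#' @export
sam_score <- function(m, s0 = "auto") {
  stopifnot(inherits(m, "expression_matrix"))
  case <- m$values[, m$labels == "case", drop = FALSE]
  ctrl <- m$values[, m$labels == "control", drop = FALSE]
  n1 <- ncol(case); n2 <- ncol(ctrl)
  diff <- rowMeans(case) - rowMeans(ctrl)
  ss <- rowSums((case - rowMeans(case))^2) + rowSums((ctrl - rowMeans(ctrl))^2)
  s <- sqrt((1 / n1 + 1 / n2) * ss / (n1 + n2 - 2))
  if (identical(s0, "auto")) {
    s0 <- stats::median(s)
  } else if (!is.numeric(s0) || length(s0) != 1L || s0 < 0) {
    stop("s0 must be a non-negative number or \"auto\"", call. = FALSE)
  }
  d <- diff / (s + s0)
  if (any(!is.finite(d))) {
    stop("non-finite d-statistic; use a positive s0 for zero-variance genes",
         call. = FALSE)
  }
  structure(d, class = "sam_scores", s0 = s0)
}

#' Rank genes by a differential-expression score
#'
#' Rank 1 goes to the largest (most up-regulated) score, rank `n` to the
#' smallest; ties are broken by lexicographic gene id for determinism.
#'
#' @param scores Named numeric vector (e.g. a [sam_score()] result).
#' @param entity Entity identifier for the resulting profile.
#' @return A [ranked_profile()].
#' @export
rank_from_scores <- function(scores, entity = "entity") {
  genes <- names(scores)
  if (is.null(genes)) stop("scores must be named by gene", call. = FALSE)
  ord <- order(-as.numeric(scores), genes, method = "radix")
  ranks <- integer(length(scores))
  ranks[ord] <- seq_along(scores)
  names(ranks) <- genes
  ranked_profile(ranks, entity)
}

#' Select the top/bottom-k signature of a ranked profile
#'
#' Returns the `k` most up-regulated (rank <= k) plus the `k` most
#' down-regulated (rank > n - k) genes: 2k genes when the profile is long
#' enough, all genes otherwise.
#'
#' @param profile A [ranked_profile()].
#' @param k Positive tail size (default 25 gives the 50-gene signature).
#' @return Character vector of gene ids.
#' @export
select_signature <- function(profile, k = 25L) {
  stopifnot(inherits(profile, "ranked_profile"))
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("k must be a positive integer", call. = FALSE)
  }
  n <- length(profile)
  sel <- profile <= k | profile > n - k
  names(profile)[sel]
}
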