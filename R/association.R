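# Drug-disease association model: per disease, an L1-penalized logistic
# regression of the disease's Boolean gene vector on all drugs' Boolean gene
# vectors. Genes are the observations (one per universe gene), drugs the
# predictors; the published description mixes "logistic regression" and
# "lasso regression", reconciled here as lasso-penalized logistic
# regression: a binary response explained by a sparse combination of drug
# subnetworks.

#' Fit the sparse logistic model for one disease
#'
#' Regresses a disease's Boolean gene membership vector on the columns of
#' the drug membership matrix with an L1 penalty (and an unpenalized
#' intercept). A constant response (e.g. an all-zero disease row) cannot
#' support a fit and returns all-zero coefficients flagged as degenerate.
#'
#' @param disease_row Logical (or 0/1) vector over the universe.
#' @param drug_matrix A [membership_matrix()] of drugs over the same
#'   universe.
#' @param penalty Positive L1 penalty, or `"path"` to pick the penalty from
#'   glmnet's regularization path by held-out deviance (an 80/20 gene split
#'   drawn from `seed`), then refit on all genes.
#' @param seed Integer seed (used only by the `"path"` split).
#' @return List with `coef` (named per-drug coefficient vector),
#'   `intercept`, and `diagnostics` (penalty used, nonzero count,
#'   convergence flag, iterations).
#' @export
fit_disease_model <- function(disease_row, drug_matrix, penalty = 0.05,
                              seed = 1L) {
  stopifnot(inherits(drug_matrix, "membership_matrix"))
  y <- as.numeric(disease_row)
  if (length(y) != ncol(drug_matrix)) {
    stop("disease vector and drug matrix differ in gene dimension", call. = FALSE)
  }
  x <- t(matrix(as.numeric(drug_matrix), nrow = nrow(drug_matrix),
                dimnames = dimnames(drug_matrix)))
  drugs <- colnames(x)
  zero_fit <- function(flag) {
    p <- mean(y)
    list(coef = stats::setNames(numeric(length(drugs)), drugs),
         intercept = stats::qlogis(min(max(p, 1e-12), 1 - 1e-12)),
         diagnostics = list(penalty = NA_real_, nonzero = 0L,
                            converged = flag, iterations = 0L))
  }
  if (length(unique(y)) < 2L) return(zero_fit("degenerate"))
  if (all(x == x[1L, ][col(x)])) return(zero_fit("no-variance-predictors"))
  if (ncol(x) < 2L) x <- cbind(x, .pad = 0)  # glmnet needs >= 2 columns
  if (identical(penalty, "path")) {
    penalty <- pick_penalty_by_deviance(x, y, seed)
  }
  # fit the whole regularization path and read off the requested penalty:
  # warm starts along the path converge where a cold single-lambda fit may
  # not, and interpolation between path knots is deterministic
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        standardize = TRUE)
  cf <- as.matrix(stats::coef(fit, s = penalty))[, 1L]
  beta <- cf[-1L][match(drugs, names(cf[-1L]))]
  names(beta) <- drugs
  list(coef = beta,
       intercept = unname(cf[1L]),
       diagnostics = list(penalty = penalty,
                          nonzero = sum(beta != 0),
                          converged = if (fit$jerr == 0) "yes" else "no",
                          iterations = fit$npasses))
}

# Held-out binomial deviance over glmnet's default path; refit penalty.
pick_penalty_by_deviance <- function(x, y, seed) {
  n <- length(y)
  idx <- local_seed(seed, sample.int(n, size = max(2L, floor(n / 5))))
  # guard: validation/training must both keep two classes
  if (length(unique(y[idx])) < 2L || length(unique(y[-idx])) < 2L) {
    return(0.05)
  }
  path <- glmnet::glmnet(x[-idx, , drop = FALSE], y[-idx],
                         family = "binomial", alpha = 1, nlambda = 30)
  p <- stats::predict(path, x[idx, , drop = FALSE], type = "response")
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  dev <- colSums(-2 * (y[idx] * log(p) + (1 - y[idx]) * log(1 - p)))
  path$lambda[which.min(dev)]
}

#' Build the full drug-by-disease association matrix
#'
#' Column `d` holds the coefficients of [fit_disease_model()] for disease
#' `d`. The association score of a (drug, disease) pair is the signed
#' coefficient; only strictly positive coefficients — a drug subnetwork that
#' helps explain the disease subnetwork — become predicted association
#' calls.
#'
#' @param disease_matrix,drug_matrix [membership_matrix()] objects over a
#'   shared universe.
#' @param config A [pipeline_config()] supplying `penalty` and `seed`.
#' @return A list of class `"association_matrix"`: `scores` (drug x disease
#'   numeric), `calls` (logical, score > 0), `diagnostics` (per-disease
#'   list).
#' @export
build_association_matrix <- function(disease_matrix, drug_matrix,
                                     config = pipeline_config()) {
  stopifnot(inherits(disease_matrix, "membership_matrix"),
            inherits(drug_matrix, "membership_matrix"))
  if (!identical(colnames(disease_matrix), colnames(drug_matrix))) {
    stop("disease and drug matrices must share one universe order", call. = FALSE)
  }
  diseases <- rownames(disease_matrix)
  drugs <- rownames(drug_matrix)
  scores <- matrix(0, nrow = length(drugs), ncol = length(diseases),
                   dimnames = list(drugs, diseases))
  diagnostics <- vector("list", length(diseases))
  names(diagnostics) <- diseases
  for (d in diseases) {
    fit <- fit_disease_model(disease_matrix[d, ], drug_matrix,
                             penalty = config$penalty, seed = config$seed)
    scores[, d] <- fit$coef
    diagnostics[[d]] <- fit$diagnostics
    if (identical(fit$diagnostics$converged, "no")) {
      warning("fit for disease ", d, " did not converge", call. = FALSE)
    }
  }
  structure(list(scores = scores, calls = scores > 0, diagnostics = diagnostics),
            class = "association_matrix")
}

#' @export
print.association_matrix <- function(x, ...) {
  cat("Association matrix: ", nrow(x$scores), " drugs x ", ncol(x$scores),
      " diseases, ", sum(x$calls), " positive call(s)\n", sep = "")
  invisible(x)
}

#' Combine text- and expression-based membership matrices
#'
#' Element-wise Boolean OR of two matrices built under the same centrality
#' measure: a gene represents an entity in the combined source when either
#' evidence stream selected it.
#'
#' @param text_m,expr_m [membership_matrix()] objects with identical
#'   entities, universe and measure.
#' @return A [membership_matrix()] with source `"combined"`.
#' @export
combine_sources <- function(text_m, expr_m) {
  stopifnot(inherits(text_m, "membership_matrix"),
            inherits(expr_m, "membership_matrix"))
  if (!identical(dimnames(text_m), dimnames(expr_m))) {
    stop("matrices must agree on entities and universe", call. = FALSE)
  }
  if (!identical(attr(text_m, "measure"), attr(expr_m, "measure"))) {
    stop("matrices come from different centrality measures", call. = FALSE)
  }
  membership_matrix(unclass(text_m) | unclass(expr_m),
                    gene_universe(colnames(text_m)),
                    source = "combined", measure = attr(text_m, "measure"))
}
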