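# Internal helpers shared across the pipeline.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Emit an informational message about a filtering or generation step
#'
#' All filtering operations report counts in/out through this hook. Silence
#' with `options(reponet.verbose = FALSE)`.
#' @noRd
rn_info <- function(fmt, ...) {
  if (isTRUE(getOption("reponet.verbose", TRUE))) {
    message("[reponet] ", sprintf(fmt, ...))
  }
  invisible(NULL)
}

#' Evaluate code under a local RNG seed, restoring global state afterwards
#'
#' Keeps randomized operations reproducible without touching the caller's
#' random stream (no global random state leaks out of the package).
#' @noRd
local_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Assert that a matrix is indexed by the given gene universe
#'
#' Dimension-check utility called at every stage boundary: all matrices in a
#' run must share one universe column order.
#' @noRd
check_universe_columns <- function(m, universe, what = "matrix") {
  genes <- as.character(universe)
  if (is.null(colnames(m)) || !identical(colnames(m), genes)) {
    stop(what, " columns do not match the gene universe (order matters)",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Canonical representation of undirected edges: two-column character matrix
# with endpoint1 < endpoint2 per row, duplicates removed.
canonical_edges <- function(from, to) {
  a <- pmin(from, to)
  b <- pmax(from, to)
  keep <- !duplicated(paste(a, b, sep = "\r"))
  cbind(a[keep], b[keep])
}
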