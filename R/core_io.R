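# Shared domain types and their TSV readers/writers.
#
# All tabular files are tab-separated; lines starting with "#" are comments.
# Gene and entity identifiers are opaque, case-sensitive strings: no symbol
# normalization is attempted anywhere.

#' Construct a gene universe
#'
#' The gene universe is the ordered set of gene identifiers over which every
#' matrix in the pipeline is indexed; its order defines the column order of
#' all membership, co-occurrence and score matrices.
#'
#' @param genes Character vector of unique gene identifiers.
#' @return A character vector of class `"gene_universe"`.
#' @export
gene_universe <- function(genes) {
  genes <- as.character(genes)
  if (length(genes) == 0L) stop("gene universe must be non-empty", call. = FALSE)
  if (anyNA(genes) || any(!nzchar(genes))) {
    stop("gene universe contains missing or empty identifiers", call. = FALSE)
  }
  dup <- genes[duplicated(genes)]
  if (length(dup)) {
    stop("duplicate gene identifier(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  structure(genes, class = "gene_universe")
}

#' @export
print.gene_universe <- function(x, ...) {
  cat("Gene universe:", length(x), "genes\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}

#' Read a gene universe from a plain-text file
#'
#' One identifier per line, file order preserved; `#` comment lines and blank
#' lines are ignored.
#'
#' @param path Path to the gene list file.
#' @return A [gene_universe()].
#' @export
read_gene_universe <- function(path) {
  lines <- read_clean_lines(path)
  if (length(lines) == 0L) stop("empty gene universe file: ", path, call. = FALSE)
  gene_universe(lines)
}

#' Write a gene universe
#' @param universe A [gene_universe()].
#' @param path Output path.
#' @export
write_gene_universe <- function(universe, path) {
  writeLines(as.character(universe), path)
  invisible(path)
}

read_clean_lines <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines[nzchar(lines) & !startsWith(lines, "#")]
}

#' Construct an entity seed map
#'
#' Maps each drug or disease to its seed gene set: drug targets in the style
#' of DrugBank, disease genes in the style of OMIM. Every gene must belong to
#' the universe; every entity must have at least one gene.
#'
#' @param entries Named list of character vectors (entity id -> gene set).
#' @param universe A [gene_universe()].
#' @param kind `"drug"` or `"disease"`.
#' @return A named list of class `"seed_map"` with attributes `kind`.
#' @export
seed_map <- function(entries, universe, kind = c("drug", "disease")) {
  kind <- match.arg(kind)
  if (length(entries) == 0L) stop("seed map must contain at least one entity", call. = FALSE)
  ids <- names(entries)
  if (is.null(ids) || anyNA(ids) || any(!nzchar(ids))) {
    stop("every entity must be named", call. = FALSE)
  }
  if (anyDuplicated(ids)) stop("duplicate entity identifiers", call. = FALSE)
  entries <- lapply(entries, function(g) unique(as.character(g)))
  empty <- ids[vapply(entries, length, 1L) == 0L]
  if (length(empty)) {
    stop("entity with empty seed set: ", paste(empty, collapse = ", "), call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(entries, use.names = FALSE)), as.character(universe))
  if (length(unknown)) {
    stop("seed gene(s) outside the universe: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  }
  structure(entries, class = "seed_map", kind = kind)
}

#' Read an entity seed map from a two-column TSV (entity, gene)
#'
#' @inheritParams seed_map
#' @param path Path to the TSV file.
#' @return A [seed_map()].
#' @export
read_seed_map <- function(path, universe, kind = c("drug", "disease")) {
  kind <- match.arg(kind)
  tab <- read_tsv_cols(path, 2L, c("entity", "gene"))
  seed_map(split(tab$gene, factor(tab$entity, levels = unique(tab$entity))),
           universe, kind)
}

#' Write a seed map as a two-column TSV (entity, gene)
#' @param seeds A [seed_map()].
#' @param path Output path.
#' @export
write_seed_map <- function(seeds, path) {
  ent <- rep(names(seeds), lengths(seeds))
  utils::write.table(data.frame(entity = ent,
                                gene = unlist(seeds, use.names = FALSE)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv_cols <- function(path, ncol_expected, col_names) {
  lines <- read_clean_lines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != ncol_expected)
  # tolerate a header row matching the expected column names
  if (length(lines) && identical(tolower(parts[[1]]), tolower(col_names))) {
    parts <- parts[-1]
    bad <- bad[bad != 1L] - 1L
  }
  if (length(bad)) {
    stop("malformed line ", bad[1L], " in ", path, ": expected ",
         ncol_expected, " tab-separated fields", call. = FALSE)
  }
  out <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(out) <- col_names
  out
}

#' Construct an interaction network
#'
#' An undirected gene-gene network from one evidence source (e.g. functional
#' protein interactions, a signaling network, or a text-mining channel).
#' Self-loops are dropped, reversed duplicates collapsed, and endpoints are
#' restricted to the universe.
#'
#' @param from,to Character vectors of edge endpoints.
#' @param universe A [gene_universe()].
#' @param source Label for the evidence source.
#' @return An object of class `"interaction_network"`: a list with `edges`
#'   (two-column character matrix, canonical order), `universe` and `source`.
#' @export
interaction_network <- function(from, to, universe, source = "network") {
  from <- as.character(from); to <- as.character(to)
  stopifnot(length(from) == length(to))
  genes <- as.character(universe)
  n_in <- length(from)
  loops <- from == to
  if (any(loops)) {
    rn_info("dropping %d self-loop(s) from %s", sum(loops), source)
    from <- from[!loops]; to <- to[!loops]
  }
  outside <- !(from %in% genes) | !(to %in% genes)
  if (any(outside)) {
    rn_info("dropping %d edge(s) with endpoints outside the universe from %s",
            sum(outside), source)
    from <- from[!outside]; to <- to[!outside]
  }
  edges <- canonical_edges(from, to)
  rn_info("network %s: %d raw line(s) -> %d unique edge(s)", source, n_in, nrow(edges))
  structure(list(edges = edges, universe = universe, source = source),
            class = "interaction_network")
}

#' @export
print.interaction_network <- function(x, ...) {
  cat("Interaction network [", x$source, "]: ", nrow(x$edges), " edges over ",
      length(x$universe), " genes\n", sep = "")
  invisible(x)
}

#' Read an undirected edge list from a two-column TSV
#'
#' @inheritParams interaction_network
#' @param path Path to the edge-list TSV.
#' @return An [interaction_network()].
#' @export
read_edge_list <- function(path, universe, source = basename(path)) {
  tab <- read_tsv_cols(path, 2L, c("from", "to"))
  interaction_network(tab$from, tab$to, universe, source)
}

#' Write an interaction network as a two-column TSV
#' @param network An [interaction_network()].
#' @param path Output path.
#' @export
write_edge_list <- function(network, path) {
  utils::write.table(network$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("from", "to"))
  invisible(path)
}

#' Construct a Boolean membership matrix
#'
#' One of the Boolean entity-by-gene networks: `values[e, g]` is `TRUE` when
#' gene `g` represents entity `e` under a given evidence source and
#' centrality measure.
#'
#' @param values Logical matrix with entity row names; columns must follow
#'   the universe order.
#' @param universe A [gene_universe()].
#' @param source One of `"text"`, `"expression"`, `"combined"`.
#' @param measure One of `"degree"`, `"betweenness"`, `"closeness"`, or
#'   `"none"` for matrices built upstream of centrality selection.
#' @return A logical matrix of class `"membership_matrix"` with attributes
#'   `source` and `measure`.
#' @export
membership_matrix <- function(values, universe,
                              source = c("text", "expression", "combined"),
                              measure = c("degree", "betweenness", "closeness", "none")) {
  source <- match.arg(source)
  measure <- match.arg(measure)
  genes <- as.character(universe)
  if (!is.matrix(values) || !is.logical(values)) {
    stop("membership values must be a logical matrix", call. = FALSE)
  }
  if (ncol(values) != length(genes)) {
    stop("membership matrix has ", ncol(values), " columns but the universe has ",
         length(genes), " genes", call. = FALSE)
  }
  if (is.null(colnames(values))) colnames(values) <- genes
  check_universe_columns(values, universe, "membership matrix")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    stop("membership matrix needs unique entity row names", call. = FALSE)
  }
  if (anyNA(values)) stop("membership matrix must be strictly Boolean", call. = FALSE)
  structure(values, class = c("membership_matrix", class(values)),
            source = source, measure = measure)
}

#' @export
print.membership_matrix <- function(x, ...) {
  cat("Membership matrix [", attr(x, "source"), "/", attr(x, "measure"), "]: ",
      nrow(x), " entities x ", ncol(x), " genes, ", sum(x), " memberships\n",
      sep = "")
  invisible(x)
}

#' Write a membership matrix as TSV (0/1 cells)
#'
#' Header row holds gene ids, first column entity ids. Round-trips
#' bit-exactly through [read_membership_matrix()].
#'
#' @param m A [membership_matrix()].
#' @param path Output path.
#' @export
write_membership_matrix <- function(m, path) {
  df <- data.frame(entity = rownames(m),
                   matrix(as.integer(m), nrow = nrow(m),
                          dimnames = list(NULL, colnames(m))),
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# source=", attr(m, "source"), " measure=", attr(m, "measure")),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a membership matrix written by [write_membership_matrix()]
#'
#' @param path Path to the TSV file.
#' @return A [membership_matrix()].
#' @export
read_membership_matrix <- function(path) {
  hdr <- readLines(path, n = 1L)
  source <- "combined"; measure <- "none"
  if (startsWith(hdr, "#")) {
    source <- sub(".*source=(\\S+).*", "\\1", hdr)
    measure <- sub(".*measure=(\\S+).*", "\\1", hdr)
  }
  tab <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                           stringsAsFactors = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE]) > 0L
  rownames(vals) <- tab[[1L]]
  membership_matrix(vals, gene_universe(colnames(vals)), source, measure)
}

#' Pipeline configuration
#'
#' Bundles the procedural constants of the method. The defaults reproduce the
#' published settings: regularizer `lambda = 1`, co-occurrence filter
#' threshold `min_cooccurrence = 5` (counts below 5 are zeroed), signature
#' tail size `tail_k = 25` (25 most up- plus 25 most down-regulated genes),
#' and the modified connectivity-score variant that avoids the corpus-size
#' term.
#'
#' @param lambda Positive regularizer added inside both logarithms of the
#'   connectivity score.
#' @param min_cooccurrence Non-negative integer; co-mention counts strictly
#'   below it are set to zero before scoring.
#' @param tail_k Tail size of the expression signature.
#' @param variant Connectivity-score variant, `"modified"` (default) or
#'   `"original"`.
#' @param centrality Default centrality measure for prioritization.
#' @param penalty L1 penalty strength for the per-disease logistic fit: a
#'   positive number, or `"path"` to select from a small grid by held-out
#'   deviance.
#' @param s0 SAM exchangeability constant, a non-negative number or `"auto"`
#'   (median per-gene standard error).
#' @param seed Integer seed used by every randomized operation.
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(lambda = 1, min_cooccurrence = 5L, tail_k = 25L,
                            variant = c("modified", "original"),
                            centrality = c("degree", "betweenness", "closeness"),
                            penalty = 0.05, s0 = "auto", seed = 1L) {
  variant <- match.arg(variant)
  centrality <- match.arg(centrality)
  stopifnot(is.numeric(lambda), length(lambda) == 1L, lambda > 0,
            is.numeric(min_cooccurrence), min_cooccurrence >= 0,
            is.numeric(tail_k), tail_k >= 1)
  if (!(identical(penalty, "path") ||
        (is.numeric(penalty) && length(penalty) == 1L && penalty > 0))) {
    stop("penalty must be a positive number or \"path\"", call. = FALSE)
  }
  structure(list(lambda = lambda,
                 min_cooccurrence = as.integer(min_cooccurrence),
                 tail_k = as.integer(tail_k),
                 variant = variant, centrality = centrality,
                 penalty = penalty, s0 = s0, seed = as.integer(seed)),
            class = "pipeline_config")
}
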