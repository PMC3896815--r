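# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph) so that agreement is evidence, not
# tautology.

# Shortest-path distances and path counts by adjacency-matrix powers: a walk
# of length d(s,t) between s and t is necessarily a shortest path, so the
# (s,t) entry of A^k at the first k with a nonzero entry counts shortest
# paths exactly. Works for the tiny graphs the oracle is used on.
oracle_paths <- function(adj) {
  n <- nrow(adj)
  D <- matrix(Inf, n, n); diag(D) <- 0
  S <- diag(n)  # path counts at distance 0
  Ak <- diag(n)
  for (k in seq_len(n - 1)) {
    Ak <- Ak %*% adj
    new <- is.infinite(D) & Ak > 0
    D[new] <- k
    S[new] <- Ak[new]
  }
  list(D = D, S = S)
}

# Unnormalized betweenness: sum over unordered pairs (s,t), s != t != v, of
# the fraction of s-t shortest paths passing through v.
oracle_betweenness <- function(adj) {
  o <- oracle_paths(adj)
  n <- nrow(adj)
  out <- numeric(n)
  for (v in seq_len(n)) {
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(o$D[s, t])) next
        if (o$D[s, v] + o$D[v, t] == o$D[s, t]) {
          out[v] <- out[v] + o$S[s, v] * o$S[v, t] / o$S[s, t]
        }
      }
    }
  }
  out
}

# Component-wise closeness: (c - 1) / sum of within-component distances;
# isolated nodes 0.
oracle_closeness <- function(adj) {
  o <- oracle_paths(adj)
  n <- nrow(adj)
  vapply(seq_len(n), function(v) {
    d <- o$D[v, ]
    reach <- which(is.finite(d) & seq_len(n) != v)
    if (length(reach) == 0L) 0 else length(reach) / sum(d[reach])
  }, 0)
}

# Pair-counting AUC by explicit enumeration (ties 1/2).
oracle_auc <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Trapezoidal area under an ROC curve given the raw scores.
oracle_auc_trapezoid <- function(pos, neg) {
  thr <- sort(unique(c(pos, neg, Inf)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos >= t), 0)
  fpr <- vapply(thr, function(t) mean(neg >= t), 0)
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

# Build a subnetwork object directly from an adjacency matrix over named
# nodes, all flagged as signature (valid per the class contract).
adj_subnetwork <- function(adj, nodes = sprintf("n%02d", seq_len(nrow(adj))),
                           entity = "test") {
  idx <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
  edges <- cbind(nodes[idx[, 1]], nodes[idx[, 2]])
  flags <- rep("signature", length(nodes))
  names(flags) <- nodes
  structure(list(nodes = flags, edges = edges, entity = entity,
                 source = "test"),
            class = "subnetwork")
}

# Small fixture: a universe, a hand-built network and seed maps.
tiny_world_fixture <- function() {
  uni <- gene_universe(c("a", "b", "c", "d", "e"))
  net <- interaction_network(c("a", "b", "c"), c("b", "c", "d"), uni, "toy")
  drugs <- seed_map(list(dr1 = c("a"), dr2 = c("e")), uni, "drug")
  diseases <- seed_map(list(ds1 = c("b")), uni, "disease")
  list(universe = uni, network = net, drugs = drugs, diseases = diseases)
}
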