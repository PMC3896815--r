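rp <- function(ranks, genes = paste0("g", seq_along(ranks)), entity = "e") {
  ranked_profile(stats::setNames(ranks, genes), entity)
}

test_that("rank-list merging is mean-rank aggregation with lexicographic ties", {
  # single profile is returned unchanged
  p <- rp(c(2L, 1L, 3L))
  expect_identical(as.integer(merge_ranked_lists(list(p))), c(2L, 1L, 3L))
  # means (1.5, 1.5, 3): tie between g1 and g2 falls to gene id
  m <- merge_ranked_lists(list(rp(c(1L, 2L, 3L)), rp(c(2L, 1L, 3L))))
  expect_identical(m[c("g1", "g2", "g3")], c(g1 = 1L, g2 = 2L, g3 = 3L))
  # total tie: pure lexicographic order
  m2 <- merge_ranked_lists(list(rp(c(1L, 2L, 3L)), rp(c(3L, 2L, 1L))))
  expect_identical(m2[c("g1", "g2", "g3")], c(g1 = 1L, g2 = 2L, g3 = 3L))
  expect_error(merge_ranked_lists(list(p, rp(c(1L, 2L), genes = c("g1", "g2")))),
               "same universe")
})

test_that("merging is invariant to input order and idempotent on replicates", {
  set.seed(5)
  profs <- lapply(1:4, function(i) rp(sample(1:20), genes = sprintf("g%02d", 1:20)))
  expect_identical(merge_ranked_lists(profs), merge_ranked_lists(rev(profs)))
  expect_identical(as.integer(merge_ranked_lists(profs[c(1, 1, 1)])),
                   as.integer(profs[[1]]))
})

test_that("rank normalization maps onto [0, 1] with fixed endpoints", {
  expect_equal(unname(normalize_ranks(rp(c(1L, 2L, 3L)))), c(0, 0.5, 1))
  expect_equal(unname(normalize_ranks(rp(c(1L, 2L)))[1]), 0)
  expect_equal(unname(normalize_ranks(rp(1L, genes = "g1"))), 0)
})

test_that("the moderated d-statistic matches hand and brute-force computation", {
  vals <- matrix(c(5, 7, 1, 3), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:4)))
  m <- expression_matrix(rbind(vals, g2 = c(2, 2, 2, 2.5)),
                         c("case", "case", "control", "control"))
  d <- sam_score(m, s0 = 0)
  expect_equal(unname(d["g1"]), 4 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(d["g1"]), 2.8284, tolerance = 1e-4)

  # random matrix vs an independent per-gene re-implementation
  set.seed(9)
  vals <- matrix(rnorm(20 * 7), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:7)))
  labels <- c("case", "case", "case", "control", "control", "control", "control")
  m <- expression_matrix(vals, labels)
  d <- sam_score(m, s0 = 0.1)
  for (g in rownames(vals)) {
    x1 <- vals[g, labels == "case"]; x2 <- vals[g, labels == "control"]
    ss <- sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)
    s <- sqrt((1 / 3 + 1 / 4) * ss / 5)
    expect_equal(unname(d[g]), (mean(x1) - mean(x2)) / (s + 0.1))
  }
  # identical group means give d = 0
  flat <- expression_matrix(matrix(c(1, 2, 1, 2), 1,
                                   dimnames = list("g1", paste0("s", 1:4))),
                            c("case", "case", "control", "control"))
  expect_equal(unname(sam_score(flat, s0 = 1)["g1"]), 0)
  expect_error(expression_matrix(matrix(1, 1, 3, dimnames = list("g1", 1:3)),
                                 c("case", "control", "control")),
               "at least 2")
})

test_that("swapping case and control labels negates every d-statistic", {
  set.seed(13)
  vals <- matrix(rnorm(15 * 6), nrow = 15,
                 dimnames = list(sprintf("g%02d", 1:15), paste0("s", 1:6)))
  lab <- rep(c("case", "control"), each = 3)
  d1 <- sam_score(expression_matrix(vals, lab), s0 = 0.2)
  d2 <- sam_score(expression_matrix(vals, rev(lab)), s0 = 0.2)
  expect_equal(as.numeric(d1), -as.numeric(d2))
})

test_that("auto s0 is the median per-gene standard error", {
  set.seed(21)
  vals <- matrix(rnorm(30 * 6), nrow = 30,
                 dimnames = list(sprintf("g%02d", 1:30), paste0("s", 1:6)))
  m <- expression_matrix(vals, rep(c("case", "control"), each = 3))
  d_auto <- sam_score(m, "auto")
  s <- vapply(rownames(vals), function(g) {
    x1 <- vals[g, 1:3]; x2 <- vals[g, 4:6]
    sqrt((1 / 3 + 1 / 3) * (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / 4)
  }, 0)
  expect_equal(attr(d_auto, "s0"), stats::median(s))
})

test_that("score ranking is descending with lexicographic tie-break", {
  d <- c(g1 = 2.0, g2 = -1.0, g3 = 0.5)
  r <- rank_from_scores(d)
  expect_identical(r[c("g1", "g3", "g2")], c(g1 = 1L, g3 = 2L, g2 = 3L))
  tie <- rank_from_scores(c(g2 = 1, g1 = 1, g3 = 1))
  expect_identical(tie[c("g1", "g2", "g3")], c(g1 = 1L, g2 = 2L, g3 = 3L))
  dec <- rank_from_scores(c(g1 = 3, g2 = 2, g3 = 1))
  expect_identical(unname(dec[paste0("g", 1:3)]), 1:3)
})

test_that("signature selection takes both tails, saturating on short profiles", {
  p6 <- rp(1:6, genes = paste0("g", 1:6))
  expect_setequal(select_signature(p6, 2L), c("g1", "g2", "g5", "g6"))
  p4 <- rp(1:4, genes = paste0("g", 1:4))
  expect_setequal(select_signature(p4, 3L), paste0("g", 1:4))
  expect_error(select_signature(p6, 0L), "positive")
  # tails are disjoint and sized min(2k, n) on random profiles
  set.seed(17)
  for (n in c(10, 51, 120)) {
    p <- rp(sample(1:n), genes = sprintf("g%03d", 1:n))
    for (k in c(3L, 25L, 70L)) {
      sig <- select_signature(p, k)
      expect_length(sig, min(2 * k, n))
    }
  }
})
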