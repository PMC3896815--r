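make_table <- function(counts, entity_abs = NULL, gene_abs = NULL,
                       n_total = NULL) {
  uni <- gene_universe(colnames(counts))
  entity_abs <- entity_abs %||%
    stats::setNames(rowSums(counts) + 50, rownames(counts))
  gene_abs <- gene_abs %||% stats::setNames(colSums(counts) + 30, colnames(counts))
  cooccurrence_table(counts, entity_abs, gene_abs,
                     n_total %||% (sum(counts) + sum(entity_abs) + sum(gene_abs)),
                     uni)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

test_that("co-occurrence filter zeroes counts below the threshold only", {
  cnt <- matrix(c(0L, 3L, 4L, 5L, 7L), nrow = 1,
                dimnames = list("d1", paste0("g", 1:5)))
  tab <- make_table(cnt)
  out <- filter_cooccurrence(tab, 5L)
  expect_identical(unname(out$counts[1, ]), c(0L, 0L, 0L, 5L, 7L))
  expect_identical(out$entity_abs, tab$entity_abs)  # marginals untouched
  expect_identical(out$n_total, tab$n_total)
  expect_identical(filter_cooccurrence(tab, 0L)$counts, tab$counts)
  all4 <- make_table(matrix(4L, 2, 3, dimnames = list(c("a", "b"), paste0("g", 1:3))))
  expect_true(all(filter_cooccurrence(all4, 5L)$counts == 0L))
})

test_that("connectivity score matches its closed forms", {
  # modified: ln(abs_dg * max + lambda) - ln(sum + lambda)
  expect_equal(connect_score(0, 0, 0, lambda = 1, variant = "modified"), 0)
  expect_equal(connect_score(10, 100, 50, lambda = 1, variant = "modified"),
               log(1001) - log(151))
  expect_equal(connect_score(10, 100, 50, lambda = 1, variant = "modified"),
               1.8915, tolerance = 1e-4)
  # original: ln(abs_dg * n + lambda) - ln(abs_d * abs_g + lambda)
  expect_equal(connect_score(10, 100, 50, n = 1000, lambda = 1,
                             variant = "original"),
               log(10001) - log(5001))
  expect_equal(connect_score(10, 100, 50, n = 1000, lambda = 1,
                             variant = "original"), 0.6930, tolerance = 1e-4)
  expect_error(connect_score(1, 1, 1, lambda = 0), "lambda")
  expect_error(connect_score(1, 1, 1, variant = "original"), "corpus")
})

test_that("modified score is symmetric in the marginals and monotone in the count", {
  set.seed(7)
  d <- sample(0:500, 500, TRUE); g <- sample(0:500, 500, TRUE)
  dg <- pmin(d, g, sample(0:100, 500, TRUE))
  expect_equal(connect_score(dg, d, g), connect_score(dg, g, d))
  # strictly increasing in abs_dg for fixed marginals
  expect_true(all(diff(connect_score(0:50, 100, 60)) > 0))
})

test_that("score_table equals the element-wise score on random tables", {
  set.seed(11)
  cnt <- matrix(sample(0:20, 25, TRUE), 5, 5,
                dimnames = list(paste0("d", 1:5), paste0("g", 1:5)))
  tab <- make_table(cnt)
  for (variant in c("modified", "original")) {
    cfg <- pipeline_config(variant = variant)
    sc <- score_table(tab, cfg)
    oracle <- matrix(0, 5, 5)
    for (i in 1:5) for (j in 1:5) {
      oracle[i, j] <- connect_score(cnt[i, j], tab$entity_abs[i],
                                    tab$gene_abs[j], n = tab$n_total,
                                    lambda = 1, variant = variant)
    }
    expect_equal(unname(unclass(sc)[, ]), oracle)
  }
  # duplicated entity row gives an identical score row
  cnt2 <- rbind(cnt, d6 = cnt["d1", ])
  tab2 <- make_table(cnt2, entity_abs = stats::setNames(
    c(tab$entity_abs, tab$entity_abs[["d1"]]), rownames(cnt2)),
    gene_abs = tab$gene_abs, n_total = tab$n_total)
  sc2 <- score_table(tab2, pipeline_config())
  expect_equal(sc2["d6", ], sc2["d1", ])
})

test_that("positive selection keeps strictly positive scores only", {
  uni <- gene_universe(paste0("g", 1:3))
  sc <- structure(matrix(c(-1, 0, 0.3), 1, 3,
                         dimnames = list("d1", as.character(uni))),
                  class = c("connect_score_matrix", "matrix", "array"),
                  variant = "modified", lambda = 1, universe = uni)
  expect_identical(select_positive(sc)$d1, "g3")
  sc0 <- sc; sc0[1, ] <- 0
  expect_warning(sel <- select_positive(sc0), "no positively connected")
  expect_length(sel$d1, 0L)
})

test_that("a filtered sub-threshold count can never enter a positive set", {
  set.seed(3)
  for (rep in 1:10) {
    cnt <- matrix(sample(0:8, 40, TRUE), 4, 10,
                  dimnames = list(paste0("d", 1:4), sprintf("g%02d", 1:10)))
    tab <- filter_cooccurrence(make_table(cnt), 5L)
    sel <- suppressWarnings(select_positive(score_table(tab, pipeline_config())))
    for (d in rownames(cnt)) {
      low <- colnames(cnt)[cnt[d, ] > 0 & cnt[d, ] < 5]
      expect_length(intersect(sel[[d]], low), 0L)
    }
  }
})

test_that("inconsistent tables error in strict mode but only warn in tolerant mode", {
  cnt <- matrix(10L, 1, 1, dimnames = list("d1", "g1"))
  uni <- gene_universe("g1")
  expect_error(cooccurrence_table(cnt, c(d1 = 3), c(g1 = 50), 100, uni),
               "inconsistent")
  expect_warning(cooccurrence_table(cnt, c(d1 = 3), c(g1 = 50), 100, uni,
                                    on_inconsistent = "warn"),
                 "inconsistent")
})
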