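random_membership <- function(n_ent, genes, prefix, density = 0.1,
                              source = "text") {
  vals <- matrix(stats::runif(n_ent * length(genes)) < density,
                 nrow = n_ent,
                 dimnames = list(sprintf("%s%02d", prefix, seq_len(n_ent)),
                                 genes))
  membership_matrix(vals, gene_universe(genes), source, "degree")
}

test_that("the planted predictor receives the largest positive coefficient", {
  set.seed(101)
  genes <- sprintf("g%03d", 1:500)
  drug_m <- random_membership(21, genes, "dr")
  disease_row <- unclass(drug_m)["dr07", ]
  fit <- fit_disease_model(disease_row, drug_m, penalty = 0.05, seed = 1)
  expect_gt(fit$coef["dr07"], 0)
  expect_identical(names(which.max(fit$coef)), "dr07")
  expect_lte(fit$diagnostics$nonzero, 21L)
  # unpenalized single-predictor oracle agrees on the direction of the signal
  # (perfect separation here, so glm cannot converge; the sign still settles)
  oracle <- suppressWarnings(stats::glm(disease_row ~ unclass(drug_m)["dr07", ],
                                        family = stats::binomial()))
  expect_gt(stats::coef(oracle)[2], 0)
})

test_that("degenerate responses and empty predictors yield flagged zero fits", {
  genes <- sprintf("g%03d", 1:100)
  drug_m <- random_membership(5, genes, "dr")
  fit0 <- fit_disease_model(rep(FALSE, 100), drug_m, penalty = 0.05)
  expect_true(all(fit0$coef == 0))
  expect_identical(fit0$diagnostics$converged, "degenerate")
  zero_m <- membership_matrix(matrix(FALSE, 5, 100,
                                     dimnames = list(paste0("dr", 1:5), genes)),
                              gene_universe(genes), "text", "degree")
  y <- rep(c(TRUE, FALSE), c(30, 70))
  fitz <- fit_disease_model(y, zero_m, penalty = 0.05)
  expect_true(all(fitz$coef == 0))
  expect_equal(fitz$intercept, stats::qlogis(0.3), tolerance = 1e-9)
})

test_that("path-selected penalties are reproducible and keep the planted drug", {
  set.seed(211)
  genes <- sprintf("g%03d", 1:400)
  drug_m <- random_membership(12, genes, "dr", density = 0.1)
  y <- unclass(drug_m)["dr05", ]
  f1 <- fit_disease_model(y, drug_m, penalty = "path", seed = 4)
  f2 <- fit_disease_model(y, drug_m, penalty = "path", seed = 4)
  expect_identical(f1, f2)
  expect_gt(f1$diagnostics$penalty, 0)
  expect_identical(names(which.max(f1$coef)), "dr05")
})

test_that("coefficients vanish as the penalty grows", {
  set.seed(103)
  genes <- sprintf("g%03d", 1:300)
  drug_m <- random_membership(10, genes, "dr", density = 0.2)
  y <- unclass(drug_m)["dr01", ] | unclass(drug_m)["dr02", ]
  nnz <- vapply(c(0.001, 0.01, 0.05, 0.2, 1, 10), function(p) {
    fit_disease_model(y, drug_m, penalty = p)$diagnostics$nonzero
  }, 0L)
  expect_true(all(diff(nnz) <= 0L))
  expect_identical(nnz[length(nnz)], 0L)
})

test_that("association matrices recover planted pairs and respect drug order", {
  set.seed(107)
  genes <- sprintf("g%03d", 1:400)
  drug_m <- random_membership(15, genes, "dr", density = 0.08)
  dis_vals <- rbind(ds1 = unclass(drug_m)["dr03", ],
                    ds2 = unclass(drug_m)["dr11", ])
  disease_m <- membership_matrix(dis_vals, gene_universe(genes), "text", "degree")
  assoc <- build_association_matrix(disease_m, drug_m, pipeline_config())
  expect_identical(dim(assoc$scores), c(15L, 2L))
  expect_true(assoc$calls["dr03", "ds1"])
  expect_true(assoc$calls["dr11", "ds2"])
  expect_identical(names(which.max(assoc$scores[, "ds1"])), "dr03")
  expect_identical(names(which.max(assoc$scores[, "ds2"])), "dr11")
  expect_true(all(assoc$scores[assoc$calls] > 0))

  # permuting drug rows permutes score rows identically
  perm <- sample(rownames(drug_m))
  drug_p <- membership_matrix(unclass(drug_m)[perm, ], gene_universe(genes),
                              "text", "degree")
  assoc_p <- build_association_matrix(disease_m, drug_p, pipeline_config())
  expect_equal(assoc_p$scores, assoc$scores[perm, ])

  # all-zero disease rows give all-zero score columns
  zero_dis <- membership_matrix(matrix(FALSE, 1, 400,
                                       dimnames = list("ds0", genes)),
                                gene_universe(genes), "text", "degree")
  assoc0 <- build_association_matrix(zero_dis, drug_m, pipeline_config())
  expect_true(all(assoc0$scores == 0))
})

test_that("source combination is an element-wise OR with provenance checks", {
  genes <- paste0("g", 1:3)
  uni <- gene_universe(genes)
  m1 <- membership_matrix(matrix(c(TRUE, FALSE, FALSE), 1,
                                 dimnames = list("e1", genes)),
                          uni, "text", "degree")
  m2 <- membership_matrix(matrix(c(FALSE, FALSE, TRUE), 1,
                                 dimnames = list("e1", genes)),
                          uni, "expression", "degree")
  comb <- combine_sources(m1, m2)
  expect_identical(unname(unclass(comb)[1, ]), c(TRUE, FALSE, TRUE))
  expect_identical(attr(comb, "source"), "combined")
  expect_identical(unclass(combine_sources(m1, m1))[, ], unclass(m1)[, ])
  m3 <- membership_matrix(matrix(FALSE, 1, 3, dimnames = list("e1", genes)),
                          uni, "expression", "closeness")
  expect_error(combine_sources(m1, m3), "measure")
  # row sums of the OR dominate each source
  set.seed(109)
  for (rep in 1:10) {
    a <- random_membership(4, genes, "e", density = 0.5, source = "text")
    b_vals <- matrix(stats::runif(12) < 0.5, 4, dimnames = dimnames(a))
    b <- membership_matrix(b_vals, uni, "expression", "degree")
    comb <- combine_sources(a, b)
    expect_true(all(rowSums(comb) >= pmax(rowSums(a), rowSums(b))))
  }
})
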