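test_genes <- function(tss, ids = NULL, chrom = "c") {
  tibble::tibble(
    gene_id = ids %||% sprintf("g%02d", seq_along(tss)),
    chrom = chrom, tss = as.integer(tss), strand = "+"
  )
}

test_that("closest gene minimizes edge distance with documented tie rules", {
  g <- test_genes(c(1000, 5000))
  res <- closest_gene(iv("c", 1900, 2100, id = "e"), g)
  expect_equal(res$gene_id, "g01")  # 900 vs 2900
  expect_equal(res$distance, 900)

  res2 <- closest_gene(iv("c", 1900, 2100), test_genes(2000))
  expect_equal(res2$distance, 0)

  # equidistant: lexicographically smaller id wins
  res3 <- closest_gene(iv("c", 2000, 2100),
                       test_genes(c(1900, 2200), ids = c("gB", "gA")))
  expect_equal(res3$distance, 100)
  expect_equal(res3$gene_id, "gA")

  expect_warning(
    res4 <- closest_gene(iv("other", 0, 100), g),
    "without genes"
  )
  expect_true(is.na(res4$gene_id))
})

test_that("closest-gene assignment is translation invariant", {
  withr::with_seed(21, {
    s <- sample(0:50000, 30)
    els <- iv("c", s, s + sample(100:900, 30, replace = TRUE),
              id = sprintf("e%02d", 1:30))
    genes <- test_genes(sample(0:50000, 15))
  })
  base <- closest_gene(els, genes)
  shift <- 12345L
  moved <- closest_gene(
    dplyr::mutate(els, start = start + shift, end = end + shift),
    dplyr::mutate(genes, tss = tss + shift)
  )
  expect_equal(moved$gene_id, base$gene_id)
  expect_equal(moved$distance, base$distance)
})

test_that("category expression deduplicates genes within a category", {
  catalogs <- list(
    C = iv("c", c(900, 1100), c(1000, 1200), id = c("x", "y"), category = "C"),
    F = iv("c", 8000, 9000, id = "z", category = "F")
  )
  genes <- test_genes(c(1050, 8500), ids = c("gC", "gF"))
  expr <- tibble::tibble(gene_id = c("gC", "gF"), tpm = c(50, 2))
  ce <- category_expression(catalogs, genes, expr)
  expect_equal(ce$tpm[ce$category == "C"], 50)   # both elements, one gene
  expect_equal(nrow(ce[ce$category == "C", ]), 1)
  expect_equal(ce$tpm[ce$category == "F"], 2)
  # empty category contributes nothing rather than failing
  catalogs$A <- catalogs$C[0, ]
  ce2 <- category_expression(catalogs, genes, expr)
  expect_false("A" %in% ce2$category)
})

test_that("planted expression boost ranks active categories above the rest", {
  b <- generate_scenario(mini_config(seed = 31))
  part <- b$truth$partition
  catalogs <- category_elements(part, b$noncrms)
  catalogs$E <- attr(catalogs, "peaks_by_category")$E
  ce <- category_expression(catalogs, b$genes, b$expression)
  med <- tapply(ce$tpm, ce$category, stats::median)
  expect_gt(min(med[c("B", "C")]), max(med[c("A", "D", "E", "F")],
                                       na.rm = TRUE))
})

test_that("exact MWU branch matches full enumeration for n+m <= 10", {
  expect_equal(mwu_test(c(1, 2, 3), c(4, 5, 6))$p_two_sided, 0.1)
  expect_equal(mwu_test(c(1, 2, 3), c(4, 5, 6))$U, 0)
  withr::with_seed(51, {
    for (i in 1:25) {
      n <- sample(2:5, 1); m <- sample(2:5, 1)
      vals <- sample(1:1000, n + m)  # distinct -> no ties
      x <- vals[1:n]; y <- vals[-(1:n)]
      res <- mwu_test(x, y)
      expect_equal(res$method, "exact")
      expect_equal(res$p_two_sided, oracle_mwu_p(x, y), tolerance = 1e-12,
                   info = paste("case", i))
    }
  })
})

test_that("MWU is symmetric and saturates at 1 for identical samples", {
  x <- c(1.5, 2.5, 9, 4)
  y <- c(8, 0.5, 3, 7, 11)
  expect_equal(mwu_test(x, y)$p_two_sided, mwu_test(y, x)$p_two_sided)
  same <- c(2, 2, 5, 7)
  expect_equal(mwu_test(same, same)$p_two_sided, 1)
  # ties force the corrected normal approximation
  expect_equal(mwu_test(same, same)$method, "normal")
})

test_that("KS statistic is the sup ECDF distance and rank-invariant", {
  expect_equal(ks_test(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_test(c(0, 0), c(1, 1))$D, 1)
  withr::with_seed(61, {
    x <- stats::rnorm(40)
    y <- stats::rnorm(40, 1)
  })
  d1 <- ks_test(x, y)$D
  d2 <- ks_test(exp(x), exp(y))$D  # strictly monotone transform
  expect_equal(d1, d2)
})

test_that("pairwise expression tests cover every category pair", {
  ce <- tibble::tibble(
    category = rep(c("B", "E", "F"), each = 20),
    gene_id = sprintf("g%02d", 1:60),
    tpm = c(stats::rlnorm(20, 3), stats::rlnorm(20, 1), stats::rlnorm(20, 1))
  )
  tests <- expression_test_matrix(ce, adjust = TRUE)
  expect_equal(nrow(tests), 3)
  expect_true(all(c("p_mwu", "p_ks", "p_mwu_bh") %in% names(tests)))
  expect_true(all(tests$p_mwu >= 0 & tests$p_mwu <= 1))
})
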