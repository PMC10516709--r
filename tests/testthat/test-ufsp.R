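make_features <- function(n, means, sd = 0.1, seed = 1, prefix = "e") {
  withr::with_seed(seed, {
    tibble::tibble(
      element_id = sprintf("%s%04d", prefix, seq_len(n)),
      ca = stats::rnorm(n, means[1], sd),
      h3k4me1 = stats::rnorm(n, means[2], sd),
      h3k4me3 = stats::rnorm(n, means[3], sd),
      h3k27ac = stats::rnorm(n, means[4], sd)
    )
  })
}

test_that("feature extraction is a log1p mean fold enrichment", {
  g <- tiny_genome(1000)
  s2 <- const_track(g, 2, library_size = 10)
  s0 <- const_track(g, 0, library_size = 10)
  inp <- const_track(g, 1, library_size = 10)
  marks <- list(ca = s2, h3k4me1 = s0, h3k4me3 = s2, h3k27ac = s2)
  f <- extract_features(iv("chr1", 100, 300, id = "x"), marks, inp)
  expect_equal(f$ca, log1p(2))
  expect_equal(f$h3k4me1, 0)

  # doubling signal values and library size leaves the feature unchanged
  s4 <- const_track(g, 4, library_size = 20)
  f2 <- extract_features(iv("chr1", 100, 300),
                         list(ca = s4, h3k4me1 = s0, h3k4me3 = s2, h3k27ac = s2),
                         inp)
  expect_equal(f2$ca, f$ca)

  expect_error(
    extract_features(iv("chr2", 0, 10), marks, inp),
    "chr2"
  )
})

test_that("training separates separable classes fully and is deterministic", {
  pos <- make_features(100, rep(2, 4), seed = 1)
  neg <- make_features(100, rep(-2, 4), seed = 2, prefix = "n")
  m <- ufsp_train(pos, neg)
  pr <- ufsp_predict(m, rbind(pos, neg))
  labels <- rep(c(1, 0), each = 100)
  expect_equal(auroc(pr$probability, labels), 1.0)
  expect_gte(min(pr$probability[1:100]), max(pr$probability[101:200]))

  m2 <- ufsp_train(pos, neg)
  expect_identical(m$weights, m2$weights)
  expect_identical(m$intercept, m2$intercept)
})

test_that("random labels give chance-level training AUROC across seeds", {
  aucs <- vapply(1:20, function(s) {
    feats <- make_features(2000, rep(0, 4), sd = 1, seed = s)
    lab <- withr::with_seed(1000 + s, sample(c(TRUE, FALSE), 2000, replace = TRUE))
    m <- ufsp_train(feats[lab, ], feats[!lab, ])
    pr <- ufsp_predict(m, feats)
    auroc(pr$probability, lab)
  }, 0)
  expect_true(all(abs(aucs - 0.5) <= 0.05))
})

test_that("identical classes give near-zero weights and prior probabilities", {
  f <- make_features(200, rep(1, 4), seed = 3)
  expect_warning(m <- ufsp_train(f, f), NA) # no zero-variance warning expected
  expect_lt(max(abs(m$weights)), 1e-3)
  pr <- ufsp_predict(m, f)
  expect_true(all(abs(pr$probability - 0.5) < 1e-3))
})

test_that("prediction follows the inclusive threshold and flags bad input", {
  m <- structure(
    list(feature_names = c("ca", "h3k4me1", "h3k4me3", "h3k27ac"),
         weights = stats::setNames(rep(0, 4), c("ca", "h3k4me1", "h3k4me3", "h3k27ac")),
         intercept = 0,
         center = stats::setNames(rep(0, 4), c("ca", "h3k4me1", "h3k4me3", "h3k27ac")),
         scale = stats::setNames(rep(1, 4), c("ca", "h3k4me1", "h3k4me3", "h3k27ac")),
         lambda = 0, threshold = 0.5, n_positive = 1, n_negative = 1),
    class = "ufsp_model")
  f <- make_features(5, rep(1, 4))
  pr <- ufsp_predict(m, f)
  expect_true(all(pr$probability == 0.5))
  expect_true(all(pr$state == "active"))  # probability == threshold -> active
  expect_error(ufsp_predict(m, f[, c("element_id", "ca")]), "missing")
})

test_that("probability is monotone in a positively weighted feature", {
  pos <- make_features(200, c(2, 1, 1, 1), seed = 4)
  neg <- make_features(200, c(-2, 1, 1, 1), seed = 5, prefix = "n")
  m <- ufsp_train(pos, neg)
  expect_gt(m$weights[["ca"]], 0)
  base <- make_features(1, rep(1, 4))
  grid <- base[rep(1, 15), ]
  grid$ca <- seq(-2, 2, length.out = 15)
  p <- ufsp_predict(m, grid)$probability
  expect_true(all(diff(p) >= 0))
})

test_that("zero-variance features warn and are retained", {
  pos <- make_features(50, rep(1, 4), seed = 6)
  neg <- make_features(50, rep(0, 4), seed = 7, prefix = "n")
  pos$h3k4me3 <- 1; neg$h3k4me3 <- 1
  expect_warning(m <- ufsp_train(pos, neg), "zero-variance")
  expect_length(m$weights, 4)
})

test_that("JSON serialization round-trips the model and its predictions", {
  pos <- make_features(80, rep(1.5, 4), seed = 8)
  neg <- make_features(80, rep(0, 4), seed = 9, prefix = "n")
  m <- ufsp_train(pos, neg)
  f <- withr::local_tempfile(fileext = ".json")
  write_ufsp(m, f)
  m2 <- read_ufsp(f)
  expect_equal(m2$weights, m$weights)
  expect_equal(ufsp_predict(m2, pos)$probability,
               ufsp_predict(m, pos)$probability)
})
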