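test_that("constant fields give constant bins; zero signal gives zeros", {
  g <- tiny_genome(20000)
  inp <- const_track(g, 1, library_size = 10)
  pm <- profile_matrix(iv("chr1", 9000, 9400), const_track(g, 2, 10), inp)
  expect_equal(dim(pm$values), c(1, 60))
  expect_true(all(pm$values == 2))
  expect_false(any(pm$mask))
  pm0 <- profile_matrix(iv("chr1", 9000, 9400), const_track(g, 0, 10), inp)
  expect_true(all(pm0$values == 0))
})

test_that("windows extending past the chromosome are masked, not zeroed", {
  g <- tiny_genome(20000)
  inp <- const_track(g, 1, library_size = 10)
  sig <- const_track(g, 3, library_size = 10)
  pm <- profile_matrix(iv("chr1", 50, 150), sig, inp)
  # midpoint 100; window [-2900, 3100): first 29 bins off-chromosome
  expect_true(all(pm$mask[1, 1:29]))
  expect_true(all(!pm$mask[1, 30:60]))
  expect_true(all(is.na(pm$values[1, 1:29])))
  expect_true(all(pm$values[1, 30:60] == 3))
})

test_that("column means ignore masked bins and flag fully masked columns", {
  g <- tiny_genome(20000)
  inp <- const_track(g, 1, library_size = 10)
  rows <- iv("chr1", c(5000, 9000), c(5400, 9400))
  two <- signal_track(iv("chr1", c(0, 7000), c(7000, 20000), value = c(1, 3)),
                      g, library_size = 10)
  pm <- profile_matrix(rows, two, inp)
  # windows [2200, 8200) and [6200, 12200): bins left of the step average 1,
  # bins straddling the two rows average 2, bins right of the step average 3
  expect_equal(unname(profile_mean(pm)),
               c(rep(1, 8), rep(2, 40), rep(3, 12)))
  # single row equals the row itself
  pm1 <- profile_matrix(rows[1, ], two, inp)
  expect_equal(unname(profile_mean(pm1)), unname(pm1$values[1, ]))
  # an element close to the start: leading column means NA for that-only matrix
  pm2 <- profile_matrix(iv("chr1", 50, 150), two, inp)
  expect_true(all(is.na(profile_mean(pm2)[1:29])))
})

test_that("profiles are invariant to joint scaling of signal and library", {
  g <- tiny_genome(20000)
  inp <- const_track(g, 1, library_size = 10)
  el <- iv("chr1", 9000, 9500)
  a <- profile_matrix(el, const_track(g, 2, library_size = 10), inp)
  b <- profile_matrix(el, const_track(g, 10, library_size = 50), inp)
  expect_equal(a$values, b$values)
})

test_that("planted center bump separates C elements from flat F background", {
  b <- generate_scenario(mini_config(seed = 41))
  catalogs <- category_elements(b$truth$partition, b$noncrms)
  c_rows <- sample_category_rows(catalogs, "C", seed = 1)
  f_rows <- sample_category_rows(catalogs, "F", seed = 1)
  ratio <- function(rows) {
    pm <- profile_matrix(rows, b$tracks$h3k27ac, b$tracks$input,
                         window = 4000, bin = 100)
    mu <- profile_mean(pm)
    center <- mean(mu[19:22], na.rm = TRUE)
    flank <- mean(mu[c(1:4, 37:40)], na.rm = TRUE)
    center / flank
  }
  # C elements carry the planted mark; F windows are flat inside the element
  # (their flanks may touch marked CRM neighbors, so only the ordering and a
  # clear center excess for C are asserted)
  expect_gt(ratio(c_rows), 2)
  expect_gt(ratio(c_rows), ratio(f_rows) * 1.5)
})

test_that("row order permutation changes no column mean", {
  g <- tiny_genome(30000)
  inp <- const_track(g, 1, library_size = 10)
  withr::with_seed(71, {
    s <- sample(5000:25000, 12)
    rows <- iv("chr1", s, s + 300)
    sig <- signal_track(
      iv("chr1", seq(0, 29000, by = 1000), seq(1000, 30000, by = 1000),
         value = sample(0:5, 30, replace = TRUE)), g, library_size = 10)
  })
  m1 <- profile_mean(profile_matrix(rows, sig, inp))
  m2 <- profile_mean(profile_matrix(rows[sample(12), ], sig, inp))
  expect_equal(m2, m1)
})

test_that("category row sampling follows the per-category rules", {
  b <- generate_scenario(mini_config(seed = 42))
  catalogs <- category_elements(b$truth$partition, b$noncrms)
  # categories C-E: everything is returned
  expect_equal(nrow(sample_category_rows(catalogs, "C", seed = 1)),
               nrow(catalogs$C))
  # cap applies to A and B
  capped <- sample_category_rows(catalogs, "A", cap = 3, seed = 1)
  expect_equal(nrow(capped), min(3, nrow(catalogs$A)))
  # |A| < cap returns all of A
  expect_equal(nrow(sample_category_rows(catalogs, "A", cap = 1e6, seed = 1)),
               nrow(catalogs$A))
  # F is downsampled to |E|
  f_rows <- sample_category_rows(catalogs, "F", seed = 1)
  expect_equal(nrow(f_rows), min(nrow(catalogs$F), nrow(catalogs$E)))
  # determinism
  expect_identical(sample_category_rows(catalogs, "A", cap = 3, seed = 9),
                   sample_category_rows(catalogs, "A", cap = 3, seed = 9))
})
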