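worked_example <- function() {
  list(
    genome = tiny_genome(1000),
    active = iv("chr1", 100, 300),
    nonactive = iv("chr1", 500, 700),
    noncrms = iv("chr1", c(0, 300, 700), c(100, 500, 1000)),
    peaks = iv("chr1", c(250, 600), c(450, 900))
  )
}

test_that("the 1-kb worked example is labeled exactly and matches the oracle", {
  w <- worked_example()
  p <- partition_genome(w$genome, w$active, w$nonactive, w$noncrms, w$peaks)
  expect_equal(p$base_counts,
               c(A = 100, B = 150, C = 50, D = 100, E = 350, F = 250))
  expect_equal(sum(p$base_counts), 1000)
  oracle <- oracle_base_counts(c(chr1 = 1000), w$active, w$nonactive,
                               w$noncrms, w$peaks)
  expect_equal(p$base_counts, oracle)
})

test_that("degenerate peak inputs saturate or empty the peak categories", {
  w <- worked_example()
  no_peaks <- iv(character(), integer(), integer())
  p0 <- partition_genome(w$genome, w$active, w$nonactive, w$noncrms, no_peaks)
  expect_equal(unname(p0$base_counts[c("C", "D", "E")]), c(0, 0, 0))
  expect_equal(unname(p0$base_counts[["B"]]), 200)
  expect_equal(unname(p0$base_counts[["F"]]), 600)

  all_peaks <- iv("chr1", 0, 1000)
  p1 <- partition_genome(w$genome, w$active, w$nonactive, w$noncrms, all_peaks)
  expect_equal(unname(p1$base_counts[c("A", "B", "F")]), c(0, 0, 0))
})

test_that("coverage gaps and CRM overlaps are rejected with diagnostics", {
  w <- worked_example()
  expect_error(
    partition_genome(w$genome, w$active, iv("chr1", 250, 700), w$noncrms, w$peaks),
    "overlap"
  )
  expect_error(
    partition_genome(w$genome, w$active, w$nonactive,
                     iv("chr1", c(0, 300, 700), c(100, 500, 900)), w$peaks),
    "cover"
  )
})

test_that("partition equals the per-base oracle on random small genomes", {
  for (seed in 1:25) {
    inp <- random_partition_inputs(max_len = 3000, seed = seed)
    g <- genome_spec(inp$sizes)
    p <- partition_genome(g, inp$active, inp$nonactive, inp$noncrms, inp$peaks)
    oracle <- oracle_base_counts(inp$sizes, inp$active, inp$nonactive,
                                 inp$noncrms, inp$peaks)
    expect_equal(p$base_counts, oracle, info = paste("seed", seed))
  }
})

test_that("conservation identities hold and input order never matters", {
  for (seed in 26:40) {
    inp <- random_partition_inputs(max_len = 4000, seed = seed)
    g <- genome_spec(inp$sizes)
    p <- partition_genome(g, inp$active, inp$nonactive, inp$noncrms, inp$peaks)
    k <- p$base_counts
    expect_equal(sum(k), total_length(g$analyzable))
    expect_equal(k[["C"]] + k[["D"]] + k[["E"]],
                 intersect_length(inp$peaks, g$analyzable))
    expect_equal(k[["B"]] + k[["C"]], total_length(inp$active))
    expect_equal(k[["A"]] + k[["D"]], total_length(inp$nonactive))
    expect_equal(k[["E"]] + k[["F"]], total_length(inp$noncrms))

    shuf <- function(x) x[sample.int(nrow(x)), , drop = FALSE]
    withr::with_seed(seed, {
      p2 <- partition_genome(g, shuf(inp$active), shuf(inp$nonactive),
                             shuf(inp$noncrms), shuf(inp$peaks))
    })
    expect_equal(p2$base_counts, k)
  }
})

test_that("peak bases outside the analyzable regions are counted separately", {
  g <- genome_spec(c(chr1 = 1000), analyzable = iv("chr1", 0, 800))
  p <- partition_genome(
    g,
    iv("chr1", 100, 300), iv("chr1", 500, 700),
    iv("chr1", c(0, 300, 700), c(100, 500, 800)),
    iv("chr1", 700, 900)
  )
  expect_equal(unname(p$base_counts[["E"]]), 100)
  expect_equal(p$unassessed_peak_bases, 100)
  expect_equal(sum(p$base_counts), 800)
})

test_that("element matching follows the 50% reciprocal rule", {
  pairs <- match_peaks_to_crms(iv("chr1", 250, 450, id = "p"),
                               iv("chr1", 100, 300, id = "c"))
  expect_equal(nrow(pairs), 0)  # overlap 50 of 200: 0.25 < 0.5
  pairs <- match_peaks_to_crms(iv("chr1", 150, 350, id = "p"),
                               iv("chr1", 100, 300, id = "c"))
  expect_equal(nrow(pairs), 1)  # 150/200 = 0.75 both
  expect_equal(pairs$containment, "partial")
  expect_equal(nrow(match_peaks_to_crms(iv(character(), integer(), integer()),
                                        iv("chr1", 0, 100))), 0)
})

test_that("containment is full only when the CRM lies inside the peak", {
  expect_equal(containment_class(iv("c", 50, 350), iv("c", 100, 300)), "full")
  expect_equal(containment_class(iv("c", 150, 350), iv("c", 100, 300)), "partial")
  expect_equal(containment_class(iv("c", 100, 300), iv("c", 100, 300)), "full")
})

test_that("peaks-per-CRM counts distinct matched peaks", {
  crms <- iv("chr1", c(100, 1000), c(300, 1400), id = c("c1", "c2"))
  peaks <- iv("chr1", c(120, 1000, 1180), c(320, 1200, 1400),
              id = c("p1", "p2", "p3"))
  pairs <- match_peaks_to_crms(peaks, crms)
  ppc <- peaks_per_crm(crms, pairs)
  expect_equal(ppc$n_peaks[ppc$crm_id == "c1"], 1L)
  expect_equal(ppc$n_peaks[ppc$crm_id == "c2"], 2L)
  ppc0 <- peaks_per_crm(crms, pairs[0, ])
  expect_equal(ppc0$n_peaks, c(0L, 0L))
})

test_that("cross-sample activity computes percentages with a zero diagonal", {
  d <- list(s1 = c("c1", "c2"), s2 = character())
  c_ <- list(s1 = c("c9"), s2 = c("c1"))
  m <- cross_sample_activity(d, c_)
  expect_equal(m["s1", "s2"], 50)
  expect_equal(m["s1", "s1"], 0)
  expect_true(is.na(m["s2", "s1"]))  # empty D set -> undefined
  full <- cross_sample_activity(list(a = "x", b = "x"), list(a = "x", b = "x"))
  expect_equal(full["a", "b"], 100)
})

test_that("derived ratios re-derive from base counts", {
  w <- worked_example()
  p <- partition_genome(w$genome, w$active, w$nonactive, w$noncrms, w$peaks)
  r <- partition_ratios(p)
  k <- p$base_counts
  expect_equal(r$c_share, 100 * k[["C"]] / (k[["C"]] + k[["D"]] + k[["E"]]),
               tolerance = 1e-12)
  expect_equal(r$b_of_active, 100 * k[["B"]] / (k[["B"]] + k[["C"]]),
               tolerance = 1e-12)
  expect_equal(r$c_share + r$d_share + r$e_share, 100, tolerance = 1e-12)
})
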