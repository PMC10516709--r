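test_that("identical config and seed give byte-identical bundles on disk", {
  cfg <- mini_config(seed = 101)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  generate_scenario(cfg, dir = d1)
  generate_scenario(cfg, dir = d2)
  files <- list.files(d1, recursive = TRUE)
  expect_gt(length(files), 10)
  expect_setequal(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
})

test_that("every emitted file re-parses through the package readers", {
  d <- withr::local_tempdir()
  b <- generate_scenario(mini_config(seed = 102), dir = d)
  g <- genome_spec(stats::setNames(
    readr::read_tsv(file.path(d, "genome.tsv"), show_col_types = FALSE)$length,
    readr::read_tsv(file.path(d, "genome.tsv"), show_col_types = FALSE)$chrom
  ))
  expect_equal(g$chrom_sizes, b$genome$chrom_sizes)
  expect_no_warning({
    crms <- read_bed(file.path(d, "crms.bed"), genome = g)
    peaks <- read_bed(file.path(d, "peaks.bed"), genome = g)
    tfbs <- read_bed(file.path(d, "tfbs.bed"), genome = g)
    chromhmm <- read_bed(file.path(d, "chromhmm.bed"), genome = g)
    te <- read_bed(file.path(d, "te.bed"), genome = g)
    genes <- read_genes(file.path(d, "genes.tsv"))
    expr <- read_expression(file.path(d, "expression.tsv"))
    net <- read_motif_network(file.path(d, "network.tsv"))
    fa <- read_genome_fasta(file.path(d, "genome.fa"))
    atac <- signal_track(file.path(d, "tracks", "ca.bedGraph"), g)
  })
  expect_equal(nrow(crms), nrow(b$crms))
  expect_equal(nrow(peaks), nrow(b$peaks))
  expect_equal(sort(names(fa)), sort(names(g$chrom_sizes)))
  expect_equal(unname(vapply(as.character(fa), nchar, 0)),
               unname(g$chrom_sizes[names(fa)]))
  expect_equal(sum(net$degree), 2 * nrow(net$edges))
  expect_equal(sort(expr$gene_id), sort(genes$gene_id))
  expect_equal(nrow(tfbs), nrow(b$tfbs))
  expect_gt(nrow(chromhmm), 0)
  expect_gt(nrow(te), 0)
})

test_that("truth labels are consistent with the generated intervals", {
  b <- generate_scenario(mini_config(seed = 103))
  # every intended-C peak lies inside an intended-active CRM
  states <- b$truth$crm_states
  active <- b$crms[match(states$id[states$state == "active"], b$crms$id), ]
  for (k in c("C", "D", "E")) {
    pk <- b$peaks[b$peaks$category == k, ]
    host <- switch(k,
      C = active[, c("chrom", "start", "end")],
      D = b$crms[b$crms$state == "non-active", c("chrom", "start", "end")],
      E = b$noncrms[, c("chrom", "start", "end")]
    )
    expect_equal(intersect_length(pk[, c("chrom", "start", "end")], host),
                 sum(pk$end - pk$start), info = k)
  }
  # the oracle partition reproduces the intended category of every peak
  catalogs <- category_elements(b$truth$partition, b$noncrms)
  pk_cat <- attr(catalogs, "peaks_by_category")
  for (k in c("C", "D", "E")) {
    expect_setequal(pk_cat[[k]]$id, b$peaks$id[b$peaks$category == k])
  }
})

test_that("planted C:D:E mixtures are recovered within binomial error", {
  b <- generate_scenario(scenario_config(seed = 7))
  r <- partition_ratios(b$truth$partition)
  mix <- b$config$peak_category_mix
  expect_lt(abs(r$c_share - 100 * mix[["C"]]), 3)
  expect_lt(abs(r$d_share - 100 * mix[["D"]]), 3)
  expect_lt(abs(r$e_share - 100 * mix[["E"]]), 3)
})

test_that("active_fraction 0 reallocates intended-C mass or errors", {
  cfg <- mini_config(seed = 104, active_fraction = 0)
  b <- generate_scenario(cfg)
  expect_equal(sum(b$peaks$category == "C"), 0)
  expect_equal(nrow(b$peaks), cfg$peak_count)
  cfg_err <- mini_config(seed = 104, active_fraction = 0,
                         on_infeasible = "error")
  expect_error(generate_scenario(cfg_err), "not enough C hosts")
})

test_that("null scenarios plant no effects", {
  b <- generate_null_scenario(mini_config(seed = 105))
  # no expression boost recorded
  expect_true(all(!b$truth$gene_effects$boosted %in% TRUE) ||
                b$config$expression_effect == 1)
  # mark contrast absent: feature means similar between states
  feats <- extract_features(b$crms, b$tracks[c("ca", "h3k4me1", "h3k4me3",
                                               "h3k27ac")], b$tracks$input)
  st <- b$truth$crm_states$state[match(feats$element_id, b$truth$crm_states$id)]
  gap <- abs(mean(feats$ca[st == "active"]) - mean(feats$ca[st == "non-active"]))
  expect_lt(gap, 0.05)
  # conservation centered at zero inside CRMs
  cons <- conservation_distribution(b$crms[1:20, ], b$tracks$conservation)
  expect_lt(abs(mean(cons)), 0.1)
})

test_that("infeasible packing is rejected before writing", {
  cfg <- scenario_config(n_chroms = 1, chrom_length = 50000, crm_count = 200,
                         seed = 1)
  expect_error(generate_scenario(cfg), "infeasible packing")
})
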