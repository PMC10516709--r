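# Small builders shared across test files.

iv <- function(chrom, start, end, ...) {
  tibble::tibble(chrom = chrom, start = start, end = end, ...)
}

# single-chromosome genome with a constant-value track pair
tiny_genome <- function(len = 1000, chrom = "chr1") {
  genome_spec(stats::setNames(len, chrom))
}

const_track <- function(genome, value, library_size = NULL) {
  signal_track(dplyr::mutate(genome$analyzable, value = value), genome,
               library_size = library_size)
}

# a small but complete scenario: quick enough to generate repeatedly
mini_config <- function(seed = 1, ...) {
  scenario_config(
    n_chroms = 1, chrom_length = 150000, crm_count = 60,
    peak_count = 80, n_genes = 150, seed = seed, ...
  )
}
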