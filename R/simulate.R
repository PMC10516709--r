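#' Scenario configuration for the synthetic-genome generator
#'
#' Defines the study conditions a synthetic scenario emulates: a small
#' multi-chromosome genome whose analyzable bases are exhaustively split
#' into CRMs and non-CRMs, a planted active fraction, STARR peaks drawn with
#' a configurable C/D/E base-share mixture, epigenetic-mark tracks with
#' category-specific fold enrichments, genes with a multiplicative
#' expression boost near active CRMs, TFBS hits tied to a degree-annotated
#' motif network, a heterochromatin-state annotation elevated inside
#' category-E peaks, transposable-element intervals depleted in CRMs, and a
#' conservation track elevated inside CRMs.
#'
#' Default sizes target the source study's element geometry at desk scale:
#' CRM lengths are log-normal with mean 1181 bp, peak lengths log-normal
#' with median 500 bp, and the default peak mixture C:D:E = 0.23:0.28:0.49
#' matches the averaged category shares of STARR peak positions.
#'
#' @param n_chroms,chrom_length Genome shape (default 3 x 800 kb).
#' @param crm_count Number of CRMs planted (default 900).
#' @param crm_meanlog,crm_sdlog Log-normal CRM length parameters (defaults
#'   give mean 1181 bp).
#' @param active_fraction Fraction of CRMs planted active (default 0.4).
#' @param peak_count Number of STARR peaks (default 1000).
#' @param peak_meanlog,peak_sdlog Log-normal peak length parameters
#'   (defaults give median 500 bp).
#' @param peak_category_mix Named numeric (C, D, E) target mixture; must sum
#'   to 1.
#' @param mark_effects 6 x 6 matrix (marks x categories A-F) of mean fold
#'   enrichments planted for each mark.
#' @param starr_effects Named numeric (C, D, E) STARR-signal fold
#'   enrichments inside peaks of each category.
#' @param input_rate Expected input reads per track step (default 5).
#' @param track_step Track resolution in bp (default 10).
#' @param expression_effect Multiplicative TPM boost for genes nearest an
#'   active CRM (default 4).
#' @param n_genes Number of genes (default 500).
#' @param tfbs_rates Named numeric hits/kb for `c_like`, `other_crm`,
#'   `e_like`, `background`.
#' @param n_motifs Motif network size (default 60).
#' @param conservation_effect Mean conservation shift inside CRMs (default
#'   1.5).
#' @param gc Genome GC fraction (default 0.41) or, when `gc_profile` is
#'   given, ignored.
#' @param gc_profile Optional length-2 numeric: linear GC gradient from the
#'   start to the end of every chromosome.
#' @param te_rate,te_length,te_crm_keep Transposable-element density
#'   (elements/kb), length, and the retention probability of TEs whose
#'   center falls in a CRM.
#' @param het_e_cover Fraction of each category-E peak covered by the `Het`
#'   state (default 0.6).
#' @param het_genome Genome-wide `Het` base fraction (default 0.1); the
#'   background rate outside E peaks is solved so this holds exactly in
#'   expectation.
#' @param min_gap Minimum non-CRM gap between CRMs in bp (default 300).
#' @param min_peak_len Minimum peak length in bp (default 200).
#' @param on_infeasible `"reallocate"` (move C mass to D/E when there are
#'   not enough active hosts) or `"error"`.
#' @param seed RNG seed; the whole bundle is deterministic given the seed.
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(
    n_chroms = 3, chrom_length = 800000,
    crm_count = 900,
    crm_meanlog = log(1181) - 0.5^2 / 2, crm_sdlog = 0.5,
    active_fraction = 0.4,
    peak_count = 1000,
    peak_meanlog = log(500), peak_sdlog = 0.25,
    peak_category_mix = c(C = 0.23, D = 0.28, E = 0.49),
    mark_effects = default_mark_effects(),
    starr_effects = c(C = 6, D = 4.5, E = 3),
    input_rate = 5, track_step = 10,
    expression_effect = 4, n_genes = 500,
    tfbs_rates = c(c_like = 10, other_crm = 5, e_like = 6, background = 2),
    n_motifs = 60,
    conservation_effect = 1.5,
    gc = 0.41, gc_profile = NULL,
    te_rate = 0.3, te_length = 300, te_crm_keep = 0.15,
    het_e_cover = 0.6, het_genome = 0.1,
    min_gap = 300, min_peak_len = 200,
    on_infeasible = c("reallocate", "error"),
    seed = 1) {
  on_infeasible <- match.arg(on_infeasible)
  stopifnot(
    abs(sum(peak_category_mix) - 1) < 1e-8,
    all(peak_category_mix >= 0),
    all(tfbs_rates >= 0),
    chrom_length %% track_step == 0,
    het_e_cover >= 0, het_e_cover <= 1, het_genome >= 0, het_genome < 1
  )
  cfg <- as.list(environment())
  class(cfg) <- "scenario_config"
  cfg
}

#' Default per-category mark fold enrichments
#'
#' Rows are the six marks, columns the six categories A-F. Active CRMs
#' (B, C) carry strong accessibility and active histone marks; non-active
#' CRMs are depleted of them, with A moderately marked by both repressive
#' marks, D heavily marked by the Polycomb mark H3K27me3, and category-E
#' non-CRM peaks heavily marked by the heterochromatin mark H3K9me3.
#'
#' @return A 6 x 6 numeric matrix.
#' @export
default_mark_effects <- function() {
  m <- rbind(
    ca       = c(A = 1.0, B = 6.0, C = 8.0, D = 1.0, E = 1.0, F = 1.0),
    h3k4me1  = c(A = 1.5, B = 5.0, C = 6.0, D = 1.5, E = 1.0, F = 1.0),
    h3k4me3  = c(A = 1.0, B = 2.5, C = 3.0, D = 1.0, E = 1.0, F = 1.0),
    h3k27ac  = c(A = 1.0, B = 6.0, C = 8.0, D = 1.0, E = 1.0, F = 1.0),
    h3k9me3  = c(A = 2.0, B = 1.0, C = 1.0, D = 1.5, E = 5.0, F = 1.0),
    h3k27me3 = c(A = 2.0, B = 1.0, C = 1.0, D = 4.0, E = 1.0, F = 1.0)
  )
  m
}

#' Generate a null scenario
#'
#' Same skeleton as [generate_scenario()] but with every planted effect
#' removed: identical mark and STARR rates across categories, no expression
#' boost, no conservation shift, uniform TFBS rate, uniform `Het` coverage,
#' and no TE depletion. Used for type-I-error and enrichment calibration.
#'
#' @param config A [scenario_config()].
#' @param dir Optional output directory (see [generate_scenario()]).
#' @return A `synthetic_bundle`.
#' @export
generate_null_scenario <- function(config = scenario_config(), dir = NULL) {
  config$mark_effects[] <- 1
  config$starr_effects[] <- 1
  config$expression_effect <- 1
  config$conservation_effect <- 0
  config$tfbs_rates[] <- config$tfbs_rates[["background"]]
  config$het_e_cover <- config$het_genome
  config$te_crm_keep <- 1
  generate_scenario(config, dir = dir)
}

#' Generate a complete synthetic scenario
#'
#' Produces an in-memory bundle (and, when `dir` is given, an on-disk copy)
#' with every input the audit pipeline consumes, plus ground-truth labels.
#' Byte-identical output for identical config and seed.
#'
#' @param config A [scenario_config()].
#' @param dir Optional directory; when given, all files are written via
#'   [write_bundle()].
#' @return An object of class `synthetic_bundle`: genome spec, sequences,
#'   element tibbles (CRMs with states, non-CRMs, peaks with intended
#'   categories, TFBS hits, ChromHMM-like states, TEs), signal tracks,
#'   genes/expression, motif network, and `truth` labels.
#' @export
generate_scenario <- function(config = scenario_config(), dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  bundle <- withr::with_seed(config$seed, build_bundle(config))
  if (!is.null(dir)) write_bundle(bundle, dir)
  bundle
}

## ---- internal generator machinery -------------------------------------

build_bundle <- function(cfg) {
  chroms <- paste0("chr", seq_len(cfg$n_chroms))
  sizes <- stats::setNames(rep(cfg$chrom_length, cfg$n_chroms), chroms)
  genome <- genome_spec(sizes)

  layout <- plant_elements(cfg, chroms, sizes)
  crms <- layout$crms
  noncrms <- layout$noncrms

  peaks <- plant_peaks(cfg, crms, noncrms)
  active <- crms[crms$state == "active", c("chrom", "start", "end", "id")]
  nonactive <- crms[crms$state == "non-active", c("chrom", "start", "end", "id")]

  part <- partition_genome(genome, active, nonactive,
                           noncrms[, c("chrom", "start", "end", "id")],
                           peaks[, c("chrom", "start", "end", "id")],
                           sample_id = "truth")

  sequences <- simulate_sequences(cfg, chroms, sizes)
  tracks <- simulate_tracks(cfg, genome, part$labels)
  genes <- simulate_genes(cfg, chroms, sizes, crms, noncrms)
  tf <- simulate_tfbs(cfg, crms, noncrms, peaks, genome)
  chromhmm <- simulate_chromhmm(cfg, genome, crms, peaks)
  te <- simulate_te(cfg, genome, crms)

  structure(
    list(
      genome = genome,
      sequences = sequences,
      crms = crms,
      noncrms = noncrms,
      peaks = peaks,
      tfbs = tf$hits,
      network = tf$network,
      chromhmm = chromhmm,
      te = te,
      tracks = tracks,
      genes = genes$genes,
      expression = genes$expression,
      truth = list(
        crm_states = crms[, c("id", "state")],
        peak_categories = peaks[, c("id", "category")],
        gene_effects = genes$genes[, c("gene_id", "boosted")],
        partition = part
      ),
      config = cfg
    ),
    class = "synthetic_bundle"
  )
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle> ", length(x$genome$chrom_sizes), " chromosome(s), ",
      nrow(x$crms), " CRMs (", sum(x$crms$state == "active"), " active), ",
      nrow(x$noncrms), " non-CRMs, ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

## alternate CRMs and non-CRM gaps along each chromosome
plant_elements <- function(cfg, chroms, sizes) {
  counts <- round(cfg$crm_count * sizes / sum(sizes))
  counts[length(counts)] <- cfg$crm_count - sum(counts[-length(counts)])
  crm_rows <- list()
  gap_rows <- list()
  for (ci in seq_along(chroms)) {
    k <- counts[[ci]]
    len <- pmax(100L, round(stats::rlnorm(k, cfg$crm_meanlog, cfg$crm_sdlog)))
    free <- sizes[[ci]] - sum(len)
    need <- (k + 1) * cfg$min_gap
    if (free < need) {
      stop(sprintf(
        "infeasible packing on %s: %d bp of CRMs + %d bp of minimum gaps > %d bp",
        chroms[ci], sum(len), need, sizes[[ci]]
      ))
    }
    w <- stats::rexp(k + 1)
    extra <- floor((free - need) * w / sum(w))
    extra[k + 1] <- (free - need) - sum(extra[-(k + 1)])
    gaps <- cfg$min_gap + extra
    starts <- cumsum(c(gaps[1], utils::head(len + gaps[-1], -1)))
    crm_rows[[ci]] <- tibble::tibble(
      chrom = chroms[ci], start = as.integer(starts),
      end = as.integer(starts + len)
    )
    ge <- c(starts, sizes[[ci]])
    gs <- c(0, starts + len)
    gap_rows[[ci]] <- tibble::tibble(
      chrom = chroms[ci], start = as.integer(gs), end = as.integer(ge)
    )
  }
  crms <- dplyr::bind_rows(crm_rows)
  crms$id <- sprintf("crm_%05d", seq_len(nrow(crms)))
  n_active <- round(cfg$active_fraction * nrow(crms))
  act <- sample.int(nrow(crms), n_active)
  crms$state <- ifelse(seq_len(nrow(crms)) %in% act, "active", "non-active")
  noncrms <- dplyr::bind_rows(gap_rows)
  noncrms <- noncrms[noncrms$end > noncrms$start, , drop = FALSE]
  noncrms$id <- sprintf("noncrm_%05d", seq_len(nrow(noncrms)))
  list(crms = crms, noncrms = noncrms)
}

## place each peak fully inside a host element of its intended category
plant_peaks <- function(cfg, crms, noncrms) {
  n_cat <- as.vector(stats::rmultinom(1, cfg$peak_count, cfg$peak_category_mix))
  names(n_cat) <- names(cfg$peak_category_mix)
  hosts <- list(
    C = crms[crms$state == "active", , drop = FALSE],
    D = crms[crms$state == "non-active", , drop = FALSE],
    E = noncrms
  )
  for (k in c("C", "D", "E")) {
    short <- n_cat[[k]] - nrow(hosts[[k]])
    if (short > 0) {
      if (cfg$on_infeasible == "error") {
        stop(sprintf("not enough %s hosts for %d intended category-%s peaks",
                     k, n_cat[[k]], k))
      }
      others <- setdiff(c("C", "D", "E"), k)
      avail <- vapply(others, function(o) nrow(hosts[[o]]) - n_cat[[o]], 0)
      avail <- pmax(avail, 0)
      if (sum(avail) < short) stop("cannot reallocate peak mass: genome too full")
      move <- floor(short * avail / sum(avail))
      move[1] <- short - sum(move[-1])
      n_cat[[k]] <- n_cat[[k]] - short
      for (j in seq_along(others)) n_cat[[others[j]]] <- n_cat[[others[j]]] + move[j]
    }
  }
  rows <- list()
  for (k in c("C", "D", "E")) {
    n <- n_cat[[k]]
    if (n == 0) next
    h <- hosts[[k]]
    pick <- sample.int(nrow(h), n)
    hl <- h$end[pick] - h$start[pick]
    draw <- round(stats::rlnorm(n, cfg$peak_meanlog, cfg$peak_sdlog))
    plen <- pmin(pmax(draw, cfg$min_peak_len), hl)
    off <- vapply(hl - plen + 1L, function(m) sample.int(m, 1L), 1L) - 1L
    rows[[k]] <- tibble::tibble(
      chrom = h$chrom[pick],
      start = as.integer(h$start[pick] + off),
      end = as.integer(h$start[pick] + off + plen),
      category = k,
      host_id = h$id[pick]
    )
  }
  peaks <- sort_intervals(dplyr::bind_rows(rows))
  peaks$id <- sprintf("peak_%05d", seq_len(nrow(peaks)))
  peaks
}

simulate_sequences <- function(cfg, chroms, sizes) {
  seqs <- lapply(seq_along(chroms), function(ci) {
    n <- sizes[[ci]]
    if (is.null(cfg$gc_profile)) {
      gc <- rep(cfg$gc, n)
    } else {
      gc <- seq(cfg$gc_profile[1], cfg$gc_profile[2], length.out = n)
    }
    at <- (1 - gc) / 2
    u <- stats::runif(n)
    # cumulative cut points A | C | G | T with per-base GC
    base <- ifelse(u < at, "A",
            ifelse(u < at + gc / 2, "C",
            ifelse(u < at + gc, "G", "T")))
    paste(base, collapse = "")
  })
  ss <- Biostrings::DNAStringSet(unlist(seqs))
  names(ss) <- chroms
  ss
}

## internal constructor bypassing bedGraph parsing (dense, fully covered)
track_from_values <- function(values, library_size = NULL) {
  if (is.null(library_size)) {
    library_size <- sum(vapply(values, function(v) {
      sum(as.numeric(S4Vectors::runValue(v)) * S4Vectors::runLength(v))
    }, 0))
    if (library_size == 0) library_size <- 1
  }
  covered <- lapply(values, function(v) S4Vectors::Rle(TRUE, length(v)))
  structure(list(values = values, covered = covered,
                 library_size = library_size),
            class = "signal_track")
}

simulate_tracks <- function(cfg, genome, labels) {
  step <- cfg$track_step
  chroms <- names(genome$chrom_sizes)
  # per-chromosome category label at each track step (label of the bin start)
  lab_codes <- lapply(chroms, function(chr) {
    li <- labels[labels$chrom == chr, , drop = FALSE]
    code <- S4Vectors::Rle(factor(li$category, levels = category_levels),
                           li$end - li$start)
    n_bins <- genome$chrom_sizes[[chr]] %/% step
    as.integer(code[seq(1L, by = step, length.out = n_bins)])
  })
  names(lab_codes) <- chroms
  mark_names <- rownames(cfg$mark_effects)
  make_track <- function(rate_by_cat) {
    vals <- lapply(chroms, function(chr) {
      lam <- rate_by_cat[lab_codes[[chr]]]
      S4Vectors::Rle(rep(stats::rpois(length(lam), lam), each = step))
    })
    names(vals) <- chroms
    track_from_values(vals)
  }
  tracks <- list()
  tracks$input <- make_track(rep(cfg$input_rate, 6))
  for (m in mark_names) {
    tracks[[m]] <- make_track(cfg$input_rate * cfg$mark_effects[m, category_levels])
  }
  starr_rate <- rep(cfg$input_rate, 6)
  names(starr_rate) <- category_levels
  starr_rate[names(cfg$starr_effects)] <-
    cfg$input_rate * cfg$starr_effects
  tracks$starr <- make_track(unname(starr_rate))
  # conservation: gaussian around 0, shifted inside CRMs (categories A-D)
  cons <- lapply(chroms, function(chr) {
    lab <- lab_codes[[chr]]
    mu <- ifelse(lab <= 4, cfg$conservation_effect, 0)
    S4Vectors::Rle(rep(round(stats::rnorm(length(mu), mu, 0.5), 3), each = step))
  })
  names(cons) <- chroms
  tracks$conservation <- track_from_values(cons, library_size = 1)
  tracks
}

simulate_genes <- function(cfg, chroms, sizes, crms, noncrms) {
  n <- cfg$n_genes
  chr <- sample(chroms, n, replace = TRUE, prob = sizes)
  tss <- vapply(chr, function(c) sample.int(sizes[[c]], 1L) - 1L, 1L)
  genes <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = chr, tss = as.integer(tss),
    strand = sample(c("+", "-"), n, replace = TRUE)
  )
  elements <- dplyr::bind_rows(
    dplyr::mutate(crms[, c("chrom", "start", "end")], kind = crms$state),
    dplyr::mutate(noncrms[, c("chrom", "start", "end")], kind = "noncrm")
  )
  eg <- as_gr(elements)
  tg <- GenomicRanges::GRanges(genes$chrom,
                               IRanges::IRanges(genes$tss + 1L, genes$tss + 1L))
  near <- GenomicRanges::nearest(tg, eg)
  boosted <- !is.na(near) & elements$kind[near] == "active"
  tpm <- stats::rlnorm(n, meanlog = 1.5, sdlog = 1)
  tpm[boosted] <- tpm[boosted] * cfg$expression_effect
  genes$boosted <- boosted
  list(
    genes = genes,
    expression = tibble::tibble(gene_id = genes$gene_id, tpm = round(tpm, 4))
  )
}

simulate_tfbs <- function(cfg, crms, noncrms, peaks, genome) {
  n_motifs <- cfg$n_motifs
  motifs <- sprintf("M%03d", seq_len(n_motifs))
  n_hub <- max(2L, round(n_motifs / 6))
  hub <- motifs[seq_len(n_hub)]
  periph <- motifs[-seq_len(n_hub)]
  edges <- dplyr::bind_rows(
    purrr::map_dfr(hub, function(h) {
      to <- sample(periph, min(12, length(periph)))
      tibble::tibble(from = h, to = to)
    }),
    tibble::tibble(from = periph,
                   to = sample(periph, length(periph), replace = TRUE))
  )
  edges <- edges[edges$from != edges$to, , drop = FALSE]
  network <- motif_network(edges)

  c_hosts <- unique(peaks$host_id[peaks$category == "C"])
  e_hosts <- unique(peaks$host_id[peaks$category == "E"])
  class_of <- function(el, is_crm) {
    if (is_crm) ifelse(el$id %in% c_hosts, "c_like", "other_crm")
    else ifelse(el$id %in% e_hosts, "e_like", "background")
  }
  elements <- dplyr::bind_rows(
    dplyr::mutate(crms[, c("chrom", "start", "end", "id")],
                  class = class_of(crms, TRUE)),
    dplyr::mutate(noncrms[, c("chrom", "start", "end", "id")],
                  class = class_of(noncrms, FALSE))
  )
  hit_w <- 8L
  rows <- purrr::map_dfr(seq_len(nrow(elements)), function(i) {
    len <- elements$end[i] - elements$start[i]
    if (len <= hit_w) return(NULL)
    rate <- cfg$tfbs_rates[[elements$class[i]]]
    nh <- stats::rpois(1, rate * len / 1000)
    if (nh == 0) return(NULL)
    s <- elements$start[i] + sample.int(len - hit_w, nh, replace = TRUE)
    pool <- if (elements$class[i] == "c_like") hub else motifs
    tibble::tibble(chrom = elements$chrom[i], start = as.integer(s),
                   end = as.integer(s + hit_w),
                   motif_id = sample(pool, nh, replace = TRUE))
  })
  hits <- sort_intervals(rows)
  list(hits = hits, network = network)
}

simulate_chromhmm <- function(cfg, genome, crms, peaks) {
  e_peaks <- peaks[peaks$category == "E", , drop = FALSE]
  genome_bp <- sum(genome$chrom_sizes)
  f <- sum(e_peaks$end - e_peaks$start) / genome_bp
  r <- (cfg$het_genome - cfg$het_e_cover * f) / (1 - f)
  r <- max(0, r)
  tile <- 200L
  tiles <- purrr::map_dfr(names(genome$chrom_sizes), function(chr) {
    n <- genome$chrom_sizes[[chr]] %/% tile
    tibble::tibble(chrom = chr, start = (seq_len(n) - 1L) * tile,
                   end = seq_len(n) * tile)
  })
  in_e <- split_bases(tiles, e_peaks[, c("chrom", "start", "end")]) > 0
  keep <- !in_e & stats::runif(nrow(tiles)) < r
  het_bg <- tiles[keep, , drop = FALSE]
  ep_len <- e_peaks$end - e_peaks$start
  het_e <- tibble::tibble(
    chrom = e_peaks$chrom,
    start = as.integer(e_peaks$start + round(ep_len * (1 - cfg$het_e_cover) / 2)),
    end = as.integer(e_peaks$start + round(ep_len * (1 - cfg$het_e_cover) / 2)
                     + round(ep_len * cfg$het_e_cover))
  )
  het_e <- het_e[het_e$end > het_e$start, , drop = FALSE]
  het <- merge_intervals(dplyr::bind_rows(het_bg, het_e))
  active <- crms[crms$state == "active", c("chrom", "start", "end")]
  enh <- interval_setdiff(active, het)
  quies <- interval_setdiff(genome$analyzable,
                            dplyr::bind_rows(het, enh))
  sort_intervals(dplyr::bind_rows(
    dplyr::mutate(het, label = "Het"),
    dplyr::mutate(enh, label = "EnhA1"),
    dplyr::mutate(quies, label = "Quies")
  ))
}

simulate_te <- function(cfg, genome, crms) {
  genome_bp <- sum(genome$chrom_sizes)
  n <- stats::rpois(1, cfg$te_rate * genome_bp / 1000)
  chroms <- names(genome$chrom_sizes)
  chr <- sample(chroms, n, replace = TRUE, prob = genome$chrom_sizes)
  maxs <- genome$chrom_sizes[chr] - cfg$te_length
  s <- vapply(maxs, function(m) sample.int(m, 1L), 1L)
  te <- tibble::tibble(chrom = chr, start = as.integer(s),
                       end = as.integer(s + cfg$te_length))
  center <- tibble::tibble(chrom = te$chrom,
                           start = te$start + cfg$te_length %/% 2L,
                           end = te$start + cfg$te_length %/% 2L + 1L)
  in_crm <- split_bases(center, crms[, c("chrom", "start", "end")]) > 0
  keep <- !in_crm | stats::runif(n) < cfg$te_crm_keep
  te <- te[keep, , drop = FALSE]
  te$label <- sample(c("LINE", "SINE", "LTR"), nrow(te), replace = TRUE)
  sort_intervals(te)
}

#' Write a synthetic bundle to disk
#'
#' Emits the bundle as plain-text files: `genome.fa`, `genome.tsv`
#' (chromosome sizes), BED files for every element set (TFBS hits carry the
#' motif id and ChromHMM/TE files the label in the name field), bedGraph
#' tracks under `tracks/`, `genes.tsv`, `expression.tsv`, `network.tsv`,
#' and ground-truth labels under `truth/`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "tracks"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$sequences, file.path(dir, "genome.fa"))
  readr::write_tsv(
    tibble::tibble(chrom = names(bundle$genome$chrom_sizes),
                   length = unname(bundle$genome$chrom_sizes)),
    file.path(dir, "genome.tsv"), progress = FALSE
  )
  crms <- bundle$crms
  write_bed(crms[, c("chrom", "start", "end", "id")], file.path(dir, "crms.bed"))
  write_bed(crms[crms$state == "active", c("chrom", "start", "end", "id")],
            file.path(dir, "active_crms.bed"))
  write_bed(crms[crms$state == "non-active", c("chrom", "start", "end", "id")],
            file.path(dir, "nonactive_crms.bed"))
  write_bed(bundle$noncrms[, c("chrom", "start", "end", "id")],
            file.path(dir, "noncrms.bed"))
  write_bed(bundle$peaks[, c("chrom", "start", "end", "id")],
            file.path(dir, "peaks.bed"))
  tf <- bundle$tfbs
  tf$id <- tf$motif_id
  write_bed(tf[, c("chrom", "start", "end", "id")], file.path(dir, "tfbs.bed"))
  ch <- bundle$chromhmm
  ch$id <- ch$label
  write_bed(ch[, c("chrom", "start", "end", "id")],
            file.path(dir, "chromhmm.bed"))
  te <- bundle$te
  te$id <- te$label
  write_bed(te[, c("chrom", "start", "end", "id")], file.path(dir, "te.bed"))
  for (tn in names(bundle$tracks)) {
    bg <- rle_to_bedgraph(bundle$tracks[[tn]]$values)
    write_bedgraph(bg, file.path(dir, "tracks", paste0(tn, ".bedGraph")))
  }
  readr::write_tsv(bundle$genes[, c("gene_id", "chrom", "tss", "strand")],
                   file.path(dir, "genes.tsv"), progress = FALSE)
  readr::write_tsv(bundle$expression, file.path(dir, "expression.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$network$edges, file.path(dir, "network.tsv"),
                   col_names = FALSE, progress = FALSE)
  readr::write_tsv(bundle$truth$crm_states, file.path(dir, "truth", "crm_states.tsv"),
                   progress = FALSE)
  readr::write_tsv(bundle$truth$peak_categories,
                   file.path(dir, "truth", "peak_categories.tsv"), progress = FALSE)
  readr::write_tsv(bundle$truth$gene_effects,
                   file.path(dir, "truth", "gene_effects.tsv"), progress = FALSE)
  invisible(dir)
}
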