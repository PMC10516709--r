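#' Genome specification
#'
#' A genome specification names the chromosomes, their lengths, and the
#' regions of the genome that are analyzable, i.e. the portion for which a
#' CRM / non-CRM annotation exists. Everything downstream (partitioning,
#' enrichment sampling, track simulation) is defined relative to this object.
#'
#' @param chrom_sizes Named numeric vector of chromosome lengths in bp.
#' @param analyzable Optional interval tibble (`chrom`, `start`, `end`) of
#'   analyzable regions. Defaults to the whole of every chromosome.
#'
#' @return An object of class `genome_spec`: a list with `chrom_sizes`
#'   (named integer vector) and `analyzable` (sorted, merged interval tibble).
#' @export
#' @examples
#' genome_spec(c(chrI = 10000, chrII = 5000))
genome_spec <- function(chrom_sizes, analyzable = NULL) {
  if (is.null(names(chrom_sizes)) || anyNA(names(chrom_sizes)) ||
      any(names(chrom_sizes) == "")) {
    stop("`chrom_sizes` must be a named vector of chromosome lengths")
  }
  if (any(chrom_sizes <= 0)) stop("chromosome lengths must be positive")
  sizes <- stats::setNames(as.integer(chrom_sizes), names(chrom_sizes))
  if (is.null(analyzable)) {
    # whole chromosomes: already disjoint and sorted, no merge needed
    analyzable <- tibble::new_tibble(
      list(chrom = names(sizes), start = rep(0L, length(sizes)),
           end = unname(sizes)),
      nrow = length(sizes)
    )
  } else {
    analyzable <- validate_intervals(analyzable)
    bad <- !analyzable$chrom %in% names(sizes) |
      analyzable$end > sizes[analyzable$chrom]
    if (any(bad)) {
      stop("analyzable regions outside chromosome bounds: ",
           paste(utils::head(format_intervals(analyzable[bad, ]), 5),
                 collapse = ", "))
    }
    analyzable <- merge_intervals(analyzable)
  }
  structure(
    list(chrom_sizes = sizes, analyzable = analyzable),
    class = "genome_spec"
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat("<genome_spec> ", length(x$chrom_sizes), " chromosome(s), ",
      format(sum(x$chrom_sizes), big.mark = ","), " bp; analyzable ",
      format(total_length(x$analyzable), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

format_intervals <- function(x) {
  sprintf("%s:[%d,%d)", x$chrom, x$start, x$end)
}

#' Validate an interval tibble
#'
#' Intervals use 0-based half-open coordinates (BED convention) throughout.
#'
#' @param x Data frame with at least `chrom`, `start`, `end` columns.
#' @param genome Optional [genome_spec()]; when given, chromosome names and
#'   bounds are checked.
#' @return The input as a tibble with integer coordinates, invisibly checked.
#' @export
validate_intervals <- function(x, genome = NULL) {
  x <- tibble::as_tibble(x)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("missing interval column(s): ", paste(miss, collapse = ", "))
  x$chrom <- as.character(x$chrom)
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  bad <- is.na(x$start) | is.na(x$end) | x$start < 0L | x$start >= x$end
  if (any(bad)) {
    stop("invalid interval(s) (need 0 <= start < end): ",
         paste(utils::head(format_intervals(x[bad, ]), 5), collapse = ", "))
  }
  if (!is.null(genome)) {
    unknown <- setdiff(unique(x$chrom), names(genome$chrom_sizes))
    if (length(unknown)) {
      stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
    }
    oob <- x$end > genome$chrom_sizes[x$chrom]
    if (any(oob)) {
      stop("interval(s) beyond chromosome end: ",
           paste(utils::head(format_intervals(x[oob, ]), 5), collapse = ", "))
    }
  }
  x
}

## internal: tibble <-> GRanges (IRanges is 1-based closed; we store 0-based
## half-open, so start+1 on the way in and start-1 on the way out)
as_gr <- function(x) {
  x <- validate_intervals(x)
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

## harmonize seqlevels so binary GRanges ops never warn about disjoint sets
pair_gr <- function(a, b) {
  ga <- as_gr(a)
  gb <- as_gr(b)
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  list(ga, gb)
}

gr_tbl <- function(gr) {
  tibble::new_tibble(
    list(
      chrom = as.character(S4Vectors::decode(GenomicRanges::seqnames(gr))),
      start = GenomicRanges::start(gr) - 1L,
      end = GenomicRanges::end(gr)
    ),
    nrow = length(gr)
  )
}

#' Sort and merge an interval set
#'
#' Overlapping and book-ended intervals are merged; the result is sorted by
#' (chrom, start, end). Extra columns are dropped (merged intervals have no
#' single identity).
#'
#' @param x Interval tibble.
#' @return Sorted, disjoint interval tibble.
#' @export
#' @examples
#' merge_intervals(tibble::tibble(chrom = "c", start = c(0, 50), end = c(60, 100)))
merge_intervals <- function(x) {
  gr_tbl(GenomicRanges::reduce(as_gr(x)))
}

#' Sort an interval tibble without merging
#'
#' @param x Interval tibble.
#' @return The same rows ordered by (chrom, start, end).
#' @export
sort_intervals <- function(x) {
  x <- validate_intervals(x)
  dplyr::arrange(x, .data$chrom, .data$start, .data$end)
}

#' Total merged length of an interval set
#'
#' @param x Interval tibble.
#' @return Number of distinct bases covered (double).
#' @export
total_length <- function(x) {
  if (nrow(tibble::as_tibble(x)) == 0) return(0)
  sum(as.numeric(GenomicRanges::width(GenomicRanges::reduce(as_gr(x)))))
}

#' Base-level intersection of two interval sets
#'
#' @param a,b Interval tibbles.
#' @return Interval tibble covering the bases present in both sets.
#' @export
interval_intersect <- function(a, b) {
  if (nrow(tibble::as_tibble(a)) == 0 || nrow(tibble::as_tibble(b)) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  gr <- pair_gr(a, b)
  gr_tbl(GenomicRanges::intersect(gr[[1]], gr[[2]]))
}

#' Base-level set difference of two interval sets
#'
#' @param a,b Interval tibbles.
#' @return Interval tibble covering the bases of `a` not in `b`.
#' @export
interval_setdiff <- function(a, b) {
  if (nrow(tibble::as_tibble(a)) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  if (nrow(tibble::as_tibble(b)) == 0) return(merge_intervals(a))
  gr <- pair_gr(a, b)
  gr_tbl(GenomicRanges::setdiff(gr[[1]], gr[[2]]))
}

#' Number of bases shared by two interval sets
#'
#' @param a,b Interval tibbles.
#' @return Base count (double); commutative.
#' @export
#' @examples
#' intersect_length(
#'   tibble::tibble(chrom = "c", start = 0, end = 100),
#'   tibble::tibble(chrom = "c", start = 50, end = 150)
#' )
intersect_length <- function(a, b) {
  total_length(interval_intersect(a, b))
}

#' Reciprocal overlap predicate
#'
#' Two intervals overlap reciprocally at a threshold when their intersection
#' covers at least that fraction of each interval's length. This is the rule
#' used to decide whether a STARR peak and a CRM are the "same" element
#' (default threshold 0.5, i.e. at least 50% of both lengths). The predicate
#' is symmetric and inclusive at the boundary.
#'
#' @param a,b Interval tibbles with the same number of rows; compared pairwise.
#' @param threshold Fraction in (0, 1].
#' @return Logical vector, one per pair. Pairs on different chromosomes are
#'   `FALSE`.
#' @export
#' @examples
#' reciprocal_overlap(
#'   tibble::tibble(chrom = "c", start = 100, end = 200),
#'   tibble::tibble(chrom = "c", start = 150, end = 250)
#' )
reciprocal_overlap <- function(a, b, threshold = 0.5) {
  a <- validate_intervals(a)
  b <- validate_intervals(b)
  if (nrow(a) != nrow(b)) stop("`a` and `b` must have the same number of rows")
  stopifnot(threshold > 0, threshold <= 1)
  ov <- pmax(0L, pmin(a$end, b$end) - pmax(a$start, b$start))
  ov[a$chrom != b$chrom] <- 0L
  ov >= threshold * (a$end - a$start) & ov >= threshold * (b$end - b$start)
}

#' All pairs of reciprocally overlapping intervals between two sets
#'
#' @param a,b Interval tibbles; rows are identified by an `id` column when
#'   present, otherwise by row number.
#' @param threshold Reciprocal-overlap fraction (default 0.5).
#' @return Tibble with `a_id`, `b_id`, `overlap_bp`, `frac_a`, `frac_b`, one
#'   row per passing pair.
#' @export
reciprocal_pairs <- function(a, b, threshold = 0.5) {
  a <- validate_intervals(a)
  b <- validate_intervals(b)
  a_id <- if ("id" %in% names(a)) as.character(a$id) else as.character(seq_len(nrow(a)))
  b_id <- if ("id" %in% names(b)) as.character(b$id) else as.character(seq_len(nrow(b)))
  empty <- tibble::tibble(
    a_id = character(), b_id = character(),
    overlap_bp = integer(), frac_a = double(), frac_b = double()
  )
  if (nrow(a) == 0 || nrow(b) == 0) return(empty)
  hits <- GenomicRanges::findOverlaps(as_gr(a), as_gr(b))
  if (length(hits) == 0) return(empty)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  ov <- pmin(a$end[qi], b$end[si]) - pmax(a$start[qi], b$start[si])
  fa <- ov / (a$end[qi] - a$start[qi])
  fb <- ov / (b$end[si] - b$start[si])
  keep <- fa >= threshold & fb >= threshold
  tibble::tibble(
    a_id = a_id[qi][keep], b_id = b_id[si][keep],
    overlap_bp = as.integer(ov[keep]), frac_a = fa[keep], frac_b = fb[keep]
  )
}

#' GC content of DNA sequences
#'
#' @param seq Character vector of DNA sequences over \{A, C, G, T, N\},
#'   case-insensitive. `N` bases are excluded from the denominator.
#' @return Numeric vector of fractions; `NA` (with a warning) for sequences
#'   with no informative bases.
#' @export
#' @examples
#' gc_content(c("GGCC", "ACGT", "ANGT"))
gc_content <- function(seq) {
  if (length(seq) == 0) return(numeric())
  ss <- Biostrings::DNAStringSet(toupper(seq))
  counts <- Biostrings::letterFrequency(ss, letters = c("A", "C", "G", "T"))
  denom <- rowSums(counts)
  gc <- (counts[, "G"] + counts[, "C"]) / denom
  if (any(denom == 0)) {
    warning("sequence(s) with no informative (non-N) bases: GC is NA")
    gc[denom == 0] <- NA_real_
  }
  unname(gc)
}
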