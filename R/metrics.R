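#' Motif interaction network
#'
#' A light wrapper around an undirected motif-motif edge list; node degree
#' (number of incident edges) feeds the complexity score.
#'
#' @param edges Tibble/data frame with columns `from`, `to` (motif ids).
#' @return Object of class `motif_network` with `edges` and a named `degree`
#'   vector.
#' @export
motif_network <- function(edges) {
  edges <- tibble::as_tibble(edges)
  stopifnot(all(c("from", "to") %in% names(edges)))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  deg <- table(c(edges$from, edges$to))
  structure(
    list(edges = edges,
         degree = stats::setNames(as.numeric(deg), names(deg))),
    class = "motif_network"
  )
}

#' @export
print.motif_network <- function(x, ...) {
  cat("<motif_network>", length(x$degree), "motifs,", nrow(x$edges),
      "edges\n")
  invisible(x)
}

#' Degree of motifs in a network
#'
#' @param network A `motif_network`.
#' @param motif_id Character vector of motif ids; ids absent from the
#'   network get degree 0 (flagged with a warning).
#' @return Numeric vector of degrees.
#' @export
motif_degree <- function(network, motif_id) {
  stopifnot(inherits(network, "motif_network"))
  d <- network$degree[motif_id]
  if (anyNA(d)) {
    warning(sum(is.na(d)), " motif id(s) absent from network; degree 0 used")
    d[is.na(d)] <- 0
  }
  unname(d)
}

#' Structural complexity of CRMs / STARR peaks
#'
#' The complexity of an element is `log(N_TFBS x D + 1)` where `N_TFBS` is
#' the number of TFBS hits mapped into the element per 100 bp and `D` is the
#' average degree, in the motif interaction network, of the unique motifs
#' among those hits (a motif with several hits in one element contributes its
#' degree once). A hit maps into an element when it overlaps by at least
#' 1 bp. Elements with no hits score 0.
#'
#' @param elements Interval tibble.
#' @param hits Interval tibble of TFBS hits with a `motif_id` column (BED6
#'   name field when read from disk).
#' @param network A `motif_network`.
#' @param base Logarithm base (default natural log).
#' @return Tibble with `element_id`, `n_hits`, `hits_per_100bp`,
#'   `mean_degree`, `complexity`.
#' @export
complexity_score <- function(elements, hits, network, base = exp(1)) {
  elements <- validate_intervals(elements)
  hits <- validate_intervals(hits)
  if (!"motif_id" %in% names(hits)) {
    if ("id" %in% names(hits)) hits$motif_id <- hits$id
    else stop("`hits` needs a `motif_id` (or `id`) column")
  }
  eid <- element_ids(elements, "elem")
  n <- integer(nrow(elements))
  mdeg <- numeric(nrow(elements))
  if (nrow(hits) > 0 && nrow(elements) > 0) {
    ov <- GenomicRanges::findOverlaps(as_gr(elements), as_gr(hits))
    qi <- S4Vectors::queryHits(ov)
    si <- S4Vectors::subjectHits(ov)
    if (length(qi)) {
      cnt <- table(qi)
      n[as.integer(names(cnt))] <- as.integer(cnt)
      degs <- motif_degree(network, hits$motif_id[si])
      by_elem <- split(data.frame(motif = hits$motif_id[si], deg = degs), qi)
      md <- vapply(by_elem, function(df) {
        mean(df$deg[!duplicated(df$motif)])
      }, 0)
      mdeg[as.integer(names(by_elem))] <- md
    }
  }
  len <- elements$end - elements$start
  n_per_100 <- n / (len / 100)
  tibble::tibble(
    element_id = eid,
    n_hits = n,
    hits_per_100bp = n_per_100,
    mean_degree = mdeg,
    complexity = log(n_per_100 * mdeg + 1, base = base)
  )
}

#' TFBS density over an interval set
#'
#' @param intervals Interval tibble (merged before counting bases).
#' @param hits Interval tibble of TFBS hits.
#' @return Hits overlapping the set (each hit counted once) per 100 bp.
#' @export
tfbs_density <- function(intervals, hits) {
  bases <- total_length(intervals)
  if (bases == 0) stop("interval set has zero total length")
  hits <- validate_intervals(hits)
  if (nrow(hits) == 0) return(0)
  merged <- merge_intervals(intervals)
  n <- sum(IRanges::overlapsAny(as_gr(hits), as_gr(merged)))
  n / (bases / 100)
}

#' Length summaries of an element set
#'
#' Elements keep their identity (no merging); the median of an even count
#' is the midpoint of the two central values.
#'
#' @param elements Interval tibble.
#' @return One-row tibble with `n`, `mean`, `median`.
#' @export
length_summary <- function(elements) {
  elements <- validate_intervals(elements)
  if (nrow(elements) == 0) stop("element set is empty")
  len <- elements$end - elements$start
  tibble::tibble(n = length(len), mean = mean(len),
                 median = stats::median(len))
}

#' Per-base conservation scores over elements
#'
#' Collects the multiset of per-base conservation (e.g. phyloP-like) scores
#' across all element bases; bases not covered by the track are skipped and
#' counted in the `n_uncovered` attribute.
#'
#' @param elements Interval tibble.
#' @param cons_track A `signal_track` of conservation scores.
#' @return Numeric vector of per-base scores (attribute `n_uncovered`).
#' @export
conservation_distribution <- function(elements, cons_track) {
  track_base_values(cons_track, elements)
}

#' STARR signal strength of peaks
#'
#' Per-bp mean of library-size-normalized fold enrichment of the STARR
#' signal over the input across each peak - the same fold-enrichment
#' definition as the functional-state features and the profile matrices.
#'
#' @param peaks Interval tibble.
#' @param starr_signal,input_track `signal_track` objects.
#' @return Tibble with `peak_id` and `strength`.
#' @export
peak_signal_strength <- function(peaks, starr_signal, input_track) {
  peaks <- validate_intervals(peaks)
  fe <- fold_enrichment(starr_signal, input_track)
  tibble::tibble(
    peak_id = element_ids(peaks, "peak"),
    strength = track_mean(fe, peaks)
  )
}

#' GC content of elements from a genome sequence
#'
#' @param elements Interval tibble.
#' @param sequences Named `DNAStringSet` (names = chromosomes).
#' @return Numeric vector of per-element GC fractions.
#' @export
element_gc <- function(elements, sequences) {
  elements <- validate_intervals(elements)
  miss <- setdiff(unique(elements$chrom), names(sequences))
  if (length(miss)) stop("chromosome(s) missing from sequences: ",
                         paste(miss, collapse = ", "))
  seqs <- as.character(Biostrings::subseq(
    sequences[elements$chrom], start = elements$start + 1L, end = elements$end
  ))
  gc_content(seqs)
}
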