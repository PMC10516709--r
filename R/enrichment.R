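#' Sample random genomic intervals matched to a template set
#'
#' Draws random interval sets reproducing the template's number of elements
#' and exact multiset of lengths, optionally also matching each template's
#' GC content by rejection sampling. Placement is uniform over chromosomes
#' proportional to length; draws crossing chromosome ends or an exclusion
#' set are rejected. Deterministic given `seed`.
#'
#' @param genome A [genome_spec()].
#' @param templates Interval tibble whose lengths (and GC, if matching) are
#'   reproduced.
#' @param n_draws Number of independent background draws (default 10).
#' @param seed RNG seed.
#' @param gc_match Match GC content per template (default FALSE).
#' @param gc_tolerance Absolute GC tolerance (default 0.02).
#' @param sequences Named `DNAStringSet`; required when `gc_match`.
#' @param exclusion Optional interval tibble barred from sampling.
#' @param max_attempts Rejection-sampling cap per template (default 10000).
#' @return List of `n_draws` interval tibbles.
#' @export
sample_matched <- function(genome, templates, n_draws = 10, seed = 1,
                           gc_match = FALSE, gc_tolerance = 0.02,
                           sequences = NULL, exclusion = NULL,
                           max_attempts = 10000) {
  templates <- validate_intervals(templates)
  if (nrow(templates) == 0) stop("template set is empty")
  if (gc_match && is.null(sequences)) {
    stop("`sequences` required when gc_match = TRUE")
  }
  lens <- templates$end - templates$start
  sizes <- genome$chrom_sizes
  if (max(lens) > max(sizes)) {
    stop("template length ", max(lens), " exceeds the longest chromosome")
  }
  target_gc <- if (gc_match) element_gc(templates, sequences) else NULL
  excl_gr <- if (!is.null(exclusion) && nrow(tibble::as_tibble(exclusion)) > 0) {
    as_gr(exclusion)
  } else NULL
  withr::with_seed(seed, {
    lapply(seq_len(n_draws), function(d) {
      chrom <- character(length(lens))
      start <- integer(length(lens))
      for (i in seq_along(lens)) {
        ok_chroms <- names(sizes)[sizes >= lens[i]]
        w <- sizes[ok_chroms] - lens[i] + 1
        placed <- FALSE
        for (att in seq_len(max_attempts)) {
          chr <- sample(ok_chroms, 1, prob = w)
          s <- sample.int(sizes[[chr]] - lens[i] + 1L, 1L) - 1L
          if (!is.null(excl_gr)) {
            cand <- GenomicRanges::GRanges(chr, IRanges::IRanges(s + 1L, s + lens[i]))
            if (length(GenomicRanges::findOverlaps(cand, excl_gr)) > 0) next
          }
          if (gc_match) {
            g <- gc_content(as.character(Biostrings::subseq(
              sequences[[chr]], start = s + 1L, end = s + lens[i]
            )))
            if (is.na(g) || abs(g - target_gc[i]) > gc_tolerance) next
          }
          chrom[i] <- chr
          start[i] <- s
          placed <- TRUE
          break
        }
        if (!placed) {
          stop(sprintf(
            "could not place template %d (length %d%s) within %d attempts",
            i, lens[i],
            if (gc_match) sprintf(", GC %.3f", target_gc[i]) else "",
            max_attempts
          ))
        }
      }
      tibble::tibble(chrom = chrom, start = start, end = start + lens)
    })
  })
}

#' Fold-change enrichment
#'
#' `(N - M) / M`: the excess of the foreground quantity `N` over the matched
#' random background quantity `M`, relative to the background.
#'
#' @param N Foreground quantity (bp covered, or element count).
#' @param M Background quantity.
#' @return `(N - M) / M`; `NA` with a warning when `M == 0`.
#' @export
#' @examples
#' fold_change(150, 100)
fold_change <- function(N, M) {
  out <- ifelse(M > 0, (N - M) / M, NA_real_)
  if (any(M == 0)) warning("fold change undefined where background M == 0")
  out
}

#' Enrichment of annotation labels in a foreground set
#'
#' For every label of an annotation (ChromHMM-like states or TE classes),
#' computes the foreground quantity `N` and the mean background quantity `M`
#' over the supplied draws, and their fold change `(N - M) / M`. In
#' `"length"` mode the quantity is the number of foreground bases covered by
#' the label; in `"count"` mode it is the number of annotation elements
#' overlapping the foreground by at least 1 bp.
#'
#' @param foreground Interval tibble.
#' @param annotation Interval tibble with a `label` column (BED name field).
#' @param background_draws List of interval tibbles (from
#'   [sample_matched()]).
#' @param mode `"length"` or `"count"`.
#' @return Tibble with `label`, `N`, `M`, `fold_change`, `mode`, `n_draws`.
#' @export
state_enrichment <- function(foreground, annotation, background_draws,
                             mode = c("length", "count")) {
  mode <- match.arg(mode)
  foreground <- validate_intervals(foreground)
  annotation <- validate_intervals(annotation)
  if (!"label" %in% names(annotation)) {
    if ("id" %in% names(annotation)) annotation$label <- annotation$id
    else stop("`annotation` needs a `label` (or `id`) column")
  }
  labels <- sort(unique(annotation$label))
  quantify <- function(set) {
    vapply(labels, function(lb) {
      ann <- annotation[annotation$label == lb, , drop = FALSE]
      if (mode == "length") {
        intersect_length(set, ann)
      } else {
        sum(IRanges::overlapsAny(as_gr(ann), as_gr(merge_intervals(set))))
      }
    }, 0)
  }
  N <- quantify(foreground)
  Ms <- vapply(background_draws, quantify, numeric(length(labels)))
  M <- if (length(labels) == 1) mean(Ms) else rowMeans(matrix(Ms, nrow = length(labels)))
  fc <- suppressWarnings(fold_change(N, M))
  if (any(M == 0)) {
    warning("label(s) with zero background quantity: ",
            paste(labels[M == 0], collapse = ", "))
  }
  tibble::tibble(
    label = labels, N = unname(N), M = unname(M),
    fold_change = unname(fc), mode = mode,
    n_draws = length(background_draws)
  )
}
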