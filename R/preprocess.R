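#' Filter CRMs overlapping silencers or CTCF insulator peaks
#'
#' A CRM is removed when it reciprocally overlaps (at least `threshold` of
#' both lengths) at least one silencer or one CTCF peak, since such elements
#' may act as silencers or insulators rather than enhancers.
#'
#' @param crms Interval tibble of CRMs (an `id` column is preserved).
#' @param silencers,ctcf_peaks Interval tibbles.
#' @param threshold Reciprocal-overlap fraction (default 0.5).
#' @return List with `retained` (interval tibble) and `report` (a
#'   `filter_report` tibble; removals counted under the first matching
#'   filter, silencer before CTCF).
#' @export
filter_silencer_insulator <- function(crms, silencers, ctcf_peaks,
                                      threshold = 0.5) {
  crms <- validate_intervals(crms)
  crms$.row <- seq_len(nrow(crms))
  crm_key <- tibble::tibble(chrom = crms$chrom, start = crms$start,
                            end = crms$end, id = as.character(crms$.row))
  hit_rows <- function(others) {
    if (nrow(tibble::as_tibble(others)) == 0) return(integer())
    as.integer(unique(reciprocal_pairs(crm_key, others, threshold)$a_id))
  }
  sil_hit <- hit_rows(silencers)
  ctcf_hit <- setdiff(hit_rows(ctcf_peaks), sil_hit)
  removed <- union(sil_hit, ctcf_hit)
  retained <- crms[!crms$.row %in% removed, setdiff(names(crms), ".row"),
                   drop = FALSE]
  report <- tibble::tibble(
    n_input = nrow(crms),
    n_removed_silencer = length(sil_hit),
    n_removed_ctcf = length(ctcf_hit),
    n_removed_promoter = 0L,
    n_retained = nrow(retained)
  )
  class(report) <- c("filter_report", class(report))
  list(retained = retained, report = report)
}

#' Filter promoter-proximal CRMs
#'
#' Removes CRMs whose nearest transcription start site lies within
#' `max_dist` bp of the CRM edge (distance 0 for a TSS inside the CRM;
#' boundary inclusive), excluding likely promoters from the enhancer audit.
#'
#' @param crms Interval tibble of CRMs.
#' @param tss Integer vector of TSS positions, or a gene tibble with `chrom`
#'   and `tss` columns. A bare vector is interpreted on the single chromosome
#'   present in `crms`.
#' @param max_dist Maximum edge distance in bp (default 1000).
#' @return List with `retained` and `report` as in
#'   [filter_silencer_insulator()].
#' @export
filter_promoter_proximal <- function(crms, tss, max_dist = 1000) {
  crms <- validate_intervals(crms)
  if (!is.data.frame(tss)) {
    chroms <- unique(crms$chrom)
    if (length(chroms) > 1) {
      stop("bare TSS vector is ambiguous with multi-chromosome CRMs; ",
           "pass a tibble with `chrom` and `tss`")
    }
    tss <- tibble::tibble(chrom = if (length(chroms)) chroms else character(),
                          tss = as.integer(tss))
  }
  if (nrow(tss) == 0) stop("TSS set is empty")
  d <- element_tss_distance(crms, tss)
  removed <- !is.na(d) & d <= max_dist
  retained <- crms[!removed, , drop = FALSE]
  report <- tibble::tibble(
    n_input = nrow(crms),
    n_removed_silencer = 0L,
    n_removed_ctcf = 0L,
    n_removed_promoter = sum(removed),
    n_retained = nrow(retained)
  )
  class(report) <- c("filter_report", class(report))
  list(retained = retained, report = report)
}

## internal: min edge distance from each element to any TSS on its chromosome
## (0 when the TSS falls inside the element; NA when the chromosome has none)
element_tss_distance <- function(elements, tss) {
  out <- rep(NA_real_, nrow(elements))
  for (chr in unique(elements$chrom)) {
    pos <- sort(tss$tss[tss$chrom == chr])
    if (length(pos) == 0) next
    idx <- which(elements$chrom == chr)
    s <- elements$start[idx]
    e <- elements$end[idx]
    # nearest TSS at or left of start, and nearest at or right of end
    left <- findInterval(e, pos)          # pos[left] <= e (rightmost)
    cand_left <- ifelse(left >= 1, pos[pmax(left, 1)], NA_real_)
    right <- findInterval(s, pos) + 1     # pos[right] >= s (leftmost > start-)
    cand_right <- ifelse(right <= length(pos), pos[pmin(right, length(pos))],
                         NA_real_)
    d_left <- ifelse(is.na(cand_left), Inf, pmax(0, s - cand_left))
    d_right <- ifelse(is.na(cand_right), Inf, pmax(0, cand_right - e))
    inside <- !is.na(cand_left) & cand_left >= s   # a TSS in [s, e)
    d <- pmin(d_left, d_right)
    d[inside] <- 0
    out[idx] <- d
  }
  out
}

#' Consensus STARR peaks across two replicates
#'
#' For each replicate-1 peak overlapping at least one replicate-2 peak by at
#' least 1 bp, returns the base-level intersection of that peak with the
#' union of its replicate-2 partners. Every consensus base is therefore
#' supported by both replicates.
#'
#' @param rep1,rep2 Interval tibbles of replicate peak calls.
#' @return Sorted, merged interval tibble of consensus peaks.
#' @export
consensus_replicate_peaks <- function(rep1, rep2) {
  rep1 <- validate_intervals(rep1)
  rep2 <- validate_intervals(rep2)
  if (nrow(rep1) == 0 || nrow(rep2) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  interval_intersect(rep1, rep2)
}

#' Fold more than two replicates by sequential consensus
#'
#' @param reps List of interval tibbles (length >= 1).
#' @return Consensus interval tibble.
#' @export
consensus_peaks <- function(reps) {
  stopifnot(is.list(reps), length(reps) >= 1)
  Reduce(consensus_replicate_peaks, reps)
}
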