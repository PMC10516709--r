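category_levels <- c("A", "B", "C", "D", "E", "F")

#' Partition the analyzable genome into categories A-F
#'
#' Every analyzable base is assigned exactly one label by crossing its CRM
#' annotation with STARR-peak overlap:
#' \describe{
#'   \item{A}{non-active CRM, no peak}
#'   \item{B}{active CRM, no peak}
#'   \item{C}{active CRM, peak}
#'   \item{D}{non-active CRM, peak}
#'   \item{E}{non-CRM, peak}
#'   \item{F}{non-CRM, no peak}
#' }
#' Base labels use direct base intersection; the 50% reciprocal-overlap rule
#' governs only element-level pairing (see [match_peaks_to_crms()]). Peak
#' bases outside the analyzable regions are counted separately as
#' "unassessed" and excluded from the label track, mirroring the exclusion
#' of peak positions falling where no CRM/non-CRM annotation exists.
#'
#' @param genome A [genome_spec()].
#' @param active_crms,nonactive_crms,noncrms Interval tibbles that must be
#'   mutually disjoint and jointly cover the analyzable regions exactly.
#' @param peaks Interval tibble of STARR peaks.
#' @param sample_id Optional sample label carried into the result.
#' @return An object of class `starr_partition` with `base_counts` (named
#'   vector A-F), `labels` (sorted interval tibble with a `category` column),
#'   `peak_assignments` and `crm_assignments` (per-element base splits),
#'   `unassessed_peak_bases`, and `analyzable_bases`.
#' @export
partition_genome <- function(genome, active_crms, nonactive_crms, noncrms,
                             peaks, sample_id = "sample") {
  active_crms <- validate_intervals(active_crms, genome)
  nonactive_crms <- validate_intervals(nonactive_crms, genome)
  noncrms <- validate_intervals(noncrms, genome)
  peaks <- validate_intervals(peaks, genome)

  ana <- genome$analyzable
  chroms <- names(genome$chrom_sizes)
  ir_active <- ir_by_chrom(active_crms, chroms)
  ir_non <- ir_by_chrom(nonactive_crms, chroms)
  ir_nc <- ir_by_chrom(noncrms, chroms)
  ir_pk <- ir_by_chrom(peaks, chroms)
  ir_ana <- ir_by_chrom(ana, chroms)

  ana_bp <- ir_bp(ir_ana)
  parts <- list(active = active_crms, nonactive = nonactive_crms,
                noncrm = noncrms)
  tot <- ir_bp(lapply(ir_active, IRanges::reduce)) +
    ir_bp(lapply(ir_non, IRanges::reduce)) +
    ir_bp(lapply(ir_nc, IRanges::reduce))
  ir_all <- ir_map2(ir_map2(ir_active, ir_non, IRanges::union),
                    ir_nc, IRanges::union)
  cover <- ir_bp(ir_all)
  if (tot != cover) {
    ov <- purrr::imap(utils::combn(names(parts), 2, simplify = FALSE),
                      function(pr, i) {
      both <- interval_intersect(parts[[pr[1]]], parts[[pr[2]]])
      if (nrow(both)) sprintf("%s/%s: %s", pr[1], pr[2],
                              paste(utils::head(format_intervals(both), 3),
                                    collapse = ", "))
    })
    stop("CRM / non-CRM sets overlap; ",
         paste(unlist(ov), collapse = "; "))
  }
  if (cover != ana_bp ||
      ir_bp(ir_map2(ir_all, ir_ana, IRanges::union)) != ana_bp) {
    gaps <- ir_tbl(ir_map2(ir_ana, ir_all, IRanges::setdiff))
    extra <- ir_tbl(ir_map2(ir_all, ir_ana, IRanges::setdiff))
    stop("CRM / non-CRM sets do not exactly cover the analyzable regions; ",
         if (nrow(gaps)) paste("uncovered:",
           paste(utils::head(format_intervals(gaps), 3), collapse = ", ")),
         if (nrow(extra)) paste(" outside-analyzable:",
           paste(utils::head(format_intervals(extra), 3), collapse = ", ")))
  }

  ir_pk_in <- ir_map2(lapply(ir_pk, IRanges::reduce), ir_ana,
                      IRanges::intersect)
  unassessed <- ir_bp(lapply(ir_pk, IRanges::reduce)) - ir_bp(ir_pk_in)

  cat_ir <- list(
    A = ir_map2(ir_non, ir_pk_in, IRanges::setdiff),
    B = ir_map2(ir_active, ir_pk_in, IRanges::setdiff),
    C = ir_map2(ir_active, ir_pk_in, IRanges::intersect),
    D = ir_map2(ir_non, ir_pk_in, IRanges::intersect),
    E = ir_map2(ir_nc, ir_pk_in, IRanges::intersect),
    F = ir_map2(ir_nc, ir_pk_in, IRanges::setdiff)
  )
  base_counts <- vapply(cat_ir, ir_bp, 0)
  cat_tracks <- lapply(cat_ir, ir_tbl)
  lab_chrom <- unlist(lapply(cat_tracks, `[[`, "chrom"), use.names = FALSE)
  lab_start <- unlist(lapply(cat_tracks, `[[`, "start"), use.names = FALSE)
  lab_end <- unlist(lapply(cat_tracks, `[[`, "end"), use.names = FALSE)
  lab_cat <- rep(names(cat_tracks),
                 vapply(cat_tracks, nrow, 0L))
  ord <- order(lab_chrom, lab_start, lab_end)
  labels <- tibble::new_tibble(
    list(chrom = lab_chrom[ord], start = lab_start[ord], end = lab_end[ord],
         category = lab_cat[ord]),
    nrow = length(ord)
  )

  peak_id <- element_ids(peaks, "peak")
  a_cols <- active_crms[, intersect(names(active_crms),
                                    c("chrom", "start", "end", "id")),
                        drop = FALSE]
  n_cols <- nonactive_crms[, intersect(names(nonactive_crms),
                                       c("chrom", "start", "end", "id")),
                           drop = FALSE]
  a_cols$.state <- rep("active", nrow(a_cols))
  n_cols$.state <- rep("non-active", nrow(n_cols))
  crms <- dplyr::bind_rows(a_cols, n_cols)
  crm_id <- element_ids(crms, "crm")

  peak_assignments <- tibble::new_tibble(list(
    peak_id = peak_id,
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    C = split_bases_ir(peaks, cat_ir$C, chroms),
    D = split_bases_ir(peaks, cat_ir$D, chroms),
    E = split_bases_ir(peaks, cat_ir$E, chroms),
    unassessed = (peaks$end - peaks$start) -
      split_bases_ir(peaks, ir_pk_in, chroms)
  ), nrow = nrow(peaks))
  crm_assignments <- tibble::new_tibble(list(
    crm_id = crm_id,
    chrom = crms$chrom, start = crms$start, end = crms$end,
    state = crms$.state,
    A = split_bases_ir(crms, cat_ir$A, chroms),
    B = split_bases_ir(crms, cat_ir$B, chroms),
    C = split_bases_ir(crms, cat_ir$C, chroms),
    D = split_bases_ir(crms, cat_ir$D, chroms)
  ), nrow = nrow(crms))

  structure(
    list(
      sample_id = sample_id,
      base_counts = base_counts,
      labels = labels,
      peak_assignments = peak_assignments,
      crm_assignments = crm_assignments,
      unassessed_peak_bases = unassessed,
      analyzable_bases = ana_bp
    ),
    class = "starr_partition"
  )
}

## internal: stable element ids (use `id` column when present)
element_ids <- function(x, prefix) {
  if ("id" %in% names(x) && !anyNA(x$id)) return(as.character(x$id))
  sprintf("%s_%05d", prefix, seq_len(nrow(x)))
}

## internal: per-chromosome IRanges views of an interval tibble (1-based
## closed, matching IRanges conventions; the tibble stays 0-based half-open)
ir_by_chrom <- function(x, chroms) {
  out <- stats::setNames(vector("list", length(chroms)), chroms)
  idx <- split(seq_len(nrow(x)), factor(x$chrom, levels = chroms))
  for (chr in chroms) {
    i <- idx[[chr]]
    out[[chr]] <- IRanges::IRanges(start = x$start[i] + 1L, end = x$end[i])
  }
  out
}

ir_bp <- function(irl) {
  sum(vapply(irl, function(ir) sum(as.numeric(IRanges::width(ir))), 0))
}

ir_map2 <- function(a, b, f) {
  out <- a
  for (chr in names(a)) out[[chr]] <- f(a[[chr]], b[[chr]])
  out
}

ir_tbl <- function(irl) {
  dplyr::bind_rows(purrr::imap(irl, function(ir, chr) {
    tibble::new_tibble(
      list(chrom = rep(chr, length(ir)),
           start = IRanges::start(ir) - 1L,
           end = IRanges::end(ir)),
      nrow = length(ir)
    )
  }))
}

## internal: per-element base overlap with a disjoint track, elements as a
## tibble and the track as a per-chromosome IRanges list
split_bases_ir <- function(elements, track_ir, chroms) {
  out <- numeric(nrow(elements))
  fac <- factor(elements$chrom, levels = chroms)
  idx <- split(seq_len(nrow(elements)), fac)
  for (chr in chroms) {
    i <- idx[[chr]]
    if (length(i) == 0 || length(track_ir[[chr]]) == 0) next
    eir <- IRanges::IRanges(elements$start[i] + 1L, elements$end[i])
    hits <- IRanges::findOverlaps(eir, track_ir[[chr]])
    if (length(hits) == 0) next
    qi <- S4Vectors::queryHits(hits)
    w <- IRanges::width(IRanges::pintersect(
      eir[qi], track_ir[[chr]][S4Vectors::subjectHits(hits)]
    ))
    agg <- tapply(w, qi, sum)
    out[i[as.integer(names(agg))]] <- out[i[as.integer(names(agg))]] +
      as.numeric(agg)
  }
  out
}

## tibble-in tibble-out wrapper used outside partition_genome
split_bases <- function(elements, track) {
  elements <- validate_intervals(elements)
  track <- tibble::as_tibble(track)
  if (nrow(track) == 0 || nrow(elements) == 0) {
    return(numeric(nrow(elements)))
  }
  chroms <- union(unique(elements$chrom), unique(track$chrom))
  split_bases_ir(elements, ir_by_chrom(track, chroms), chroms)
}

#' @export
print.starr_partition <- function(x, ...) {
  cat("<starr_partition> sample", x$sample_id, "-",
      format(x$analyzable_bases, big.mark = ","), "analyzable bases\n")
  print(round(x$base_counts))
  if (x$unassessed_peak_bases > 0) {
    cat("unassessed peak bases (outside analyzable):",
        round(x$unassessed_peak_bases), "\n")
  }
  invisible(x)
}

#' Derived category ratios of a partition
#'
#' The headline quantities of the audit, all on the percent scale:
#' `c_share`, `d_share`, `e_share` are C, D, E as shares of all in-region
#' STARR-peak bases; `c_of_active` and `b_of_active` split active-CRM bases
#' by peak overlap (the STARR-seq sensitivity and miss rate for active
#' CRMs); `nonactive_of_crm` is the non-active share of CRM bases;
#' `d_of_nonactive` is the peak-overlapped share of non-active CRM bases;
#' `unassessed_share` is the share of all peak bases outside the analyzable
#' regions.
#'
#' @param x A `starr_partition`.
#' @return One-row tibble of percentages.
#' @export
partition_ratios <- function(x) {
  stopifnot(inherits(x, "starr_partition"))
  k <- as.list(x$base_counts)
  pk <- k$C + k$D + k$E
  pct <- function(num, den) if (den > 0) 100 * num / den else NA_real_
  tibble::tibble(
    sample_id = x$sample_id,
    c_share = pct(k$C, pk),
    d_share = pct(k$D, pk),
    e_share = pct(k$E, pk),
    c_of_active = pct(k$C, k$B + k$C),
    b_of_active = pct(k$B, k$B + k$C),
    nonactive_of_crm = pct(k$A + k$D, k$A + k$B + k$C + k$D),
    d_of_nonactive = pct(k$D, k$A + k$D),
    unassessed_share = pct(x$unassessed_peak_bases,
                           pk + x$unassessed_peak_bases)
  )
}

#' Match STARR peaks to CRMs by reciprocal overlap
#'
#' Element-level pairing: a peak and a CRM are matched when they overlap at
#' least `threshold` of both their lengths. Used for the element-level
#' statistics (containment, peaks-per-CRM), not for base labels.
#'
#' @param peaks,crms Interval tibbles (`id` columns used when present).
#' @param threshold Reciprocal-overlap fraction (default 0.5).
#' @return Tibble with `peak_id`, `crm_id`, `overlap_bp`, and `containment`
#'   (`"full"` when the CRM lies entirely within the peak, else
#'   `"partial"`).
#' @export
match_peaks_to_crms <- function(peaks, crms, threshold = 0.5) {
  peaks <- validate_intervals(peaks)
  crms <- validate_intervals(crms)
  pid <- element_ids(peaks, "peak")
  cid <- element_ids(crms, "crm")
  p_key <- tibble::tibble(chrom = peaks$chrom, start = peaks$start,
                          end = peaks$end, id = as.character(seq_len(nrow(peaks))))
  c_key <- tibble::tibble(chrom = crms$chrom, start = crms$start,
                          end = crms$end, id = as.character(seq_len(nrow(crms))))
  pairs <- reciprocal_pairs(p_key, c_key, threshold)
  pi <- as.integer(pairs$a_id)
  ci <- as.integer(pairs$b_id)
  tibble::tibble(
    peak_id = pid[pi],
    crm_id = cid[ci],
    overlap_bp = pairs$overlap_bp,
    containment = ifelse(
      crms$start[ci] >= peaks$start[pi] & crms$end[ci] <= peaks$end[pi],
      "full", "partial"
    )
  )
}

#' Containment class of a matched peak/CRM pair
#'
#' @param peak,crm Single-row interval tibbles.
#' @return `"full"` when the CRM lies entirely within the peak, else
#'   `"partial"`.
#' @export
containment_class <- function(peak, crm) {
  peak <- validate_intervals(peak)
  crm <- validate_intervals(crm)
  stopifnot(nrow(peak) == 1, nrow(crm) == 1)
  if (crm$chrom == peak$chrom && crm$start >= peak$start &&
      crm$end <= peak$end) "full" else "partial"
}

#' Number of matched peaks per CRM
#'
#' @param crms Interval tibble of CRMs (ids as in [match_peaks_to_crms()]).
#' @param matched_pairs Output of [match_peaks_to_crms()].
#' @return Tibble with `crm_id` and `n_peaks` (0 for unmatched CRMs).
#' @export
peaks_per_crm <- function(crms, matched_pairs) {
  crms <- validate_intervals(crms)
  cid <- element_ids(crms, "crm")
  counts <- table(matched_pairs$crm_id[!duplicated(
    paste(matched_pairs$crm_id, matched_pairs$peak_id)
  )])
  tibble::tibble(
    crm_id = cid,
    n_peaks = as.integer(ifelse(cid %in% names(counts), counts[cid], 0L))
  )
}

#' Cross-sample activity of category-D CRMs
#'
#' Entry (x, y) is the percentage of CRMs that are non-active but
#' peak-overlapped (category D) in sample x that are active and
#' peak-overlapped (category C) in sample y. The diagonal is defined as 0.
#'
#' @param d_sets,c_sets Named lists (by sample) of CRM id vectors: category D
#'   and category C memberships, respectively. The same samples must appear
#'   in both.
#' @return Numeric matrix of percentages (rows = D sample, cols = C sample);
#'   `NA` rows where the sample has no category-D CRMs.
#' @export
cross_sample_activity <- function(d_sets, c_sets) {
  stopifnot(identical(names(d_sets), names(c_sets)))
  samples <- names(d_sets)
  m <- matrix(NA_real_, length(samples), length(samples),
              dimnames = list(samples, samples))
  for (x in samples) {
    nd <- length(unique(d_sets[[x]]))
    for (y in samples) {
      if (x == y) { m[x, y] <- 0; next }
      if (nd == 0) next
      m[x, y] <- 100 * length(intersect(d_sets[[x]], c_sets[[y]])) / nd
    }
  }
  m
}

#' Assign elements to categories
#'
#' Element-level catalogs for downstream per-category statistics: an active
#' CRM is in category C when any of its bases overlaps a peak, otherwise B;
#' a non-active CRM is in D when peak-overlapped, otherwise A; a STARR peak
#' is assigned to C, D, or E by its largest in-region base share; a non-CRM
#' element is in F when it overlaps no peak.
#'
#' @param partition A `starr_partition`.
#' @param noncrms Interval tibble of non-CRM elements (for categories E/F
#'   context; only needed for F).
#' @return Named list of interval tibbles (categories A-F), each with `id`
#'   and `category` columns. A-D hold CRMs, E holds peaks, F holds non-CRM
#'   elements without any peak overlap.
#' @export
category_elements <- function(partition, noncrms = NULL) {
  stopifnot(inherits(partition, "starr_partition"))
  ca <- partition$crm_assignments
  crm_cat <- ifelse(ca$state == "active",
                    ifelse(ca$C > 0, "C", "B"),
                    ifelse(ca$D > 0, "D", "A"))
  pa <- partition$peak_assignments
  pk_bases <- cbind(C = pa$C, D = pa$D, E = pa$E)
  pk_cat <- category_levels[3:5][max.col(pk_bases, ties.method = "first")]
  pk_cat[rowSums(pk_bases) == 0] <- NA_character_
  out <- list()
  for (k in c("A", "B", "C", "D")) {
    sel <- crm_cat == k
    out[[k]] <- tibble::tibble(
      chrom = ca$chrom[sel], start = ca$start[sel], end = ca$end[sel],
      id = ca$crm_id[sel], category = k
    )
  }
  sel <- !is.na(pk_cat) & pk_cat == "E"
  out$E <- tibble::tibble(
    chrom = pa$chrom[sel], start = pa$start[sel], end = pa$end[sel],
    id = pa$peak_id[sel], category = "E"
  )
  if (!is.null(noncrms)) {
    noncrms <- validate_intervals(noncrms)
    nid <- element_ids(noncrms, "noncrm")
    pk_all <- pa[, c("chrom", "start", "end")]
    hit <- split_bases(noncrms, merge_intervals(pk_all)) > 0
    out$F <- tibble::tibble(
      chrom = noncrms$chrom[!hit], start = noncrms$start[!hit],
      end = noncrms$end[!hit], id = nid[!hit], category = "F"
    )
  } else {
    out$F <- tibble::tibble(chrom = character(), start = integer(),
                            end = integer(), id = character(),
                            category = character())
  }
  # peaks assigned to C and D (element view) are also exposed for metrics
  attr(out, "peaks_by_category") <- purrr::map(c(C = "C", D = "D", E = "E"),
    function(k) {
      sel <- !is.na(pk_cat) & pk_cat == k
      tibble::tibble(chrom = pa$chrom[sel], start = pa$start[sel],
                     end = pa$end[sel], id = pa$peak_id[sel], category = k)
    })
  out
}
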