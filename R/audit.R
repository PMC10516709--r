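#' Run the full STARR-seq audit on one sample
#'
#' Composes the pipeline stages: optional silencer/CTCF/promoter filtering
#' of the CRM catalog, functional-state calling (from ground-truth labels or
#' a trained predictor), the A-F base partition, element matching and
#' containment, per-category metrics, ChromHMM-like and TE enrichment, and
#' the per-category expression comparison. When filters remove CRMs, their
#' footprints are removed from the analyzable regions so that the remaining
#' CRM / non-CRM annotation still exhaustively covers what is analyzed.
#'
#' @param bundle A `synthetic_bundle` (or a list with the same fields built
#'   from real data files).
#' @param state `"oracle"` (use the bundle's ground-truth CRM states) or
#'   `"ufsp"` (train the predictor on the ground-truth states' features and
#'   call states from the marks).
#' @param apply_filters Apply the silencer/CTCF/promoter filters when the
#'   bundle provides `silencers` / `ctcf` elements or genes (default FALSE;
#'   synthetic bundles carry no silencer catalog).
#' @param overlap_threshold Reciprocal-overlap fraction (default 0.5).
#' @param promoter_dist Promoter-proximity cutoff in bp (default 1000).
#' @param n_draws Background draws for enrichment (default 10).
#' @param seed Seed for background sampling and any subsampling.
#' @param sample_id Sample label.
#' @return An object of class `starr_audit`: partition, ratios, matched
#'   pairs, containment and peaks-per-CRM summaries, category element ids,
#'   per-category metrics, enrichment tables, and the expression test
#'   matrix.
#' @export
run_audit <- function(bundle, state = c("oracle", "ufsp"),
                      apply_filters = FALSE, overlap_threshold = 0.5,
                      promoter_dist = 1000, n_draws = 10, seed = 1,
                      sample_id = "sample") {
  state <- match.arg(state)
  crms <- bundle$crms
  noncrms <- bundle$noncrms
  genome <- bundle$genome
  filter_reports <- list()

  if (apply_filters) {
    if (!is.null(bundle$silencers) || !is.null(bundle$ctcf)) {
      empty <- tibble::tibble(chrom = character(), start = integer(),
                              end = integer())
      fs <- filter_silencer_insulator(
        crms, bundle$silencers %||% empty, bundle$ctcf %||% empty,
        threshold = overlap_threshold
      )
      filter_reports$silencer_ctcf <- fs$report
      crms <- fs$retained
    }
    if (!is.null(bundle$genes)) {
      fp <- filter_promoter_proximal(crms, bundle$genes,
                                     max_dist = promoter_dist)
      filter_reports$promoter <- fp$report
      crms <- fp$retained
    }
    removed <- dplyr::anti_join(bundle$crms, crms, by = "id")
    if (nrow(removed)) {
      genome <- genome_spec(
        genome$chrom_sizes,
        interval_setdiff(genome$analyzable,
                         removed[, c("chrom", "start", "end")])
      )
    }
  }

  if (state == "oracle") {
    states <- bundle$truth$crm_states
    crms$state <- states$state[match(crms$id, states$id)]
    model <- NULL
    state_calls <- NULL
  } else {
    feats <- extract_features(crms, bundle$tracks[ufsp_feature_names],
                              bundle$tracks$input)
    truth_state <- bundle$truth$crm_states$state[
      match(crms$id, bundle$truth$crm_states$id)]
    model <- ufsp_train(feats[truth_state == "active", ],
                        feats[truth_state == "non-active", ])
    state_calls <- ufsp_predict(model, feats)
    crms$state <- state_calls$state[match(crms$id, state_calls$element_id)]
  }

  active <- crms[crms$state == "active", c("chrom", "start", "end", "id")]
  nonactive <- crms[crms$state == "non-active", c("chrom", "start", "end", "id")]
  part <- partition_genome(genome, active, nonactive,
                           noncrms[, c("chrom", "start", "end", "id")],
                           bundle$peaks[, c("chrom", "start", "end", "id")],
                           sample_id = sample_id)
  ratios <- partition_ratios(part)

  pairs <- match_peaks_to_crms(bundle$peaks, crms,
                               threshold = overlap_threshold)
  containment <- if (nrow(pairs)) {
    tibble::tibble(
      pct_full = 100 * mean(pairs$containment == "full"),
      pct_partial = 100 * mean(pairs$containment == "partial")
    )
  } else tibble::tibble(pct_full = NA_real_, pct_partial = NA_real_)
  ppc <- peaks_per_crm(crms, pairs)

  catalogs <- category_elements(part, noncrms)
  peaks_by_cat <- attr(catalogs, "peaks_by_category")

  metrics <- purrr::map_dfr(c("A", "B", "C", "D", "E"), function(k) {
    el <- if (k == "E") peaks_by_cat$E else catalogs[[k]]
    if (nrow(el) == 0) return(NULL)
    cx <- complexity_score(el, bundle$tfbs, bundle$network)
    strength <- if (k %in% c("C", "D", "E")) {
      pk <- peaks_by_cat[[k]]
      if (!is.null(pk) && nrow(pk)) {
        mean(peak_signal_strength(pk, bundle$tracks$starr,
                                  bundle$tracks$input)$strength)
      } else NA_real_
    } else NA_real_
    ls <- length_summary(el)
    tibble::tibble(
      category = k, n_elements = nrow(el),
      mean_length = ls$mean, median_length = ls$median,
      mean_gc = if (!is.null(bundle$sequences))
        mean(element_gc(el, bundle$sequences)) else NA_real_,
      mean_complexity = mean(cx$complexity),
      mean_conservation = mean(conservation_distribution(
        el, bundle$tracks$conservation)),
      mean_signal_strength = strength
    )
  })

  enrich <- NULL
  if (!is.null(bundle$chromhmm)) {
    enrich <- purrr::map_dfr(c("A", "B", "C", "D", "E"), function(k) {
      el <- if (k == "E") peaks_by_cat$E else catalogs[[k]]
      if (nrow(el) == 0) return(NULL)
      bg <- sample_matched(genome, el, n_draws = n_draws,
                           seed = seed + match(k, category_levels))
      dplyr::bind_rows(
        dplyr::mutate(
          state_enrichment(el, bundle$chromhmm, bg, mode = "length"),
          category = k, annotation = "chromhmm"),
        if (!is.null(bundle$te)) dplyr::mutate(
          state_enrichment(el, bundle$te, bg, mode = "count"),
          category = k, annotation = "te")
      )
    })
  }

  expr <- NULL
  expr_tests <- NULL
  if (!is.null(bundle$genes) && !is.null(bundle$expression)) {
    cat_for_expr <- catalogs
    cat_for_expr$E <- peaks_by_cat$E
    expr <- category_expression(cat_for_expr, bundle$genes, bundle$expression)
    if (length(unique(expr$category)) >= 2) {
      expr_tests <- expression_test_matrix(expr)
    }
  }

  structure(
    list(
      sample_id = sample_id,
      filter_reports = filter_reports,
      model = model,
      state_calls = state_calls,
      partition = part,
      ratios = ratios,
      matched_pairs = pairs,
      containment = containment,
      peaks_per_crm = ppc,
      category_c_crms = catalogs$C$id,
      category_d_crms = catalogs$D$id,
      metrics = metrics,
      enrichment = enrich,
      category_expression = expr,
      expression_tests = expr_tests
    ),
    class = "starr_audit"
  )
}

#' @export
print.starr_audit <- function(x, ...) {
  cat("<starr_audit> sample", x$sample_id, "\n")
  print(round(x$partition$base_counts))
  print(as.data.frame(round(x$ratios[, -1], 1)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize audits across samples
#'
#' Pools per-sample audits: the unweighted mean of every derived ratio
#' (matching a mean-percentage summary across cell lines/tissues), and the
#' cross-sample activity matrix of category-D CRMs.
#'
#' @param reports List of `starr_audit` objects.
#' @return List with `mean_ratios` (one-row tibble), `ratios` (per-sample
#'   tibble), and `cross_sample` (matrix from [cross_sample_activity()]).
#' @export
summarize_across_samples <- function(reports) {
  stopifnot(length(reports) >= 1)
  ratios <- purrr::map_dfr(reports, "ratios")
  mean_ratios <- dplyr::summarise(
    ratios, dplyr::across(-"sample_id", ~ mean(.x, na.rm = TRUE))
  )
  ids <- purrr::map_chr(reports, "sample_id")
  d_sets <- stats::setNames(purrr::map(reports, "category_d_crms"), ids)
  c_sets <- stats::setNames(purrr::map(reports, "category_c_crms"), ids)
  list(
    mean_ratios = mean_ratios,
    ratios = ratios,
    cross_sample = cross_sample_activity(d_sets, c_sets)
  )
}

#' Write an audit report to disk
#'
#' JSON report of base counts, ratios, and containment plus TSVs of the
#' element-level tables.
#'
#' @param audit A `starr_audit`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_audit <- function(audit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(
      sample_id = audit$sample_id,
      base_counts = as.list(audit$partition$base_counts),
      unassessed_peak_bases = audit$partition$unassessed_peak_bases,
      ratios = as.list(audit$ratios[, -1]),
      containment = as.list(audit$containment)
    ),
    file.path(dir, "report.json"), auto_unbox = TRUE, digits = NA
  )
  readr::write_tsv(audit$partition$peak_assignments,
                   file.path(dir, "peak_assignments.tsv"), progress = FALSE)
  readr::write_tsv(audit$partition$crm_assignments,
                   file.path(dir, "crm_assignments.tsv"), progress = FALSE)
  if (!is.null(audit$metrics)) {
    readr::write_tsv(audit$metrics, file.path(dir, "metrics.tsv"),
                     progress = FALSE)
  }
  if (!is.null(audit$enrichment)) {
    readr::write_tsv(audit$enrichment, file.path(dir, "enrichment.tsv"),
                     progress = FALSE)
  }
  if (!is.null(audit$expression_tests)) {
    readr::write_tsv(audit$expression_tests,
                     file.path(dir, "expression_tests.tsv"), progress = FALSE)
  }
  invisible(dir)
}
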