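#' Closest-gene assignment
#'
#' Assigns each element the gene whose TSS is closest by edge distance on the
#' linear chromosome (distance 0 when the TSS falls inside the element).
#' Ties are broken by smaller distance then lexicographically smaller
#' `gene_id`; strand is ignored.
#'
#' @param elements Interval tibble.
#' @param genes Tibble with `gene_id`, `chrom`, `tss` columns.
#' @return Tibble with `element_id`, `gene_id`, `distance`; `gene_id` is
#'   `NA` for elements on chromosomes without genes.
#' @export
closest_gene <- function(elements, genes) {
  elements <- validate_intervals(elements)
  stopifnot(all(c("gene_id", "chrom", "tss") %in% names(genes)))
  eid <- element_ids(elements, "elem")
  out_gene <- rep(NA_character_, nrow(elements))
  out_dist <- rep(NA_real_, nrow(elements))
  for (chr in unique(elements$chrom)) {
    g <- genes[genes$chrom == chr, , drop = FALSE]
    if (nrow(g) == 0) next
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    idx <- which(elements$chrom == chr)
    s <- elements$start[idx]
    e <- elements$end[idx]
    # distance from element [s, e) to TSS t: max(0, s - t, t - e)
    for (j in seq_along(idx)) {
      d <- pmax(0, pmax(s[j] - g$tss, g$tss - e[j]))
      best <- which(d == min(d))
      pick <- best[order(g$gene_id[best])][1]
      out_gene[idx[j]] <- g$gene_id[pick]
      out_dist[idx[j]] <- d[pick]
    }
  }
  if (anyNA(out_gene)) {
    warning("element(s) on chromosome(s) without genes: assignment NA")
  }
  tibble::tibble(element_id = eid, gene_id = out_gene, distance = out_dist)
}

#' Expression of genes associated with each category
#'
#' A gene is associated with a category when it is the closest gene of at
#' least one element of that category; within a category each gene
#' contributes one expression value (deduplicated), but a gene may appear
#' under several categories.
#'
#' @param catalogs Named list of per-category element tibbles, e.g. from
#'   [category_elements()].
#' @param genes Gene tibble (`gene_id`, `chrom`, `tss`).
#' @param expression Tibble with `gene_id`, `tpm`.
#' @return Tibble with `category`, `gene_id`, `tpm` (one row per associated
#'   gene per category); empty categories contribute no rows.
#' @export
category_expression <- function(catalogs, genes, expression) {
  stopifnot(all(c("gene_id", "tpm") %in% names(expression)))
  purrr::map_dfr(names(catalogs), function(k) {
    el <- catalogs[[k]]
    if (nrow(el) == 0) return(NULL)
    asg <- suppressWarnings(closest_gene(el, genes))
    gid <- unique(asg$gene_id[!is.na(asg$gene_id)])
    if (length(gid) == 0) return(NULL)
    tibble::tibble(
      category = k, gene_id = gid,
      tpm = expression$tpm[match(gid, expression$gene_id)]
    )
  })
}

#' Two-tailed Mann-Whitney U test
#'
#' Compares two samples by ranks. The exact null distribution is used when
#' the smaller sample has at most 8 observations and there are no ties
#' between or within samples; otherwise the normal approximation with tie
#' and continuity corrections is used.
#'
#' @param x,y Numeric samples (nonempty).
#' @return List with `U` (the U statistic for `x`), `p_two_sided`, and
#'   `method` (`"exact"` or `"normal"`).
#' @export
#' @examples
#' mwu_test(c(1, 2, 3), c(4, 5, 6))
mwu_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  has_ties <- anyDuplicated(c(x, y)) > 0
  exact <- min(length(x), length(y)) <= 8 && !has_ties
  wt <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = exact, correct = TRUE
  ))
  list(
    U = unname(wt$statistic),
    p_two_sided = min(1, wt$p.value),
    method = if (exact) "exact" else "normal"
  )
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' @param x,y Numeric samples (nonempty).
#' @return List with `D` (sup distance between empirical CDFs) and `p`
#'   (asymptotic two-sided p-value).
#' @export
ks_test <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  kt <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Pairwise category expression tests
#'
#' Runs the two-tailed Mann-Whitney U test (and optionally the K-S test) on
#' every pair of category expression distributions.
#'
#' @param cat_expr Output of [category_expression()].
#' @param adjust Add a Benjamini-Hochberg adjusted column (default FALSE;
#'   raw p-values are the primary output).
#' @return Tibble with `category_1`, `category_2`, `n_1`, `n_2`, `U`,
#'   `p_mwu`, `D`, `p_ks` (and `p_mwu_bh` when `adjust`).
#' @export
expression_test_matrix <- function(cat_expr, adjust = FALSE) {
  cats <- sort(unique(cat_expr$category))
  if (length(cats) < 2) {
    stop("need at least two categories with associated genes")
  }
  pairs <- utils::combn(cats, 2, simplify = FALSE)
  out <- purrr::map_dfr(pairs, function(pr) {
    x <- cat_expr$tpm[cat_expr$category == pr[1]]
    y <- cat_expr$tpm[cat_expr$category == pr[2]]
    mw <- mwu_test(x, y)
    ks <- ks_test(x, y)
    tibble::tibble(
      category_1 = pr[1], category_2 = pr[2],
      n_1 = length(x), n_2 = length(y),
      U = mw$U, p_mwu = mw$p_two_sided, D = ks$D, p_ks = ks$p
    )
  })
  if (adjust) out$p_mwu_bh <- stats::p.adjust(out$p_mwu, method = "BH")
  out
}
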