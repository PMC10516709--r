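#' Element-centered signal profile matrix
#'
#' For each element, takes a `window` bp segment centered on the element
#' midpoint (lower-median base for even lengths), tiles it into
#' non-overlapping `bin` bp bins, and records the mean fold enrichment of
#' the signal over the input in each bin. Bins extending beyond the
#' chromosome are masked, not zero-filled.
#'
#' @param elements Interval tibble.
#' @param signal,input `signal_track` objects.
#' @param window Window width in bp (default 6000).
#' @param bin Bin width in bp (default 100); must divide `window`.
#' @return Object of class `profile_matrix`: list with `values` (elements x
#'   bins matrix), `mask` (TRUE where the bin is off-chromosome), and
#'   `bin_mid` (bin midpoints relative to the element center).
#' @export
profile_matrix <- function(elements, signal, input, window = 6000, bin = 100) {
  elements <- validate_intervals(elements)
  if (nrow(elements) == 0) stop("element set is empty")
  if (window %% bin != 0) stop("`window` must be divisible by `bin`")
  n_bins <- window %/% bin
  fe <- fold_enrichment(signal, input)
  values <- track_values(fe)
  miss <- setdiff(unique(elements$chrom), names(values))
  if (length(miss)) {
    stop("element(s) on chromosome(s) absent from track: ",
         paste(miss, collapse = ", "))
  }
  chrom_len <- vapply(values, length, 0L)
  mid <- (elements$start + elements$end) %/% 2L
  win_start <- mid - window %/% 2L
  mat <- matrix(NA_real_, nrow(elements), n_bins)
  mask <- matrix(FALSE, nrow(elements), n_bins)
  offs <- (seq_len(n_bins) - 1L) * bin
  for (i in seq_len(nrow(elements))) {
    chr <- elements$chrom[i]
    bs <- win_start[i] + offs          # 0-based bin starts
    be <- bs + bin
    off_chrom <- bs < 0L | be > chrom_len[[chr]]
    mask[i, off_chrom] <- TRUE
    if (any(!off_chrom)) {
      v <- IRanges::Views(values[[chr]], start = bs[!off_chrom] + 1L,
                          end = be[!off_chrom])
      mat[i, !off_chrom] <- IRanges::viewMeans(v)
    }
  }
  rownames(mat) <- element_ids(elements, "elem")
  structure(
    list(values = mat, mask = mask,
         bin_mid = offs + bin / 2 - window / 2),
    class = "profile_matrix"
  )
}

#' @export
print.profile_matrix <- function(x, ...) {
  cat("<profile_matrix>", nrow(x$values), "elements x", ncol(x$values),
      "bins\n")
  invisible(x)
}

#' Column means of a profile matrix
#'
#' @param matrix A `profile_matrix`.
#' @return Numeric vector of per-bin means over unmasked entries; `NA` for
#'   fully masked bins.
#' @export
profile_mean <- function(matrix) {
  stopifnot(inherits(matrix, "profile_matrix"))
  v <- matrix$values
  v[matrix$mask] <- NA_real_
  out <- colMeans(v, na.rm = TRUE)
  out[colSums(!matrix$mask) == 0] <- NA_real_
  out
}

#' Sample the elements profiled for a category
#'
#' Follows the row-sampling rules of the audit's heatmaps: all elements for
#' categories C, D, and E; a uniform random subsample of at most `cap`
#' elements for A and B; and for F, a subsample of the same size as the
#' category-E peak set. Deterministic given `seed`.
#'
#' @param catalogs Named list of per-category element tibbles
#'   ([category_elements()]).
#' @param category One of `"A"`-`"F"`.
#' @param cap Maximum rows for categories A and B (default 10000).
#' @param seed RNG seed.
#' @return Interval tibble of sampled elements.
#' @export
sample_category_rows <- function(catalogs, category, cap = 10000, seed = 1) {
  stopifnot(category %in% category_levels)
  el <- catalogs[[category]]
  n_target <- switch(category,
    A = , B = min(nrow(el), cap),
    F = min(nrow(el), nrow(catalogs$E)),
    nrow(el)
  )
  if (n_target >= nrow(el)) return(el)
  withr::with_seed(seed, el[sort(sample.int(nrow(el), n_target)), , drop = FALSE])
}

#' Write a profile matrix as TSV
#'
#' @param matrix A `profile_matrix`.
#' @param path Output path (row id + one column per bin; masked bins empty).
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(matrix, path) {
  v <- matrix$values
  v[matrix$mask] <- NA_real_
  df <- tibble::as_tibble(v, .name_repair = ~ paste0("bin_", seq_along(.x)))
  df <- dplyr::bind_cols(tibble::tibble(element_id = rownames(matrix$values)), df)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
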