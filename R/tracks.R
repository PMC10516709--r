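#' Build a per-base signal track
#'
#' A signal track holds per-base, piecewise-constant coverage values
#' (bedGraph semantics) for every chromosome of a genome, plus a library-size
#' normalizer. Bases not covered by any bedGraph interval read as 0 but are
#' remembered as uncovered so that distribution extractors can skip them.
#'
#' @param x Tibble with `chrom`, `start`, `end`, `value` (0-based half-open),
#'   or a path to a bedGraph file.
#' @param genome A [genome_spec()].
#' @param library_size Normalizer; defaults to the total signal mass
#'   (sum of value times width) of the track.
#' @return An object of class `signal_track`: list with `values` and
#'   `covered` (per-chromosome run-length encoded vectors) and
#'   `library_size`.
#' @export
signal_track <- function(x, genome, library_size = NULL) {
  if (is.character(x) && length(x) == 1) x <- read_bedgraph(x)
  x <- validate_intervals(x, genome = genome)
  if (!"value" %in% names(x)) stop("track input needs a `value` column")
  if (any(x$value < 0)) stop("track values must be >= 0")
  sizes <- genome$chrom_sizes
  values <- covered <- vector("list", length(sizes))
  names(values) <- names(covered) <- names(sizes)
  for (chr in names(sizes)) {
    n <- sizes[[chr]]
    v <- S4Vectors::Rle(0, n)
    cov <- S4Vectors::Rle(FALSE, n)
    xi <- x[x$chrom == chr, , drop = FALSE]
    if (nrow(xi)) {
      xi <- dplyr::arrange(xi, .data$start)
      if (any(xi$start[-1] < xi$end[-nrow(xi)])) {
        stop("overlapping bedGraph intervals on ", chr)
      }
      ir <- IRanges::IRanges(xi$start + 1L, xi$end)
      v[ir] <- S4Vectors::Rle(rep(xi$value, IRanges::width(ir)))
      cov[ir] <- TRUE
    }
    values[[chr]] <- v
    covered[[chr]] <- cov
  }
  if (is.null(library_size)) {
    library_size <- sum(vapply(values, function(v) {
      sum(as.numeric(S4Vectors::runValue(v)) * S4Vectors::runLength(v))
    }, 0))
    if (library_size == 0) library_size <- 1
  }
  structure(list(values = values, covered = covered,
                 library_size = library_size),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat("<signal_track> ", length(x$values), " chromosome(s), library size ",
      format(x$library_size, big.mark = ","), "\n", sep = "")
  invisible(x)
}

## internal: constant track over a genome (used by tests and examples)
constant_track <- function(genome, value, library_size = NULL) {
  signal_track(
    dplyr::mutate(genome$analyzable, value = value),
    genome, library_size = library_size
  )
}

#' Per-base fold enrichment of a signal over an input track
#'
#' Fold enrichment at a base is the library-size-normalized signal divided by
#' the library-size-normalized input. Bases where the input is zero receive a
#' pseudocount of one read-equivalent in both numerator and denominator,
#' keeping the ratio bounded. The same definition feeds the functional-state
#' features, the peak signal strengths, and the profile matrices.
#'
#' @param signal,input `signal_track` objects over the same genome.
#' @return A `fe_track`: per-chromosome run-length encoded fold-enrichment
#'   values.
#' @export
fold_enrichment <- function(signal, input) {
  stopifnot(inherits(signal, "signal_track"), inherits(input, "signal_track"))
  if (!identical(names(signal$values), names(input$values))) {
    stop("signal and input tracks cover different chromosomes")
  }
  ls <- signal$library_size
  li <- input$library_size
  out <- lapply(names(signal$values), function(chr) {
    s <- signal$values[[chr]]
    i <- input$values[[chr]]
    r <- (s * li) / (i * ls)
    zero <- i == 0
    if (any(zero)) r[zero] <- ((s[zero] + 1) * li) / ls
    r
  })
  names(out) <- names(signal$values)
  structure(list(values = out), class = "fe_track")
}

## internal: extract chromosome-level values object from either track type
track_values <- function(track) {
  if (inherits(track, "signal_track") || inherits(track, "fe_track")) {
    return(track$values)
  }
  stop("expected a signal_track or fe_track")
}

## internal: check elements lie within the track's chromosomes
check_track_cover <- function(values, elements) {
  miss <- setdiff(unique(elements$chrom), names(values))
  if (length(miss)) {
    stop("element(s) on chromosome(s) absent from track: ",
         paste(miss, collapse = ", "))
  }
  too_far <- elements$end > vapply(values[elements$chrom], length, 0L)
  if (any(too_far)) {
    stop("element(s) beyond track coverage: ",
         paste(utils::head(format_intervals(elements[too_far, ]), 5),
               collapse = ", "))
  }
}

#' Mean track value over each element
#'
#' @param track A `signal_track` or `fe_track`.
#' @param elements Interval tibble.
#' @return Numeric vector of per-element means (over all element bases).
#' @export
track_mean <- function(track, elements) {
  elements <- validate_intervals(elements)
  values <- track_values(track)
  check_track_cover(values, elements)
  out <- numeric(nrow(elements))
  for (chr in unique(elements$chrom)) {
    idx <- which(elements$chrom == chr)
    v <- IRanges::Views(values[[chr]],
                        start = elements$start[idx] + 1L,
                        end = elements$end[idx])
    out[idx] <- IRanges::viewMeans(v)
  }
  out
}

#' Per-base track values over a set of elements
#'
#' Returns the multiset of per-base values across all element bases, in
#' element order. For `signal_track` inputs, bases not covered by the
#' original bedGraph are skipped and counted in the `n_uncovered` attribute.
#'
#' @param track A `signal_track` or `fe_track`.
#' @param elements Interval tibble.
#' @return Numeric vector of per-base values with attribute `n_uncovered`.
#' @export
track_base_values <- function(track, elements) {
  elements <- validate_intervals(elements)
  values <- track_values(track)
  check_track_cover(values, elements)
  has_cov <- inherits(track, "signal_track")
  vals <- vector("list", nrow(elements))
  n_unc <- 0L
  for (i in seq_len(nrow(elements))) {
    chr <- elements$chrom[i]
    w <- IRanges::IRanges(elements$start[i] + 1L, elements$end[i])
    v <- as.numeric(values[[chr]][w])
    if (has_cov) {
      cov <- as.logical(track$covered[[chr]][w])
      n_unc <- n_unc + sum(!cov)
      v <- v[cov]
    }
    vals[[i]] <- v
  }
  out <- unlist(vals, use.names = FALSE)
  if (is.null(out)) out <- numeric()
  attr(out, "n_uncovered") <- n_unc
  out
}

## internal: run-length values -> bedGraph tibble (zero runs kept; callers
## may drop them)
rle_to_bedgraph <- function(values, drop_zero = FALSE) {
  purrr::map_dfr(names(values), function(chr) {
    v <- values[[chr]]
    ends <- cumsum(S4Vectors::runLength(v))
    out <- tibble::tibble(
      chrom = chr,
      start = as.integer(ends - S4Vectors::runLength(v)),
      end = as.integer(ends),
      value = as.numeric(S4Vectors::runValue(v))
    )
    if (drop_zero) out <- out[out$value != 0, , drop = FALSE]
    out
  })
}
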