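#' Read a BED file into an interval tibble
#'
#' Accepts BED3, BED6, and BED-with-extra-columns dialects. Coordinates are
#' kept 0-based half-open. Column 4 (when present) becomes `id`, column 5
#' `score`, column 6 `strand`; strand is parsed but ignored by all overlap
#' logic in this package.
#'
#' @param path Path to a tab-separated BED file.
#' @param genome Optional [genome_spec()] used to validate chromosome names
#'   and bounds.
#' @param aliases Optional named character vector mapping input chromosome
#'   names to canonical ones (e.g. `c("1" = "chr1")`). Unknown names are an
#'   error, never silently harmonized.
#' @return Sorted interval tibble with `chrom`, `start`, `end` and any of
#'   `id`, `score`, `strand` present in the file.
#' @export
read_bed <- function(path, genome = NULL, aliases = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(), end = integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d in %s: fewer than 3 fields",
                 which(nf < 3)[1], path))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
  bad <- is.na(start) | is.na(end)
  if (any(bad)) {
    stop(sprintf("malformed BED line %d in %s: non-numeric coordinates",
                 which(bad)[1], path))
  }
  bad <- start < 0L | start >= end
  if (any(bad)) {
    stop(sprintf("invalid interval at line %d in %s: start %d, end %d",
                 which(bad)[1], path, start[which(bad)[1]], end[which(bad)[1]]))
  }
  if (!is.null(aliases)) {
    hit <- chrom %in% names(aliases)
    chrom[hit] <- unname(aliases[chrom[hit]])
  }
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (any(nf >= 4)) out$id <- vapply(fields, function(f) if (length(f) >= 4) f[[4]] else NA_character_, "")
  if (any(nf >= 5)) {
    out$score <- suppressWarnings(as.numeric(
      vapply(fields, function(f) if (length(f) >= 5) f[[5]] else NA_character_, "")
    ))
  }
  if (any(nf >= 6)) out$strand <- vapply(fields, function(f) if (length(f) >= 6) f[[6]] else NA_character_, "")
  out <- validate_intervals(out, genome = genome)
  sort_intervals(out)
}

#' Write an interval tibble as sorted BED
#'
#' Emits BED3 plus `id`, `score`, `strand` columns when present (missing
#' values filled with BED conventions: `.`, `0`, `.`).
#'
#' @param x Interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  x <- sort_intervals(x)
  cols <- list(x$chrom, x$start, x$end)
  if ("strand" %in% names(x) && !"score" %in% names(x)) x$score <- 0
  if (("score" %in% names(x) || "strand" %in% names(x)) && !"id" %in% names(x)) {
    x$id <- "."
  }
  if ("id" %in% names(x)) cols <- c(cols, list(ifelse(is.na(x$id), ".", x$id)))
  if ("score" %in% names(x)) cols <- c(cols, list(ifelse(is.na(x$score), 0, x$score)))
  if ("strand" %in% names(x)) cols <- c(cols, list(ifelse(is.na(x$strand), ".", x$strand)))
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path Path to a 4-column tab-separated bedGraph (chrom, start, end,
#'   value; 0-based half-open).
#' @return Tibble with `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  x <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "value"),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_integer(),
      end = readr::col_integer(), value = readr::col_double()
    ),
    comment = "#", progress = FALSE
  )
  validate_intervals(x)
}

#' Write a bedGraph file
#'
#' @param x Tibble with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(x, path) {
  x <- sort_intervals(x)
  readr::write_tsv(x[, c("chrom", "start", "end", "value")], path,
                   col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' @param path TSV with columns `gene_id`, `chrom`, `tss` (0-based position),
#'   `strand`.
#' @return Tibble with those columns.
#' @export
read_genes <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), chrom = readr::col_character(),
    tss = readr::col_integer(), strand = readr::col_character()
  ), progress = FALSE)
}

#' Read a gene-expression table
#'
#' @param path TSV with columns `gene_id`, `tpm`.
#' @return Tibble with those columns.
#' @export
read_expression <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(), tpm = readr::col_double()
  ), progress = FALSE)
}

#' Read a motif interaction network edge list
#'
#' @param path Two-column TSV (`from`, `to`) of undirected motif-motif edges.
#' @return A `motif_network` object; see [motif_network()].
#' @export
read_motif_network <- function(path) {
  x <- readr::read_tsv(path, col_names = c("from", "to"),
                       col_types = "cc", progress = FALSE)
  if (nrow(x) > 0 && identical(unlist(x[1, ], use.names = FALSE), c("from", "to"))) {
    x <- x[-1, ]
  }
  motif_network(x)
}

#' Read a FASTA genome
#'
#' @param path FASTA path.
#' @return Named `DNAStringSet`.
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}
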