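# Independent oracles used by the unit and acceptance tests. These are kept
# deliberately literal (per-base loops, full enumeration) so they share no
# code path with the implementation they check.

# Literal per-base labeling of a genome: materializes one membership flag per
# base position and assigns each position its category by case analysis.
oracle_base_counts <- function(chrom_sizes, active, nonactive, noncrms, peaks,
                               analyzable = NULL) {
  counts <- c(A = 0, B = 0, C = 0, D = 0, E = 0, F = 0)
  flags <- function(set, chr, n) {
    v <- logical(n)
    s <- set[set$chrom == chr, , drop = FALSE]
    for (i in seq_len(nrow(s))) v[(s$start[i] + 1):s$end[i]] <- TRUE
    v
  }
  for (chr in names(chrom_sizes)) {
    n <- chrom_sizes[[chr]]
    act <- flags(active, chr, n)
    non <- flags(nonactive, chr, n)
    nc <- flags(noncrms, chr, n)
    pk <- flags(peaks, chr, n)
    keep <- if (is.null(analyzable)) rep(TRUE, n) else flags(analyzable, chr, n)
    lab <- ifelse(act, ifelse(pk, "C", "B"),
           ifelse(non, ifelse(pk, "D", "A"),
           ifelse(nc, ifelse(pk, "E", "F"), NA_character_)))
    tab <- table(lab[keep])
    counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
  }
  counts
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n + m, n) label assignments of the pooled sample.
oracle_mwu_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  u_stat <- function(xs, ys) {
    sum(vapply(xs, function(a) sum(a > ys) + 0.5 * sum(a == ys), 0))
  }
  u_obs <- u_stat(x, y)
  mu <- n * length(y) / 2
  combos <- utils::combn(length(pooled), n)
  us <- apply(combos, 2, function(idx) u_stat(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Random small scenario for fuzzing the partition: alternating CRM / non-CRM
# elements with random states, plus random peaks.
random_partition_inputs <- function(max_len = 10000, seed = 1) {
  withr::with_seed(seed, {
    n_chroms <- sample(1:2, 1)
    sizes <- stats::setNames(sample(500:max_len, n_chroms),
                             paste0("chr", seq_len(n_chroms)))
    segs <- lapply(names(sizes), function(chr) {
      # draw more alternating segment lengths than can fit, then truncate
      lens <- sample(50:800, ceiling(sizes[[chr]] / 50) + 1, replace = TRUE)
      ends <- pmin(cumsum(lens), sizes[[chr]])
      keep <- c(TRUE, ends[-length(ends)] < sizes[[chr]])
      ends <- ends[keep]
      starts <- c(0L, ends[-length(ends)])
      is_crm <- sample(c(TRUE, FALSE), 1)
      tibble::tibble(
        chrom = chr, start = as.integer(starts), end = as.integer(ends),
        crm = rep(c(is_crm, !is_crm), length.out = length(ends))
      )
    })
    segs <- dplyr::bind_rows(segs)
    crms <- segs[segs$crm, c("chrom", "start", "end")]
    noncrms <- segs[!segs$crm, c("chrom", "start", "end")]
    if (nrow(crms) == 0) {
      crms <- noncrms[1, ]
      noncrms <- noncrms[-1, ]
    }
    state <- sample(c("active", "non-active"), nrow(crms), replace = TRUE)
    n_peaks <- sample(0:8, 1)
    peaks <- if (n_peaks > 0) {
      chr <- sample(names(sizes), n_peaks, replace = TRUE)
      s <- vapply(chr, function(c) sample.int(sizes[[c]] - 60L, 1L), 1L)
      e <- pmin(as.integer(s + sample(30:600, n_peaks, replace = TRUE)),
                sizes[chr])
      # literal merge of overlapping/adjacent peaks per chromosome
      o <- order(chr, s)
      chr <- chr[o]; s <- as.integer(s[o]); e <- as.integer(e[o])
      keep_chr <- chr[1]; keep_s <- s[1]; keep_e <- e[1]
      if (n_peaks > 1) {
        for (i in 2:n_peaks) {
          j <- length(keep_s)
          if (chr[i] == keep_chr[j] && s[i] <= keep_e[j]) {
            keep_e[j] <- max(keep_e[j], e[i])
          } else {
            keep_chr <- c(keep_chr, chr[i])
            keep_s <- c(keep_s, s[i])
            keep_e <- c(keep_e, e[i])
          }
        }
      }
      tibble::tibble(chrom = keep_chr, start = keep_s, end = keep_e)
    } else {
      tibble::tibble(chrom = character(), start = integer(), end = integer())
    }
    list(
      sizes = sizes,
      active = crms[state == "active", , drop = FALSE],
      nonactive = crms[state == "non-active", , drop = FALSE],
      noncrms = noncrms,
      peaks = peaks
    )
  })
}
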