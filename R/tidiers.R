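#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a UFSP model
#'
#' @param x A `ufsp_model`.
#' @param ... Unused.
#' @return Tibble with one row per term (intercept + four features):
#'   `term`, `estimate` (on the standardized feature scale), `center`,
#'   `scale`.
#' @export
tidy.ufsp_model <- function(x, ...) {
  tibble::tibble(
    term = c("(Intercept)", x$feature_names),
    estimate = c(x$intercept, unname(x$weights)),
    center = c(NA_real_, unname(x$center)),
    scale = c(NA_real_, unname(x$scale))
  )
}

#' One-row summary of a UFSP model
#'
#' @param x A `ufsp_model`.
#' @param ... Unused.
#' @return Tibble with `n_positive`, `n_negative`, `lambda`, `threshold`.
#' @export
glance.ufsp_model <- function(x, ...) {
  tibble::tibble(
    n_positive = x$n_positive, n_negative = x$n_negative,
    lambda = x$lambda, threshold = x$threshold
  )
}

#' Tidy a genome partition
#'
#' @param x A `starr_partition`.
#' @param ... Unused.
#' @return Tibble with `category`, `bases`, `pct` (share of analyzable
#'   bases).
#' @export
tidy.starr_partition <- function(x, ...) {
  tibble::tibble(
    category = names(x$base_counts),
    bases = unname(x$base_counts),
    pct = 100 * unname(x$base_counts) / x$analyzable_bases
  )
}

#' One-row ratio summary of a genome partition
#'
#' @param x A `starr_partition`.
#' @param ... Unused.
#' @return The [partition_ratios()] tibble.
#' @export
glance.starr_partition <- function(x, ...) partition_ratios(x)

#' Tidy an audit report
#'
#' @param x A `starr_audit`.
#' @param ... Unused.
#' @return Per-category base counts and shares (see
#'   [tidy.starr_partition()]).
#' @export
tidy.starr_audit <- function(x, ...) tidy(x$partition)

#' One-row summary of an audit report
#'
#' @param x A `starr_audit`.
#' @param ... Unused.
#' @return The audit's derived ratio tibble.
#' @export
glance.starr_audit <- function(x, ...) x$ratios

#' Plot the category composition of a partition
#'
#' @param object A `starr_partition`.
#' @param ... Unused.
#' @return A ggplot bar chart of base shares per category.
#' @export
autoplot.starr_partition <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$pct,
                                   fill = .data$category)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(x = "category", y = "% of analyzable bases") +
    ggplot2::theme_minimal()
}

#' Plot the mean signal profile of a profile matrix
#'
#' @param object A `profile_matrix`.
#' @param ... Unused.
#' @return A ggplot line chart of the per-bin mean fold enrichment.
#' @export
autoplot.profile_matrix <- function(object, ...) {
  df <- tibble::tibble(position = object$bin_mid,
                       mean_fe = profile_mean(object))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$mean_fe)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to element center (bp)",
                  y = "mean fold enrichment") +
    ggplot2::theme_minimal()
}

#' Plot per-label enrichment fold changes
#'
#' @param enrichment Tibble from [state_enrichment()] (optionally with a
#'   `category` column from [run_audit()]).
#' @return A ggplot bar chart of fold changes per label.
#' @export
plot_enrichment <- function(enrichment) {
  p <- ggplot2::ggplot(enrichment,
                       ggplot2::aes(x = .data$label, y = .data$fold_change)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = NULL, y = "fold change (N - M) / M") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("category" %in% names(enrichment)) {
    p <- p + ggplot2::facet_wrap(~category)
  }
  p
}

#' Plot per-category expression distributions
#'
#' @param cat_expr Tibble from [category_expression()].
#' @return A ggplot boxplot of log10(TPM + 1) by category.
#' @export
plot_category_expression <- function(cat_expr) {
  ggplot2::ggplot(cat_expr,
                  ggplot2::aes(x = .data$category,
                               y = log10(.data$tpm + 1),
                               fill = .data$category)) +
    ggplot2::geom_boxplot(show.legend = FALSE, outlier.size = 0.4) +
    ggplot2::labs(x = "category", y = "log10(TPM + 1)") +
    ggplot2::theme_minimal()
}
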