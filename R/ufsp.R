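ufsp_feature_names <- c("ca", "h3k4me1", "h3k4me3", "h3k27ac")

#' Extract functional-state features for a set of elements
#'
#' For each element and each of the four active marks (chromatin
#' accessibility / ATAC, H3K4me1, H3K4me3, H3K27ac), the feature is
#' `log1p(mean fold enrichment over input)` across the element's bases,
#' with library-size normalization and the zero-input pseudocount described
#' in [fold_enrichment()].
#'
#' @param elements Interval tibble (an `id` column is used as `element_id`;
#'   otherwise row numbers are used).
#' @param marks Named list of four `signal_track`s, names `ca`, `h3k4me1`,
#'   `h3k4me3`, `h3k27ac` (any order).
#' @param input A `signal_track` of the matching input/control library.
#' @return Tibble with `element_id` and the four feature columns.
#' @export
extract_features <- function(elements, marks, input) {
  elements <- validate_intervals(elements)
  if (!setequal(names(marks), ufsp_feature_names)) {
    stop("`marks` must be a named list with elements: ",
         paste(ufsp_feature_names, collapse = ", "))
  }
  id <- if ("id" %in% names(elements)) as.character(elements$id) else
    as.character(seq_len(nrow(elements)))
  out <- tibble::tibble(element_id = id)
  for (m in ufsp_feature_names) {
    fe <- fold_enrichment(marks[[m]], input)
    out[[m]] <- log1p(track_mean(fe, elements))
  }
  out
}

#' Train the universal functional-state predictor (UFSP)
#'
#' Fits a logistic-regression classifier of CRM functional state (active vs
#' non-active) on four-mark feature vectors: a maximum-likelihood logistic
#' fit with a small L2 ridge so the fit stays defined on separable data.
#' Features are z-standardized at training time and the standardization is
#' stored in the model so prediction reproduces training-time features
#' exactly.
#'
#' @param positives,negatives Feature tibbles from [extract_features()]
#'   (positives = active examples).
#' @param lambda Ridge penalty (default 1e-3).
#' @param threshold Probability cutoff for calling "active" (default 0.5;
#'   inclusive).
#' @return An object of class `ufsp_model`.
#' @export
ufsp_train <- function(positives, negatives, lambda = 1e-3, threshold = 0.5) {
  stopifnot(nrow(positives) > 0, nrow(negatives) > 0)
  x <- as.matrix(rbind(positives[, ufsp_feature_names],
                       negatives[, ufsp_feature_names]))
  y <- c(rep(1L, nrow(positives)), rep(0L, nrow(negatives)))
  if (any(!is.finite(x))) stop("non-finite feature value(s)")
  center <- colMeans(x)
  scale <- apply(x, 2, stats::sd)
  flat <- scale == 0 | !is.finite(scale)
  if (any(flat)) {
    warning("zero-variance feature(s): ",
            paste(ufsp_feature_names[flat], collapse = ", "),
            "; retained with unit scale")
    scale[flat] <- 1
  }
  z <- sweep(sweep(x, 2, center), 2, scale, "/")
  fit <- glmnet::glmnet(z, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE,
                        thresh = 1e-10, maxit = 1e6)
  beta <- as.numeric(fit$beta[, 1])
  structure(
    list(
      feature_names = ufsp_feature_names,
      weights = stats::setNames(beta, ufsp_feature_names),
      intercept = as.numeric(fit$a0[1]),
      center = stats::setNames(as.numeric(center), ufsp_feature_names),
      scale = stats::setNames(as.numeric(scale), ufsp_feature_names),
      lambda = lambda,
      threshold = threshold,
      n_positive = nrow(positives),
      n_negative = nrow(negatives)
    ),
    class = "ufsp_model"
  )
}

#' @export
print.ufsp_model <- function(x, ...) {
  cat("<ufsp_model> logistic state predictor on",
      paste(x$feature_names, collapse = "/"),
      sprintf("\n  trained on %d active / %d non-active; threshold %.2f\n",
              x$n_positive, x$n_negative, x$threshold))
  print(round(x$weights, 4))
  invisible(x)
}

#' Predict CRM functional states
#'
#' @param model A `ufsp_model`.
#' @param features Feature tibble from [extract_features()].
#' @return Tibble with `element_id`, `probability`, and `state`
#'   (`"active"` iff probability is at or above the model threshold).
#' @export
ufsp_predict <- function(model, features) {
  stopifnot(inherits(model, "ufsp_model"))
  miss <- setdiff(model$feature_names, names(features))
  if (length(miss)) {
    stop("feature column(s) missing: ", paste(miss, collapse = ", "))
  }
  x <- as.matrix(features[, model$feature_names])
  z <- sweep(sweep(x, 2, model$center), 2, model$scale, "/")
  eta <- drop(z %*% model$weights) + model$intercept
  p <- stats::plogis(eta)
  tibble::tibble(
    element_id = if ("element_id" %in% names(features))
      as.character(features$element_id) else as.character(seq_len(nrow(features))),
    probability = unname(p),
    state = ifelse(p >= model$threshold, "active", "non-active")
  )
}

#' Serialize a UFSP model to JSON
#'
#' @param model A `ufsp_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ufsp <- function(model, path) {
  stopifnot(inherits(model, "ufsp_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a UFSP model from JSON
#'
#' @param path Path written by [write_ufsp()].
#' @return A `ufsp_model`.
#' @export
read_ufsp <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("weights", "center", "scale")) {
    m[[f]] <- stats::setNames(as.numeric(m[[f]]), m$feature_names)
  }
  structure(m, class = "ufsp_model")
}

#' Area under the ROC curve
#'
#' Rank-based AUROC (equivalent to the normalized Mann-Whitney U statistic);
#' ties share ranks.
#'
#' @param scores Numeric predictions.
#' @param labels Binary labels (1 / TRUE = positive).
#' @return AUROC in \\[0, 1\\].
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need both classes to compute AUROC")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
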