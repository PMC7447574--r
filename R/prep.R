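#' Filter features and samples by missingness
#'
#' Drops features whose missing fraction is strictly greater than
#' \code{threshold}, then samples whose missing fraction (computed over the
#' surviving features) is strictly greater than \code{threshold}. Row and
#' column order are preserved. A fully observed feature or sample is never
#' removed.
#'
#' @param m An \code{omics_matrix}.
#' @param threshold Maximum tolerated missing fraction, in \eqn{[0, 1]};
#'   default 0.2 (the usual 20\% exclusion rule).
#' @return Filtered \code{omics_matrix}.
#' @export
filter_missing <- function(m, threshold = 0.2) {
  stopifnot(inherits(m, "omics_matrix"))
  if (threshold < 0 || threshold > 1) stop_("'threshold' must be in [0, 1]")
  v <- m$values
  keep_f <- colMeans(is.na(v)) <= threshold
  if (!any(keep_f))
    stop_("degenerate input: every feature exceeds the %.0f%% missingness threshold",
          100 * threshold)
  v <- v[, keep_f, drop = FALSE]
  keep_s <- rowMeans(is.na(v)) <= threshold
  if (!any(keep_s))
    stop_("degenerate input: every sample exceeds the %.0f%% missingness threshold",
          100 * threshold)
  omics_matrix(v[keep_s, , drop = FALSE], m$omics_name)
}

#' Median-impute missing values
#'
#' Replaces each missing cell by the median of the observed values of its
#' feature (even counts: midpoint of the two central values). Observed cells
#' are untouched.
#'
#' @param m An \code{omics_matrix}; every feature needs at least one
#'   observed value (run \code{\link{filter_missing}} first).
#' @return Fully observed \code{omics_matrix}.
#' @export
impute_median <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  v <- m$values
  all_na <- colSums(!is.na(v)) == 0L
  if (any(all_na))
    stop_("degenerate input: feature(s) with no observed values: %s",
          paste(colnames(v)[all_na], collapse = ", "))
  for (j in which(colSums(is.na(v)) > 0L)) {
    med <- stats::median(v[, j], na.rm = TRUE)
    v[is.na(v[, j]), j] <- med
  }
  omics_matrix(v, m$omics_name)
}

#' Min-max scale features to [-1, 1]
#'
#' Rescales each feature linearly so its observed minimum maps to -1 and its
#' maximum to +1; constant features map to 0. The representation feeds tanh
#' layers, whose outputs live in (-1, 1), so reconstruction targets must lie
#' in that range. The per-feature minima and maxima are stored on the result
#' (attribute \code{"scaling"}) so the identical transform can be applied to
#' new cohorts with \code{apply_scaling}.
#'
#' @param m A fully observed \code{omics_matrix}.
#' @return Scaled \code{omics_matrix} carrying a \code{"scaling"} attribute
#'   (data frame: feature, min, max).
#' @export
scale_features <- function(m) {
  stopifnot(inherits(m, "omics_matrix"))
  if (anyNA(m$values)) stop_("scale_features requires a fully observed matrix")
  lo <- apply(m$values, 2L, min)
  hi <- apply(m$values, 2L, max)
  out <- scale_with(m$values, lo, hi)
  res <- omics_matrix(out, m$omics_name)
  attr(res, "scaling") <- data.frame(feature = colnames(m$values),
                                     min = unname(lo), max = unname(hi),
                                     stringsAsFactors = FALSE)
  res
}

scale_with <- function(v, lo, hi) {
  rng <- hi - lo
  const <- rng == 0
  rng[const] <- 1  # constant features -> 0 after centering
  out <- sweep(sweep(v, 2L, (lo + hi) / 2, "-"), 2L, rng / 2, "/")
  out[, const] <- 0
  out
}

#' @rdname scale_features
#' @param scaling A scaling table as produced by \code{scale_features}
#'   (or the \code{omics_matrix} it is attached to).
#' @export
apply_scaling <- function(m, scaling) {
  stopifnot(inherits(m, "omics_matrix"))
  if (inherits(scaling, "omics_matrix")) scaling <- attr(scaling, "scaling")
  if (is.null(scaling)) stop_("no scaling parameters supplied")
  miss <- setdiff(feature_names(m), scaling$feature)
  if (length(miss))
    stop_("no scaling parameters for feature(s): %s", paste(miss, collapse = ", "))
  idx <- match(feature_names(m), scaling$feature)
  out <- scale_with(m$values, scaling$min[idx], scaling$max[idx])
  res <- omics_matrix(out, m$omics_name)
  attr(res, "scaling") <- scaling
  res
}

#' Standard per-block preprocessing
#'
#' Convenience chain: missingness filter, median imputation, min-max
#' scaling, in that order. The chain is idempotent.
#'
#' @inheritParams filter_missing
#' @return Preprocessed \code{omics_matrix} with scaling attribute.
#' @export
preprocess_block <- function(m, threshold = 0.2) {
  scale_features(impute_median(filter_missing(m, threshold)))
}

#' Assemble aligned omics blocks and clinical data
#'
#' Intersects sample IDs across all blocks and the clinical table, aligns
#' every block to the same row order (order of appearance in the first
#' block), and concatenates features into one wide matrix with
#' block-prefixed column names (\code{<block>.<feature>}).
#'
#' @param blocks List of \code{omics_matrix} objects.
#' @param clinical Data frame with columns sample_id, time, event covering
#'   the shared samples.
#' @return An object of class \code{multiomics_dataset}: list with
#'   \code{blocks} (aligned), \code{clinical} (aligned), \code{x} (the
#'   concatenated matrix) and \code{sample_ids}.
#' @export
assemble <- function(blocks, clinical) {
  if (!length(blocks)) stop_("need at least one omics block")
  stopifnot(all(vapply(blocks, inherits, TRUE, "omics_matrix")))
  validate_clinical(clinical)
  ids <- Reduce(intersect, lapply(blocks, sample_ids))
  ids <- intersect(ids, clinical$sample_id)
  if (!length(ids)) {
    counts <- vapply(blocks, function(b) length(sample_ids(b)), 0L)
    stop_("no common samples across blocks and clinical (block sizes: %s; clinical: %d)",
          paste(vapply(blocks, `[[`, "", "omics_name"), counts,
                sep = "=", collapse = ", "),
          nrow(clinical))
  }
  ## keep the first block's order for determinism
  ids <- sample_ids(blocks[[1L]])[sample_ids(blocks[[1L]]) %in% ids]
  aligned <- lapply(blocks, function(b) {
    out <- b$values[ids, , drop = FALSE]
    res <- omics_matrix(out, b$omics_name)
    attr(res, "scaling") <- attr(b, "scaling")
    res
  })
  names(aligned) <- vapply(aligned, `[[`, "", "omics_name")
  x <- do.call(cbind, lapply(aligned, function(b) {
    v <- b$values
    colnames(v) <- paste(b$omics_name, colnames(v), sep = ".")
    v
  }))
  structure(list(blocks = aligned,
                 clinical = clinical[match(ids, clinical$sample_id), , drop = FALSE],
                 x = x,
                 sample_ids = ids),
            class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("multiomics_dataset: %d samples, %d blocks (%s), %d concatenated features\n",
              length(x$sample_ids), length(x$blocks),
              paste(sprintf("%s:%d", names(x$blocks),
                            vapply(x$blocks, function(b) ncol(b$values), 0L)),
                    collapse = ", "),
              ncol(x$x)))
  invisible(x)
}
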