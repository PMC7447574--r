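#' PCA and kernel-PCA baseline reductions
#'
#' Linear and kernel principal-component baselines for comparison with the
#' autoencoder representation. \code{pca_reduce} returns the top-d
#' principal-component scores (centered, unscaled); \code{kpca_reduce} the
#' top-d kernel principal components via \pkg{kernlab}.
#'
#' @param dataset A \code{multiomics_dataset}, \code{omics_matrix} or
#'   matrix with no missing values.
#' @param d Target dimension; at most \code{min(n_samples, n_features)}.
#' @return An \code{embedding}.
#' @export
pca_reduce <- function(dataset, d = 2L) {
  x <- as_input_matrix(dataset)
  if (d > min(dim(x)))
    stop_("d = %d exceeds min(n_samples, n_features) = %d", d, min(dim(x)))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  new_embedding(rownames(x) %||% as.character(seq_len(nrow(x))),
                pc$x[, seq_len(d), drop = FALSE])
}

#' @rdname pca_reduce
#' @param kernel A \pkg{kernlab} kernel name (default \code{"rbfdot"};
#'   \code{"vanilladot"} gives the linear kernel).
#' @param kpar Kernel parameter list, e.g. \code{list(sigma = 0.1)};
#'   \code{"automatic"} lets \pkg{kernlab} choose where supported.
#' @export
kpca_reduce <- function(dataset, d = 2L, kernel = "rbfdot", kpar = "automatic") {
  x <- as_input_matrix(dataset)
  if (d > min(dim(x)))
    stop_("d = %d exceeds min(n_samples, n_features) = %d", d, min(dim(x)))
  if (identical(kpar, "automatic")) {
    ## kpca's matrix method needs explicit kernel parameters; for the RBF
    ## kernel use the (deterministic) median heuristic on a bounded
    ## subsample: sigma * median ||x - y||^2 = 1
    kpar <- if (kernel == "rbfdot") {
      sub <- x[seq_len(min(nrow(x), 200L)), , drop = FALSE]
      d2 <- as.numeric(stats::dist(sub))^2
      list(sigma = 1 / stats::median(d2[d2 > 0]))
    } else list()
  }
  kp <- kernlab::kpca(x, kernel = kernel, kpar = kpar, features = d)
  new_embedding(rownames(x) %||% as.character(seq_len(nrow(x))),
                kernlab::rotated(kp)[, seq_len(d), drop = FALSE])
}
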