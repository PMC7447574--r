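#' K-means clustering of an embedding
#'
#' Standard Euclidean k-means with k-means++ seeding, re-run
#' \code{restarts} times keeping the solution with the lowest
#' within-cluster sum of squares. Internal-validity metrics (silhouette,
#' Davies-Bouldin) are computed on the same representation that was
#' clustered. Deterministic for a fixed seed.
#'
#' @param embedding An \code{embedding} or numeric matrix (samples in
#'   rows).
#' @param k Number of clusters, \code{2 <= k <= n_samples}.
#' @param seed Integer seed.
#' @param restarts Number of k-means++ restarts (default 10).
#' @param method_name Label stored on the result.
#' @return A \code{cluster_result}: named integer \code{labels} in
#'   \code{1..k}, \code{k}, \code{silhouette}, \code{dbi},
#'   \code{method_name}, \code{seed}, and the k-means objective
#'   \code{tot_withinss}.
#' @export
kmeans_cluster <- function(embedding, k, seed = 1L, restarts = 10L,
                           method_name = "kmeans") {
  pts <- embedding_points(embedding)
  n <- nrow(pts)
  if (k < 2L) stop_("k must be >= 2")
  if (k > n) stop_("k = %d exceeds the number of samples (%d)", k, n)
  with_seed(seed, {
    best <- NULL
    attempts <- 0L
    for (r in seq_len(restarts)) {
      fit <- NULL
      while (is.null(fit)) {
        attempts <- attempts + 1L
        if (attempts > restarts + 20L)
          stop_("k-means produced empty clusters repeatedly (k = %d)", k)
        centers <- kmeanspp_centers(pts, k)
        ## Hartigan-Wong requires k < n; Lloyd handles the k = n case
        algo <- if (k == n) "Lloyd" else "Hartigan-Wong"
        fit <- tryCatch(
          suppressWarnings(stats::kmeans(pts, centers = centers,
                                         iter.max = 100L, algorithm = algo)),
          error = function(e) NULL)
        if (!is.null(fit) && any(fit$size == 0L)) fit <- NULL
      }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    labels <- as.integer(best$cluster)
    names(labels) <- rownames(pts)
    structure(list(labels = labels, k = as.integer(k),
                   silhouette = if (k < n) silhouette_score(pts, labels) else NA_real_,
                   dbi = if (k < n) davies_bouldin(pts, labels) else NA_real_,
                   method_name = method_name, seed = as.integer(seed),
                   tot_withinss = best$tot.withinss,
                   centers = best$centers),
              class = "cluster_result")
  })
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result [%s]: k = %d (sizes %s), silhouette %.3f, DBI %.3f\n",
              x$method_name, x$k, paste(tabulate(x$labels, x$k), collapse = "/"),
              x$silhouette, x$dbi))
  invisible(x)
}

embedding_points <- function(embedding) {
  if (inherits(embedding, "embedding")) embedding$coordinates
  else if (is.matrix(embedding)) embedding
  else if (is.numeric(embedding)) matrix(embedding, ncol = 1L)
  else stop_("expected an embedding or numeric matrix")
}

## k-means++ seeding: first center uniform, then proportional to squared
## distance from the nearest chosen center.
kmeanspp_centers <- function(pts, k) {
  n <- nrow(pts)
  centers <- matrix(NA_real_, k, ncol(pts))
  centers[1L, ] <- pts[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(pts, 2L, centers[1L, ], "-")^2)
  for (j in seq_len(k - 1L) + 1L) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j, ] <- pts[sample.int(n, 1L, prob = probs), ]
    d2 <- pmin(d2, rowSums(sweep(pts, 2L, centers[j, ], "-")^2))
  }
  ## de-duplicate identical seeds (can happen with duplicated points)
  if (anyDuplicated(centers)) {
    for (j in which(duplicated(centers)))
      centers[j, ] <- pts[sample.int(n, 1L), ] + stats::rnorm(ncol(pts), sd = 1e-8)
  }
  centers
}

#' Mean silhouette width
#'
#' For each point, \eqn{s = (b - a) / \max(a, b)} with \eqn{a} the mean
#' distance to the other members of its own cluster and \eqn{b} the
#' smallest mean distance to any other cluster. Points in singleton
#' clusters score 0, as does the degenerate 0/0 case; the dataset score is
#' the mean over points. Range [-1, 1], higher = better separation.
#'
#' @param points Numeric matrix (samples in rows) or \code{embedding}.
#' @param labels Integer cluster labels, one per row; at least two
#'   non-empty clusters.
#' @return Mean silhouette width.
#' @export
silhouette_score <- function(points, labels) {
  pts <- embedding_points(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop_("silhouette undefined for a single cluster")
  D <- as.matrix(stats::dist(pts))
  sizes <- tabulate(labels, k)
  ind <- outer(labels, seq_len(k), "==") * 1     # n x k membership
  sums <- D %*% ind                              # distance sums to each cluster
  means <- sweep(sums, 2L, sizes, "/")
  own <- sizes[labels]
  a <- ifelse(own > 1L, sums[cbind(seq_along(labels), labels)] / (own - 1L), 0)
  other <- means
  other[cbind(seq_along(labels), labels)] <- Inf
  b <- apply(other, 1L, min)
  s <- (b - a) / pmax(a, b)
  s[!is.finite(s) | is.nan(s)] <- 0
  s[own == 1L] <- 0
  mean(s)
}

#' Davies-Bouldin index
#'
#' Mean over clusters of the worst-case similarity ratio
#' \eqn{(s_i + s_j) / M_{ij}}, where \eqn{s_i} is the mean Euclidean
#' distance of cluster \eqn{i}'s points to its centroid and \eqn{M_{ij}}
#' the distance between centroids. Lower is better. Coincident centroids
#' give an infinite pair ratio, which propagates.
#'
#' @inheritParams silhouette_score
#' @return The index (>= 0, possibly \code{Inf}).
#' @export
davies_bouldin <- function(points, labels) {
  pts <- embedding_points(points)
  labels <- as.integer(factor(labels))
  k <- max(labels)
  if (k < 2L) stop_("Davies-Bouldin undefined for a single cluster")
  centroids <- do.call(rbind, lapply(seq_len(k), function(c)
    colMeans(pts[labels == c, , drop = FALSE])))
  s <- vapply(seq_len(k), function(c) {
    mean(sqrt(rowSums(sweep(pts[labels == c, , drop = FALSE], 2L,
                            centroids[c, ], "-")^2)))
  }, 0)
  M <- as.matrix(stats::dist(centroids))
  R <- outer(s, s, "+") / M
  R[M == 0] <- Inf  # coincident centroids: worst-case ratio propagates
  diag(R) <- -Inf
  mean(apply(R, 1L, max))
}

#' Select the number of clusters by silhouette
#'
#' Runs \code{\link{kmeans_cluster}} for every k in
#' \code{k_min..k_max} and returns the k with the highest silhouette
#' (ties broken toward the smallest k).
#'
#' @inheritParams kmeans_cluster
#' @param k_min,k_max Inclusive candidate range (default 2..8).
#' @return List with \code{best_k}, \code{metrics} (data frame: k,
#'   silhouette, dbi, tot_withinss) and \code{results} (the per-k
#'   \code{cluster_result}s, named by k).
#' @export
select_k <- function(embedding, k_min = 2L, k_max = 8L, seed = 1L,
                     restarts = 10L) {
  pts <- embedding_points(embedding)
  if (k_max > nrow(pts)) stop_("k_max exceeds the number of samples")
  if (k_min < 2L || k_min > k_max) stop_("need 2 <= k_min <= k_max")
  ks <- k_min:k_max
  results <- lapply(ks, function(k)
    kmeans_cluster(embedding, k, seed = seed, restarts = restarts))
  names(results) <- ks
  metrics <- data.frame(
    k = ks,
    silhouette = vapply(results, `[[`, 0, "silhouette"),
    dbi = vapply(results, `[[`, 0, "dbi"),
    tot_withinss = vapply(results, `[[`, 0, "tot_withinss"),
    row.names = NULL)
  list(best_k = ks[which.max(metrics$silhouette)], metrics = metrics,
       results = results)
}

#' Benchmark clustering strategies on one dataset
#'
#' Runs each requested method at a fixed k and reports silhouette and
#' Davies-Bouldin computed on the representation that was clustered, plus
#' the adjusted Rand index against \code{true_labels} when available.
#' Methods: \code{kmeans} and \code{hierarchical} (average-linkage
#' agglomerative, cut at k) on the concatenated features; \code{pca_kmeans},
#' \code{kpca_kmeans}, \code{ae_kmeans} and \code{dae_kmeans} on the
#' respective d-dimensional reductions.
#'
#' @param dataset A preprocessed \code{multiomics_dataset} (or matrix).
#' @param methods Character vector of method names (see above).
#' @param k Number of clusters (default 2).
#' @param seed Integer seed shared by every stochastic stage.
#' @param d Reduction dimension for PCA/KPCA (default: the autoencoder
#'   bottleneck).
#' @param config \code{\link{dae_config}} for the AE/DAE methods (its seed
#'   is replaced by \code{seed}).
#' @param true_labels Optional reference partition for the ARI column.
#' @param linkage Agglomeration method for hierarchical clustering.
#' @return Data frame: method, silhouette, dbi (and ari), one row per
#'   requested method.
#' @export
compare_methods <- function(dataset,
                            methods = c("kmeans", "hierarchical",
                                        "pca_kmeans", "kpca_kmeans",
                                        "ae_kmeans", "dae_kmeans"),
                            k = 2L, seed = 1L, d = NULL,
                            config = dae_config(), true_labels = NULL,
                            linkage = "average") {
  x <- as_input_matrix(dataset)
  known <- c("kmeans", "hierarchical", "pca_kmeans", "kpca_kmeans",
             "ae_kmeans", "dae_kmeans")
  bad <- setdiff(methods, known)
  if (length(bad)) stop_("unknown method(s): %s", paste(bad, collapse = ", "))
  config$seed <- as.integer(seed)
  d <- d %||% config$hidden_sizes[(length(config$hidden_sizes) + 1L) %/% 2L]
  one <- function(method) {
    if (method == "hierarchical") {
      labels <- stats::cutree(stats::hclust(stats::dist(x), method = linkage), k)
      pts <- x
    } else {
      pts <- switch(method,
        kmeans = x,
        pca_kmeans = pca_reduce(x, d)$coordinates,
        kpca_kmeans = kpca_reduce(x, d)$coordinates,
        ae_kmeans = embed_samples(fit_ae(x, config), x)$coordinates,
        dae_kmeans = embed_samples(fit_dae(x, config), x)$coordinates)
      labels <- kmeans_cluster(pts, k, seed = seed, method_name = method)$labels
    }
    out <- data.frame(method = method,
                      silhouette = silhouette_score(pts, labels),
                      dbi = davies_bouldin(pts, labels))
    if (!is.null(true_labels))
      out$ari <- mclust::adjustedRandIndex(labels, true_labels)
    out
  }
  do.call(rbind, lapply(methods, one))
}
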