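two_pairs_1d <- matrix(c(0, 0.1, 10, 10.1), ncol = 1,
                       dimnames = list(paste0("s", 1:4), "z1"))

test_that("k-means recovers separated blobs and respects its contracts", {
  cl <- kmeans_cluster(two_pairs_1d, 2, seed = 1)
  expect_equal(mclust::adjustedRandIndex(cl$labels, c(1, 1, 2, 2)), 1)

  ## k = n: every point its own cluster, zero within-cluster SS
  set.seed(2)
  pts <- matrix(rnorm(20), 10, 2, dimnames = list(paste0("s", 1:10), NULL))
  cln <- kmeans_cluster(pts, 10, seed = 2)
  expect_equal(cln$tot_withinss, 0, tolerance = 1e-12)
  expect_equal(sort(unique(cln$labels)), 1:10)

  expect_error(kmeans_cluster(pts, 11, seed = 1), "exceeds")
  expect_error(kmeans_cluster(pts, 1, seed = 1), "k must be")

  ## objective no worse than 50 random label assignments
  set.seed(3)
  pts2 <- matrix(rnorm(80), 40, 2)
  rownames(pts2) <- paste0("s", 1:40)
  fit <- kmeans_cluster(pts2, 3, seed = 3)
  wss_of <- function(lab) {
    sum(vapply(unique(lab), function(c) {
      p <- pts2[lab == c, , drop = FALSE]
      sum(sweep(p, 2, colMeans(p))^2)
    }, 0))
  }
  rand_wss <- vapply(1:50, function(i) {
    lab <- sample(1:3, 40, replace = TRUE)
    while (length(unique(lab)) < 3) lab <- sample(1:3, 40, replace = TRUE)
    wss_of(lab)
  }, 0)
  expect_lte(fit$tot_withinss, min(rand_wss) + 1e-9)
  ## determinism
  expect_identical(fit$labels, kmeans_cluster(pts2, 3, seed = 3)$labels)
})

test_that("silhouette matches hand derivation and brute force", {
  ## two tight 1-D pairs: a = 0.1 everywhere; b alternates between 10.05
  ## (outer points) and 9.95 (inner points), giving mean
  ## (199/201 + 197/199) / 2
  expect_equal(silhouette_score(two_pairs_1d, c(1, 1, 2, 2)),
               (199 / 201 + 197 / 199) / 2, tolerance = 1e-9)
  expect_equal(silhouette_score(two_pairs_1d, c(1, 1, 2, 2)),
               brute_silhouette(two_pairs_1d, c(1, 1, 2, 2)), tolerance = 1e-12)
  ## all-identical points: 0/0 -> 0 convention
  same <- matrix(1, 6, 2)
  expect_equal(silhouette_score(same, rep(1:2, 3)), 0)
  ## singleton clusters contribute 0
  pts <- matrix(c(0, 0.1, 50), ncol = 1)
  s_singleton <- silhouette_score(pts, c(1, 1, 2))
  expect_equal(s_singleton, brute_silhouette(pts, c(1, 1, 2)), tolerance = 1e-12)
  expect_error(silhouette_score(pts, c(1, 1, 1)), "single cluster")

  set.seed(4)
  for (i in 1:10) {
    p <- matrix(rnorm(60), 30, 2)
    lab <- sample(1:3, 30, replace = TRUE)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_score(p, lab), brute_silhouette(p, lab),
                 tolerance = 1e-9)
  }
})

test_that("Davies-Bouldin matches the closed form and brute force", {
  expect_equal(davies_bouldin(two_pairs_1d, c(1, 1, 2, 2)), 0.01,
               tolerance = 1e-9)
  ## translation invariance
  set.seed(5)
  p <- matrix(rnorm(60), 30, 2)
  lab <- rep(1:3, each = 10)
  expect_equal(davies_bouldin(p, lab), davies_bouldin(p + 1000, lab),
               tolerance = 1e-9)
  for (i in 1:10) {
    p <- matrix(rnorm(60), 30, 2)
    lab <- sample(1:3, 30, replace = TRUE)
    if (min(table(lab)) < 1 || length(unique(lab)) < 2) next
    expect_equal(davies_bouldin(p, lab), brute_dbi(p, lab), tolerance = 1e-9)
  }
  ## coincident centroids blow up to +Inf rather than erroring
  dupc <- rbind(matrix(0, 4, 2), matrix(0, 4, 2))
  expect_equal(davies_bouldin(dupc, rep(1:2, each = 4)), Inf)
})

test_that("metrics are invariant to label permutation and rigid motion", {
  set.seed(6)
  p <- matrix(rnorm(80), 40, 2)
  lab <- sample(1:4, 40, replace = TRUE)
  perm <- c(3, 1, 4, 2)[lab]
  expect_equal(silhouette_score(p, lab), silhouette_score(p, perm),
               tolerance = 1e-12)
  expect_equal(davies_bouldin(p, lab), davies_bouldin(p, perm),
               tolerance = 1e-12)
  th <- 0.7
  rot <- p %*% matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  expect_equal(silhouette_score(p, lab), silhouette_score(rot, lab),
               tolerance = 1e-9)
  expect_equal(davies_bouldin(p, lab), davies_bouldin(rot + 5, lab),
               tolerance = 1e-9)
})

test_that("silhouette-based selection finds the planted cluster count", {
  blob <- function(center, n, seed) {
    set.seed(seed)
    sweep(matrix(rnorm(n * 2, sd = 0.2), n, 2), 2, center, "+")
  }
  two <- rbind(blob(c(0, 0), 30, 7), blob(c(5, 5), 30, 8))
  rownames(two) <- paste0("s", 1:60)
  sel2 <- select_k(two, 2, 6, seed = 1)
  expect_equal(sel2$best_k, 2L)
  expect_equal(nrow(sel2$metrics), 5L)

  three <- rbind(blob(c(0, 0), 20, 9), blob(c(6, 0), 20, 10),
                 blob(c(3, 6), 20, 11))
  rownames(three) <- paste0("s", 1:60)
  sel3 <- select_k(three, 2, 8, seed = 1)
  expect_equal(sel3$best_k, 3L)
  expect_equal(nrow(sel3$metrics), 7L)
  ## deterministic given seed
  expect_equal(select_k(three, 2, 8, seed = 1)$metrics, sel3$metrics)
})

test_that("the method comparison table covers requested methods with metrics", {
  ## noiseless, far-separated blobs: every method should nail the truth
  sim <- simulate_multiomics(sim_config(
    n_samples = 80L,
    block_specs = list(mrna = list(n_features = 40L, n_informative = 20L)),
    effect_size = 8, noise_sd = 0.3, missing_rate = 0, seed = 15))
  ds <- assemble(lapply(sim$dataset$blocks, preprocess_block),
                 sim$dataset$clinical)
  cfg <- dae_config(hidden_sizes = c(16L, 2L, 16L), epochs = 30L,
                    batch_size = 32L)
  methods <- c("kmeans", "hierarchical", "pca_kmeans", "dae_kmeans")
  tab <- compare_methods(ds, methods = methods, k = 2, seed = 15,
                         config = cfg, true_labels = sim$truth$labels)
  expect_identical(tab$method, methods)
  expect_true(all(tab$ari == 1))
  expect_true(all(tab$silhouette >= -1 & tab$silhouette <= 1))
  expect_true(all(tab$dbi >= 0))
  expect_error(compare_methods(ds, methods = "florble"), "unknown method")
})
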