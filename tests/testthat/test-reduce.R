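tiny_cfg <- function(...) {
  dae_config(hidden_sizes = c(16L, 2L, 16L), epochs = 15L, batch_size = 32L, ...)
}

## Easy, well-separated single-block cohort used in several tests.
easy_dataset <- function(n = 300, p = 200, seed = 1) {
  sim <- simulate_multiomics(sim_config(
    n_samples = n,
    block_specs = list(mrna = list(n_features = p, n_informative = as.integer(p / 10))),
    effect_size = 3, noise_sd = 1, missing_rate = 0, seed = seed))
  list(ds = assemble(lapply(sim$dataset$blocks, preprocess_block),
                     sim$dataset$clinical),
       truth = sim$truth$labels)
}

test_that("corruption is pure, bounded and distribution-correct", {
  set.seed(1)
  x <- matrix(rnorm(100 * 100), 100, 100)
  expect_identical(corrupt(x, 0, "masking"), x)
  expect_identical(corrupt(x, 0, "gaussian"), x)
  expect_true(all(corrupt(x, 1, "masking") == 0))
  ## masked fraction within the 99.9% binomial CI of the rate
  set.seed(2)
  xc <- corrupt(x, 0.5, "masking")
  frac <- mean(xc == 0)
  expect_lt(abs(frac - 0.5), 3.29 * sqrt(0.25 / length(x)))
  expect_error(corrupt(x, 1.5, "masking"), "rate")
  ## gaussian corruption perturbs every cell but preserves scale order
  set.seed(3)
  xg <- corrupt(x, 0.1, "gaussian")
  expect_equal(dim(xg), dim(x))
  expect_gt(cor(as.vector(xg), as.vector(x)), 0.99)
})

test_that("reconstruction loss is the mean per-sample squared L2 norm", {
  expect_equal(reconstruction_loss(diag(3), diag(3)), 0)
  expect_equal(reconstruction_loss(matrix(c(1, 2), 1), matrix(c(0, 0), 1)), 5)
  set.seed(4)
  x <- matrix(rnorm(210), 30, 7)
  xp <- matrix(rnorm(210), 30, 7)
  expect_equal(reconstruction_loss(x, xp), brute_reconstruction_loss(x, xp),
               tolerance = 1e-9)
  expect_error(reconstruction_loss(x, xp[, 1:3]), "dimension mismatch")
})

test_that("zero corruption makes DAE training identical to AE training", {
  set.seed(5)
  x <- matrix(runif(80 * 20, -1, 1), 80, 20,
              dimnames = list(sprintf("s%02d", 1:80), sprintf("f%02d", 1:20)))
  cfg <- tiny_cfg(corruption_rate = 0, seed = 99)
  dae <- fit_dae(x, cfg)
  ae <- fit_ae(x, cfg)
  expect_identical(dae$loss_history, ae$loss_history)
  expect_identical(dae$layers, ae$layers)
  ## and with corruption on, the paths genuinely differ
  dae2 <- fit_dae(x, tiny_cfg(corruption_rate = 0.3, seed = 99))
  expect_false(identical(dae2$loss_history, ae$loss_history))
})

test_that("training reduces the loss, is seeded-reproducible, and flags divergence", {
  set.seed(6)
  x <- matrix(runif(100 * 30, -1, 1), 100, 30,
              dimnames = list(sprintf("s%03d", 1:100), sprintf("f%02d", 1:30)))
  cfg <- tiny_cfg(seed = 7)
  m1 <- fit_dae(x, cfg)
  m2 <- fit_dae(x, cfg)
  expect_identical(m1$loss_history, m2$loss_history)  # bit-reproducible
  expect_lt(m1$loss_history[length(m1$loss_history)], m1$loss_history[1])
  ## an all-zero input is perfectly reconstructable by the AE
  z <- matrix(0, 50, 10, dimnames = list(sprintf("s%02d", 1:50),
                                         sprintf("f%02d", 1:10)))
  ma <- fit_ae(z, tiny_cfg(seed = 8))
  expect_lt(ma$loss_history[length(ma$loss_history)], ma$loss_history[1] + 1e-12)
  ## targets far outside representable squared range blow up the loss
  huge <- matrix(1e200, 20, 5, dimnames = list(sprintf("s%02d", 1:20),
                                               sprintf("f%d", 1:5)))
  expect_error(fit_dae(huge, tiny_cfg(seed = 1)), "diverged")
})

test_that("embedding is deterministic, 2-D by default, and a pure function", {
  ez <- easy_dataset(n = 120, p = 60, seed = 3)
  cfg <- dae_config(hidden_sizes = c(32L, 2L, 32L), epochs = 20L, seed = 3)
  model <- fit_dae(ez$ds, cfg)
  emb <- embed_samples(model, ez$ds)
  expect_equal(ncol(emb$coordinates), 2L)
  expect_identical(emb$coordinates, embed_samples(model, ez$ds)$coordinates)
  ## duplicated input rows map to identical coordinates
  x <- ez$ds$x[c(1, 1, 2), ]
  rownames(x) <- c("a", "b", "c")
  dup <- embed_samples(model, x)
  expect_identical(dup$coordinates[1, ], dup$coordinates[2, ],
                   ignore_attr = TRUE)
  expect_error(embed_samples(model, ez$ds$x[, 1:10]), "model feature")
})

test_that("default-architecture bottleneck recovers planted subtypes", {
  ez <- easy_dataset(n = 300, p = 200, seed = 10)
  model <- fit_dae(ez$ds, dae_config(epochs = 30L, seed = 10))
  z <- embed_samples(model, ez$ds)
  cl <- kmeans_cluster(z, 2, seed = 10)
  ari <- mclust::adjustedRandIndex(cl$labels, ez$truth[z$sample_ids])
  expect_gte(ari, 0.9)
})

test_that("denoising at least matches the plain autoencoder on noisy cohorts", {
  ## high-noise regime: doubled noise, 20% missingness then imputation
  wins <- 0L
  for (s in 1:10) {
    sim <- simulate_multiomics(sim_config(noise_sd = 2, missing_rate = 0.2,
                                          seed = s))
    ds <- assemble(lapply(sim$dataset$blocks, preprocess_block),
                   sim$dataset$clinical)
    cfg <- dae_config(seed = s)
    s_dae <- kmeans_cluster(embed_samples(fit_dae(ds, cfg), ds), 2,
                            seed = s)$silhouette
    s_ae <- kmeans_cluster(embed_samples(fit_ae(ds, cfg), ds), 2,
                           seed = s)$silhouette
    wins <- wins + (s_dae >= s_ae)
  }
  expect_gte(wins, 7L)
})

test_that("PCA and kernel PCA baselines behave as linear projections should", {
  ## points exactly on a 3-D line: one component reconstructs them
  t <- seq(-1, 1, length.out = 40)
  line <- cbind(2 * t, -t, 3 * t)
  rownames(line) <- sprintf("s%02d", 1:40)
  p1 <- pca_reduce(line, 1)
  recon_err <- sum((scale(line, scale = FALSE) -
                      p1$coordinates %*% t(prcomp(line)$rotation[, 1, drop = FALSE]))^2)
  expect_lt(recon_err, 1e-18)

  set.seed(11)
  x <- matrix(rnorm(50 * 6), 50, 6, dimnames = list(sprintf("s%02d", 1:50),
                                                    sprintf("f%d", 1:6)))
  pc <- pca_reduce(x, 4)$coordinates
  cv <- unname(cov(pc))
  expect_equal(cv, diag(diag(cv)), tolerance = 1e-10)  # uncorrelated scores
  expect_true(all(diff(diag(cv)) <= 1e-10))            # non-increasing variance

  ## linear-kernel KPCA spans the same directions as PCA
  kp <- kpca_reduce(x, 3, kernel = "vanilladot")$coordinates
  for (j in 1:3)
    expect_equal(abs(cor(kp[, j], pc[, j])), 1, tolerance = 1e-6)
  expect_error(pca_reduce(x, 51), "exceeds")
})

test_that("trained models survive a save/load round-trip", {
  set.seed(12)
  x <- matrix(runif(60 * 10, -1, 1), 60, 10,
              dimnames = list(sprintf("s%02d", 1:60), sprintf("f%02d", 1:10)))
  m <- fit_dae(x, tiny_cfg(seed = 13))
  path <- withr::local_tempfile(fileext = ".rds")
  save_embedding_model(m, path)
  m2 <- load_embedding_model(path)
  expect_identical(embed_samples(m2, x)$coordinates,
                   embed_samples(m, x)$coordinates)
})
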