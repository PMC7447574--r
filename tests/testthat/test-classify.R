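test_that("predicted probabilities follow the logistic closed form, stably", {
  model <- structure(list(intercept = 0,
                          coefficients = c(g1 = 0, g2 = 0),
                          lambda = 1, feature_names = c("g1", "g2"),
                          selected_features = character(0)),
                     class = "sparse_logistic")
  x <- matrix(rnorm(10), 5, 2, dimnames = list(NULL, c("g1", "g2")))
  expect_equal(unname(predict_proba(model, x)), rep(0.5, 5))

  model$intercept <- log(3)
  expect_equal(unname(predict_proba(model, x)), rep(0.75, 5), tolerance = 1e-12)

  ## huge linear predictor saturates without overflow
  model$coefficients <- c(g1 = 1000, g2 = 0)
  x1 <- matrix(c(1, 0), 1, 2, dimnames = list(NULL, c("g1", "g2")))
  expect_equal(unname(predict_proba(model, x1)), 1)
  x2 <- matrix(c(-1, 0), 1, 2, dimnames = list(NULL, c("g1", "g2")))
  expect_equal(unname(predict_proba(model, x2)), 0)  # saturates, no NaN

  ## probabilities always in (0,1); column order does not matter
  co <- make_cohort(seed = 2)
  fit <- fit_l1_logistic(co$x, co$y, lambda = 1)
  p <- predict_proba(fit, co$x)
  expect_true(all(p > 0 & p < 1))
  expect_equal(predict_proba(fit, co$x[, rev(colnames(co$x))]), p)
  expect_error(predict_proba(fit, co$x[, 1:2]), "lacks")
})

test_that("an overwhelming penalty leaves only the prevalence intercept", {
  set.seed(3)
  n <- 80
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("g", 1:4)))
  y <- rep(c(1, 0), times = c(60, 20))  # 75% positive
  fit <- fit_l1_logistic(x, y, lambda = 1e6)
  expect_true(all(fit$coefficients == 0))
  expect_length(fit$selected_features, 0)
  expect_equal(fit$intercept, log(0.75 / 0.25), tolerance = 1e-4)
  expect_error(fit_l1_logistic(x, rep(1, n), 1), "degenerate")
})

test_that("the fitted optimum beats random search and matches grid search", {
  ## 20 samples, 2 features standardized to mean 0 / population sd 1 so the
  ## fitter's internal standardization is the identity and the raw-scale
  ## objective is the one optimized
  set.seed(4)
  n <- 20
  x <- matrix(rnorm(n * 2), n, 2)
  x <- sweep(x, 2, colMeans(x))
  x <- sweep(x, 2, sqrt(colMeans(x^2)), "/")
  colnames(x) <- c("g1", "g2")
  y <- rbinom(n, 1, plogis(1.5 * x[, 1] - x[, 2]))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  lambda <- 2
  fit <- fit_l1_logistic(x, y, lambda)
  obj_fit <- logistic_objective(fit$intercept, fit$coefficients, x, y, lambda)

  ## 10,000 random draws never beat the optimum
  set.seed(5)
  draws <- matrix(runif(30000, -4, 4), ncol = 3)
  obj_rand <- apply(draws, 1, function(d)
    logistic_objective(d[1], d[2:3], x, y, lambda))
  expect_gte(obj_fit, max(obj_rand))

  ## fine 2-D grid with the intercept profiled out per grid point
  grid <- seq(-2, 2, by = 0.05)
  best_grid <- -Inf
  for (b1 in grid) {
    for (b2 in grid) {
      prof <- optimize(function(b0)
        logistic_objective(b0, c(b1, b2), x, y, lambda),
        interval = c(-5, 5), maximum = TRUE, tol = 1e-10)
      if (prof$objective > best_grid) best_grid <- prof$objective
    }
  }
  expect_equal(obj_fit, best_grid, tolerance = 1e-3)
})

test_that("sparsity is monotone along the penalty path", {
  co <- make_cohort(n = 100, p_noise = 8, seed = 6)
  nz <- vapply(c(0.01, 0.5, 2, 10, 50),
               function(l) length(fit_l1_logistic(co$x, co$y, l)$selected_features),
               0L)
  expect_true(all(diff(nz) <= 0))
})

test_that("cross-validated penalty selection is sound and deterministic", {
  expect_equal(select_lambda(make_cohort(seed = 7)$x, make_cohort(seed = 7)$y,
                             grid = 3)$lambda, 3)
  co <- make_cohort(n = 150, p_noise = 10, beta = c(3, -3), seed = 8)
  sel <- select_lambda(co$x, co$y, grid = c(0.1, 1, 5, 20), seed = 1)
  expect_identical(sel$lambda,
                   select_lambda(co$x, co$y, grid = c(0.1, 1, 5, 20),
                                 seed = 1)$lambda)
  ## the selected model separates a strongly informative cohort
  fit <- fit_l1_logistic(co$x, co$y, sel$lambda)
  acc <- mean((predict_proba(fit, co$x) >= 0.5) == co$y)
  expect_gte(acc, 0.9)
})

test_that("transfer evaluation guards its feature and group contracts", {
  co <- make_cohort(n = 100, seed = 9)
  fit <- fit_l1_logistic(co$x, co$y, lambda = 1)
  clin <- simulate_survival(co$y, 0.1, 3, 0.04, seed = 9)$clinical
  rownames(co$x) <- clin$sample_id

  res <- transfer_evaluate(fit, co$x, clin)
  expect_true(res$p_value >= 0 && res$p_value <= 1)
  expect_setequal(unique(res$risk_group), 0:1)

  ## missing selected features are a hard error, not a zero-fill
  drop1 <- setdiff(colnames(co$x), fit$selected_features[1])
  expect_error(transfer_evaluate(fit, co$x[, drop1], clin), "lacks")
  unrelated <- matrix(rnorm(100), 100, 1,
                      dimnames = list(rownames(co$x), "other_gene"))
  expect_error(transfer_evaluate(fit, unrelated, clin), "no overlap")

  ## all-identical predictions surface the undefined log-rank cleanly
  allzero <- fit
  allzero$coefficients[] <- 0
  allzero$selected_features <- fit$selected_features
  allzero$intercept <- 5
  expect_error(transfer_evaluate(allzero, co$x, clin), "one group")
})

test_that("models round-trip through the plain-text format", {
  co <- make_cohort(seed = 10)
  fit <- fit_l1_logistic(co$x, co$y, lambda = 0.5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sparse_logistic(fit, path)
  back <- read_sparse_logistic(path)
  expect_equal(back$intercept, fit$intercept)
  expect_equal(back$coefficients, fit$coefficients)
  expect_identical(back$selected_features, fit$selected_features)
  expect_equal(predict_proba(back, co$x), predict_proba(fit, co$x))
})
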