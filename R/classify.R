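#' Fit an L1-penalized logistic classifier
#'
#' Maximizes the penalized binomial log-likelihood
#' \deqn{\sum_i \{ y_i \ln p_i + (1 - y_i) \ln(1 - p_i) \} - \lambda \|\beta\|_1}
#' with an unpenalized intercept, where
#' \eqn{p_i = \mathrm{logit}^{-1}(\beta_0 + \beta x_i)}. The L1 penalty
#' drives coefficients exactly to zero, yielding a sparse ("light-weight")
#' gene signature. Features are standardized inside the fitter and the
#' coefficients back-transformed, so \eqn{\lambda} is scale-free.
#' Optimization uses \pkg{glmnet} coordinate descent (the objective above
#' equals \code{n} times glmnet's, so \code{lambda/n} is passed through)
#' with convergence threshold 1e-12; the fit is deterministic.
#'
#' @param x Numeric matrix (samples x features, named columns) or an
#'   \code{omics_matrix}.
#' @param y 0/1 labels (e.g. risk groups: Low = 0, High = 1); both classes
#'   must be present.
#' @param lambda Penalty weight on the summed-log-likelihood scale, >= 0.
#' @return A \code{sparse_logistic}: \code{intercept}, named
#'   \code{coefficients}, \code{lambda}, \code{feature_names},
#'   \code{selected_features} (names with nonzero coefficient).
#' @export
fit_l1_logistic <- function(x, y, lambda) {
  if (inherits(x, "omics_matrix")) x <- x$values
  if (!is.matrix(x) || is.null(colnames(x)))
    stop_("'x' must be a matrix with feature names")
  if (length(y) != nrow(x)) stop_("length(y) != nrow(x)")
  if (!all(y %in% c(0, 1))) stop_("labels must be 0/1")
  if (length(unique(y)) < 2L)
    stop_("degenerate labels: both classes must be present")
  if (lambda < 0) stop_("'lambda' must be >= 0")
  n <- nrow(x)
  lam <- lambda / n
  ## descend a short warm-start path ending at the requested lambda
  path <- sort(unique(c(lam * c(100, 10, 2), lam)), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                        lambda = path, standardize = TRUE,
                        thresh = 1e-12, maxit = 1e6)
  beta <- as.numeric(stats::coef(fit, s = lam))  # lam is on the path: exact
  names(beta) <- c("(Intercept)", colnames(x))
  coefs <- beta[-1L]
  structure(list(intercept = unname(beta[1L]),
                 coefficients = coefs,
                 lambda = lambda,
                 feature_names = colnames(x),
                 selected_features = names(coefs)[coefs != 0]),
            class = "sparse_logistic")
}

#' @export
print.sparse_logistic <- function(x, ...) {
  cat(sprintf("sparse_logistic: %d/%d features selected (lambda = %g), intercept %.4f\n",
              length(x$selected_features), length(x$feature_names),
              x$lambda, x$intercept))
  invisible(x)
}

#' Predicted probability of the high-risk class
#'
#' \eqn{p(y = 1) = \exp(\beta_0 + \beta x) / (1 + \exp(\beta_0 + \beta x))},
#' evaluated with the numerically stable \code{plogis}, so extreme linear
#' predictors saturate without overflow. Features are aligned by name;
#' model features absent from \code{x} are an error (no silent zero-fill),
#' extra columns in \code{x} are ignored.
#'
#' @param model A \code{sparse_logistic}.
#' @param x Matrix with named columns, or \code{omics_matrix}.
#' @return Probability per sample, named by row when available.
#' @export
predict_proba <- function(model, x) {
  stopifnot(inherits(model, "sparse_logistic"))
  if (inherits(x, "omics_matrix")) x <- x$values
  if (is.null(colnames(x))) {
    if (ncol(x) != length(model$feature_names))
      stop_("unnamed input has %d features; model expects %d",
            ncol(x), length(model$feature_names))
    colnames(x) <- model$feature_names
  }
  miss <- setdiff(model$feature_names, colnames(x))
  if (length(miss))
    stop_("input lacks %d model feature(s): %s", length(miss),
          paste(utils::head(miss, 10L), collapse = ", "))
  eta <- model$intercept +
    drop(x[, model$feature_names, drop = FALSE] %*% model$coefficients)
  stats::plogis(eta)
}

#' Cross-validated penalty selection
#'
#' Selects \eqn{\lambda} from a grid by 5-fold (default) stratified
#' cross-validation, maximizing the mean held-out log-likelihood; ties go
#' to the larger \eqn{\lambda} (the sparser model). Folds are stratified
#' by class so every training fold sees both labels. Deterministic for a
#' fixed seed.
#'
#' @inheritParams fit_l1_logistic
#' @param grid Candidate penalties (non-empty, >= 0).
#' @param folds Number of CV folds.
#' @param seed Integer seed for the fold assignment.
#' @return List with \code{lambda} (the choice), and \code{cv} (data
#'   frame: lambda, mean held-out log-likelihood).
#' @export
select_lambda <- function(x, y, grid, folds = 5L, seed = 1L) {
  if (inherits(x, "omics_matrix")) x <- x$values
  if (!length(grid)) stop_("empty lambda grid")
  if (any(grid < 0)) stop_("lambda grid must be >= 0")
  if (length(unique(y)) < 2L) stop_("both classes required")
  fold_id <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  holdout_ll <- function(lambda) {
    mean(vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      m <- fit_l1_logistic(x[tr, , drop = FALSE], y[tr], lambda)
      p <- pmin(pmax(predict_proba(m, x[!tr, , drop = FALSE]), 1e-12), 1 - 1e-12)
      sum(y[!tr] * log(p) + (1 - y[!tr]) * log(1 - p))
    }, 0))
  }
  grid <- sort(unique(grid))
  ll <- vapply(grid, holdout_ll, 0)
  best <- max(grid[ll == max(ll)])  # ties -> sparser model
  list(lambda = best, cv = data.frame(lambda = grid, mean_loglik = ll))
}

#' Transfer subtypes to an external expression cohort
#'
#' Applies a trained classifier to an independent cohort: samples with
#' predicted probability >= 0.5 are called High risk, the rest Low, and
#' the two predicted groups are compared with the log-rank test. All the
#' model's selected (nonzero) features must be present in the cohort;
#' missing ones raise an error rather than being zero-filled.
#'
#' @param model A \code{sparse_logistic}.
#' @param x External expression matrix (named columns) or
#'   \code{omics_matrix}.
#' @param clinical Clinical data frame (sample_id, time, event) covering
#'   the cohort rows (matched by row name when present, else by order).
#' @param threshold Classification cut-off on the probability scale.
#' @return List with \code{risk_group} (0/1 per sample),
#'   \code{probability}, \code{statistic} and \code{p_value} of the
#'   log-rank comparison between predicted groups.
#' @export
transfer_evaluate <- function(model, x, clinical, threshold = 0.5) {
  stopifnot(inherits(model, "sparse_logistic"))
  if (inherits(x, "omics_matrix")) x <- x$values
  sel <- model$selected_features
  if (!length(intersect(sel, colnames(x))))
    stop_("no overlap between the model's selected features and the cohort")
  miss <- setdiff(sel, colnames(x))
  if (length(miss))
    stop_("cohort lacks %d selected feature(s): %s", length(miss),
          paste(utils::head(miss, 10L), collapse = ", "))
  ## reduce to the selected signature; dropped zero-coefficient features
  ## contribute nothing to the linear predictor
  reduced <- model
  reduced$coefficients <- model$coefficients[sel]
  reduced$feature_names <- sel
  p <- predict_proba(reduced, x[, sel, drop = FALSE])
  grp <- as.integer(p >= threshold)
  validate_clinical(clinical)
  ids <- rownames(x)
  cl <- if (!is.null(ids)) {
    idx <- match(ids, clinical$sample_id)
    if (anyNA(idx)) stop_("clinical table does not cover all cohort samples")
    clinical[idx, ]
  } else {
    if (nrow(clinical) != nrow(x))
      stop_("clinical rows (%d) do not match cohort rows (%d)",
            nrow(clinical), nrow(x))
    clinical
  }
  if (length(unique(grp)) < 2L)
    stop_("all samples predicted into one group; log-rank test undefined")
  lr <- logrank_test(cl$time, cl$event, grp)
  list(risk_group = stats::setNames(grp, ids),
       probability = stats::setNames(p, ids),
       statistic = lr$statistic, p_value = lr$p_value)
}

#' Read or write a sparse logistic model as plain text
#'
#' Tab-separated table (feature, coefficient) preceded by header comment
#' lines carrying the intercept and penalty.
#'
#' @param model A \code{sparse_logistic}.
#' @param path File path.
#' @export
write_sparse_logistic <- function(model, path) {
  stopifnot(inherits(model, "sparse_logistic"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# intercept\t%.17g", model$intercept),
               sprintf("# lambda\t%.17g", model$lambda),
               "feature\tcoefficient"), con)
  writeLines(sprintf("%s\t%.17g", model$feature_names, model$coefficients), con)
  invisible(path)
}

#' @rdname write_sparse_logistic
#' @export
read_sparse_logistic <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(lines[1:2], "\t", fixed = TRUE)
  tab <- utils::read.table(text = lines[-(1:2)], header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  coefs <- stats::setNames(tab$coefficient, tab$feature)
  structure(list(intercept = as.numeric(hdr[[1]][2]),
                 coefficients = coefs,
                 lambda = as.numeric(hdr[[2]][2]),
                 feature_names = tab$feature,
                 selected_features = tab$feature[coefs != 0]),
            class = "sparse_logistic")
}
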