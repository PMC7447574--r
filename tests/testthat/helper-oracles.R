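## Independent brute-force oracles. Deliberately written as plain loops over
## definitions, sharing no code with the package implementations they check.

brute_silhouette <- function(pts, labels) {
  pts <- as.matrix(pts)
  n <- nrow(pts)
  d <- function(i, j) sqrt(sum((pts[i, ] - pts[j, ])^2))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(vapply(own, d, 0, i = i))
    b <- Inf
    for (cl in setdiff(unique(labels), labels[i])) {
      other <- which(labels == cl)
      b <- min(b, mean(vapply(other, d, 0, i = i)))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

brute_dbi <- function(pts, labels) {
  pts <- as.matrix(pts)
  cls <- sort(unique(labels))
  cent <- lapply(cls, function(c) colMeans(pts[labels == c, , drop = FALSE]))
  scat <- vapply(seq_along(cls), function(ci) {
    rows <- which(labels == cls[ci])
    mean(vapply(rows, function(i) sqrt(sum((pts[i, ] - cent[[ci]])^2)), 0))
  }, 0)
  worst <- vapply(seq_along(cls), function(i) {
    r <- -Inf
    for (j in seq_along(cls)) {
      if (j == i) next
      m <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      r <- max(r, (scat[i] + scat[j]) / m)
    }
    r
  }, 0)
  mean(worst)
}

## Product-limit estimator from first principles: at each distinct event
## time, multiply by (1 - deaths / at-risk). Events precede censorings.
brute_km <- function(times, events) {
  ev_times <- sort(unique(times[events == 1]))
  surv <- numeric(length(ev_times))
  s <- 1
  for (i in seq_along(ev_times)) {
    t <- ev_times[i]
    at_risk <- sum(times >= t)
    deaths <- sum(times == t & events == 1)
    s <- s * (1 - deaths / at_risk)
    surv[i] <- s
  }
  data.frame(time = ev_times, survival = surv)
}

## Two-group log-rank from the risk-table definition: O, E and the
## hypergeometric variance accumulated over distinct event times.
brute_logrank <- function(times, events, groups) {
  g <- as.integer(factor(groups)) - 1L
  OE <- 0
  V <- 0
  for (t in sort(unique(times[events == 1]))) {
    n_t <- sum(times >= t)
    n1_t <- sum(times >= t & g == 1)
    d_t <- sum(times == t & events == 1)
    d1_t <- sum(times == t & events == 1 & g == 1)
    OE <- OE + d1_t - d_t * n1_t / n_t
    if (n_t > 1)
      V <- V + d_t * (n1_t / n_t) * (1 - n1_t / n_t) * (n_t - d_t) / (n_t - 1)
  }
  stat <- OE^2 / V
  list(statistic = stat, p_value = pchisq(stat, 1, lower.tail = FALSE))
}

brute_reconstruction_loss <- function(x, xp) {
  total <- 0
  for (i in seq_len(nrow(x)))
    for (j in seq_len(ncol(x)))
      total <- total + (x[i, j] - xp[i, j])^2
  total / nrow(x)
}

## Binomial log-likelihood of a logistic model, raw scale (for oracles).
logistic_objective <- function(b0, b, x, y, lambda) {
  eta <- b0 + drop(x %*% b)
  sum(y * eta - log1p(exp(eta))) - lambda * sum(abs(b))
}

## Small helpers ---------------------------------------------------------

rand_omics <- function(n, p, name = "omx", missing = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", seq_len(n)),
                              sprintf("f%03d", seq_len(p))))
  if (missing > 0) v[matrix(runif(n * p) < missing, n, p)] <- NA
  omics_matrix(v, name)
}

## Tiny labeled cohort for classifier tests: two informative standardized
## features plus noise columns.
make_cohort <- function(n = 60, p_noise = 3, beta = c(2, -2), seed = 1) {
  set.seed(seed)
  p <- length(beta) + p_noise
  x <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%03d", 1:n), sprintf("g%02d", 1:p)))
  eta <- drop(x[, seq_along(beta), drop = FALSE] %*% beta)
  y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = y)
}
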