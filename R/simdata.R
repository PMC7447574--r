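#' Configuration for the synthetic multi-omics generator
#'
#' Defines a two-subtype cohort: several Gaussian omics blocks sharing one
#' latent subtype, a shift of size \code{effect_size} on each block's
#' informative features, MCAR missingness, and subtype-dependent exponential
#' survival with independent exponential censoring.
#'
#' The defaults describe the cohort used throughout the package's own
#' validation: 300 samples, three blocks of 200/60/120 features with
#' 20/6/12 informative each, a mean shift of 3 against unit noise, 10\%
#' missingness, a survival hazard ratio of 3 between subtypes
#' (baseline hazard 0.1), and a censoring rate of 0.04, which yields about
#' 20\% censored observations at these hazards.
#'
#' @param n_samples Number of samples.
#' @param block_specs Named list; one element per block, each a list with
#'   \code{n_features} and \code{n_informative}.
#' @param effect_size Mean shift \eqn{\delta} between subtypes on
#'   informative features (subtype 0 centered at \eqn{-\delta/2}, subtype 1
#'   at \eqn{+\delta/2}).
#' @param noise_sd Gaussian noise standard deviation (> 0).
#' @param missing_rate MCAR missingness probability per cell, in [0, 1).
#' @param subtype_proportion Fraction of samples in subtype 1, in (0, 1).
#' @param baseline_hazard Exponential event rate for subtype 0 (> 0).
#' @param hazard_ratio Multiplicative hazard for subtype 1 (> 0).
#' @param censoring_rate Rate of the independent exponential censoring
#'   process; 0 disables censoring.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_samples = 300L,
                       block_specs = list(
                         mrna  = list(n_features = 200L, n_informative = 20L),
                         mirna = list(n_features = 60L,  n_informative = 6L),
                         cnv   = list(n_features = 120L, n_informative = 12L)),
                       effect_size = 3,
                       noise_sd = 1,
                       missing_rate = 0.1,
                       subtype_proportion = 0.5,
                       baseline_hazard = 0.1,
                       hazard_ratio = 3,
                       censoring_rate = 0.04,
                       seed = 1L) {
  if (n_samples < 2L) stop_("need at least 2 samples")
  if (is.null(names(block_specs)) || any(!nzchar(names(block_specs))))
    stop_("'block_specs' must be a named list")
  for (nm in names(block_specs)) {
    bs <- block_specs[[nm]]
    if (is.null(bs$n_features) || is.null(bs$n_informative) ||
        bs$n_informative > bs$n_features || bs$n_features < 1L)
      stop_("block '%s': need n_informative <= n_features >= 1", nm)
  }
  if (noise_sd <= 0) stop_("'noise_sd' must be > 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop_("'missing_rate' must be in [0, 1)")
  if (subtype_proportion <= 0 || subtype_proportion >= 1)
    stop_("'subtype_proportion' must be in (0, 1)")
  if (baseline_hazard <= 0) stop_("'baseline_hazard' must be > 0")
  if (hazard_ratio <= 0) stop_("'hazard_ratio' must be > 0")
  if (censoring_rate < 0) stop_("'censoring_rate' must be >= 0")
  structure(list(n_samples = as.integer(n_samples), block_specs = block_specs,
                 effect_size = effect_size, noise_sd = noise_sd,
                 missing_rate = missing_rate,
                 subtype_proportion = subtype_proportion,
                 baseline_hazard = baseline_hazard, hazard_ratio = hazard_ratio,
                 censoring_rate = censoring_rate, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a multi-omics cohort with known subtypes and survival
#'
#' Subtype labels are assigned deterministically (the first
#' \code{ceiling(n * subtype_proportion)} samples get label 1) and then
#' shuffled with the seeded generator, so label counts are exact. Within
#' each block, informative features are drawn
#' \eqn{N(\pm\delta/2, noise\_sd)} by subtype and the remaining features
#' \eqn{N(0, noise\_sd)}. MCAR missingness is applied cell-wise at
#' \code{missing_rate}. Survival follows
#' \code{\link{simulate_survival}} on the true labels.
#'
#' @param config A \code{\link{sim_config}}.
#' @return List with \code{dataset} (a \code{\link{assemble}}d
#'   \code{multiomics_dataset}, missingness still present) and \code{truth}
#'   (list: \code{labels} named 0/1 vector, \code{informative_features} per
#'   block, \code{event_times}, \code{censor_times}).
#' @export
simulate_multiomics <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, {
    n <- config$n_samples
    ids <- sprintf("S%04d", seq_len(n))
    n1 <- ceiling(n * config$subtype_proportion)
    labels <- c(rep(1L, n1), rep(0L, n - n1))[sample.int(n)]
    names(labels) <- ids

    blocks <- vector("list", length(config$block_specs))
    informative <- vector("list", length(config$block_specs))
    names(blocks) <- names(informative) <- names(config$block_specs)
    for (nm in names(config$block_specs)) {
      bs <- config$block_specs[[nm]]
      p <- bs$n_features
      feat <- sprintf("%s_f%04d", nm, seq_len(p))
      mu <- matrix(0, n, p)
      if (bs$n_informative > 0L) {
        shift <- ifelse(labels == 1L, config$effect_size / 2,
                        -config$effect_size / 2)
        mu[, seq_len(bs$n_informative)] <- shift
      }
      v <- mu + matrix(stats::rnorm(n * p, sd = config$noise_sd), n, p)
      if (config$missing_rate > 0) {
        drop <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
        v[drop] <- NA_real_
      }
      dimnames(v) <- list(ids, feat)
      blocks[[nm]] <- omics_matrix(v, nm)
      informative[[nm]] <- feat[seq_len(bs$n_informative)]
    }

    surv <- simulate_survival(labels,
                              baseline_hazard = config$baseline_hazard,
                              hazard_ratio = config$hazard_ratio,
                              censoring_rate = config$censoring_rate,
                              seed = NULL)
    list(dataset = assemble(blocks, surv$clinical),
         truth = list(labels = labels,
                      informative_features = informative,
                      event_times = surv$event_times,
                      censor_times = surv$censor_times))
  })
}

#' Simulate subtype-dependent survival outcomes
#'
#' Event times are exponential with rate \code{baseline_hazard} for label 0
#' and \code{baseline_hazard * hazard_ratio} for label 1; censoring times
#' are independent exponential with rate \code{censoring_rate}. The observed
#' time is the minimum of the two, with the event indicator 1 when the
#' event came first.
#'
#' @param labels 0/1 subtype vector, optionally named by sample ID.
#' @param baseline_hazard,hazard_ratio,censoring_rate See
#'   \code{\link{sim_config}}.
#' @param seed Optional seed; \code{NULL} draws from the current RNG stream.
#' @return List with \code{clinical} (data frame sample_id, time, event),
#'   \code{event_times} and \code{censor_times}.
#' @export
simulate_survival <- function(labels, baseline_hazard = 0.1, hazard_ratio = 3,
                              censoring_rate = 0.04, seed = NULL) {
  if (!all(labels %in% c(0, 1))) stop_("labels must be 0/1")
  if (baseline_hazard <= 0) stop_("'baseline_hazard' must be > 0")
  if (hazard_ratio <= 0) stop_("'hazard_ratio' must be > 0")
  if (censoring_rate < 0) stop_("'censoring_rate' must be >= 0")
  with_seed(seed, {
    n <- length(labels)
    ids <- names(labels) %||% sprintf("S%04d", seq_len(n))
    rate <- baseline_hazard * ifelse(labels == 1, hazard_ratio, 1)
    ev <- stats::rexp(n, rate)
    cs <- if (censoring_rate > 0) stats::rexp(n, censoring_rate) else rep(Inf, n)
    list(clinical = data.frame(sample_id = ids,
                               time = pmin(ev, cs),
                               event = as.integer(ev <= cs),
                               stringsAsFactors = FALSE),
         event_times = ev, censor_times = cs)
  })
}

#' Write a simulated cohort to disk
#'
#' One CSV matrix per block, a clinical CSV, and a \code{truth.csv} sidecar
#' (sample_id, true_label) — the same formats the readers consume.
#'
#' @param sim Result of \code{\link{simulate_multiomics}}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (b in sim$dataset$blocks)
    write_omics_matrix(b, file.path(dir, paste0(b$omics_name, ".csv")))
  write_clinical(sim$dataset$clinical, file.path(dir, "clinical.csv"))
  utils::write.table(
    data.frame(sample_id = names(sim$truth$labels),
               true_label = unname(sim$truth$labels)),
    file.path(dir, "truth.csv"), sep = ",", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
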