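#' Read a pipeline run configuration
#'
#' YAML file with optional sections: \code{simulate} (fields of
#' \code{\link{sim_config}}), \code{data} (\code{blocks}: named block
#' paths, \code{clinical}: clinical path, \code{orientation}),
#' \code{preprocess} (\code{missing_threshold}), \code{dae} (fields of
#' \code{\link{dae_config}}), \code{cluster} (\code{k_min}, \code{k_max}),
#' \code{benchmark} (\code{methods}), \code{classify}
#' (\code{lambda_grid}, \code{block}: which block carries the expression
#' features, default \code{"mrna"}), plus top-level \code{seed} and
#' \code{outdir}. Either \code{simulate} or \code{data} must be present.
#'
#' @param path YAML file path.
#' @return A \code{run_config} list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_("config file not found: %s", path)
  cfg <- yaml::read_yaml(path)
  as_run_config(cfg)
}

#' @rdname read_run_config
#' @param cfg A list with the fields above (e.g. from
#'   \code{yaml::read_yaml} or built in code).
#' @export
as_run_config <- function(cfg) {
  if (is.null(cfg$simulate) && is.null(cfg$data))
    stop_("config needs a 'simulate' or 'data' section")
  cfg$seed <- as.integer(cfg$seed %||% 1L)
  cfg$outdir <- cfg$outdir %||% "subtype_dae_run"
  cfg$preprocess$missing_threshold <- cfg$preprocess$missing_threshold %||% 0.2
  cfg$cluster$k_min <- as.integer(cfg$cluster$k_min %||% 2L)
  cfg$cluster$k_max <- as.integer(cfg$cluster$k_max %||% 8L)
  cfg$classify$block <- cfg$classify$block %||% "mrna"
  cfg$classify$lambda_grid <- cfg$classify$lambda_grid %||% c(0.5, 1, 2, 5, 10, 20)
  structure(cfg, class = "run_config")
}

config_dae <- function(cfg) {
  d <- cfg$dae %||% list()
  dae_config(hidden_sizes = d$hidden_sizes %||% c(200L, 50L, 2L, 50L, 200L),
             learning_rate = d$learning_rate %||% 0.001,
             batch_size = d$batch_size %||% 256L,
             epochs = d$epochs %||% 100L,
             corruption_rate = d$corruption_rate %||% 0.2,
             corruption_kind = d$corruption_kind %||% "masking",
             seed = cfg$seed)
}

config_sim <- function(cfg) {
  s <- cfg$simulate %||% list()
  args <- s[intersect(names(s), names(formals(sim_config)))]
  args$seed <- cfg$seed
  if (!is.null(args$block_specs))
    args$block_specs <- lapply(args$block_specs, function(b)
      list(n_features = as.integer(b$n_features),
           n_informative = as.integer(b$n_informative)))
  do.call(sim_config, args)
}

load_blocks <- function(cfg) {
  orientation <- cfg$data$orientation %||% "samples"
  if (is.null(cfg$data$clinical) || !file.exists(cfg$data$clinical))
    stop_("clinical file missing or not found: %s",
          cfg$data$clinical %||% "<unset>")
  blocks <- lapply(names(cfg$data$blocks), function(nm) {
    path <- cfg$data$blocks[[nm]]
    if (!file.exists(path)) stop_("block '%s': file not found: %s", nm, path)
    read_omics_matrix(path, omics_name = nm, orientation = orientation)
  })
  list(blocks = blocks, clinical = read_clinical(cfg$data$clinical))
}

#' Run the full subtyping pipeline
#'
#' Chains every stage: simulate or ingest the omics blocks, preprocess
#' each block (missingness filter, median imputation, [-1, 1] scaling),
#' assemble, train the denoising autoencoder, embed, select k by
#' silhouette over the configured range, cluster, map clusters to
#' Low/High risk via Kaplan-Meier, run the log-rank test, fit the
#' L1-penalized expression classifier on the risk labels with
#' cross-validated penalty, and — for simulated runs — evaluate the
#' classifier's transfer on an independently generated cohort. All
#' artifacts plus a machine-readable \code{manifest.json} are written
#' under \code{config$outdir}.
#'
#' @param config A \code{run_config} (see \code{\link{read_run_config}}).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the main in-memory results (dataset,
#'   model, embedding, k selection, clustering, risk groups, log-rank,
#'   classifier, optional transfer and benchmark).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  config <- as_run_config(unclass(config))
  say <- function(...) if (!quiet) message(sprintf(...))
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()

  ## -- ingest ------------------------------------------------------------
  truth <- NULL
  if (!is.null(config$simulate)) {
    say("stage simulate: generating synthetic cohort")
    sim <- simulate_multiomics(config_sim(config))
    raw_blocks <- sim$dataset$blocks
    clinical <- sim$dataset$clinical
    truth <- sim$truth
    write_simulation(sim, file.path(outdir, "simulated"))
  } else {
    say("stage ingest: reading %d block(s)", length(config$data$blocks))
    loaded <- load_blocks(config)
    raw_blocks <- loaded$blocks
    clinical <- loaded$clinical
  }

  ## -- preprocess --------------------------------------------------------
  say("stage preprocess: filter/impute/scale per block")
  blocks <- lapply(raw_blocks, preprocess_block,
                   threshold = config$preprocess$missing_threshold)
  dataset <- assemble(blocks, clinical)

  ## -- reduce ------------------------------------------------------------
  dcfg <- config_dae(config)
  say("stage reduce: training DAE (%s) for %d epochs",
      paste(dcfg$hidden_sizes, collapse = "-"), dcfg$epochs)
  model <- fit_dae(dataset, dcfg)
  embedding <- embed_samples(model, dataset)
  write_embedding(embedding, file.path(outdir, "embedding.csv"))
  utils::write.table(
    data.frame(epoch = seq_along(model$loss_history), loss = model$loss_history),
    file.path(outdir, "loss_history.csv"), sep = ",", quote = FALSE,
    row.names = FALSE)
  save_embedding_model(model, file.path(outdir, "dae_model.rds"))

  ## -- cluster -----------------------------------------------------------
  say("stage cluster: selecting k in [%d, %d] by silhouette",
      config$cluster$k_min, config$cluster$k_max)
  sel <- select_k(embedding, config$cluster$k_min, config$cluster$k_max,
                  seed = config$seed)
  clustering <- sel$results[[as.character(sel$best_k)]]
  utils::write.table(sel$metrics, file.path(outdir, "k_selection.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE)

  ## -- survival ----------------------------------------------------------
  risk <- NULL
  logrank <- NULL
  if (clustering$k == 2L) {
    say("stage survival: risk groups and log-rank test")
    risk <- assign_risk_groups(clustering, clinical)
    grp <- risk$risk_group
    lr_groups <- grp
  } else {
    say("stage survival: k = %d, comparing clusters 1 vs rest", clustering$k)
    lr_groups <- as.integer(clustering$labels != 1L)
  }
  idx <- match(names(clustering$labels), clinical$sample_id)
  logrank <- logrank_test(clinical$time[idx], clinical$event[idx], lr_groups)
  write_km_tables(clinical$time[idx], clinical$event[idx], lr_groups,
                  file.path(outdir, "km_curves.csv"))
  labels_df <- data.frame(sample_id = names(clustering$labels),
                          cluster = unname(clustering$labels),
                          risk_group = if (is.null(risk)) NA_integer_
                                       else unname(risk$risk_group))
  utils::write.table(labels_df, file.path(outdir, "labels.csv"), sep = ",",
                     quote = FALSE, row.names = FALSE)

  ## -- classify ----------------------------------------------------------
  classifier <- NULL
  transfer <- NULL
  expr_block <- config$classify$block
  if (!is.null(risk) && expr_block %in% names(dataset$blocks)) {
    say("stage classify: L1 logistic on '%s' features", expr_block)
    xm <- dataset$blocks[[expr_block]]$values
    y <- unname(risk$risk_group[rownames(xm)])
    lam <- select_lambda(xm, y, grid = config$classify$lambda_grid,
                         seed = config$seed)
    classifier <- fit_l1_logistic(xm, y, lam$lambda)
    write_sparse_logistic(classifier, file.path(outdir, "classifier.tsv"))
    utils::write.table(lam$cv, file.path(outdir, "lambda_cv.csv"), sep = ",",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(config$simulate)) {
      say("stage transfer: independent simulated cohort")
      tcfg <- config_sim(config)
      tcfg$seed <- tcfg$seed + 10000L
      tsim <- simulate_multiomics(tcfg)
      traw <- tsim$dataset$blocks[[expr_block]]
      tproc <- apply_scaling(impute_median(filter_missing(
        traw, config$preprocess$missing_threshold)),
        attr(dataset$blocks[[expr_block]], "scaling"))
      transfer <- try(transfer_evaluate(classifier, tproc,
                                        tsim$dataset$clinical), silent = TRUE)
      if (inherits(transfer, "try-error")) {
        say("transfer evaluation failed: %s", attr(transfer, "condition")$message)
        transfer <- NULL
      } else {
        jsonlite::write_json(
          list(statistic = transfer$statistic, p_value = transfer$p_value,
               n = length(transfer$risk_group)),
          file.path(outdir, "transfer.json"), auto_unbox = TRUE, digits = NA)
      }
    }
  }

  ## -- benchmark ---------------------------------------------------------
  benchmark <- NULL
  if (!is.null(config$benchmark)) {
    methods <- config$benchmark$methods %||%
      c("kmeans", "hierarchical", "pca_kmeans", "kpca_kmeans",
        "ae_kmeans", "dae_kmeans")
    say("stage benchmark: %s", paste(methods, collapse = ", "))
    benchmark <- compare_methods(dataset, methods = methods,
                                 k = max(2L, clustering$k),
                                 seed = config$seed, config = dcfg,
                                 true_labels = if (!is.null(truth))
                                   truth$labels[dataset$sample_ids])
    utils::write.table(benchmark, file.path(outdir, "benchmark.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  ## -- manifest ----------------------------------------------------------
  manifest <- list(
    package = "subtypeDAE",
    version = as.character(utils::packageVersion("subtypeDAE")),
    seed = config$seed,
    parameters = list(preprocess = config$preprocess,
                      dae = unclass(dcfg),
                      cluster = config$cluster,
                      classify = config$classify),
    inputs = if (is.null(config$simulate)) config$data else "simulated",
    n_samples = length(dataset$sample_ids),
    n_features = ncol(dataset$x),
    best_k = sel$best_k,
    silhouette = clustering$silhouette,
    dbi = clustering$dbi,
    logrank_p = logrank$p_value,
    elapsed_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("done in %.1fs; outputs in %s", manifest$elapsed_sec, outdir)

  invisible(list(dataset = dataset, truth = truth, model = model,
                 embedding = embedding, k_selection = sel,
                 clustering = clustering, risk = risk, logrank = logrank,
                 classifier = classifier, transfer = transfer,
                 benchmark = benchmark, manifest = manifest))
}
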