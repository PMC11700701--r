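# End-to-end orchestration: simulate -> preprocess -> train -> evaluate ->
# features -> cluster, with YAML config, per-stage derived seeds, file
# outputs and a JSON run manifest.

#' Pipeline configuration
#'
#' Nested configuration for a full run. Every default equals the
#' pipeline's reference parameter where one exists (2.58-SD outlier cut,
#' 63/21 rolling ball with auxiliary slot 7, despike threshold 4, Whittaker
#' lambda 10000, 5 PCs, 70:30 split). Round-trips losslessly through YAML
#' via [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param seed Global seed; per-stage seeds are derived from it.
#' @param synthetic A [synthetic_config()] (default [plasma_preset()]).
#' @param preprocess A [preprocess_config()].
#' @param n_pcs Principal components for the classifier.
#' @param train_fraction Training fraction of the stratified split.
#' @param split_grouping `"sample"` or `"spectrum"`.
#' @param loocv_unit `"spectrum"` or `"sample"`.
#' @param alpha Band-significance level.
#' @param adjust `"none"` or `"bh"` multiple-testing adjustment.
#' @param cluster_k Number of clusters at the reported tree cut.
#' @param stages Character vector of enabled stages, any of `"simulate"`,
#'   `"preprocess"`, `"train"`, `"evaluate"`, `"features"`, `"cluster"`.
#' @return An object of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            synthetic = plasma_preset(seed = seed),
                            preprocess = preprocess_config(),
                            n_pcs = 5L, train_fraction = 0.7,
                            split_grouping = "sample",
                            loocv_unit = "spectrum",
                            alpha = 0.05, adjust = "none",
                            cluster_k = 3L,
                            stages = c("simulate", "preprocess", "train",
                                       "evaluate", "features", "cluster")) {
  structure(list(seed = as.integer(seed), synthetic = synthetic,
                 preprocess = preprocess, n_pcs = as.integer(n_pcs),
                 train_fraction = train_fraction,
                 split_grouping = split_grouping, loocv_unit = loocv_unit,
                 alpha = alpha, adjust = adjust,
                 cluster_k = as.integer(cluster_k), stages = stages),
            class = "pipeline_config")
}

#' Write a pipeline configuration to YAML
#' @param config A [pipeline_config()].
#' @param path Output YAML path.
#' @return Invisibly, `path`.
#' @export
write_pipeline_config <- function(config, path) {
  ser <- unclass(config)
  ser$synthetic <- unclass(ser$synthetic)
  ser$synthetic$bands <- as.list(ser$synthetic$bands)
  ser$synthetic$effects <- list(
    classes = rownames(config$synthetic$effects),
    bands = colnames(config$synthetic$effects),
    values = as.vector(config$synthetic$effects))
  ser$synthetic$n_samples <- as.list(ser$synthetic$n_samples)
  ser$preprocess <- unclass(ser$preprocess)
  yaml::write_yaml(ser, path, precision = 15)
  invisible(path)
}

#' Read a pipeline configuration from YAML
#' @param path YAML path written by [write_pipeline_config()].
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  eff <- matrix(unlist(y$synthetic$effects$values),
                nrow = length(y$synthetic$effects$classes),
                dimnames = list(unlist(y$synthetic$effects$classes),
                                unlist(y$synthetic$effects$bands)))
  n_samples <- unlist(y$synthetic$n_samples)
  syn <- synthetic_config(
    grid_start = y$synthetic$grid_start, grid_stop = y$synthetic$grid_stop,
    grid_step = y$synthetic$grid_step, n_samples = n_samples,
    n_replicates = y$synthetic$n_replicates,
    bands = as.data.frame(y$synthetic$bands), effects = eff,
    baseline_coef = unlist(y$synthetic$baseline_coef),
    noise_sigma = y$synthetic$noise_sigma,
    patient_sigma = y$synthetic$patient_sigma,
    spike_prob = y$synthetic$spike_prob,
    spike_amp = unlist(y$synthetic$spike_amp),
    outlier_prob = y$synthetic$outlier_prob,
    outlier_offset = unlist(y$synthetic$outlier_offset),
    seed = y$synthetic$seed)
  pp <- do.call(preprocess_config, y$preprocess)
  pipeline_config(seed = y$seed, synthetic = syn, preprocess = pp,
                  n_pcs = y$n_pcs, train_fraction = y$train_fraction,
                  split_grouping = y$split_grouping,
                  loocv_unit = y$loocv_unit, alpha = y$alpha,
                  adjust = y$adjust, cluster_k = y$cluster_k,
                  stages = unlist(y$stages))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order — simulate, preprocess, train
#' (split + LOOCV), evaluate (ensemble validation + ROC), features
#' (per-subtype band analysis), cluster — writing each stage's outputs
#' under `out_dir` and a JSON manifest recording the seed, the config, the
#' executed stage order, and the MD5 hash of every file written. Two runs
#' with identical config and seed produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory.
#' @return Invisibly, a list with the manifest and the in-memory stage
#'   results (`data`, `preprocessed`, `split`, `ensemble`, `validation`,
#'   `roc`, `bands`, `linkage`, `purity`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stages_run <- character(0)
  results <- list()
  files <- character(0)
  add_file <- function(p) files <<- c(files, p)
  stage_on <- function(s) s %in% config$stages

  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(config, cfg_path)
  add_file(cfg_path)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop2("stage '%s' failed: %s", name, conditionMessage(e)))
  }

  if (stage_on("simulate")) {
    results$data <- run_stage("simulate",
      simulate_spectra(config$synthetic, seed = derive_seed(config$seed, 1L)))
    paths <- write_spectra(results$data, out_dir, "raw")
    add_file(paths[[1]]); add_file(paths[[2]])
    tp <- file.path(out_dir, "truth.json")
    write_truth_json(results$data, tp); add_file(tp)
    stages_run <- c(stages_run, "simulate")
  }

  if (stage_on("preprocess")) {
    if (is.null(results$data)) stop2("stage 'preprocess' needs simulated data")
    pp <- run_stage("preprocess",
                    preprocess_spectra(results$data, config$preprocess))
    results$preprocessed <- pp$set
    results$preprocess_report <- pp$report
    paths <- write_spectra(pp$set, out_dir, "preprocessed")
    add_file(paths[[1]]); add_file(paths[[2]])
    rp <- file.path(out_dir, "preprocess_report.json")
    jsonlite::write_json(
      list(stages = pp$report$stages,
           outliers = pp$report$outliers,
           scale = pp$report$scale,
           spikes = lapply(pp$report$spikes, as.integer)),
      rp, digits = NA, auto_unbox = TRUE)
    add_file(rp)
    if (!is.null(pp$report$baseline)) {
      bl <- data.frame(wavenumber_cm1 = results$data$grid, check.names = FALSE)
      for (id in rownames(pp$report$baseline))
        bl[[id]] <- pp$report$baseline[id, ]
      bp <- file.path(out_dir, "baseline_wide.csv")
      utils::write.csv(format_full_precision(bl), bp, row.names = FALSE,
                       quote = FALSE)
      add_file(bp)
    }
    stages_run <- c(stages_run, "preprocess")
  }

  if (stage_on("train")) {
    if (is.null(results$preprocessed)) stop2("stage 'train' needs preprocessed data")
    results$split <- run_stage("train",
      split_train_validation(results$preprocessed, config$train_fraction,
                             config$split_grouping,
                             seed = derive_seed(config$seed, 2L)))
    sp <- file.path(out_dir, "split_manifest.csv")
    utils::write.csv(results$split$manifest, sp, row.names = FALSE,
                     quote = FALSE)
    add_file(sp)
    results$ensemble <- run_stage("train",
      loocv_train(results$split$train, n_pcs = config$n_pcs,
                  unit = config$loocv_unit))
    fm <- file.path(out_dir, "fold_metrics.csv")
    utils::write.csv(format_full_precision(results$ensemble$fold_metrics),
                     fm, row.names = FALSE, quote = FALSE)
    add_file(fm)
    results$model <- run_stage("train", pcalda(results$split$train,
                                               n_pcs = config$n_pcs))
    mb <- file.path(out_dir, "model.json")
    jsonlite::write_json(list(
      pca_mean = results$model$pca$mean,
      eigenvectors = results$model$pca$rotation,
      explained_variance_ratio = results$model$pca$explained_variance_ratio,
      lda_means = results$model$lda$means,
      lda_cov = results$model$lda$cov,
      lda_priors = results$model$lda$priors,
      lda_axes = results$model$lda$axes,
      classes = results$model$lda$classes), mb, digits = NA)
    add_file(mb)
    stages_run <- c(stages_run, "train")
  }

  if (stage_on("evaluate")) {
    if (is.null(results$ensemble)) stop2("stage 'evaluate' needs a trained ensemble")
    results$validation <- run_stage("evaluate",
      validate_ensemble(results$ensemble, results$split$validation))
    results$roc <- run_stage("evaluate",
      roc_one_vs_rest(results$validation$posterior,
                      results$validation$labels))
    operating <- do.call(rbind, lapply(names(results$roc$per_class),
      function(cl) {
        op <- choose_threshold(results$roc$per_class[[cl]])
        data.frame(class = cl, threshold = op$threshold,
                   sensitivity = op$sensitivity,
                   specificity = op$specificity)
      }))
    ep <- file.path(out_dir, "evaluation.json")
    jsonlite::write_json(list(
      auc = as.list(results$roc$auc),
      per_model = results$validation$per_model,
      summary = results$validation$summary,
      operating_points = operating), ep, digits = NA, auto_unbox = TRUE)
    add_file(ep)
    for (cl in names(results$roc$per_class)) {
      r <- results$roc$per_class[[cl]]
      rp <- file.path(out_dir, sprintf("roc_%s.csv",
                                       gsub("[^A-Za-z0-9]", "", cl)))
      utils::write.csv(format_full_precision(
        data.frame(fpr = r$fpr, tpr = r$tpr, threshold = r$thresholds)),
        rp, row.names = FALSE, quote = FALSE)
      add_file(rp)
    }
    stages_run <- c(stages_run, "evaluate")
  }

  if (stage_on("features")) {
    if (is.null(results$preprocessed)) stop2("stage 'features' needs preprocessed data")
    subtypes <- setdiff(unique(results$preprocessed$meta$class), "control")
    results$bands <- run_stage("features", lapply(subtypes, function(cl)
      band_analysis(results$preprocessed, cl, alpha = config$alpha,
                    adjust = config$adjust)))
    names(results$bands) <- subtypes
    for (cl in subtypes) {
      bp <- file.path(out_dir, sprintf("bands_%s.csv",
                                       gsub("[^A-Za-z0-9]", "", cl)))
      utils::write.csv(format_full_precision(results$bands[[cl]]$bands),
                       bp, row.names = FALSE, quote = FALSE)
      add_file(bp)
    }
    stages_run <- c(stages_run, "features")
  }

  if (stage_on("cluster")) {
    if (is.null(results$model)) stop2("stage 'cluster' needs a trained model")
    sc <- run_stage("cluster",
      sample_discriminant_coords(results$model, results$preprocessed))
    results$linkage <- run_stage("cluster",
      complete_linkage(sc$coords, labels = rownames(sc$coords)))
    results$purity <- run_stage("cluster",
      cluster_purity(results$linkage, sc$classes, config$cluster_k))
    np <- file.path(out_dir, "dendrogram.nwk")
    writeLines(dendrogram_export(results$linkage, "newick"), np)
    add_file(np)
    mp <- file.path(out_dir, "merge_table.csv")
    utils::write.csv(format_full_precision(
      data.frame(left = results$linkage$merge[, 1],
                 right = results$linkage$merge[, 2],
                 height = results$linkage$height,
                 size = results$linkage$sizes)),
      mp, row.names = FALSE, quote = FALSE)
    add_file(mp)
    pp <- file.path(out_dir, "purity.json")
    jsonlite::write_json(list(
      k = config$cluster_k,
      purity = results$purity$purity,
      cluster = as.integer(results$purity$cluster),
      sample = names(results$purity$cluster),
      class = sc$classes), pp, digits = NA, auto_unbox = TRUE)
    add_file(pp)
    stages_run <- c(stages_run, "cluster")
  }

  manifest <- list(
    seed = config$seed,
    config_hash = unname(tools::md5sum(cfg_path)),
    stages_enabled = config$stages,
    stages_run = stages_run,
    stages_skipped = setdiff(c("simulate", "preprocess", "train", "evaluate",
                               "features", "cluster"), config$stages),
    files = lapply(stats::setNames(files, basename(files)),
                   function(p) unname(tools::md5sum(p)))
  )
  mp <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, mp, digits = NA, auto_unbox = TRUE)
  invisible(c(list(manifest = manifest), results))
}
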