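# Training/validation split, leave-one-out cross-validation ensemble, and
# the frozen-eigenvector validation protocol.

#' Stratified 70:30 train/validation split
#'
#' Splits a labelled spectra set stratified by class. With
#' `grouping = "sample"` (the default) all replicates of a sample stay on
#' the same side, preventing replicate leakage between partitions; with
#' `grouping = "spectrum"` individual spectra are assigned independently.
#'
#' @param set A labelled `spectra_set`.
#' @param fraction Training fraction, default 0.70.
#' @param grouping `"sample"` or `"spectrum"`.
#' @param seed Integer seed for the random assignment.
#' @return List with `train`, `validation` (both `spectra_set`) and
#'   `manifest` (data frame spectrum_id -> partition).
#' @export
split_train_validation <- function(set, fraction = 0.7,
                                   grouping = c("sample", "spectrum"),
                                   seed = 1L) {
  grouping <- match.arg(grouping)
  if (fraction <= 0 || fraction >= 1) stop2("fraction must lie in (0, 1)")
  set.seed(as.integer(seed))
  meta <- set$meta
  unit_id <- if (grouping == "sample") meta$sample_id else meta$spectrum_id
  units <- unique(data.frame(unit = unit_id, class = meta$class))
  train_units <- character(0)
  for (cl in unique(units$class)) {
    u <- units$unit[units$class == cl]
    k <- round(fraction * length(u))
    k <- max(1L, min(length(u) - 1L, k))
    if (length(u) < 2L)
      stop2("class '%s' has %d %s unit(s); cannot appear on both sides",
            cl, length(u), grouping)
    train_units <- c(train_units, sample(u, k))
  }
  in_train <- unit_id %in% train_units
  manifest <- data.frame(spectrum_id = meta$spectrum_id,
                         partition = ifelse(in_train, "train", "validation"))
  list(train = set[in_train], validation = set[!in_train],
       manifest = manifest)
}

# Macro-averaged F1 over the classes present in `levels`.
macro_f1 <- function(pred, labels, levels = NULL) {
  if (is.null(levels)) levels <- unique(c(labels, pred))
  f1 <- vapply(levels, function(cl) {
    tp <- sum(pred == cl & labels == cl)
    fp <- sum(pred == cl & labels != cl)
    fn <- sum(pred != cl & labels == cl)
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1, na.rm = TRUE)
}

#' Leave-one-out cross-validated LDA ensemble
#'
#' Fits PCA once on the full training set (the frozen projection), then for
#' each left-out unit fits LDA on the remaining training scores, predicts
#' the held-out unit, records its accuracy and F1, and preserves the fold
#' model. `unit = "sample"` leaves out all replicates of one sample per
#' fold; `unit = "spectrum"` leaves out a single spectrum.
#'
#' @param train A labelled `spectra_set` (or numeric matrix with `labels`).
#' @param labels Labels when `train` is a plain matrix.
#' @param n_pcs Principal components, default 5.
#' @param unit `"spectrum"` (default) or `"sample"`.
#' @param refit_pca Refit PCA per fold instead of freezing the
#'   full-training-set projection (a deviation from the reference protocol,
#'   available for comparison), default `FALSE`.
#' @inheritParams fit_lda
#' @return An object of class `"cv_ensemble"`: the frozen `pca`, a list of
#'   `folds` (each with its `lda`, held-out ids, predictions and accuracy),
#'   a per-fold metric table and the overall LOOCV accuracy.
#' @export
loocv_train <- function(train, labels = NULL, n_pcs = 5L,
                        unit = c("spectrum", "sample"),
                        priors = c("proportions", "uniform"),
                        ridge = 1e-8, refit_pca = FALSE) {
  unit <- match.arg(unit)
  priors <- match.arg(priors)
  if (inherits(train, "spectra_set")) {
    m <- train$intensities
    if (is.null(labels)) labels <- train$meta$class
    units <- if (unit == "sample") train$meta$sample_id else
      train$meta$spectrum_id
  } else {
    m <- as.matrix(train)
    units <- as.character(seq_len(nrow(m)))
  }
  labels <- as.character(labels)
  cnt <- table(labels)
  if (any(cnt < 3L))
    stop2("LOOCV needs >= 3 training items per class; short: %s",
          paste(names(cnt)[cnt < 3L], collapse = ", "))
  pca <- fit_pca(m, n_pcs)
  scores <- pca$scores
  fold_units <- unique(units)
  folds <- vector("list", length(fold_units))
  metrics <- vector("list", length(fold_units))
  for (f in seq_along(fold_units)) {
    held <- units == fold_units[f]
    tr_scores <- if (refit_pca) {
      fold_pca <- fit_pca(m[!held, , drop = FALSE], n_pcs)
      fold_pca$scores
    } else scores[!held, , drop = FALSE]
    lda <- fit_lda(tr_scores, labels[!held], priors = priors, ridge = ridge)
    ho_scores <- if (refit_pca)
      transform_frozen(fold_pca, m[held, , drop = FALSE]) else
      scores[held, , drop = FALSE]
    post <- lda_posterior(lda, ho_scores)
    pred <- lda_predict_class(lda, post)
    acc <- mean(pred == labels[held])
    folds[[f]] <- list(unit = fold_units[f], lda = lda, pred = pred,
                       actual = labels[held], accuracy = acc)
    metrics[[f]] <- data.frame(fold = f, unit = fold_units[f],
                               accuracy = acc,
                               f1 = macro_f1(pred, labels[held]))
  }
  metrics <- do.call(rbind, metrics)
  structure(list(pca = pca, folds = folds, fold_metrics = metrics,
                 accuracy = mean(unlist(lapply(folds, function(f)
                   f$pred == f$actual))),
                 classes = folds[[1L]]$lda$classes, n_pcs = as.integer(n_pcs)),
            class = "cv_ensemble")
}

#' @export
print.cv_ensemble <- function(x, ...) {
  cat(sprintf("LOOCV ensemble: %d folds, %d PCs, LOOCV accuracy %.3f\n",
              length(x$folds), x$n_pcs, x$accuracy))
  invisible(x)
}

#' Assess every cross-validation model on the validation set
#'
#' Projects the validation spectra through the ensemble's frozen PCA and
#' has every preserved fold model predict every validation item. Reports
#' per-model accuracy, macro F1, macro sensitivity and macro specificity,
#' their means and standard deviations across models, and the
#' ensemble-mean posterior matrix (used for ROC analysis).
#'
#' @param ensemble A `"cv_ensemble"` from [loocv_train()].
#' @param validation A labelled `spectra_set` (or matrix with `labels`).
#' @param labels Labels when `validation` is a plain matrix.
#' @return List with `per_model` (metric table), `summary` (mean/sd rows),
#'   `posterior` (ensemble-mean posteriors), `labels`, and `pred`
#'   (ensemble-mean-posterior predictions).
#' @export
validate_ensemble <- function(ensemble, validation, labels = NULL) {
  if (inherits(validation, "spectra_set")) {
    m <- validation$intensities
    if (is.null(labels)) labels <- validation$meta$class
  } else m <- as.matrix(validation)
  if (nrow(m) == 0L) stop2("validation set is empty")
  labels <- as.character(labels)
  sc <- transform_frozen(ensemble$pca, m)
  classes <- ensemble$classes
  post_sum <- 0
  rows <- vector("list", length(ensemble$folds))
  for (f in seq_along(ensemble$folds)) {
    lda <- ensemble$folds[[f]]$lda
    post <- lda_posterior(lda, sc)
    post_sum <- post_sum + post
    pred <- lda_predict_class(lda, post)
    cm <- confusion_metrics(pred, labels, levels = classes)
    macro <- cm[cm$class == "macro", ]
    rows[[f]] <- data.frame(model = f, accuracy = mean(pred == labels),
                            f1 = macro$f1, sensitivity = macro$sensitivity,
                            specificity = macro$specificity)
  }
  per_model <- do.call(rbind, rows)
  summ <- data.frame(
    metric = c("accuracy", "f1", "sensitivity", "specificity"),
    mean = vapply(per_model[, -1L], mean, numeric(1)),
    sd = vapply(per_model[, -1L], stats::sd, numeric(1)),
    row.names = NULL)
  post_mean <- post_sum / length(ensemble$folds)
  list(per_model = per_model, summary = summ, posterior = post_mean,
       labels = labels,
       pred = classes[apply(post_mean, 1, which.max)])
}
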