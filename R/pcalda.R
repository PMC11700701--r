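# PCA-LDA classifier: mean-centred SVD PCA with a deterministic sign
# convention, followed by Gaussian equal-covariance LDA on the PC scores.
# The PCA part ("projection model") is the object frozen for validation:
# held-out data only ever pass through transform_frozen(), never a refit.

#' Fit PCA on a training matrix
#'
#' Mean-centred, SVD-based principal component analysis. Components are
#' ordered by decreasing variance with a deterministic sign convention:
#' each eigenvector's largest-magnitude loading is positive.
#'
#' @param x Numeric matrix (spectra in rows) or `spectra_set`.
#' @param n_pcs Number of components to retain, default 5.
#' @return An object of class `"raman_pca"`: `mean`, `rotation`
#'   (channels x n_pcs), `explained_variance_ratio`, `scores` (training
#'   scores), `sdev`.
#' @export
fit_pca <- function(x, n_pcs = 5L) {
  m <- if (inherits(x, "spectra_set")) x$intensities else as.matrix(x)
  n_pcs <- as.integer(n_pcs)
  if (n_pcs > min(nrow(m) - 1L, ncol(m)))
    stop2("n_pcs = %d exceeds min(n_spectra - 1, n_channels) = %d",
          n_pcs, min(nrow(m) - 1L, ncol(m)))
  pc <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot == 0) stop2("degenerate matrix: zero total variance")
  rot <- pc$rotation[, seq_len(n_pcs), drop = FALSE]
  sco <- pc$x[, seq_len(n_pcs), drop = FALSE]
  for (j in seq_len(n_pcs)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  structure(list(mean = pc$center, rotation = rot,
                 explained_variance_ratio = pc$sdev[seq_len(n_pcs)]^2 / tot,
                 scores = sco, sdev = pc$sdev[seq_len(n_pcs)]),
            class = "raman_pca")
}

#' Project data with frozen eigenvectors
#'
#' Projects new rows onto a stored PCA basis: `(x - mean) %*% rotation`.
#' Never refits — this is the validation-protocol contract.
#'
#' @param model A `"raman_pca"` (or a `"pcalda"` whose `$pca` is used).
#' @param x Matrix or `spectra_set` on the training grid.
#' @return Score matrix (rows x n_pcs).
#' @export
transform_frozen <- function(model, x) {
  if (inherits(model, "pcalda")) model <- model$pca
  m <- if (inherits(x, "spectra_set")) x$intensities else
    if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  if (ncol(m) != length(model$mean))
    stop2("channel mismatch: data has %d channels, model expects %d",
          ncol(m), length(model$mean))
  sweep(m, 2, model$mean) %*% model$rotation
}

#' Linear discriminant analysis on PC scores
#'
#' Gaussian equal-covariance LDA: per-class means, pooled within-class
#' covariance (ridge-stabilized when near-singular), class priors, and the
#' discriminant axes from the generalized eigenproblem `Sw^-1 Sb`
#' (unit-norm, sign-fixed). Exposes class posterior probabilities and
#' discriminant-space coordinates.
#'
#' @param scores Numeric matrix of PC scores (items in rows).
#' @param labels Class labels, one per row; every class needs >= 2 members.
#' @param priors `"proportions"` (class frequencies) or `"uniform"`.
#' @param ridge Relative ridge added to the pooled covariance when its
#'   reciprocal condition number falls below it, default 1e-8.
#' @return An object of class `"raman_lda"`.
#' @export
fit_lda <- function(scores, labels, priors = c("proportions", "uniform"),
                    ridge = 1e-8) {
  priors <- match.arg(priors)
  scores <- as.matrix(scores)
  labels <- as.character(labels)
  classes <- intersect(subtype_levels(), unique(labels))
  if (length(classes) == 0L) classes <- sort(unique(labels))
  if (length(classes) < 2L) stop2("LDA needs at least 2 classes")
  counts <- table(factor(labels, levels = classes))
  if (any(counts < 2L))
    stop2("classes with < 2 members: %s",
          paste(names(counts)[counts < 2L], collapse = ", "))
  p <- ncol(scores)
  n <- nrow(scores)
  means <- do.call(rbind, lapply(classes, function(cl)
    colMeans(scores[labels == cl, , drop = FALSE])))
  rownames(means) <- classes
  Sw <- matrix(0, p, p)
  for (cl in classes) {
    xc <- sweep(scores[labels == cl, , drop = FALSE], 2, means[cl, ])
    Sw <- Sw + crossprod(xc)
  }
  Sw <- Sw / (n - length(classes))
  ridged <- FALSE
  if (rcond(Sw) < ridge) {
    Sw <- Sw + ridge * mean(diag(Sw)) * diag(p)
    ridged <- TRUE
  }
  pri <- if (priors == "uniform") rep(1 / length(classes), length(classes)) else
    as.numeric(counts) / n
  names(pri) <- classes
  # Between-class scatter and discriminant axes (<= n_classes - 1).
  gm <- colMeans(scores)
  Sb <- matrix(0, p, p)
  for (cl in classes) {
    d <- means[cl, ] - gm
    Sb <- Sb + as.numeric(counts[cl]) * tcrossprod(d)
  }
  Sb <- Sb / n
  eg <- eigen(solve(Sw, Sb))
  k <- min(length(classes) - 1L, p)
  axes <- Re(eg$vectors[, seq_len(k), drop = FALSE])
  for (j in seq_len(k)) {
    axes[, j] <- axes[, j] / sqrt(sum(axes[, j]^2))
    i <- which.max(abs(axes[, j]))
    if (axes[i, j] < 0) axes[, j] <- -axes[, j]
  }
  structure(list(classes = classes, means = means, cov = Sw,
                 cov_inv = solve(Sw), priors = pri, axes = axes,
                 grand_mean = gm, eigenvalues = Re(eg$values[seq_len(k)]),
                 ridged = ridged),
            class = "raman_lda")
}

# Posterior probabilities under the equal-covariance Gaussian model.
lda_posterior <- function(lda, scores) {
  scores <- as.matrix(scores)
  disc <- vapply(lda$classes, function(cl) {
    mu <- lda$means[cl, ]
    drop(scores %*% (lda$cov_inv %*% mu)) -
      0.5 * drop(t(mu) %*% lda$cov_inv %*% mu) + log(lda$priors[cl])
  }, numeric(nrow(scores)))
  disc <- matrix(disc, nrow = nrow(scores),
                 dimnames = list(rownames(scores), lda$classes))
  disc <- disc - apply(disc, 1, max)
  post <- exp(disc)
  post / rowSums(post)
}

# Highest posterior wins; exact ties broken toward the lowest class index.
lda_predict_class <- function(lda, posterior) {
  lda$classes[apply(posterior, 1, which.max)]
}

#' Fit a PCA-LDA classifier
#'
#' The central fitting function: mean-centred PCA retaining `n_pcs`
#' components, then equal-covariance LDA on the training scores. The
#' returned object carries the frozen projection (PCA mean + eigenvectors +
#' explained variance) and the discriminant model, and is the only object
#' needed to classify new spectra.
#'
#' @param x Numeric matrix (spectra in rows) or preprocessed `spectra_set`.
#' @param labels Class labels (taken from `x$meta$class` when `x` is a
#'   `spectra_set` and `labels` is missing).
#' @param n_pcs Number of principal components, default 5.
#' @inheritParams fit_lda
#' @return An object of class `"pcalda"` with `print`, `summary`,
#'   `predict`, `coef` and `plot` methods.
#' @export
pcalda <- function(x, labels = NULL, n_pcs = 5L,
                   priors = c("proportions", "uniform"), ridge = 1e-8) {
  if (inherits(x, "spectra_set") && is.null(labels)) labels <- x$meta$class
  if (is.null(labels)) stop2("labels are required")
  pca <- fit_pca(x, n_pcs)
  lda <- fit_lda(pca$scores, labels, priors = match.arg(priors), ridge = ridge)
  structure(list(pca = pca, lda = lda, n_pcs = as.integer(n_pcs),
                 labels = as.character(labels), call = match.call()),
            class = "pcalda")
}

#' @export
print.pcalda <- function(x, ...) {
  cat(sprintf("PCA-LDA classifier: %d PCs (%.1f%% variance), classes: %s\n",
              x$n_pcs, 100 * sum(x$pca$explained_variance_ratio),
              paste(x$lda$classes, collapse = ", ")))
  invisible(x)
}

#' @export
summary.pcalda <- function(object, ...) {
  evr <- object$pca$explained_variance_ratio
  cat("PCA-LDA classifier\n")
  cat(sprintf("  components: %d, cumulative variance explained: %.1f%%\n",
              object$n_pcs, 100 * sum(evr)))
  cat("  per-PC variance ratio:",
      paste(sprintf("%.3f", evr), collapse = " "), "\n")
  cat(sprintf("  classes (%d): %s\n", length(object$lda$classes),
              paste(object$lda$classes, collapse = ", ")))
  cat("  priors:", paste(sprintf("%.3f", object$lda$priors), collapse = " "), "\n")
  if (object$lda$ridged) cat("  note: ridge stabilization applied to pooled covariance\n")
  invisible(object)
}

#' Predict from a PCA-LDA fit
#'
#' New data are projected with the frozen training eigenvectors and
#' classified by the stored discriminant.
#'
#' @param object A `"pcalda"` fit.
#' @param newdata Matrix or `spectra_set` on the training grid.
#' @param type `"class"`, `"posterior"`, `"scores"` (PC scores) or
#'   `"discriminant"` (LDA-space coordinates).
#' @param ... Unused.
#' @return Per `type`: character vector, probability matrix (rows sum to 1),
#'   or coordinate matrix.
#' @export
predict.pcalda <- function(object, newdata,
                           type = c("class", "posterior", "scores",
                                    "discriminant"), ...) {
  type <- match.arg(type)
  sc <- transform_frozen(object$pca, newdata)
  switch(type,
    scores = sc,
    posterior = lda_posterior(object$lda, sc),
    class = lda_predict_class(object$lda, lda_posterior(object$lda, sc)),
    discriminant = sweep(sc, 2, object$lda$grand_mean) %*% object$lda$axes
  )
}

#' Channel-space discriminant loadings
#'
#' @param object A `"pcalda"` fit.
#' @param ... Unused.
#' @return Channels x discriminant-axes loading matrix
#'   (`rotation %*% axes`).
#' @export
coef.pcalda <- function(object, ...) {
  object$pca$rotation %*% object$lda$axes
}

#' Plot discriminant coordinates of the training data
#'
#' @param x A `"pcalda"` fit.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, the coordinate matrix.
#' @export
plot.pcalda <- function(x, ...) {
  co <- sweep(x$pca$scores, 2, x$lda$grand_mean) %*% x$lda$axes
  cls <- factor(x$labels, levels = x$lda$classes)
  if (ncol(co) >= 2L) {
    graphics::plot(co[, 1], co[, 2], col = as.integer(cls), pch = 19,
                   xlab = "LD1", ylab = "LD2", ...)
  } else {
    graphics::stripchart(co[, 1] ~ cls, vertical = TRUE, pch = 19,
                         ylab = "LD1", ...)
  }
  graphics::legend("topright", legend = levels(cls), col = seq_along(levels(cls)),
                   pch = 19, cex = 0.7)
  invisible(co)
}
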