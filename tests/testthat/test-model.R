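test_that("the stratified sample-level split is leak-free and deterministic", {
  cfg <- fast_config(seed = 2, n_samples = c(control = 12L, `HR+HER2-` = 3L,
                                             `HR+HER2+` = 3L, `HR-HER2+` = 3L,
                                             `HR-HER2-` = 3L),
                     n_replicates = 5L)
  set <- simulate_spectra(cfg)
  sp <- split_train_validation(set, 0.7, "sample", seed = 1)
  n_tr <- length(unique(sp$train$meta$sample_id))
  n_va <- length(unique(sp$validation$meta$sample_id))
  expect_true(n_tr %in% 16:17)
  expect_true(n_va %in% 7:8)
  expect_length(intersect(sp$train$meta$sample_id,
                          sp$validation$meta$sample_id), 0)
  # replicates of a sample always travel together
  expect_true(all(table(sp$train$meta$sample_id) == 5))
  # every class on both sides
  expect_setequal(unique(sp$train$meta$class), unique(set$meta$class))
  expect_setequal(unique(sp$validation$meta$class), unique(set$meta$class))

  # determinism
  sp2 <- split_train_validation(set, 0.7, "sample", seed = 1)
  expect_identical(sp$manifest, sp2$manifest)

  # leakage audit across many seeds: zero shared sample ids
  leaks <- vapply(1:200, function(s) {
    spl <- split_train_validation(set, 0.7, "sample", seed = s)
    length(intersect(spl$train$meta$sample_id,
                     spl$validation$meta$sample_id))
  }, numeric(1))
  expect_identical(sum(leaks), 0)
})

test_that("PCA matches a dense eigendecomposition and reconstructs its input", {
  # two distinct spectra: one PC carries all the variance
  m2 <- rbind(c(1, 2, 3, 4), c(2, 4, 1, 0))
  p2 <- fit_pca(m2, 1)
  expect_equal(p2$explained_variance_ratio, 1, tolerance = 1e-12)

  set.seed(6)
  m <- matrix(rnorm(48), 8, 6)
  p <- fit_pca(m, 5)
  # explained variances match covariance eigenvalues
  ev <- eigen(cov(m))$values
  expect_equal(p$sdev^2, ev[1:5], tolerance = 1e-10)
  # full-rank reconstruction reproduces the centred matrix
  pf <- fit_pca(m, 6)
  centred <- sweep(m, 2, colMeans(m))
  expect_equal(pf$scores %*% t(pf$rotation), centred, tolerance = 1e-8,
               ignore_attr = TRUE)
  # eigenvectors orthonormal; sign convention deterministic
  expect_equal(crossprod(p$rotation), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  for (j in 1:5) expect_gt(p$rotation[which.max(abs(p$rotation[, j])), j], 0)
  expect_error(fit_pca(m, 8), "exceeds")
})

test_that("frozen projection never refits and matches explicit dot products", {
  set.seed(7)
  train <- matrix(rnorm(200), 20, 10)
  p <- fit_pca(train, 4)
  expect_equal(transform_frozen(p, train), p$scores, tolerance = 1e-10)
  expect_equal(drop(transform_frozen(p, colMeans(train))), rep(0, 4),
               tolerance = 1e-10, ignore_attr = TRUE)
  valid <- matrix(rnorm(50), 5, 10)
  got <- transform_frozen(p, valid)
  manual <- t(apply(valid, 1, function(v)
    vapply(1:4, function(j) sum((v - p$mean) * p$rotation[, j]), numeric(1))))
  expect_equal(got, manual, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(transform_frozen(p, matrix(0, 2, 9)), "mismatch")
})

test_that("LDA recovers the symmetric boundary, normalizes posteriors and
           matches the generalized eigenproblem", {
  # exactly symmetric unit-variance classes at -5 and +5: boundary at 0
  x1 <- matrix(c(-6, -5, -4), ncol = 1)
  x2 <- -x1
  lda <- fit_lda(rbind(x1, x2), rep(c("control", "HR+HER2-"), each = 3))
  post0 <- ramanbc:::lda_posterior(lda, matrix(0, 1, 1))
  expect_equal(unname(post0[1, 1]), 0.5, tolerance = 1e-10)
  expect_equal(ramanbc:::lda_predict_class(lda, ramanbc:::lda_posterior(
    lda, matrix(c(-1, 1), 2, 1))), c("control", "HR+HER2-"))

  # posteriors sum to one
  sc <- matrix(rnorm(60), 30, 2)
  lab <- rep(c("control", "HR+HER2-", "HR-HER2+"), each = 10)
  lda3 <- fit_lda(sc, lab)
  post <- ramanbc:::lda_posterior(lda3, sc)
  expect_equal(rowSums(post), rep(1, 30), tolerance = 1e-12,
               ignore_attr = TRUE)

  # discriminant axes from a from-scratch generalized eigenproblem
  mu <- lapply(split(as.data.frame(sc), lab), colMeans)
  gm <- colMeans(sc)
  Sw <- matrix(0, 2, 2); Sb <- matrix(0, 2, 2)
  for (cl in names(mu)) {
    xc <- sweep(as.matrix(sc[lab == cl, ]), 2, unlist(mu[[cl]]))
    Sw <- Sw + crossprod(xc)
    Sb <- Sb + 10 * tcrossprod(unlist(mu[[cl]]) - gm)
  }
  Sw <- Sw / (30 - 3); Sb <- Sb / 30
  eg <- eigen(solve(Sw) %*% Sb)
  for (j in 1:2) {
    v <- eg$vectors[, j] / sqrt(sum(eg$vectors[, j]^2))
    got <- lda3$axes[, j]
    expect_equal(abs(sum(v * got)), 1, tolerance = 1e-6)
  }
  expect_error(fit_lda(sc, c("control", rep("HR+HER2-", 29))), "< 2 members")
})

test_that("LDA posteriors agree with the reference implementation", {
  skip_if_not_installed("MASS")
  set.seed(13)
  sc <- matrix(rnorm(150), 50, 3)
  sc[1:25, 1] <- sc[1:25, 1] + 2
  lab <- rep(c("control", "HR-HER2-"), each = 25)
  ours <- fit_lda(sc, lab)
  ref <- MASS::lda(sc, grouping = lab)
  pr <- predict(ref, sc)
  post <- ramanbc:::lda_posterior(ours, sc)
  expect_equal(unname(post[, "control"]), unname(pr$posterior[, "control"]),
               tolerance = 1e-6)
})

test_that("LOOCV bookkeeping, separable recovery and the permutation null hold", {
  cfg <- fast_config(seed = 31, noise_sigma = 4,
                     n_samples = c(control = 8L, `HR+HER2-` = 5L,
                                   `HR-HER2+` = 5L))
  cfg$effects <- cfg$effects[c("control", "HR+HER2-", "HR-HER2+"), ]
  set <- simulate_spectra(cfg)
  pp <- preprocess_spectra(set)$set
  ens <- loocv_train(pp, n_pcs = 4)
  # one fold per training item, each held out exactly once
  expect_length(ens$folds, n_spectra(pp))
  expect_setequal(vapply(ens$folds, `[[`, character(1), "unit"),
                  pp$meta$spectrum_id)
  # well-separated synthetic classes: perfect LOOCV accuracy
  expect_equal(ens$accuracy, 1.0)

  # permuted labels: accuracy near 1/n_classes (20 permutations here)
  set.seed(99)
  accs <- vapply(1:20, function(i)
    loocv_train(pp$intensities, sample(pp$meta$class), n_pcs = 4,
                priors = "uniform")$accuracy, numeric(1))
  n_tot <- 20 * n_spectra(pp)
  expect_lt(abs(mean(accs) - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / n_tot) + 0.02)
})

test_that("ensemble validation metrics match hand arithmetic", {
  # hand-built 2-model ensemble in a 1-channel space: model A classifies the
  # axis correctly, model B has its class means swapped
  pca <- structure(list(mean = 0, rotation = matrix(1, 1, 1),
                        explained_variance_ratio = 1,
                        scores = matrix(c(-5, -4, 4, 5), 4, 1),
                        sdev = 1), class = "raman_pca")
  tr <- matrix(c(-5, -4, -4.5, 4, 5, 4.5), ncol = 1)
  lab_a <- rep(c("control", "HR+HER2-"), each = 3)
  lda_a <- fit_lda(tr, lab_a)
  lda_b <- fit_lda(tr, rev(lab_a))
  ens <- structure(list(
    pca = pca,
    folds = list(list(lda = lda_a), list(lda = lda_b)),
    classes = lda_a$classes), class = "cv_ensemble")
  val <- matrix(c(-6, -3, 3, 6), ncol = 1)
  lab <- c("control", "control", "HR+HER2-", "HR+HER2-")
  out <- validate_ensemble(ens, val, lab)
  # model A: 4/4 correct; model B: 0/4
  expect_equal(out$per_model$accuracy, c(1, 0))
  expect_equal(out$summary$mean[out$summary$metric == "accuracy"], 0.5)
  expect_equal(out$summary$sd[out$summary$metric == "accuracy"], sd(c(1, 0)))

  # duplicate fold models: zero cross-model SD
  ens2 <- structure(list(pca = pca,
                         folds = list(list(lda = lda_a), list(lda = lda_a)),
                         classes = lda_a$classes), class = "cv_ensemble")
  out2 <- validate_ensemble(ens2, val, lab)
  expect_equal(out2$summary$sd, rep(0, 4))
  expect_equal(out2$per_model$accuracy, c(1, 1))
})

test_that("spectrum-level splitting is optimistic relative to sample-level", {
  # strong shared patient effect + weak class effects: replicate leakage
  # inflates spectrum-level validation accuracy
  accs <- vapply(1:10, function(s) {
    cfg <- fast_config(seed = s, noise_sigma = 8, patient_sigma = 0.20,
                       n_samples = c(control = 8L, `HR+HER2-` = 4L,
                                     `HR-HER2+` = 4L), n_replicates = 5L)
    cfg$effects <- cfg$effects[c("control", "HR+HER2-", "HR-HER2+"), ] * 0.15
    set <- simulate_spectra(cfg)
    pp <- preprocess_spectra(set)$set
    acc_of <- function(grouping) {
      sp <- split_train_validation(pp, 0.7, grouping, seed = s)
      ens <- loocv_train(sp$train, n_pcs = 5)
      validate_ensemble(ens, sp$validation)$summary$mean[1]
    }
    c(acc_of("spectrum"), acc_of("sample"))
  }, numeric(2))
  expect_gte(mean(accs[1, ]), mean(accs[2, ]))
})
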