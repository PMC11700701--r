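# Five-stage spectral preprocessing, applied in fixed order:
# PCA-score outlier rejection -> rolling-ball baseline correction ->
# mean-centering + global standardization -> cosmic-ray despiking ->
# Whittaker smoothing.

#' Preprocessing configuration
#'
#' Defaults are the pipeline's reference parameters: a 2.58-SD score cut
#' (the two-sided 99% normal multiplier) on the first two PCs, a 63-channel
#' rolling-ball structuring window smoothed over 21 channels (with an
#' auxiliary slot of 7 kept for config compatibility but unused), a
#' modified-z despike threshold of 4 with a +/-2-channel repair window, and
#' a Whittaker smoother with lambda = 10000 at difference order 2.
#'
#' @param outlier_z Score threshold in SD units (`Inf` disables the stage).
#' @param outlier_n_pcs Number of score axes checked.
#' @param ball_width Structuring window in channels (0 disables baseline
#'   correction).
#' @param ball_smooth Baseline smoothing window in channels.
#' @param ball_aux Auxiliary parameter slot; stored, unused.
#' @param standardize Logical; apply mean-centering + global standardization.
#' @param despike_threshold Modified-z cut (`Inf` disables despiking).
#' @param despike_window Repair neighbourhood half-width in channels.
#' @param whittaker_lambda Smoothness penalty (0 disables smoothing).
#' @param whittaker_order Difference order, 1 or 2.
#' @return An object of class `"preprocess_config"`.
#' @export
preprocess_config <- function(outlier_z = 2.58, outlier_n_pcs = 2L,
                              ball_width = 63L, ball_smooth = 21L,
                              ball_aux = 7L, standardize = TRUE,
                              despike_threshold = 4,
                              despike_window = 2L,
                              whittaker_lambda = 10000,
                              whittaker_order = 2L) {
  if (outlier_z <= 0) stop2("outlier_z must be > 0")
  if (whittaker_lambda < 0) stop2("whittaker_lambda must be >= 0")
  if (!whittaker_order %in% 1:2) stop2("whittaker_order must be 1 or 2")
  structure(list(outlier_z = outlier_z, outlier_n_pcs = as.integer(outlier_n_pcs),
                 ball_width = as.integer(ball_width),
                 ball_smooth = as.integer(ball_smooth),
                 ball_aux = as.integer(ball_aux), standardize = standardize,
                 despike_threshold = despike_threshold,
                 despike_window = as.integer(despike_window),
                 whittaker_lambda = whittaker_lambda,
                 whittaker_order = as.integer(whittaker_order)),
            class = "preprocess_config")
}

#' PCA-score outlier rejection
#'
#' Fits PCA to the raw intensity matrix and flags a spectrum when its score
#' on any of the first `n_pcs` axes deviates from that axis's mean by more
#' than `z` times the axis SD. A zero-variance axis flags nothing. Flagged
#' spectra are removed from the returned set and listed in the report.
#'
#' @param set A `spectra_set` with at least 3 spectra.
#' @param z Threshold in SD units, default 2.58 (two-sided 99%).
#' @param n_pcs Number of score axes checked, default 2.
#' @return List with `kept` (the filtered set) and `report` (data frame of
#'   flagged ids with their scores).
#' @export
flag_outliers <- function(set, z = 2.58, n_pcs = 2L) {
  n <- n_spectra(set)
  if (n < 3L) stop2("outlier filtering needs at least 3 spectra")
  n_pcs <- min(as.integer(n_pcs), n - 1L)
  if (is.infinite(z)) {
    return(list(kept = set,
                report = data.frame(spectrum_id = character(0))))
  }
  pc <- stats::prcomp(set$intensities, center = TRUE, scale. = FALSE)
  k <- min(n_pcs, ncol(pc$x))
  sc <- pc$x[, seq_len(k), drop = FALSE]
  mu <- colMeans(sc)
  sdv <- apply(sc, 2, stats::sd)
  dev <- abs(sweep(sc, 2, mu))
  lim <- matrix(z * sdv, nrow = n, ncol = k, byrow = TRUE)
  exceeds <- dev > lim & matrix(sdv > 0, nrow = n, ncol = k, byrow = TRUE)
  flag <- rowSums(exceeds) > 0
  report <- cbind(data.frame(spectrum_id = set$meta$spectrum_id[flag]),
                  as.data.frame(sc[flag, , drop = FALSE]))
  list(kept = set[!flag], report = report)
}

#' Rolling-ball baseline correction
#'
#' One-dimensional rolling-ball baseline: the morphological opening of the
#' spectrum (running-minimum erosion followed by running-maximum dilation,
#' both over `ball_width` channels, reflect-padded), smoothed by a moving
#' average over `ball_smooth` channels. Before smoothing the opening never
#' exceeds the spectrum, so narrow peaks and spikes are excluded from the
#' baseline estimate.
#'
#' @param y Intensity vector.
#' @param ball_width Structuring window in channels (>= 3; made odd).
#' @param ball_smooth Smoothing window in channels (made odd).
#' @return List with `baseline` and `corrected` (`y - baseline`).
#' @export
rolling_ball_baseline <- function(y, ball_width = 63L, ball_smooth = 21L) {
  if (ball_width < 3L) stop2("ball_width must be >= 3 channels")
  if (ball_width > length(y))
    stop2("ball_width (%d) exceeds spectrum length (%d)", ball_width, length(y))
  opened <- run_window(run_window(y, ball_width, "min"), ball_width, "max")
  baseline <- run_window(opened, ball_smooth, "mean")
  list(baseline = baseline, corrected = y - baseline, opening = opened)
}

#' Mean-centre and globally standardize a spectra set
#'
#' Subtracts the channelwise mean spectrum, then divides every entry by one
#' global scalar: the standard deviation over all elements of the
#' mean-centred matrix. The mean spectrum and scalar are returned so the
#' identical transform can be replayed on new (e.g. validation) data.
#'
#' @param set A `spectra_set` with at least 2 spectra.
#' @param mean_spectrum,scale Optional stored transform to replay; when
#'   supplied the transform is applied as-is instead of being estimated.
#' @return List with `set`, `mean_spectrum`, `scale`.
#' @export
center_standardize <- function(set, mean_spectrum = NULL, scale = NULL) {
  if (is.null(mean_spectrum)) {
    if (n_spectra(set) < 2L) stop2("standardization needs at least 2 spectra")
    mean_spectrum <- colMeans(set$intensities)
    centred <- sweep(set$intensities, 2, mean_spectrum)
    scale <- stats::sd(as.vector(centred))
    if (scale == 0) stop2("degenerate set: zero global standard deviation")
  } else {
    centred <- sweep(set$intensities, 2, mean_spectrum)
  }
  out <- set
  out$intensities <- centred / scale
  rownames(out$intensities) <- set$meta$spectrum_id
  list(set = out, mean_spectrum = mean_spectrum, scale = scale)
}

#' Cosmic-ray despiking by modified z-score of first differences
#'
#' Computes the modified z-score `z_i = 0.6745 (d_i - median(d)) / MAD(d)`
#' on the first differences `d` of the spectrum. A channel is flagged as a
#' spike when both adjacent differences exceed the threshold with opposite
#' signs — the up-then-down signature of a single-channel excursion; at the
#' two ends a lone exceedance suffices. Flagged intensities are replaced by
#' the mean of non-flagged neighbours within `+/- window` channels (window
#' grown if all neighbours are flagged). With `MAD = 0` and non-constant
#' differences the SD-based z-score is used; a constant spectrum flags
#' nothing.
#'
#' @param y Intensity vector of length >= 5.
#' @param threshold Modified-z cut, default 4 (`Inf` disables).
#' @param window Repair half-width in channels, default 2.
#' @return List with `cleaned` and integer `spike_channels`.
#' @export
despike <- function(y, threshold = 4, window = 2L) {
  n <- length(y)
  if (n < 5L) stop2("despiking needs at least 5 channels")
  if (is.infinite(threshold))
    return(list(cleaned = y, spike_channels = integer(0)))
  d <- diff(y)
  med <- stats::median(d)
  madv <- stats::median(abs(d - med))
  if (madv > 0) {
    z <- 0.6745 * (d - med) / madv
  } else {
    s <- stats::sd(d)
    if (is.na(s) || s == 0)
      return(list(cleaned = y, spike_channels = integer(0)))
    z <- (d - med) / s
  }
  hit <- abs(z) > threshold
  flag <- logical(n)
  if (n >= 3L) {
    i <- 2:(n - 1L)
    flag[i] <- hit[i - 1L] & hit[i] & (sign(d[i - 1L]) != sign(d[i]))
  }
  if (hit[1L] && !flag[2L]) flag[1L] <- TRUE
  if (hit[n - 1L] && !flag[n - 1L]) flag[n] <- TRUE
  channels <- which(flag)
  cleaned <- y
  for (i in channels) {
    w <- as.integer(window)
    repeat {
      nb <- setdiff(max(1L, i - w):min(n, i + w), channels)
      if (length(nb)) break
      w <- w + 1L
    }
    cleaned[i] <- mean(y[nb])
  }
  list(cleaned = cleaned, spike_channels = channels)
}

#' Whittaker smoother
#'
#' Returns the minimizer of `sum((y - z)^2) + lambda * sum((D^order z)^2)`,
#' i.e. the solution of `(I + lambda D'D) z = y` with `D` the order-th
#' difference matrix, via a sparse banded Cholesky solve. `lambda = 0`
#' returns the input exactly; for order 2 any affine input is invariant.
#'
#' @param y Intensity vector (or matrix with spectra in rows) of finite
#'   values, length > order.
#' @param lambda Smoothness penalty >= 0, default 10000.
#' @param order Difference order, 1 or 2.
#' @return Smoothed vector (or matrix).
#' @export
whittaker_smooth <- function(y, lambda = 10000, order = 2L) {
  if (lambda < 0) stop2("lambda must be >= 0")
  if (!order %in% 1:2) stop2("order must be 1 or 2")
  if (any(!is.finite(y))) stop2("non-finite input to the smoother")
  vec <- is.null(dim(y))
  ym <- if (vec) matrix(y, nrow = 1L) else as.matrix(y)
  n <- ncol(ym)
  if (n <= order) stop2("input length must exceed the difference order")
  if (lambda == 0) return(if (vec) drop(ym) else ym)
  D <- whittaker_diff_matrix(n, order)
  C <- Matrix::Diagonal(n) + lambda * Matrix::crossprod(D)
  z <- as.matrix(Matrix::solve(C, t(ym)))
  out <- t(z)
  dimnames(out) <- dimnames(ym)
  if (vec) drop(out) else out
}

# Sparse order-th difference matrix ((n - order) x n).
whittaker_diff_matrix <- function(n, order) {
  coefs <- (-1)^(0:order) * choose(order, 0:order)
  Matrix::bandSparse(n - order, n, k = 0:order,
                     diagonals = lapply(coefs, rep, n - order))
}

#' Run the full preprocessing pipeline
#'
#' Applies the five stages in fixed order: outlier filter, rolling-ball
#' baseline correction, mean-centering + global standardization, despiking,
#' Whittaker smoothing. Each stage can be disabled via its config parameter
#' (`outlier_z = Inf`, `ball_width = 0`, `standardize = FALSE`,
#' `despike_threshold = Inf`, `whittaker_lambda = 0`); a fully disabled
#' pipeline is the identity.
#'
#' @param set A `spectra_set`.
#' @param config A [preprocess_config()].
#' @return List with `set` (processed) and `report`, a list carrying the
#'   flagged outlier table, the retained baseline matrix, the
#'   standardization mean/scale, per-spectrum despiked channels, and the
#'   executed stage order.
#' @export
preprocess_spectra <- function(set, config = preprocess_config()) {
  if (!inherits(config, "preprocess_config"))
    stop2("config must be a preprocess_config")
  report <- list(stages = character(0))

  out <- tryCatch({
    fl <- flag_outliers(set, config$outlier_z, config$outlier_n_pcs)
    report$outliers <- fl$report
    report$stages <- c(report$stages, "outlier_filter")
    fl$kept
  }, error = function(e) stop2("outlier_filter: %s", conditionMessage(e)))

  if (config$ball_width >= 3L) {
    res <- tryCatch(
      lapply(seq_len(n_spectra(out)), function(i)
        rolling_ball_baseline(out$intensities[i, ], config$ball_width,
                              config$ball_smooth)),
      error = function(e) stop2("baseline: %s", conditionMessage(e)))
    baseline <- t(vapply(res, `[[`, numeric(length(out$grid)), "baseline"))
    rownames(baseline) <- out$meta$spectrum_id
    report$baseline <- baseline
    out$intensities <- out$intensities - baseline
    rownames(out$intensities) <- out$meta$spectrum_id
    report$stages <- c(report$stages, "baseline")
  }

  if (isTRUE(config$standardize)) {
    cs <- tryCatch(center_standardize(out),
                   error = function(e) stop2("standardize: %s", conditionMessage(e)))
    out <- cs$set
    report$mean_spectrum <- cs$mean_spectrum
    report$scale <- cs$scale
    report$stages <- c(report$stages, "standardize")
  }

  if (is.finite(config$despike_threshold)) {
    flags <- vector("list", n_spectra(out))
    for (i in seq_len(n_spectra(out))) {
      ds <- tryCatch(despike(out$intensities[i, ], config$despike_threshold,
                             config$despike_window),
                     error = function(e) stop2("despike: %s", conditionMessage(e)))
      out$intensities[i, ] <- ds$cleaned
      flags[[i]] <- ds$spike_channels
    }
    names(flags) <- out$meta$spectrum_id
    report$spikes <- flags
    report$stages <- c(report$stages, "despike")
  }

  if (config$whittaker_lambda > 0) {
    out$intensities <- tryCatch(
      whittaker_smooth(out$intensities, config$whittaker_lambda,
                       config$whittaker_order),
      error = function(e) stop2("smooth: %s", conditionMessage(e)))
    rownames(out$intensities) <- out$meta$spectrum_id
    report$stages <- c(report$stages, "smooth")
  }

  list(set = out, report = report)
}
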