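# Difference-spectrum computation and per-wavenumber Mann-Whitney
# significance analysis with band annotation.

#' Reference band assignment table
#'
#' Molecular assignments for the plasma bands tracked by the pipeline,
#' drawn from the standard Raman literature on blood-derived biofluids.
#'
#' @return Data frame with columns `wavenumber`, `assignment`.
#' @export
raman_assignments <- function() {
  data.frame(
    wavenumber = c(643, 757, 861, 878, 941, 1158, 1448, 1518),
    assignment = c(
      "tyrosine and phenylalanine",
      "tryptophan",
      "proline and tyrosine in collagen",
      "proline and hydroxyproline in collagen",
      "C-C stretching in proteins",
      "C-C/C-N stretching in proteins (beta-carotene)",
      "CH2 bending in lipids and proteins",
      "aromatic ring stretching in proteins (beta-carotene)"
    )
  )
}

#' Difference spectra against the control mean
#'
#' Subtracts the control-group mean spectrum from each individual disease
#' spectrum (both sets must share the grid) and returns the per-spectrum
#' difference matrix plus per-class mean difference curves.
#'
#' @param disease A `spectra_set` of disease spectra.
#' @param control A `spectra_set` of control spectra.
#' @return List with `differences` (matrix), `class_means` (named list of
#'   mean-difference curves), `control_mean`.
#' @export
difference_spectra <- function(disease, control) {
  if (!isTRUE(all.equal(disease$grid, control$grid)))
    stop2("disease and control sets are on different grids")
  cm <- colMeans(control$intensities)
  diffs <- sweep(disease$intensities, 2, cm)
  cls <- unique(disease$meta$class)
  class_means <- lapply(cls, function(cl)
    colMeans(diffs[disease$meta$class == cl, , drop = FALSE]))
  names(class_means) <- cls
  list(differences = diffs, class_means = class_means, control_mean = cm)
}

#' Per-channel Mann-Whitney test
#'
#' Applies the two-sided Mann-Whitney-Wilcoxon test at every channel,
#' comparing disease against control intensities. Exact enumeration is
#' used when both groups have at most 8 untied observations; otherwise the
#' normal approximation with tie and continuity correction. Channels where
#' every value is identical in both groups get `p = 1` and the method
#' `"degenerate"`.
#'
#' @param disease Matrix of disease intensities (spectra in rows) or a
#'   `spectra_set`.
#' @param control Matrix or `spectra_set` of control intensities.
#' @return Data frame with one row per channel: `channel`, `mean_diff`,
#'   `U`, `p`, `method`.
#' @export
mann_whitney_per_channel <- function(disease, control) {
  x <- if (inherits(disease, "spectra_set")) disease$intensities else
    as.matrix(disease)
  y <- if (inherits(control, "spectra_set")) control$intensities else
    as.matrix(control)
  if (ncol(x) != ncol(y)) stop2("channel count mismatch")
  if (nrow(x) < 2L || nrow(y) < 2L)
    stop2("each group needs at least 2 observations")
  n1 <- nrow(x); n2 <- nrow(y)
  res <- lapply(seq_len(ncol(x)), function(j) {
    a <- x[, j]; b <- y[, j]
    if (all(a == a[1L]) && all(b == b[1L]) && a[1L] == b[1L]) {
      return(data.frame(channel = j, mean_diff = 0, U = n1 * n2 / 2,
                        p = 1, method = "degenerate"))
    }
    untied <- !anyDuplicated(c(a, b))
    exact <- untied && n1 <= 8L && n2 <= 8L
    wt <- suppressWarnings(
      stats::wilcox.test(a, b, alternative = "two.sided", exact = exact,
                         correct = TRUE))
    data.frame(channel = j, mean_diff = mean(a) - mean(b),
               U = unname(wt$statistic), p = wt$p.value,
               method = if (exact) "exact" else "normal_approx")
  })
  do.call(rbind, res)
}

#' Significant spectral bands
#'
#' Thresholds channelwise Mann-Whitney p-values at `alpha` (optionally
#' after Benjamini-Hochberg adjustment), merges contiguous significant
#' channels sharing the sign of the mean difference into bands, reports
#' each band at its extreme-|difference| channel with its direction, and
#' annotates it with the nearest reference assignment within 10 cm^-1.
#'
#' @param stats Channelwise statistics from [mann_whitney_per_channel()].
#' @param grid Wavenumber vector matching the channels.
#' @param alpha Significance level in (0, 1), default 0.05.
#' @param adjust `"none"` (raw p-values, the default) or `"bh"`.
#' @param assignments Assignment table, default [raman_assignments()].
#' @return An object of class `"band_report"`: the augmented channel table
#'   (`channels`, with `p_adj` and `significant`) and the `bands` data
#'   frame (`wavenumber`, `direction`, `p`, `mean_diff`, `start`, `end`,
#'   `assignment`).
#' @export
significant_bands <- function(stats, grid, alpha = 0.05,
                              adjust = c("none", "bh"),
                              assignments = raman_assignments()) {
  adjust <- match.arg(adjust)
  if (alpha <= 0 || alpha > 1) stop2("alpha must lie in (0, 1]")
  if (length(grid) != nrow(stats)) stop2("grid/channel mismatch")
  stats$p_adj <- if (adjust == "bh") stats::p.adjust(stats$p, "BH") else stats$p
  stats$wavenumber <- grid
  sig <- stats$p_adj < alpha | (alpha == 1) # alpha = 1, raw: every channel
  stats$significant <- sig
  bands <- list()
  if (any(sig)) {
    idx <- which(sig)
    sgn <- sign(stats$mean_diff[idx])
    run_break <- c(TRUE, diff(idx) != 1L | sgn[-1] != sgn[-length(sgn)])
    run_id <- cumsum(run_break)
    for (r in unique(run_id)) {
      ch <- idx[run_id == r]
      peak <- ch[which.max(abs(stats$mean_diff[ch]))]
      wn <- grid[peak]
      near <- which.min(abs(assignments$wavenumber - wn))
      assign_txt <- if (abs(assignments$wavenumber[near] - wn) <= 10)
        assignments$assignment[near] else NA_character_
      bands[[length(bands) + 1L]] <- data.frame(
        wavenumber = wn,
        direction = if (stats$mean_diff[peak] >= 0) "increase" else "decrease",
        p = stats$p_adj[peak],
        mean_diff = stats$mean_diff[peak],
        start = grid[ch[1L]], end = grid[ch[length(ch)]],
        assignment = assign_txt)
    }
  }
  bands <- if (length(bands)) do.call(rbind, bands) else
    data.frame(wavenumber = numeric(0), direction = character(0),
               p = numeric(0), mean_diff = numeric(0), start = numeric(0),
               end = numeric(0), assignment = character(0))
  structure(list(channels = stats, bands = bands, alpha = alpha,
                 adjust = adjust),
            class = "band_report")
}

#' @export
print.band_report <- function(x, ...) {
  cat(sprintf("Band report: %d/%d channels significant at alpha = %g (%s)\n",
              sum(x$channels$significant), nrow(x$channels), x$alpha,
              if (x$adjust == "bh") "BH-adjusted" else "raw p"))
  if (nrow(x$bands)) {
    for (i in seq_len(nrow(x$bands)))
      cat(sprintf("  %4.0f cm^-1  %-8s p = %.3g  %s\n",
                  x$bands$wavenumber[i], x$bands$direction[i], x$bands$p[i],
                  ifelse(is.na(x$bands$assignment[i]), "",
                         x$bands$assignment[i])))
  } else cat("  no significant bands\n")
  invisible(x)
}

#' Band analysis of one disease class against control
#'
#' Convenience wrapper: extracts the class and control subsets from a
#' preprocessed set, runs [mann_whitney_per_channel()] and
#' [significant_bands()].
#'
#' @param set A labelled, preprocessed `spectra_set`.
#' @param class Disease class label.
#' @param control Control label, default `"control"`.
#' @param unit `"spectrum"` pools replicates as observations;
#'   `"sample"` averages replicates per sample first.
#' @inheritParams significant_bands
#' @return A `"band_report"`.
#' @export
band_analysis <- function(set, class, control = "control",
                          unit = c("spectrum", "sample"),
                          alpha = 0.05, adjust = c("none", "bh"),
                          assignments = raman_assignments()) {
  unit <- match.arg(unit)
  pick <- function(cl) {
    sub <- set[set$meta$class == cl]
    if (unit == "sample") {
      ids <- unique(sub$meta$sample_id)
      m <- t(vapply(ids, function(s)
        colMeans(sub$intensities[sub$meta$sample_id == s, , drop = FALSE]),
        numeric(length(set$grid))))
      m
    } else sub$intensities
  }
  st <- mann_whitney_per_channel(pick(class), pick(control))
  significant_bands(st, set$grid, alpha = alpha, adjust = adjust,
                    assignments = assignments)
}
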