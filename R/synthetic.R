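# Synthetic plasma-spectrum generator.
#
# Emulates the statistical structure of dried blood-plasma Raman spectra in
# the 500-1600 cm^-1 fingerprint region: a smooth fluorescence background,
# Gaussian protein/lipid/carotenoid bands, a per-sample multiplicative
# intensity factor shared by that sample's replicates, iid detector noise,
# rare single-channel cosmic-ray spikes and occasional whole-spectrum
# outliers. Class structure enters as signed fractional amplitude shifts of
# specific bands relative to control.

#' Gaussian band specification
#'
#' @param center Band center in cm^-1 (must lie on/within the grid range).
#' @param width Gaussian sigma in cm^-1 (> 0).
#' @param amplitude Control-class peak amplitude in counts (>= 0).
#' @return A one-row data frame.
#' @export
band_spec <- function(center, width, amplitude) {
  if (any(width <= 0)) stop2("band width must be > 0")
  if (any(amplitude < 0)) stop2("band amplitude must be >= 0")
  data.frame(center = center, width = width, amplitude = amplitude)
}

#' Synthetic dataset configuration
#'
#' Bundles everything [simulate_spectra()] needs. `effects` is the
#' class-by-band matrix of signed fractional amplitude changes relative to
#' control (rows named by class label, columns by band center); the control
#' row must be all zero.
#'
#' @param grid_start,grid_stop,grid_step Wavenumber grid in cm^-1
#'   (default 500-1600, step 1).
#' @param n_samples Named integer vector: samples per class.
#' @param n_replicates Replicate spectra (measurement regions) per sample.
#' @param bands Data frame of [band_spec()] rows.
#' @param effects Class-by-band effect matrix (fractions; control row zero).
#' @param baseline_coef Length-4 polynomial coefficients (counts) of the
#'   fluorescence background over the unit-scaled axis.
#' @param noise_sigma iid Gaussian noise SD in counts.
#' @param patient_sigma SD of the per-sample multiplicative signal factor.
#' @param spike_prob Per-channel cosmic-ray probability.
#' @param spike_amp Length-2 range of spike amplitudes in counts.
#' @param outlier_prob Per-spectrum probability of an additive-offset
#'   outlier spectrum.
#' @param outlier_offset Length-2 range of the outlier offset in counts.
#' @param seed Integer seed; identical config + seed gives bit-identical data.
#' @return An object of class `"synthetic_config"`.
#' @export
synthetic_config <- function(grid_start = 500, grid_stop = 1600, grid_step = 1,
                             n_samples, n_replicates = 5L,
                             bands, effects,
                             baseline_coef = c(800, 400, 300, 200),
                             noise_sigma = 8,
                             patient_sigma = 0.03,
                             spike_prob = 5e-4,
                             spike_amp = c(80, 800),
                             outlier_prob = 0.02,
                             outlier_offset = c(1500, 3000),
                             seed = 1L) {
  if (grid_step <= 0) stop2("grid_step must be > 0")
  if (grid_stop <= grid_start) stop2("empty wavenumber grid")
  if (n_replicates < 1L) stop2("n_replicates must be >= 1")
  probs <- c(spike_prob, outlier_prob)
  if (any(probs < 0 | probs > 1)) stop2("probabilities must lie in [0, 1]")
  if (noise_sigma < 0 || patient_sigma < 0) stop2("sigmas must be >= 0")
  if (any(bands$center < grid_start | bands$center > grid_stop))
    stop2("band centers must lie within the grid range")
  if (is.null(names(n_samples))) stop2("n_samples must be named by class")
  classes <- names(n_samples)
  if (!all(classes %in% subtype_levels()))
    stop2("unknown classes in n_samples")
  effects <- as.matrix(effects)
  if (!setequal(rownames(effects), classes))
    stop2("effects rows must match the classes in n_samples")
  if (ncol(effects) != nrow(bands))
    stop2("effects must have one column per band")
  if ("control" %in% classes && any(effects["control", ] != 0))
    stop2("control row of the effect matrix must be all zero")
  structure(list(
    grid_start = grid_start, grid_stop = grid_stop, grid_step = grid_step,
    n_samples = n_samples, n_replicates = as.integer(n_replicates),
    bands = bands, effects = effects[classes, , drop = FALSE],
    baseline_coef = baseline_coef, noise_sigma = noise_sigma,
    patient_sigma = patient_sigma, spike_prob = spike_prob,
    spike_amp = spike_amp, outlier_prob = outlier_prob,
    outlier_offset = outlier_offset, seed = as.integer(seed)
  ), class = "synthetic_config")
}

#' Study-design preset configuration
#'
#' Ready-made configuration mirroring the study design: 24 samples
#' (12 control, 3 per subtype), 5 replicate spectra per sample over
#' 500-1600 cm^-1, eight plasma bands (643, 757, 861, 878, 941, 1158, 1448,
#' 1518 cm^-1), and an effect matrix carrying the reported direction
#' pattern: HER2+ subtypes decrease at 1158, 1448 and 1518 cm^-1; HER2-
#' subtypes increase at 1518 and decrease at 941 and 1448 cm^-1; HR+
#' subtypes decrease at 941 and 1448 cm^-1. Effect magnitudes (0.10-0.22)
#' are engineering defaults — the directions, not the sizes, are the
#' study-reported facts.
#'
#' @param seed Integer seed stored in the config.
#' @return A [synthetic_config()].
#' @export
plasma_preset <- function(seed = 1L) {
  bands <- band_spec(
    center    = c(643, 757, 861, 878, 941, 1158, 1448, 1518),
    width     = c(9, 8, 10, 9, 10, 9, 14, 10),
    amplitude = c(220, 260, 300, 280, 320, 340, 520, 380)
  )
  cls <- subtype_levels()
  eff <- matrix(0, nrow = length(cls), ncol = nrow(bands),
                dimnames = list(cls, as.character(bands$center)))
  # HR+HER2- (Luminal A): HER2- pattern plus a collagen-band marker
  eff["HR+HER2-", c("861", "941", "1448", "1518")] <- c(-0.10, -0.15, -0.15, 0.22)
  # HR-HER2- (TNBC): HER2- pattern plus a tyrosine/phenylalanine marker
  eff["HR-HER2-", c("643", "941", "1448", "1518")] <- c(-0.10, -0.15, -0.15, 0.22)
  # HR+HER2+ (Luminal B): HER2+ pattern plus HR+ decrease at 941
  eff["HR+HER2+", c("757", "941", "1158", "1448", "1518")] <-
    c(-0.10, -0.15, -0.18, -0.18, -0.20)
  # HR-HER2+ (HER2-enriched): HER2+ pattern plus a proline/hydroxyproline marker
  eff["HR-HER2+", c("878", "1158", "1448", "1518")] <- c(-0.10, -0.18, -0.18, -0.20)
  n_samples <- c(12L, 3L, 3L, 3L, 3L)
  names(n_samples) <- cls
  synthetic_config(n_samples = n_samples, bands = bands, effects = eff,
                   seed = seed)
}

# Noise-free class mean curve (baseline + class-shifted bands) on the grid.
class_mean_curve <- function(config, class, grid) {
  t <- (grid - min(grid)) / (max(grid) - min(grid))
  baseline <- drop(cbind(1, t, t^2, t^3) %*% config$baseline_coef)
  delta <- config$effects[class, ]
  signal <- rep(0, length(grid))
  for (k in seq_len(nrow(config$bands))) {
    b <- config$bands[k, ]
    signal <- signal +
      b$amplitude * (1 + delta[k]) * exp(-(grid - b$center)^2 / (2 * b$width^2))
  }
  list(baseline = baseline, signal = signal, total = baseline + signal)
}

#' Generate a labelled synthetic dataset
#'
#' Draws `n_samples[class] * n_replicates` spectra per class on the config
#' grid. Each spectrum is
#' `baseline + (1 + u_sample) * signal_class + noise + spikes (+ offset)`,
#' where `u_sample ~ N(0, patient_sigma)` is shared by a sample's
#' replicates. Ground truth (injected spike channels, outlier spectrum ids,
#' the effect matrix and noise-free class mean curves) is attached as the
#' `truth` element for downstream recovery tests.
#'
#' @param config A [synthetic_config()].
#' @param seed Optional override of `config$seed`.
#' @return A [spectra_set()] with an extra `truth` list element.
#' @export
simulate_spectra <- function(config, seed = config$seed) {
  if (!inherits(config, "synthetic_config")) stop2("config must be a synthetic_config")
  set.seed(as.integer(seed))
  grid <- seq(config$grid_start, config$grid_stop, by = config$grid_step)
  nchan <- length(grid)
  classes <- names(config$n_samples)
  curves <- lapply(classes, function(cl) class_mean_curve(config, cl, grid))
  names(curves) <- classes

  rows <- list(); meta <- list()
  spikes <- list(); outliers <- character(0)
  sidx <- 0L
  for (cl in classes) {
    for (s in seq_len(config$n_samples[[cl]])) {
      sidx <- sidx + 1L
      sample_id <- sprintf("S%02d", sidx)
      u <- stats::rnorm(1L, 0, config$patient_sigma)
      for (r in seq_len(config$n_replicates)) {
        id <- sprintf("%s_r%d", sample_id, r)
        y <- curves[[cl]]$baseline + (1 + u) * curves[[cl]]$signal +
          stats::rnorm(nchan, 0, config$noise_sigma)
        hit <- which(stats::runif(nchan) < config$spike_prob)
        if (length(hit)) {
          y[hit] <- y[hit] +
            stats::runif(length(hit), config$spike_amp[1], config$spike_amp[2])
          spikes[[length(spikes) + 1L]] <-
            data.frame(spectrum_id = id, channel = hit, wavenumber = grid[hit])
        }
        if (stats::runif(1L) < config$outlier_prob) {
          y <- y + stats::runif(1L, config$outlier_offset[1], config$outlier_offset[2])
          outliers <- c(outliers, id)
        }
        rows[[length(rows) + 1L]] <- y
        meta[[length(meta) + 1L]] <- data.frame(
          spectrum_id = id, sample_id = sample_id,
          patient_id = sprintf("P%02d", sidx), replicate = r, class = cl)
      }
    }
  }
  set <- spectra_set(grid, do.call(rbind, rows), do.call(rbind, meta))
  set$truth <- list(
    spikes = if (length(spikes)) do.call(rbind, spikes) else
      data.frame(spectrum_id = character(0), channel = integer(0),
                 wavenumber = numeric(0)),
    outliers = outliers,
    effects = config$effects,
    class_means = lapply(curves, `[[`, "total"),
    baseline = curves[[1L]]$baseline
  )
  set
}

#' Write generator ground truth as JSON
#'
#' @param set A `spectra_set` returned by [simulate_spectra()].
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_truth_json <- function(set, path) {
  if (is.null(set$truth)) stop2("set carries no ground truth")
  jsonlite::write_json(
    list(spikes = set$truth$spikes, outliers = set$truth$outliers,
         effects = as.data.frame(set$truth$effects)),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
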