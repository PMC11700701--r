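#' Single Raman spectrum
#'
#' A minimal container for one spectrum: a strictly increasing wavenumber
#' axis (cm^-1), an intensity vector of equal length (arbitrary counts),
#' an identifier and optional sample metadata.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1. If supplied in
#'   descending order it is re-sorted ascending and the intensities permuted
#'   consistently.
#' @param intensities Numeric vector of intensities, same length.
#' @param id Character scalar, unique spectrum identifier.
#' @param sample_id,patient_id Character scalars (may be `NA` for unlabelled
#'   data).
#' @param replicate Integer replicate index (the study measured five regions
#'   per dried droplet).
#' @param class Class label, one of `"control"`, `"HR+HER2-"`, `"HR+HER2+"`,
#'   `"HR-HER2+"`, `"HR-HER2-"`, or `NA`.
#' @return An object of class `"raman_spectrum"`.
#' @export
raman_spectrum <- function(wavenumbers, intensities, id,
                           sample_id = NA_character_,
                           patient_id = NA_character_,
                           replicate = NA_integer_,
                           class = NA_character_) {
  wavenumbers <- as.numeric(wavenumbers)
  intensities <- as.numeric(intensities)
  if (length(wavenumbers) != length(intensities))
    stop2("spectrum '%s': axis and intensities differ in length", id)
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers)))
    stop2("spectrum '%s': non-finite wavenumbers", id)
  if (anyNA(intensities) || any(!is.finite(intensities)))
    stop2("spectrum '%s': non-finite intensities", id)
  ord <- order(wavenumbers)
  wavenumbers <- wavenumbers[ord]
  intensities <- intensities[ord]
  if (any(diff(wavenumbers) <= 0))
    stop2("spectrum '%s': wavenumber axis contains duplicates", id)
  if (!is.na(class) && !class %in% subtype_levels())
    stop2("spectrum '%s': unknown class label '%s'", id, class)
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         id = as.character(id), sample_id = sample_id,
         patient_id = patient_id,
         replicate = as.integer(replicate), class = class),
    class = "raman_spectrum"
  )
}

#' Wavenumber-aligned spectra collection
#'
#' The workhorse container passed between all pipeline stages: a common
#' wavenumber grid, an `n_spectra x n_channels` intensity matrix (one row
#' per spectrum) and a per-spectrum metadata table.
#'
#' @param grid Strictly increasing wavenumber vector (cm^-1).
#' @param intensities Numeric matrix, one row per spectrum, `length(grid)`
#'   columns.
#' @param meta Data frame with columns `spectrum_id`, `sample_id`,
#'   `patient_id`, `replicate`, `class` (one row per spectrum;
#'   `(sample_id, replicate)` pairs must be unique among labelled rows).
#' @return An object of class `"spectra_set"`.
#' @export
spectra_set <- function(grid, intensities, meta) {
  grid <- as.numeric(grid)
  intensities <- as.matrix(intensities)
  if (any(diff(grid) <= 0)) stop2("grid must be strictly increasing")
  if (ncol(intensities) != length(grid))
    stop2("intensity matrix has %d columns but the grid has %d channels",
          ncol(intensities), length(grid))
  need <- c("spectrum_id", "sample_id", "patient_id", "replicate", "class")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop2("metadata lacks columns: %s", paste(miss, collapse = ", "))
  meta <- as.data.frame(meta)[, need]
  if (nrow(meta) != nrow(intensities))
    stop2("metadata has %d rows for %d spectra", nrow(meta), nrow(intensities))
  if (anyDuplicated(meta$spectrum_id))
    stop2("duplicate spectrum ids: %s",
          paste(unique(meta$spectrum_id[duplicated(meta$spectrum_id)]), collapse = ", "))
  bad <- !is.na(meta$class) & !meta$class %in% subtype_levels()
  if (any(bad))
    stop2("unknown class labels: %s", paste(unique(meta$class[bad]), collapse = ", "))
  keyed <- !is.na(meta$sample_id) & !is.na(meta$replicate)
  key <- paste(meta$sample_id[keyed], meta$replicate[keyed])
  if (anyDuplicated(key))
    stop2("duplicate (sample_id, replicate) pairs")
  if (any(!is.finite(intensities)))
    stop2("non-finite intensities in spectra: %s",
          paste(meta$spectrum_id[rowSums(!is.finite(intensities)) > 0], collapse = ", "))
  rownames(intensities) <- meta$spectrum_id
  structure(list(grid = grid, intensities = intensities, meta = meta),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d spectra x %d channels (%g-%g cm^-1)\n",
              nrow(x$intensities), length(x$grid), min(x$grid), max(x$grid)))
  tab <- table(x$meta$class, useNA = "ifany")
  cat("classes:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
as.matrix.spectra_set <- function(x, ...) x$intensities

#' @export
`[.spectra_set` <- function(x, i, ...) {
  spectra_set(x$grid, x$intensities[i, , drop = FALSE], x$meta[i, , drop = FALSE])
}

#' Number of spectra in a set
#' @param set A `spectra_set`.
#' @return Integer count.
#' @export
n_spectra <- function(set) nrow(set$intensities)

#' Read spectra from CSV
#'
#' Reads intensity data in either the wide layout (first column
#' `wavenumber_cm1`, one column per spectrum id) or the long layout
#' (columns `spectrum_id`, `wavenumber_cm1`, `intensity`), joining per-spectrum
#' metadata from a separate CSV (`spectrum_id`, `sample_id`, `patient_id`,
#' `replicate`, `class`). Descending axes are re-sorted; non-finite values,
#' duplicate ids, unknown labels and missing metadata rows are errors.
#'
#' @param path Path to the intensity CSV.
#' @param format `"wide_csv"` or `"long_csv"`.
#' @param metadata Optional path to the metadata CSV.
#' @return A list of [raman_spectrum()] objects.
#' @export
read_spectra <- function(path, format = c("wide_csv", "long_csv"),
                         metadata = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop2("file not found: %s", path)
  df <- utils::read.csv(path, check.names = FALSE)
  meta <- NULL
  if (!is.null(metadata)) {
    if (!file.exists(metadata)) stop2("metadata file not found: %s", metadata)
    meta <- utils::read.csv(metadata, check.names = FALSE,
                            colClasses = c(replicate = "integer"))
  }
  lookup <- function(id) {
    if (is.null(meta)) {
      return(list(sample_id = NA_character_, patient_id = NA_character_,
                  replicate = NA_integer_, class = NA_character_))
    }
    row <- meta[meta$spectrum_id == id, , drop = FALSE]
    if (nrow(row) == 0L) stop2("no metadata row for spectrum '%s'", id)
    as.list(row[1L, c("sample_id", "patient_id", "replicate", "class")])
  }
  if (format == "wide_csv") {
    if (!"wavenumber_cm1" %in% names(df))
      stop2("wide CSV lacks a 'wavenumber_cm1' column: %s", path)
    ids <- setdiff(names(df), "wavenumber_cm1")
    if (anyDuplicated(ids)) stop2("duplicate spectrum ids in %s", path)
    lapply(ids, function(id) {
      m <- lookup(id)
      raman_spectrum(df$wavenumber_cm1, df[[id]], id, m$sample_id,
                     m$patient_id, m$replicate, m$class)
    })
  } else {
    need <- c("spectrum_id", "wavenumber_cm1", "intensity")
    if (!all(need %in% names(df)))
      stop2("long CSV needs columns %s", paste(need, collapse = ", "))
    ids <- unique(df$spectrum_id)
    lapply(ids, function(id) {
      sub <- df[df$spectrum_id == id, ]
      m <- lookup(id)
      raman_spectrum(sub$wavenumber_cm1, sub$intensity, id, m$sample_id,
                     m$patient_id, m$replicate, m$class)
    })
  }
}

#' Write a spectra set to CSV
#'
#' Writes the wide intensity CSV (`wavenumber_cm1` plus one column per
#' spectrum id) and the metadata CSV. Numeric values are written at full
#' double precision so a write/read round-trip is lossless.
#'
#' @param set A `spectra_set`.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"spectra"`.
#' @return Invisibly, the paths written.
#' @export
write_spectra <- function(set, dir, prefix = "spectra") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wide <- data.frame(wavenumber_cm1 = set$grid, check.names = FALSE)
  for (i in seq_len(n_spectra(set)))
    wide[[set$meta$spectrum_id[i]]] <- set$intensities[i, ]
  p1 <- file.path(dir, paste0(prefix, "_wide.csv"))
  utils::write.csv(format_full_precision(wide), p1, row.names = FALSE,
                   quote = FALSE)
  p2 <- file.path(dir, paste0(prefix, "_meta.csv"))
  utils::write.csv(set$meta, p2, row.names = FALSE, quote = FALSE)
  invisible(c(intensities = p1, metadata = p2))
}

#' Write spectra in long CSV layout
#'
#' @param spectra A list of [raman_spectrum()] objects or a `spectra_set`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_spectra_long <- function(spectra, path) {
  if (inherits(spectra, "spectra_set")) spectra <- as_spectrum_list(spectra)
  long <- do.call(rbind, lapply(spectra, function(s) {
    data.frame(spectrum_id = s$id, wavenumber_cm1 = s$wavenumbers,
               intensity = s$intensities)
  }))
  utils::write.csv(format_full_precision(long), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Split a spectra set into individual spectra
#' @param set A `spectra_set`.
#' @return List of [raman_spectrum()] objects.
#' @export
as_spectrum_list <- function(set) {
  lapply(seq_len(n_spectra(set)), function(i) {
    m <- set$meta[i, ]
    raman_spectrum(set$grid, set$intensities[i, ], m$spectrum_id,
                   m$sample_id, m$patient_id, m$replicate, m$class)
  })
}

#' Align spectra to a common wavenumber grid
#'
#' Linearly interpolates every spectrum onto `grid`. No extrapolation is
#' performed: each spectrum's axis must cover the grid, otherwise an error
#' names the offending spectra. Applying the function to spectra already on
#' the grid is an exact identity.
#'
#' @param spectra List of [raman_spectrum()] objects (or a single one).
#' @param grid Target wavenumber vector; default 500-1600 cm^-1 at
#'   1 cm^-1 spacing.
#' @return A [spectra_set()].
#' @export
align_to_grid <- function(spectra, grid = seq(500, 1600, by = 1)) {
  if (inherits(spectra, "raman_spectrum")) spectra <- list(spectra)
  bad <- vapply(spectra, function(s)
    min(s$wavenumbers) > min(grid) || max(s$wavenumbers) < max(grid),
    logical(1))
  if (any(bad))
    stop2("grid outside the support of spectra: %s",
          paste(vapply(spectra[bad], `[[`, character(1), "id"), collapse = ", "))
  mat <- t(vapply(spectra, function(s) {
    idx <- match(grid, s$wavenumbers)
    if (!anyNA(idx)) return(s$intensities[idx]) # exact identity when on-grid
    stats::approx(s$wavenumbers, s$intensities, xout = grid, method = "linear",
                  rule = 1)$y
  }, numeric(length(grid))))
  meta <- data.frame(
    spectrum_id = vapply(spectra, `[[`, character(1), "id"),
    sample_id = vapply(spectra, `[[`, character(1), "sample_id"),
    patient_id = vapply(spectra, `[[`, character(1), "patient_id"),
    replicate = vapply(spectra, `[[`, integer(1), "replicate"),
    class = vapply(spectra, `[[`, character(1), "class")
  )
  spectra_set(grid, mat, meta)
}

#' Read a complete spectra set from disk
#'
#' Convenience wrapper: reads a wide CSV plus metadata CSV (as written by
#' [write_spectra()]) and aligns to the file's own grid.
#'
#' @param intensities Path to the wide CSV.
#' @param metadata Path to the metadata CSV.
#' @return A [spectra_set()].
#' @export
read_spectra_set <- function(intensities, metadata) {
  sp <- read_spectra(intensities, "wide_csv", metadata)
  align_to_grid(sp, grid = sp[[1L]]$wavenumbers)
}
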