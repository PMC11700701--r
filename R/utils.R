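# Internal helpers shared across modules.

# Class vocabulary: healthy controls plus the four intrinsic subtypes coded
# by hormone-receptor (HR) and HER2 status.
subtype_levels <- function() {
  c("control", "HR+HER2-", "HR+HER2+", "HR-HER2+", "HR-HER2-")
}

stop2 <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

# Reflect-pad a vector by k points on each side (no repeated edge point).
reflect_pad <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  if (k >= n) stop2("padding width %d too large for length-%d vector", k, n)
  c(x[(k + 1L):2L], x, x[(n - 1L):(n - k)])
}

# Running window statistic with reflect padding; w must be odd.
# fun is one of "min", "max", "mean".
run_window <- function(x, w, fun = c("min", "max", "mean")) {
  fun <- match.arg(fun)
  w <- as.integer(w)
  if (w %% 2L == 0L) w <- w + 1L
  if (w <= 1L) return(x)
  n <- length(x)
  if (w > n) stop2("window of %d channels exceeds spectrum length %d", w, n)
  k <- (w - 1L) %/% 2L
  xp <- reflect_pad(x, k)
  m <- embed(xp, w) # n rows, w columns
  switch(fun,
    min  = do.call(pmin, lapply(seq_len(w), function(j) m[, j])),
    max  = do.call(pmax, lapply(seq_len(w), function(j) m[, j])),
    mean = rowMeans(m)
  )
}

# Format numeric columns at full double precision for lossless CSV round-trips.
format_full_precision <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  }
  df
}

# Derive a stage-specific 32-bit seed from a global one.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) + 97L * stage_index) %% .Machine$integer.max)
}
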