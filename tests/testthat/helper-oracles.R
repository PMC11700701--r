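# Independent brute-force oracles used across the suite. Each recomputes a
# quantity by direct enumeration or dense linear algebra, deliberately
# sharing no code with the package implementation.

# Morphological opening + moving-average baseline by explicit window scans
# with reflect padding (O(n * w)).
oracle_rolling_ball <- function(y, ball_width, ball_smooth) {
  if (ball_width %% 2 == 0) ball_width <- ball_width + 1
  if (ball_smooth %% 2 == 0 && ball_smooth > 1) ball_smooth <- ball_smooth + 1
  n <- length(y)
  pad <- function(x, k) c(x[(k + 1):2], x, x[(n - 1):(n - k)])
  scan <- function(x, w, f) {
    k <- (w - 1) / 2
    xp <- pad(x, k)
    vapply(seq_len(n), function(i) f(xp[i:(i + w - 1)]), numeric(1))
  }
  opened <- scan(scan(y, ball_width, min), ball_width, max)
  baseline <- if (ball_smooth > 1) scan(opened, ball_smooth, mean) else opened
  list(baseline = baseline, corrected = y - baseline, opening = opened)
}

# Dense direct solve of the penalized least-squares smoother.
oracle_whittaker <- function(y, lambda, order = 2) {
  n <- length(y)
  D <- diag(n)
  for (k in seq_len(order)) D <- diff(D)
  solve(diag(n) + lambda * t(D) %*% D, y)
}

# AUC as the concordant-pair (Mann-Whitney) statistic, ties counted half.
oracle_auc_pairs <- function(score, positive) {
  pos <- score[positive]
  neg <- score[!positive]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exact two-sided Mann-Whitney p-value by full enumeration of all
# choose(n1 + n2, n1) group assignments (untied data).
oracle_mw_exact <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_idx <- utils::combn(n1 + n2, n1)
  u_null <- apply(all_idx, 2, function(ix)
    sum(r[ix]) - n1 * (n1 + 1) / 2)
  mid <- n1 * n2 / 2
  mean(abs(u_null - mid) >= abs(u_obs - mid) - 1e-9)
}

# Brute-force complete-linkage agglomerator: keeps explicit member lists
# and rescans every cluster pair each step. Returns merge heights and the
# partition (as sorted member sets) after every merge.
oracle_complete_linkage <- function(points) {
  d <- as.matrix(dist(points))
  clusters <- as.list(seq_len(nrow(points)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      h <- max(d[clusters[[i]], clusters[[j]]])
      if (h < best[1]) best <- c(h, i, j)
    }
    heights <- c(heights, best[1])
    merged <- sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    clusters <- c(clusters[-c(best[2], best[3])], list(merged))
    partitions[[length(partitions) + 1]] <-
      lapply(clusters, sort)
  }
  list(heights = heights, partitions = partitions)
}

# Partition of leaves implied by a merge table after each merge row.
merge_table_partitions <- function(merge, n) {
  members <- list()
  clusters <- lapply(seq_len(n), identity)
  parts <- list()
  for (i in seq_len(nrow(merge))) {
    get <- function(k) if (k < 0) -k else members[[k]]
    m <- sort(c(get(merge[i, 1]), get(merge[i, 2])))
    members[[i]] <- m
    clusters <- Filter(function(cm) !any(cm %in% m), clusters)
    clusters <- c(clusters, list(m))
    parts[[i]] <- lapply(clusters, sort)
  }
  parts
}

# Canonical form of a partition for set comparison.
canon_partition <- function(p) {
  s <- vapply(p, function(m) paste(sort(m), collapse = ","), character(1))
  paste(sort(s), collapse = "|")
}

# Small labelled two-class set on a short grid for IO/model tests.
tiny_set <- function(n_per_class = 6, nchan = 40, seed = 1) {
  set.seed(seed)
  grid <- seq(500, 500 + nchan - 1)
  classes <- rep(c("control", "HR+HER2-"), each = n_per_class)
  shift <- ifelse(classes == "control", 0, 5)
  m <- t(vapply(seq_along(classes), function(i)
    shift[i] * exp(-(grid - 520)^2 / 50) + rnorm(nchan),
    numeric(nchan)))
  meta <- data.frame(
    spectrum_id = sprintf("sp%02d", seq_along(classes)),
    sample_id = sprintf("smp%02d", seq_along(classes)),
    patient_id = sprintf("p%02d", seq_along(classes)),
    replicate = 1L, class = classes)
  spectra_set(grid, m, meta)
}

# Small fast synthetic config (coarse grid, few samples) for property tests.
fast_config <- function(seed = 1, ...) {
  preset <- plasma_preset(seed = seed)
  args <- list(
    grid_step = 2,
    n_samples = c(control = 6L, `HR+HER2-` = 3L, `HR+HER2+` = 3L,
                  `HR-HER2+` = 3L, `HR-HER2-` = 3L),
    n_replicates = 3L,
    bands = preset$bands,
    effects = preset$effects,
    spike_prob = 0, outlier_prob = 0, seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  args$effects <- args$effects[names(args$n_samples), , drop = FALSE]
  do.call(synthetic_config, args)
}
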