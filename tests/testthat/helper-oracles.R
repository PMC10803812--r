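# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities by direct enumeration, never via the package's own
# code paths.

# Kendall tau-b by exhaustive pair counting with tie correction
tauBOracle <- function(x, y) {
  n <- length(x)
  conc <- disc <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(x[j] - x[i]) * sign(y[j] - y[i])
      if (s > 0) conc <- conc + 1L else if (s < 0) disc <- disc + 1L
    }
  }
  n0 <- n * (n - 1) / 2
  tx <- table(x)
  ty <- table(y)
  n1 <- sum(tx * (tx - 1) / 2)
  n2 <- sum(ty * (ty - 1) / 2)
  (conc - disc) / sqrt((n0 - n1) * (n0 - n2))
}

# Otsu threshold by direct exhaustive search: for every candidate t,
# compute the between-class variance from the raw sample means
otsuOracle <- function(v) {
  best_t <- NA_real_
  best <- -Inf
  n <- length(v)
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    bcv <- (length(lo) / n) * (length(hi) / n) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) {
      best <- bcv
      best_t <- t
    }
  }
  best_t
}

# Count voxels of a substrate-resting hemisphere by explicit triple loop
# over voxel centers (independent of the generator's vectorized rasterizer)
hemisphereVoxelOracle <- function(center_um, radius_um, nz, ny, nx,
                                  pixel_um, slice_um) {
  count <- 0L
  per_slice <- integer(nz)
  for (k in seq_len(nz)) {
    z <- (k - 0.5) * slice_um
    for (j in seq_len(ny)) {
      y <- (j - 0.5) * pixel_um
      for (i in seq_len(nx)) {
        x <- (i - 0.5) * pixel_um
        if ((x - center_um[1])^2 + (y - center_um[2])^2 + z^2 <= radius_um^2) {
          count <- count + 1L
          per_slice[k] <- per_slice[k] + 1L
        }
      }
    }
  }
  list(count = count, per_slice = per_slice)
}

# A small noise-free z-stack scenario shared by imaging tests
cleanStackScenario <- function(..., seed = 1L) {
  stackScenario(background_mean = 0, background_sd = 0, seed = seed, ...)
}
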