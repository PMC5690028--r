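# Shared fixtures and independent brute-force oracles. The oracles
# deliberately use plain per-pixel loops (no shared code with the package's
# vectorized paths).

random_grid <- function(nr, nc, seed, mask_frac = 1) {
  set.seed(seed)
  intens <- matrix(runif(nr * nc), nr, nc)
  mask <- matrix(TRUE, nr, nc)
  if (mask_frac < 1) {
    mask <- matrix(runif(nr * nc) < mask_frac, nr, nc)
    if (sum(mask) < 12) mask[seq_len(12)] <- TRUE
  }
  image_grid(intens, mask)
}

# Gram matrix by explicit pixel-by-pixel accumulation
oracle_gram <- function(basis) {
  idx <- which(as.vector(basis$mask))
  m <- basis$count
  A <- matrix(0, m, m)
  for (p in idx) {
    g <- basis$fields[p, ]
    for (i in seq_len(m)) for (j in seq_len(m)) A[i, j] <- A[i, j] + g[i] * g[j]
  }
  A
}

# Energy by explicit loop
oracle_energy <- function(grid, basis, labels, means, w) {
  e <- 0
  nr <- nrow(grid$intensities)
  for (r in seq_len(nr)) for (cl in seq_len(ncol(grid$intensities))) {
    if (!grid$mask[r, cl]) next
    p <- (cl - 1) * nr + r
    fs <- sum(w * basis$fields[p, ])
    e <- e + (grid$intensities[r, cl] - means[labels[r, cl]] - fs)^2
  }
  e
}

# w by generic dense least squares on the overdetermined pixel system
oracle_w <- function(grid, basis, labels, means) {
  mv <- as.vector(grid$mask)
  X <- basis$fields[mv, , drop = FALSE]
  y <- grid$intensities[mv] - means[labels[as.vector(grid$mask)]]
  qr.solve(X, y)
}

# per-class mean by explicit loop
oracle_means <- function(grid, basis, labels, w, n) {
  sums <- numeric(n); cnt <- integer(n)
  nr <- nrow(grid$intensities)
  for (r in seq_len(nr)) for (cl in seq_len(ncol(grid$intensities))) {
    if (!grid$mask[r, cl]) next
    p <- (cl - 1) * nr + r
    i <- labels[r, cl]
    sums[i] <- sums[i] + grid$intensities[r, cl] - sum(w * basis$fields[p, ])
    cnt[i] <- cnt[i] + 1L
  }
  sums / cnt
}

# membership by exhaustive per-pixel enumeration (smallest index on ties)
oracle_labels <- function(grid, basis, means, w) {
  nr <- nrow(grid$intensities)
  out <- matrix(NA_integer_, nr, ncol(grid$intensities))
  for (r in seq_len(nr)) for (cl in seq_len(ncol(grid$intensities))) {
    if (!grid$mask[r, cl]) next
    p <- (cl - 1) * nr + r
    fs <- sum(w * basis$fields[p, ])
    res <- (grid$intensities[r, cl] - means - fs)^2
    best <- 1L
    for (i in seq_along(res)) if (res[i] < res[best]) best <- i
    out[r, cl] <- best
  }
  out
}

roi_mean_loop <- function(image, roi) {
  m <- roi_mask(roi, dim(image))
  s <- 0; n <- 0L
  for (r in seq_len(nrow(image))) for (cl in seq_len(ncol(image)))
    if (m[r, cl]) { s <- s + image[r, cl]; n <- n + 1L }
  s / n
}

roi_sd_loop <- function(image, roi) {
  m <- roi_mask(roi, dim(image))
  v <- c()
  for (r in seq_len(nrow(image))) for (cl in seq_len(ncol(image)))
    if (m[r, cl]) v <- c(v, image[r, cl])
  sqrt(sum((v - sum(v) / length(v))^2) / length(v))
}
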