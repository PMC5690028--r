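#' Construct an image grid
#'
#' Wraps a reconstructed 2-D slice together with its object-support mask
#' \eqn{\Omega}. All solver operations act on masked pixels only; pixels
#' outside the mask (typically surrounding air) are ignored by the energy.
#'
#' @param intensities numeric matrix, the reconstructed slice `f(x)` in
#'   arbitrary reconstruction units. Must be finite at every masked pixel.
#' @param mask logical matrix of the same shape, `TRUE` inside the object
#'   support; `NULL` (default) uses all pixels; the string `"auto"` derives
#'   the support with [auto_mask()].
#' @return an object of class `emm_grid` with fields `intensities`, `mask`,
#'   `shape` and `intensity_scale` (the recorded `(min, max)` of the masked
#'   data, used for round-trip restoration after internal normalization).
#' @seealso [auto_mask()], [run_correction()]
#' @export
image_grid <- function(intensities, mask = NULL) {
  if (!is.matrix(intensities) || !is.numeric(intensities))
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  if (identical(mask, "auto")) mask <- auto_mask(intensities)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(intensities), ncol(intensities))
  if (!is.logical(mask) || !identical(dim(mask), dim(intensities)))
    stop("`mask` must be a logical matrix with the same shape as `intensities`",
         call. = FALSE)
  if (!any(mask)) stop("mask has no TRUE pixel", call. = FALSE)
  v <- intensities[mask]
  if (any(!is.finite(v)))
    stop("intensities must be finite at every masked pixel", call. = FALSE)
  structure(
    list(intensities = intensities,
         mask = mask,
         shape = dim(intensities),
         intensity_scale = c(min(v), max(v))),
    class = "emm_grid")
}

#' @export
print.emm_grid <- function(x, ...) {
  cat(sprintf("<emm_grid> %d x %d, %d masked pixels, intensity range [%g, %g]\n",
              x$shape[1], x$shape[2], sum(x$mask),
              x$intensity_scale[1], x$intensity_scale[2]))
  invisible(x)
}

# Affine map of masked intensities to [0, 1]; the original (min, max) stays in
# intensity_scale so results can be restored exactly. A constant image maps to 0.
normalize_grid <- function(grid) {
  sc <- grid$intensity_scale
  den <- if (sc[2] > sc[1]) sc[2] - sc[1] else 1
  g <- grid
  g$intensities <- (grid$intensities - sc[1]) / den
  g$intensity_scale <- sc
  g
}

# Width of the original intensity range (1 for a constant image, matching
# normalize_grid) -- the factor that converts normalized units back.
intensity_range <- function(grid) {
  sc <- grid$intensity_scale
  if (sc[2] > sc[1]) sc[2] - sc[1] else 1
}

#' Otsu's threshold
#'
#' Histogram-based threshold maximizing between-class variance; used by
#' [auto_mask()] to separate the object from surrounding air.
#'
#' @param x numeric vector or matrix of intensities.
#' @param nbins number of histogram bins.
#' @return the threshold value (on the intensity scale of `x`).
#' @export
otsu_threshold <- function(x, nbins = 256L) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  rng <- range(x)
  if (rng[1] == rng[2]) return(rng[1])
  br <- seq(rng[1], rng[2], length.out = nbins + 1L)
  h <- tabulate(findInterval(x, br, rightmost.closed = TRUE), nbins)
  p <- h / sum(h)
  mids <- (br[-1] + br[-length(br)]) / 2
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nbins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# 4-connected component labelling of a logical matrix via BFS.
# Returns an integer matrix (0 = background).
label_components <- function(m) {
  nr <- nrow(m); nc <- ncol(m); n <- nr * nc
  lab <- integer(n)
  mv <- as.vector(m)
  stack <- integer(n)
  nlab <- 0L
  for (start in seq_len(n)) {
    if (!mv[start] || lab[start] != 0L) next
    nlab <- nlab + 1L
    top <- 1L
    stack[1L] <- start
    lab[start] <- nlab
    while (top > 0L) {
      i <- stack[top]; top <- top - 1L
      r <- ((i - 1L) %% nr) + 1L
      if (r > 1L) {
        j <- i - 1L
        if (mv[j] && lab[j] == 0L) { lab[j] <- nlab; top <- top + 1L; stack[top] <- j }
      }
      if (r < nr) {
        j <- i + 1L
        if (mv[j] && lab[j] == 0L) { lab[j] <- nlab; top <- top + 1L; stack[top] <- j }
      }
      if (i > nr) {
        j <- i - nr
        if (mv[j] && lab[j] == 0L) { lab[j] <- nlab; top <- top + 1L; stack[top] <- j }
      }
      if (i <= n - nr) {
        j <- i + nr
        if (mv[j] && lab[j] == 0L) { lab[j] <- nlab; top <- top + 1L; stack[top] <- j }
      }
    }
  }
  matrix(lab, nr, nc)
}

# Fill interior holes: background components not touching the image border
# become foreground.
fill_holes <- function(m) {
  bg <- label_components(!m)
  border <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border <- border[border != 0L]
  m | (bg != 0L & !(bg %in% border))
}

#' Automatic object-support mask
#'
#' Default masking used by the correction pipeline when no mask is supplied:
#' Otsu threshold of the slice, then largest 4-connected component, then hole
#' filling. Fitting the smooth bias field across the object/air boundary
#' corrupts the polynomial fit, hence the mask.
#'
#' @param intensities numeric matrix.
#' @return logical matrix of the same shape.
#' @export
auto_mask <- function(intensities) {
  th <- otsu_threshold(intensities)
  m <- intensities > th
  if (!any(m)) return(matrix(TRUE, nrow(intensities), ncol(intensities)))
  lab <- label_components(m)
  counts <- tabulate(lab[lab > 0L])
  keep <- which.max(counts)
  fill_holes(lab == keep)
}
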