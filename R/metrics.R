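# ROI geometry. Pixel coordinates are 0-based throughout: a rectangle is
# half-open ([row0, row1) x [col0, col1)); circles/annuli include a pixel when
# the squared distance of its 0-based index to the center is <= radius^2
# (annulus: r_in^2 <= d^2 <= r_out^2).

#' Rectangular ROI (0-based, half-open)
#' @param row0,col0 top-left corner (0-based, inclusive).
#' @param row1,col1 bottom-right corner (exclusive).
#' @export
roi_rect <- function(row0, col0, row1, col1) {
  if (row1 <= row0 || col1 <= col0) stop("empty rectangle", call. = FALSE)
  structure(list(shape = "rect", row0 = row0, col0 = col0,
                 row1 = row1, col1 = col1), class = "emm_roi")
}

#' Circular ROI
#' @param row,col center (0-based pixel coordinates, may be fractional).
#' @param radius radius in pixels.
#' @export
roi_circle <- function(row, col, radius) {
  if (radius <= 0) stop("radius must be > 0", call. = FALSE)
  structure(list(shape = "circle", row = row, col = col, radius = radius),
            class = "emm_roi")
}

#' Annular ROI
#' @param row,col center (0-based).
#' @param r_in,r_out inner and outer radii in pixels (`r_in < r_out`).
#' @export
roi_annulus <- function(row, col, r_in, r_out) {
  if (r_out <= r_in || r_in < 0) stop("need 0 <= r_in < r_out", call. = FALSE)
  structure(list(shape = "annulus", row = row, col = col,
                 r_in = r_in, r_out = r_out), class = "emm_roi")
}

#' Rasterize an ROI
#' @param roi an `emm_roi`.
#' @param shape integer vector `(rows, cols)`.
#' @return logical matrix.
#' @export
roi_mask <- function(roi, shape) {
  nr <- shape[1]; nc <- shape[2]
  if (roi$shape == "rect") {
    if (roi$row0 < 0 || roi$col0 < 0 || roi$row1 > nr || roi$col1 > nc)
      stop("ROI exceeds image bounds", call. = FALSE)
    m <- matrix(FALSE, nr, nc)
    m[(roi$row0 + 1):roi$row1, (roi$col0 + 1):roi$col1] <- TRUE
    return(m)
  }
  ri <- matrix(0:(nr - 1), nr, nc)
  ci <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  d2 <- (ri - roi$row)^2 + (ci - roi$col)^2
  m <- switch(roi$shape,
    circle  = d2 <= roi$radius^2,
    annulus = d2 >= roi$r_in^2 & d2 <= roi$r_out^2,
    stop("unknown ROI shape ", roi$shape, call. = FALSE))
  if (!any(m)) stop("ROI rasterizes to zero pixels", call. = FALSE)
  m
}

#' Named set of evaluation ROIs
#'
#' @param center,edge ROIs for the cupping magnitude (must be disjoint).
#' @param background ROI for the CNR (outside the object), or `NULL`.
#' @param label free-text label.
#' @param shape optional image shape used to validate disjointness.
#' @export
roi_spec <- function(center, edge, background = NULL, label = "",
                     shape = NULL) {
  out <- structure(list(center = center, edge = edge,
                        background = background, label = label),
                   class = "emm_roi_spec")
  if (!is.null(shape) &&
      any(roi_mask(center, shape) & roi_mask(edge, shape)))
    stop("center and edge ROIs overlap", call. = FALSE)
  out
}

#' Default ROIs for the synthetic phantom geometries
#'
#' Center = disk of radius `0.1 R` at the phantom center; edge = annulus at
#' `0.8-0.9 R` (uniform disk) or `0.6-0.7 R` (three-tissue geometry, keeping
#' the edge ROI inside the soft-tissue zone so that center and edge sample
#' the same tissue and the cupping magnitude is not confounded with tissue
#' contrast); background = small square in the air corner.
#'
#' @param shape image shape `(rows, cols)`.
#' @param geometry `"uniform_disk"`, `"concentric_three_tissue"` or
#'   `"multi_insert"`.
#' @param radius object radius R in pixels (default `0.45 * min(shape)`, the
#'   phantom generator's default).
#' @export
default_rois <- function(shape, geometry = "uniform_disk", radius = NULL) {
  cr <- (shape[1] - 1) / 2
  cc <- (shape[2] - 1) / 2
  if (is.null(radius)) radius <- 0.45 * min(shape)
  edge <- if (geometry == "concentric_three_tissue")
    roi_annulus(cr, cc, 0.6 * radius, 0.7 * radius)
  else
    roi_annulus(cr, cc, 0.8 * radius, 0.9 * radius)
  s <- max(4L, as.integer(0.05 * min(shape)))
  roi_spec(center = roi_circle(cr, cc, 0.1 * radius),
           edge = edge,
           background = roi_rect(1, 1, 1 + s, 1 + s),
           label = geometry)
}

roi_stats <- function(image, roi) {
  v <- image[roi_mask(roi, dim(image))]
  c(mean = mean(v), sd = sqrt(mean((v - mean(v))^2)), n = length(v))
}

#' Cupping magnitude tau_cup
#'
#' `100 * (mean(edge) - mean(center)) / mean(edge)`, in percent; positive
#' for classic cupping (depressed center).
#'
#' @param image numeric matrix.
#' @param rois an [roi_spec()].
#' @return scalar percentage.
#' @export
tau_cup <- function(image, rois) {
  stopifnot(inherits(rois, "emm_roi_spec"))
  m_edge <- mean(image[roi_mask(rois$edge, dim(image))])
  m_center <- mean(image[roi_mask(rois$center, dim(image))])
  if (abs(m_edge) < .Machine$double.eps * 100)
    stop("undefined metric: edge ROI mean is zero", call. = FALSE)
  100 * (m_edge - m_center) / m_edge
}

#' Root-mean-square contrast
#'
#' The full image is affinely rescaled to `[0, 255]`, then the population
#' standard deviation (divisor MN) of the pixel intensities over `roi` is
#' returned. Invariant under any affine intensity map of the input.
#'
#' @param image numeric matrix.
#' @param roi optional `emm_roi` restricting the statistic (default: whole
#'   image).
#' @return non-negative scalar on the `[0, 255]` scale.
#' @export
rmsc <- function(image, roi = NULL) {
  rng <- range(image)
  img <- if (rng[2] > rng[1]) (image - rng[1]) / (rng[2] - rng[1]) * 255
         else image * 0
  v <- if (is.null(roi)) as.vector(img) else img[roi_mask(roi, dim(image))]
  sqrt(mean((v - mean(v))^2))
}

#' Contrast-to-noise ratio (package convention)
#'
#' CNR is reported in CBCT uniformity studies without a universal
#' definition. This package uses
#' `|mean(center) - mean(background)| / sd(background)` with the population
#' standard deviation. This is a package convention, not a value defined by
#' any single reference; treat cross-study CNR comparisons accordingly.
#'
#' @param image numeric matrix.
#' @param rois an [roi_spec()] with a non-`NULL` background ROI.
#' @return non-negative scalar.
#' @export
cnr <- function(image, rois) {
  stopifnot(inherits(rois, "emm_roi_spec"))
  if (is.null(rois$background))
    stop("CNR needs a background ROI", call. = FALSE)
  sc <- roi_stats(image, rois$center)
  sb <- roi_stats(image, rois$background)
  if (sb["sd"] <= 0)
    stop("undefined metric: background ROI has zero standard deviation",
         call. = FALSE)
  unname(abs(sc["mean"] - sb["mean"]) / sb["sd"])
}

#' Horizontal line profile
#'
#' Intensity sequence of one image row, for before/after comparison plots.
#'
#' @param image numeric matrix.
#' @param row 1-based row index; default: middle row.
#' @return numeric vector of length `ncol(image)`.
#' @export
horizontal_profile <- function(image, row = NULL) {
  if (is.null(row)) row <- (nrow(image) + 1L) %/% 2L
  if (row < 1 || row > nrow(image))
    stop(sprintf("row %d out of bounds [1, %d]", row, nrow(image)),
         call. = FALSE)
  image[row, ]
}

#' Full metrics report for one image
#'
#' @param image numeric matrix.
#' @param rois an [roi_spec()].
#' @param label row label for the report.
#' @return one-row `data.frame` with tau_cup, RMSC (whole image and per
#'   ROI), CNR (if a background ROI is given), and per-ROI mean/sd.
#' @export
metrics_report <- function(image, rois, label = "image") {
  sc <- roi_stats(image, rois$center)
  se <- roi_stats(image, rois$edge)
  out <- data.frame(
    label = label,
    tau_cup = tau_cup(image, rois),
    rmsc = rmsc(image),
    rmsc_center = rmsc(image, rois$center),
    rmsc_edge = rmsc(image, rois$edge),
    cnr = if (!is.null(rois$background)) cnr(image, rois) else NA_real_,
    center_mean = unname(sc["mean"]), center_sd = unname(sc["sd"]),
    edge_mean = unname(se["mean"]), edge_sd = unname(se["sd"]),
    stringsAsFactors = FALSE)
  if (!is.null(rois$background)) {
    sb <- roi_stats(image, rois$background)
    out$background_mean <- unname(sb["mean"])
    out$background_sd <- unname(sb["sd"])
  }
  out
}

#' Read an ROI specification from JSON
#'
#' The file holds named regions `center`, `edge` and optionally
#' `background`, each `{"shape": "rect"|"circle"|"annulus", ...}` with
#' 0-based pixel coordinates: rects use `origin = [row0, col0]` and
#' `extent = [rows, cols]` (half-open); circles `center = [row, col]`,
#' `radius`; annuli `center`, `r_in`, `r_out`.
#'
#' @param path JSON file path.
#' @return an [roi_spec()].
#' @export
read_roi_json <- function(path) {
  if (!file.exists(path)) stop("ROI file not found: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  parse1 <- function(r) {
    switch(r$shape,
      rect = roi_rect(r$origin[1], r$origin[2],
                      r$origin[1] + r$extent[1], r$origin[2] + r$extent[2]),
      circle = roi_circle(r$center[1], r$center[2], r$radius),
      annulus = roi_annulus(r$center[1], r$center[2], r$r_in, r$r_out),
      stop("unknown ROI shape in ", path, ": ", r$shape, call. = FALSE))
  }
  roi_spec(center = parse1(j$center), edge = parse1(j$edge),
           background = if (!is.null(j$background)) parse1(j$background),
           label = if (!is.null(j$label)) j$label else "")
}
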