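# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Specify a synthetic phantom
#'
#' Describes a phantom with the additive structure the correction model
#' assumes: piecewise-constant tissue image + smooth cupping field +
#' zero-mean Gaussian noise, with known ground truth for every component.
#'
#' Geometries (object support is a centred disk of radius
#' `radius_frac * min(shape)`):
#' \describe{
#'   \item{uniform_disk}{one tissue on the disk; water-phantom analogue
#'     (CTP486-like uniformity module).}
#'   \item{concentric_three_tissue}{skull-like slice: soft tissue inside
#'     `0.75 R`, a bone-like shell at `0.75-0.9 R`, a low-density background
#'     ring at `0.9-1 R`.}
#'   \item{multi_insert}{uniform disk with four small circular inserts of
#'     differing density at half radius.}
#' }
#'
#' The cupping field kinds: `"polynomial"` is
#' \eqn{a (x^2 + y^2 - 1)} in bounding-box-normalized coordinates — a
#' centre-depressed bowl lying inside the span of the degree-3 polynomial
#' basis (model-matched); `"radial_gaussian"` is
#' \eqn{-a \exp(-(x^2+y^2) / 2\sigma^2)}, outside the polynomial span
#' (model-mismatch stress case). When `tau_target` is given the amplitude
#' `a` is calibrated in closed form so the noise-free phantom has exactly
#' that pre-correction cupping magnitude at the geometry's default ROIs.
#'
#' @param shape image shape `(rows, cols)`, each >= 16.
#' @param geometry one of `"uniform_disk"`, `"concentric_three_tissue"`,
#'   `"multi_insert"`.
#' @param tissue_values true class intensities (label order is geometry
#'   order, see above); `NULL` uses per-geometry defaults.
#' @param cupping list with `kind` (`"polynomial"` or `"radial_gaussian"`),
#'   and either `amplitude` (intensity units) or `tau_target` (percent);
#'   `sigma` for the Gaussian kind (default 0.6, bounding-box units).
#' @param noise_sd standard deviation of the additive Gaussian noise, in
#'   the (order-1) intensity units of `tissue_values`.
#' @param seed integer fixing all randomness.
#' @param radius_frac object radius as a fraction of `min(shape)`.
#' @return a list of class `emm_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(229L, 229L), geometry = "uniform_disk",
                         tissue_values = NULL,
                         cupping = list(kind = "polynomial", tau_target = 20),
                         noise_sd = 0.01, seed = 1L, radius_frac = 0.45) {
  if (any(shape < 16)) stop("shape must be at least 16 x 16", call. = FALSE)
  geometry <- match.arg(geometry,
    c("uniform_disk", "concentric_three_tissue", "multi_insert"))
  defaults <- switch(geometry,
    uniform_disk = 0.7,
    concentric_three_tissue = c(0.5, 0.95, 0.15),  # soft, bone, ring
    multi_insert = c(0.5, 0.2, 0.35, 0.7, 0.9))
  if (is.null(tissue_values)) tissue_values <- defaults
  n_expected <- length(defaults)
  if (length(tissue_values) != n_expected)
    stop(sprintf("geometry '%s' needs %d tissue values, got %d",
                 geometry, n_expected, length(tissue_values)), call. = FALSE)
  if (is.null(cupping$kind)) cupping$kind <- "polynomial"
  cupping$kind <- match.arg(cupping$kind, c("polynomial", "radial_gaussian"))
  if (is.null(cupping$sigma)) cupping$sigma <- 0.6
  if (!is.finite(noise_sd) || noise_sd < 0)
    stop("noise_sd must be finite and >= 0", call. = FALSE)
  structure(list(shape = as.integer(shape), geometry = geometry,
                 tissue_values = as.numeric(tissue_values),
                 cupping = cupping, noise_sd = noise_sd,
                 seed = as.integer(seed), radius_frac = radius_frac),
            class = "emm_phantom_spec")
}

# Geometry rasterizer: labels (NA outside support) and the support mask.
phantom_geometry <- function(spec) {
  nr <- spec$shape[1]; nc <- spec$shape[2]
  cr <- (nr - 1) / 2; cc <- (nc - 1) / 2
  radius <- spec$radius_frac * min(spec$shape)
  ri <- matrix(0:(nr - 1), nr, nc)
  ci <- matrix(0:(nc - 1), nr, nc, byrow = TRUE)
  d <- sqrt((ri - cr)^2 + (ci - cc)^2)
  mask <- d <= radius
  labels <- matrix(NA_integer_, nr, nc)
  if (spec$geometry == "uniform_disk") {
    labels[mask] <- 1L
  } else if (spec$geometry == "concentric_three_tissue") {
    labels[mask & d < 0.75 * radius] <- 1L                      # soft tissue
    labels[mask & d >= 0.75 * radius & d < 0.9 * radius] <- 2L  # bone shell
    labels[mask & d >= 0.9 * radius] <- 3L                      # outer ring
  } else {  # multi_insert
    labels[mask] <- 1L
    ir <- 0.08 * radius
    ang <- c(0, 0.5, 1, 1.5) * pi
    for (k in seq_along(ang)) {
      icr <- cr + 0.5 * radius * sin(ang[k])
      icc <- cc + 0.5 * radius * cos(ang[k])
      labels[(ri - icr)^2 + (ci - icc)^2 <= ir^2] <- k + 1L
    }
    labels[!mask] <- NA_integer_
  }
  list(labels = labels, mask = mask, radius = radius)
}

# Unit-amplitude cupping shape s(x) on the full grid (bounding-box
# coordinates of the support mask); field = amplitude * s. Both kinds are
# <= 0 with minimum about -1 at the centre: classic depressed-centre cupping.
cupping_shape <- function(spec, mask) {
  co <- norm_coords(mask)
  r2 <- co$x^2 + co$y^2
  switch(spec$cupping$kind,
    polynomial = r2 - 1,
    radial_gaussian = -exp(-r2 / (2 * spec$cupping$sigma^2)))
}

# Closed-form amplitude so the noise-free phantom hits tau_target at the
# geometry's default ROIs: tau/100 = a (s_e - s_c) / (v + a s_e) where s_c,
# s_e are ROI means of the unit shape and v the (common) tissue value there.
calibrate_amplitude <- function(spec, geom, shape_field) {
  tt <- spec$cupping$tau_target
  rois <- default_rois(spec$shape, spec$geometry, radius = geom$radius)
  mc <- roi_mask(rois$center, spec$shape)
  me <- roi_mask(rois$edge, spec$shape)
  lc <- unique(geom$labels[mc]); le <- unique(geom$labels[me])
  if (length(lc) != 1L || length(le) != 1L || lc != le)
    stop("tau_target calibration needs center and edge ROIs in one tissue",
         call. = FALSE)
  v <- spec$tissue_values[lc]
  s_c <- mean(shape_field[mc]); s_e <- mean(shape_field[me])
  t <- tt / 100
  a <- t * v / ((s_e - s_c) - t * s_e)
  if (!is.finite(a) || a < 0)
    stop("tau_target calibration failed (unreachable target)", call. = FALSE)
  a
}

#' Generate a synthetic phantom with ground truth
#'
#' Builds `image = true_piecewise + true_bias + noise` exactly, with every
#' component returned. Deterministic given `spec$seed`.
#'
#' @param spec an [phantom_spec()].
#' @return a list of class `emm_phantom`: `image` (an [image_grid()] whose
#'   mask is the true object support), `true_piecewise`, `true_bias` (zero
#'   outside the support), `true_labels` (`emm_membership`), `noise`,
#'   `rois` (the geometry's [default_rois()]), `amplitude` (the realized
#'   cupping amplitude) and `spec`.
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "emm_phantom_spec"))
  geom <- phantom_geometry(spec)
  nr <- spec$shape[1]; nc <- spec$shape[2]
  fp <- matrix(0, nr, nc)
  fp[geom$mask] <- spec$tissue_values[geom$labels[geom$mask]]
  s <- cupping_shape(spec, geom$mask)
  amp <- if (!is.null(spec$cupping$amplitude)) spec$cupping$amplitude
         else if (!is.null(spec$cupping$tau_target))
           calibrate_amplitude(spec, geom, s)
         else 0
  fs <- matrix(0, nr, nc)
  fs[geom$mask] <- amp * s[geom$mask]
  noise <- if (spec$noise_sd > 0)
    with_seed(spec$seed, matrix(stats::rnorm(nr * nc, sd = spec$noise_sd), nr, nc))
  else matrix(0, nr, nc)
  img <- fp + fs + noise
  structure(
    list(image = image_grid(img, geom$mask),
         true_piecewise = fp, true_bias = fs, noise = noise,
         true_labels = new_membership(geom$labels, length(spec$tissue_values)),
         rois = default_rois(spec$shape, spec$geometry, radius = geom$radius),
         amplitude = amp, spec = spec),
    class = "emm_phantom")
}

#' @export
print.emm_phantom <- function(x, ...) {
  cat(sprintf("<emm_phantom> %s %dx%d, %d tissue(s), cupping %s (a=%.4g), noise sd %g, seed %d\n",
              x$spec$geometry, x$spec$shape[1], x$spec$shape[2],
              length(x$spec$tissue_values), x$spec$cupping$kind,
              x$amplitude, x$spec$noise_sd, x$spec$seed))
  invisible(x)
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_permutations(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# Fraction of masked pixels correctly labelled under the best class
# permutation (labels are identifiable only up to relabelling).
best_label_accuracy <- function(est, truth, mask) {
  a <- est[mask]; b <- truth[mask]
  n <- max(max(a), max(b))
  if (n > 8L) stop("label matching supports at most 8 classes", call. = FALSE)
  best <- 0
  for (p in all_permutations(n)) {
    acc <- mean(unlist(p)[a] == b)
    if (acc > best) best <- acc
  }
  best
}

#' Ground-truth recovery experiment
#'
#' Generates a phantom, runs [run_correction()], and scores the estimate
#' against the known truth. The bias-field error is reported on the
#' solver's normalized `[0, 1]` intensity scale after mask-mean-centring
#' both fields (the decomposition is identifiable only up to a constant).
#'
#' @param spec an [phantom_spec()].
#' @param config an [solver_config()].
#' @return a list of class `emm_recovery`: `bias_rmse` (normalized units),
#'   `label_accuracy` (best-permutation match, `NA` when the solver class
#'   count differs from the truth), `tau_before`, `tau_after`,
#'   `tau_reduction_pct`, `iterations`, `converged`, `energy_trace`, plus
#'   the `phantom` and `result`.
#' @export
recovery_experiment <- function(spec, config = solver_config()) {
  ph <- make_phantom(spec)
  res <- run_correction(ph$image, config)
  mask <- ph$image$mask
  scale <- intensity_range(ph$image)
  eb <- res$bias_field[mask]; tb <- ph$true_bias[mask]
  eb <- eb - mean(eb); tb <- tb - mean(tb)
  bias_rmse <- sqrt(mean((eb - tb)^2)) / scale
  acc <- if (config$n_tissues == ph$true_labels$count)
    best_label_accuracy(res$state$membership$labels, ph$true_labels$labels, mask)
  else NA_real_
  tb0 <- tau_cup(ph$image$intensities, ph$rois)
  ta <- tau_cup(res$corrected, ph$rois)
  structure(
    list(bias_rmse = bias_rmse, label_accuracy = acc,
         tau_before = tb0, tau_after = ta,
         tau_reduction_pct = 100 * (tb0 - ta) / tb0,
         iterations = res$iterations, converged = res$converged,
         energy_trace = res$energy_trace,
         phantom = ph, result = res),
    class = "emm_recovery")
}

#' @export
print.emm_recovery <- function(x, ...) {
  cat(sprintf(paste0(
    "<emm_recovery> bias RMSE %.3g (normalized), label accuracy %s\n",
    "  tau_cup %.2f%% -> %.2f%% (%.1f%% reduction), %d iteration(s)%s\n"),
    x$bias_rmse,
    if (is.na(x$label_accuracy)) "NA" else sprintf("%.1f%%", 100 * x$label_accuracy),
    x$tau_before, x$tau_after, x$tau_reduction_pct, x$iterations,
    if (x$converged) "" else " [not converged]"))
  invisible(x)
}
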