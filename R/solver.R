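#' Solver configuration
#'
#' Collects the tunable parameters of the alternating-minimization solver.
#'
#' @param n_tissues number of tissue classes N (>= 1). Use 1 for uniformity
#'   phantoms, 3 for skull/bone-like slices.
#' @param degree polynomial degree of the bias-field basis (default 3, i.e.
#'   10 basis functions).
#' @param eps convergence tolerance on the Euclidean norm of the change in
#'   the tissue-mean vector, on the internal normalized `[0, 1]` intensity
#'   scale (default 0.001).
#' @param max_iter safety bound on iterations (default 50; typical runs
#'   converge in well under 15).
#' @param orthonormalize logical; orthonormalize the basis before solving.
#' @param init_means optional numeric vector of initial tissue means on the
#'   normalized `[0, 1]` scale; overrides the quantile initialization and is
#'   used in the order given (not re-sorted).
#' @param seed integer; reserved for stochastic initializers (the default
#'   quantile initialization is deterministic).
#' @param verbose logical; log iteration index, energy and `||delta c||`.
#' @return a list of class `emm_config`.
#' @export
solver_config <- function(n_tissues = 3L, degree = 3L, eps = 1e-3,
                          max_iter = 50L, orthonormalize = FALSE,
                          init_means = NULL, seed = 1L, verbose = FALSE) {
  if (n_tissues < 1) stop("`n_tissues` must be >= 1", call. = FALSE)
  if (eps <= 0) stop("`eps` must be > 0", call. = FALSE)
  if (max_iter < 1) stop("`max_iter` must be >= 1", call. = FALSE)
  structure(list(n_tissues = as.integer(n_tissues), degree = as.integer(degree),
                 eps = eps, max_iter = as.integer(max_iter),
                 orthonormalize = isTRUE(orthonormalize),
                 init_means = init_means, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "emm_config")
}

new_membership <- function(labels, count) {
  structure(list(labels = labels, count = as.integer(count)),
            class = "emm_membership")
}

# state: membership, means, coefficients, energy_trace, iteration
new_state <- function(membership, means, coefficients, energy_trace,
                      iteration = 0L) {
  structure(list(membership = membership, means = means,
                 coefficients = coefficients, energy_trace = energy_trace,
                 iteration = as.integer(iteration)),
            class = "emm_state")
}

check_dims <- function(grid, basis, means = NULL, coefficients = NULL,
                       membership = NULL) {
  if (!is.null(basis) && !identical(dim(basis$mask), grid$shape))
    stop("basis and grid shapes differ", call. = FALSE)
  if (!is.null(coefficients) && length(coefficients) != basis$count)
    stop(sprintf("coefficient vector has length %d but basis has %d functions",
                 length(coefficients), basis$count), call. = FALSE)
  if (!is.null(membership) && !identical(dim(membership$labels), grid$shape))
    stop("membership and grid shapes differ", call. = FALSE)
  if (!is.null(membership) && !is.null(means) &&
      membership$count != length(means))
    stop("membership class count and means length differ", call. = FALSE)
  invisible(TRUE)
}

#' Evaluate the decomposition energy
#'
#' The least-squares energy
#' \deqn{F(u, c, w) = \sum_{x \in \Omega} (f(x) - c_{l(x)} - w^T G(x))^2}
#' where `l(x)` is the tissue label of pixel `x`. Each alternating update
#' minimizes this energy exactly in one variable block, so `F` is
#' non-increasing along the iteration.
#'
#' @param grid an [image_grid()].
#' @param basis an `emm_basis` on the same grid.
#' @param state an `emm_state`, or any list with elements `membership`,
#'   `means`, `coefficients`.
#' @return non-negative scalar.
#' @export
evaluate_energy <- function(grid, basis, state) {
  check_dims(grid, basis, state$means, state$coefficients, state$membership)
  mv <- as.vector(grid$mask)
  f <- grid$intensities[mv]
  lab <- state$membership$labels[mv]
  fs <- drop(basis_on_mask(basis) %*% state$coefficients)
  sum((f - state$means[lab] - fs)^2)
}

#' Update the bias-field coefficients (w-step)
#'
#' Given the membership map and tissue means, the energy is a convex
#' quadratic in `w`; the unique minimizer solves the normal equations
#' \eqn{A w = v} with \eqn{A = \sum G G^T} (the basis Gram matrix) and
#' \eqn{v = \sum G(x) (f(x) - c_{l(x)})} over masked pixels.
#'
#' @inheritParams evaluate_energy
#' @param membership an `emm_membership`.
#' @param means numeric vector of tissue means.
#' @return numeric vector of length `basis$count`.
#' @export
update_coefficients <- function(grid, basis, membership, means) {
  check_dims(grid, basis, means, membership = membership)
  mv <- as.vector(grid$mask)
  gm <- basis_on_mask(basis)
  r <- grid$intensities[mv] - means[membership$labels[mv]]
  v <- drop(crossprod(gm, r))
  ch <- tryCatch(chol(basis$gram), error = function(e) e)
  if (inherits(ch, "error"))
    stop("rank deficiency: Gram matrix is singular; reduce the basis degree or enlarge the mask",
         call. = FALSE)
  drop(backsolve(ch, backsolve(ch, v, transpose = TRUE)))
}

#' Update the tissue means (c-step)
#'
#' Minimizing the energy in `c` with `u`, `w` fixed gives, for each class i,
#' the mean of the bias-corrected intensities \eqn{f - \hat f_s} over the
#' pixels labelled i. A class with no pixels keeps its previous mean (guard
#' against division by zero).
#'
#' @inheritParams update_coefficients
#' @param coefficients numeric vector, current bias coefficients `w`.
#' @param previous optional numeric vector of current means, required when a
#'   class may be empty.
#' @return numeric vector of length `membership$count`.
#' @export
update_means <- function(grid, basis, membership, coefficients,
                         previous = NULL) {
  check_dims(grid, basis, previous, coefficients, membership)
  mv <- as.vector(grid$mask)
  lab <- membership$labels[mv]
  val <- grid$intensities[mv] - drop(basis_on_mask(basis) %*% coefficients)
  n <- membership$count
  sums <- vapply(seq_len(n), function(i) sum(val[lab == i]), 0)
  cnt <- tabulate(lab, n)
  out <- sums / cnt
  if (any(cnt == 0L)) {
    if (is.null(previous))
      stop("empty tissue class and no `previous` means to retain", call. = FALSE)
    out[cnt == 0L] <- previous[cnt == 0L]
  }
  out
}

#' Update the tissue membership map (u-step)
#'
#' Each masked pixel is assigned the class minimizing the squared residual
#' \eqn{(f(x) - c_i - w^T G(x))^2}; ties go to the smallest class index.
#' This is the exact minimizer of the energy in `u` given `(c, w)`.
#'
#' @inheritParams update_coefficients
#' @param means numeric vector of tissue means.
#' @param coefficients numeric vector of bias coefficients.
#' @return an `emm_membership`; labels are `NA` outside the mask.
#' @export
update_membership <- function(grid, basis, means, coefficients) {
  check_dims(grid, basis, means, coefficients)
  if (length(means) < 1L) stop("need at least one tissue class", call. = FALSE)
  mv <- as.vector(grid$mask)
  b <- grid$intensities[mv] - drop(basis_on_mask(basis) %*% coefficients)
  res2 <- (outer(b, means, "-"))^2
  lab <- max.col(-res2, ties.method = "first")
  labels <- matrix(NA_integer_, grid$shape[1], grid$shape[2])
  labels[grid$mask] <- lab
  new_membership(labels, length(means))
}

#' Initialize the solver state
#'
#' Tissue means start at evenly spaced quantiles (levels `(i - 0.5) / N`) of
#' the masked intensities, sorted ascending; coefficients start at zero; the
#' membership map follows from the initial `(c, w)`. Deterministic given the
#' grid and `n_tissues`.
#'
#' @inheritParams evaluate_energy
#' @param n_tissues number of classes N.
#' @param init_means optional explicit initial means (used as given).
#' @return an `emm_state` with the initial energy as first trace entry.
#' @export
initialize_state <- function(grid, basis, n_tissues, init_means = NULL) {
  check_dims(grid, basis)
  n_tissues <- as.integer(n_tissues)
  if (n_tissues < 1L) stop("`n_tissues` must be >= 1", call. = FALSE)
  f <- grid$intensities[grid$mask]
  if (length(unique(f)) < n_tissues)
    stop(sprintf(
      "degenerate input: %d tissue classes requested but only %d distinct masked intensities",
      n_tissues, length(unique(f))), call. = FALSE)
  if (is.null(init_means)) {
    means <- unname(stats::quantile(f, probs = (seq_len(n_tissues) - 0.5) / n_tissues))
  } else {
    if (length(init_means) != n_tissues)
      stop("`init_means` length must equal `n_tissues`", call. = FALSE)
    means <- as.numeric(init_means)
  }
  w <- rep(0, basis$count)
  u <- update_membership(grid, basis, means, w)
  st <- new_state(u, means, w, energy_trace = NA_real_, iteration = 0L)
  st$energy_trace <- evaluate_energy(grid, basis, st)
  st
}

#' Run the cupping-artifact correction
#'
#' Decomposes a reconstructed slice into a piecewise-constant tissue image
#' plus a smooth additive bias (cupping) field and subtracts the latter.
#' Intensities are internally normalized to `[0, 1]` over the mask (so `eps`
#' is scale-free), then the solver alternates the exact updates
#' w-step, c-step, u-step until the Euclidean change in the tissue means
#' falls below `eps` or `max_iter` is reached. Because the basis spans
#' constants, the decomposition is determined only up to a constant traded
#' between `c` and the field; the estimated field is recentred to zero mean
#' over the mask so the corrected image preserves the original mean
#' intensity (CT-number calibration).
#'
#' @param grid an [image_grid()].
#' @param config an [solver_config()].
#' @param basis optional prebuilt `emm_basis` (built from `config$degree`
#'   when omitted).
#' @return an object of class `emm_result`:
#' \describe{
#'   \item{bias_field}{estimated cupping field, original units, zero mean
#'     over the mask, zero outside the mask}
#'   \item{piecewise_image}{fitted tissue image (`NA` outside the mask)}
#'   \item{corrected}{`intensities - bias_field`}
#'   \item{bias_offset}{the mask-mean constant removed from the raw fitted
#'     field; `corrected + bias_field` reproduces the input exactly}
#'   \item{converged, iterations, final_energy, energy_trace, state}{solver
#'     diagnostics (energies on the normalized scale)}
#' }
#' @export
run_correction <- function(grid, config = solver_config(), basis = NULL) {
  stopifnot(inherits(grid, "emm_grid"))
  ng <- normalize_grid(grid)
  if (is.null(basis)) basis <- build_polynomial_basis(ng, config$degree)
  if (config$orthonormalize) basis <- orthonormalize(basis)
  st <- initialize_state(ng, basis, config$n_tissues, config$init_means)
  converged <- FALSE
  for (it in seq_len(config$max_iter)) {
    c_prev <- st$means
    st$coefficients <- update_coefficients(ng, basis, st$membership, st$means)
    st$means <- update_means(ng, basis, st$membership, st$coefficients,
                             previous = st$means)
    st$membership <- update_membership(ng, basis, st$means, st$coefficients)
    e <- evaluate_energy(ng, basis, st)
    if (!is.finite(e))
      stop(sprintf("numerical failure: non-finite energy at iteration %d", it),
           call. = FALSE)
    st$energy_trace <- c(st$energy_trace, e)
    st$iteration <- it
    dc <- sqrt(sum((st$means - c_prev)^2))
    if (config$verbose)
      message(sprintf("iter %2d  energy %.6e  |dc| %.3e", it, e, dc))
    if (dc < config$eps) { converged <- TRUE; break }
  }
  scale <- intensity_range(grid)
  mv <- as.vector(grid$mask)
  fs_norm <- drop(basis$fields %*% st$coefficients)
  offset_norm <- mean(fs_norm[mv])
  bias <- matrix(0, grid$shape[1], grid$shape[2])
  bias[grid$mask] <- (fs_norm[mv] - offset_norm) * scale
  piecewise <- matrix(NA_real_, grid$shape[1], grid$shape[2])
  piecewise[grid$mask] <- (st$means[st$membership$labels[grid$mask]] +
                             offset_norm) * scale + grid$intensity_scale[1]
  structure(
    list(bias_field = bias,
         piecewise_image = piecewise,
         corrected = grid$intensities - bias,
         bias_offset = offset_norm * scale,
         converged = converged,
         iterations = st$iteration,
         final_energy = st$energy_trace[length(st$energy_trace)],
         energy_trace = st$energy_trace,
         state = st,
         config = config),
    class = "emm_result")
}

#' @export
print.emm_result <- function(x, ...) {
  cat(sprintf("<emm_result> %s after %d iteration(s), final energy %.4e\n",
              if (x$converged) "converged" else "stopped (max_iter)",
              x$iterations, x$final_energy))
  invisible(x)
}
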