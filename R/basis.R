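# Normalized coordinates over the mask bounding box: each axis affinely
# mapped to [-1, 1]. Raw pixel indices (up to several hundred) make the
# degree-3 Gram matrix catastrophically ill-conditioned; this keeps monomial
# values in [-1, 1].
norm_coords <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  rows <- which(rowSums(mask) > 0)
  cols <- which(colSums(mask) > 0)
  r0 <- min(rows); r1 <- max(rows)
  c0 <- min(cols); c1 <- max(cols)
  sr <- if (r1 > r0) (r1 - r0) / 2 else 1
  sc <- if (c1 > c0) (c1 - c0) / 2 else 1
  y <- (seq_len(nr) - (r0 + r1) / 2) / sr
  x <- (seq_len(nc) - (c0 + c1) / 2) / sc
  list(x = matrix(x, nr, nc, byrow = TRUE),  # along columns
       y = matrix(y, nr, nc))                # along rows
}

# Monomial exponent table for total degree <= degree, ordered by total degree
# then, within a degree, by increasing power of y (x^d, x^(d-1) y, ..., y^d).
monomial_exponents <- function(degree) {
  ex <- do.call(rbind, lapply(0:degree, function(d)
    cbind(a = d - (0:d), b = 0:d)))
  ex
}

#' Build a 2-D polynomial basis on an image grid
#'
#' Constructs the complete set of bivariate monomials \eqn{x^a y^b} with
#' \eqn{a + b \le} `degree`, evaluated on coordinates affinely normalized to
#' \eqn{[-1, 1]} over the mask's bounding box, together with the Gram matrix
#' \eqn{A = \sum_{x \in \Omega} G(x) G(x)^T} over masked pixels. The default
#' degree 3 yields the 10-function basis used for the smooth bias field.
#'
#' @param grid an [image_grid()].
#' @param degree non-negative integer, maximum total degree.
#' @return an object of class `emm_basis`: `fields` (pixels-by-M matrix of
#'   basis values over the full grid, column-major pixel order), `count` (M),
#'   `gram` (M-by-M), `exponents`, `degree`, `mask` and `orthonormalized`.
#' @examples
#' g <- image_grid(matrix(rnorm(64), 8, 8))
#' b <- build_polynomial_basis(g, 3)
#' b$count  # 10
#' @export
build_polynomial_basis <- function(grid, degree = 3L) {
  stopifnot(inherits(grid, "emm_grid"))
  if (length(degree) != 1L || is.na(degree) || degree < 0 || degree != floor(degree))
    stop("`degree` must be a non-negative integer", call. = FALSE)
  ex <- monomial_exponents(degree)
  m <- nrow(ex)
  npix <- sum(grid$mask)
  if (npix < m)
    stop(sprintf(
      "rank deficiency: mask has %d pixels but the degree-%d basis has %d functions",
      npix, degree, m), call. = FALSE)
  co <- norm_coords(grid$mask)
  xv <- as.vector(co$x); yv <- as.vector(co$y)
  fields <- matrix(0, length(xv), m)
  for (k in seq_len(m)) fields[, k] <- xv^ex[k, "a"] * yv^ex[k, "b"]
  gm <- fields[as.vector(grid$mask), , drop = FALSE]
  structure(
    list(fields = fields, count = m, gram = crossprod(gm),
         exponents = ex, degree = as.integer(degree),
         mask = grid$mask, orthonormalized = FALSE),
    class = "emm_basis")
}

#' @export
print.emm_basis <- function(x, ...) {
  cat(sprintf("<emm_basis> degree %d, M = %d%s\n", x$degree, x$count,
              if (x$orthonormalized) " (orthonormalized)" else ""))
  invisible(x)
}

# Basis values restricted to masked pixels (pixels-by-M).
basis_on_mask <- function(basis) {
  basis$fields[as.vector(basis$mask), , drop = FALSE]
}

#' Orthonormalize a basis over its mask
#'
#' Returns a basis spanning the same function space whose Gram matrix over
#' the masked pixels is the identity (Cholesky-based Gram-Schmidt with
#' respect to the masked-pixel inner product). Optional conditioning aid;
#' the default solver path uses the raw polynomial basis.
#'
#' @param basis an `emm_basis`.
#' @return an `emm_basis` with `orthonormalized = TRUE` and identity `gram`.
#' @export
orthonormalize <- function(basis) {
  stopifnot(inherits(basis, "emm_basis"))
  r <- tryCatch(chol(basis$gram), error = function(e) e)
  if (inherits(r, "error")) {
    # chol reports "the leading minor of order k"; surface the offending index
    k <- suppressWarnings(as.integer(gsub("\\D", "", conditionMessage(r))))
    stop(sprintf("rank deficiency: basis function %s makes the Gram matrix singular",
                 if (length(k) && !is.na(k)) k else "?"), call. = FALSE)
  }
  out <- basis
  out$fields <- t(backsolve(r, t(basis$fields), transpose = TRUE))
  gm <- out$fields[as.vector(out$mask), , drop = FALSE]
  out$gram <- crossprod(gm)
  out$orthonormalized <- TRUE
  out
}
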