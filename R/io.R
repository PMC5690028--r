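# Supported formats. The solver only needs a numeric matrix, so I/O is kept
# lossless and dependency-free:
#   * raw float (.raw/.bin) + JSON sidecar: {"shape": [rows, cols] or
#     [slices, rows, cols], "dtype": "float32"|"float64", "order": "F"|"C"}.
#     The sidecar lives at <path>.json (or <stem>.json). float64 round-trips
#     doubles exactly; float32 to single precision.
#   * CSV/TSV numeric matrices (one row per image row, no header).
# Masks travel the same way (nonzero = TRUE).

sidecar_path <- function(path) {
  cands <- c(paste0(path, ".json"), paste0(sub("\\.[^.]+$", "", path), ".json"))
  hit <- cands[file.exists(cands)]
  if (length(hit) == 0L)
    stop(sprintf("cannot read '%s': missing JSON sidecar (looked for %s)",
                 path, paste(cands, collapse = ", ")), call. = FALSE)
  hit[1L]
}

guess_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    csv = "csv", tsv = "tsv", txt = "tsv",
    raw = "raw", bin = "raw", dat = "raw",
    stop(sprintf("cannot read '%s': unknown format '.%s' (supported: csv, tsv, raw/bin + JSON sidecar)",
                 path, ext), call. = FALSE))
}

read_raw_image <- function(path) {
  sc <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  shape <- as.integer(sc$shape)
  if (!length(shape) %in% 2:3)
    stop(sprintf("cannot read '%s': sidecar shape must have 2 or 3 entries", path),
         call. = FALSE)
  dtype <- if (is.null(sc$dtype)) "float64" else sc$dtype
  size <- switch(dtype, float32 = 4L, float64 = 8L,
    stop(sprintf("cannot read '%s': unsupported dtype '%s'", path, dtype),
         call. = FALSE))
  n <- prod(shape)
  con <- file(path, "rb"); on.exit(close(con))
  v <- readBin(con, what = "numeric", n = n, size = size, endian = "little")
  if (length(v) != n)
    stop(sprintf("cannot read '%s': expected %d values, file holds %d",
                 path, n, length(v)), call. = FALSE)
  order <- if (is.null(sc$order)) "F" else sc$order
  to_mat <- function(vals, nr, nc) {
    if (order == "C") t(matrix(vals, nc, nr)) else matrix(vals, nr, nc)
  }
  if (length(shape) == 2L) return(to_mat(v, shape[1], shape[2]))
  ns <- shape[1]; nr <- shape[2]; nc <- shape[3]
  lapply(seq_len(ns), function(k)
    to_mat(v[((k - 1) * nr * nc + 1):(k * nr * nc)], nr, nc))
}

#' Read an image
#'
#' Reads a 2-D slice (or a 3-D stack, returned as a list of slices) from a
#' raw-float file with JSON sidecar or a headerless CSV/TSV matrix.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"raw"`, `"csv"` or `"tsv"`.
#' @return numeric matrix, or a list of matrices for a 3-D raw stack.
#' @export
read_image <- function(path, format = "auto") {
  if (!file.exists(path))
    stop(sprintf("cannot read '%s': file does not exist", path), call. = FALSE)
  if (format == "auto") format <- guess_format(path)
  out <- switch(format,
    raw = read_raw_image(path),
    csv = as.matrix(utils::read.table(path, sep = ",", header = FALSE)),
    tsv = as.matrix(utils::read.table(path, header = FALSE)),
    stop(sprintf("cannot read '%s': unknown format '%s'", path, format),
         call. = FALSE))
  if (is.matrix(out)) {
    dimnames(out) <- NULL
    if (!is.numeric(out))
      stop(sprintf("cannot read '%s': non-numeric values", path), call. = FALSE)
  }
  out
}

#' Write an image
#'
#' Counterpart of [read_image()]. Raw output writes `<path>` plus a
#' `<path>.json` sidecar; `dtype = "float64"` is lossless for doubles. A
#' list of matrices is written as a 3-D raw stack in list order.
#'
#' @param field numeric matrix, or list of equally shaped matrices.
#' @param path destination file.
#' @param format `"auto"`, `"raw"`, `"csv"` or `"tsv"`.
#' @param dtype `"float64"` or `"float32"` (raw only).
#' @export
write_image <- function(field, path, format = "auto", dtype = "float64") {
  if (format == "auto") format <- guess_format(path)
  if (is.list(field) && format != "raw")
    stop("3-D stacks are only supported in raw format", call. = FALSE)
  if (format == "raw") {
    size <- switch(dtype, float32 = 4L, float64 = 8L,
                   stop("unsupported dtype: ", dtype, call. = FALSE))
    shape <- if (is.list(field))
      c(length(field), dim(field[[1]])) else dim(field)
    vals <- if (is.list(field))
      unlist(lapply(field, as.vector), use.names = FALSE) else as.vector(field)
    con <- file(path, "wb")
    writeBin(vals, con, size = size, endian = "little")
    close(con)
    jsonlite::write_json(
      list(shape = shape, dtype = dtype, order = "F"),
      paste0(path, ".json"), auto_unbox = TRUE)
  } else {
    utils::write.table(field, path, sep = if (format == "csv") "," else "\t",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(NULL)
}

#' Read a binary mask
#'
#' Same formats as [read_image()]; values > 0.5 become `TRUE`.
#' @param path input file.
#' @return logical matrix.
#' @export
read_mask <- function(path) {
  m <- read_image(path)
  if (is.list(m)) stop("mask must be a single 2-D image", call. = FALSE)
  m > 0.5
}
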