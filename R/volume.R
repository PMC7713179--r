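#' CT volume and region-mask containers
#'
#' A `ct_volume` is a 3D scalar grid of CT numbers in Hounsfield units (HU)
#' together with its physical voxel spacing; a `ct_mask` is a binary region
#' on the same kind of grid (reference regions, volumes of interest, artifact
#' sets). Arrays are stored in R's native column-major (x, y, z) order with
#' 1-based indices; all physical quantities are in millimetres.
#'
#' @param data numeric (volume) or logical (mask) 3D array.
#' @param spacing_mm numeric length-3 voxel spacing in mm, (x, y, z).
#' @param origin_mm numeric length-3 physical position of the first voxel
#'   centre, in mm. Defaults to the origin.
#' @return An object of class `ct_volume` or `ct_mask`: a list with elements
#'   `data`, `spacing_mm` and `origin_mm`.
#' @examples
#' vol <- ct_volume(array(0, c(4, 4, 2)), spacing_mm = c(0.5, 0.5, 2))
#' dim(vol)
#' @export
ct_volume <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("'data' must be a 3D array, got %s dimension(s)",
          length(dim(data)) %||% "no")
  }
  if (!is_len(spacing_mm, 3, min = 0)) {
    stopf("'spacing_mm' must be 3 positive lengths")
  }
  if (!is_len(origin_mm, 3)) stopf("'origin_mm' must be 3 finite numbers")
  storage.mode(data) <- "double"
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_volume")
}

#' @rdname ct_volume
#' @export
ct_mask <- function(data, spacing_mm, origin_mm = c(0, 0, 0)) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stopf("'data' must be a 3D array")
  }
  if (is.numeric(data)) {
    bad <- !(data %in% c(0, 1))
    if (any(bad)) stopf("mask values must be binary (0/1)")
    data <- array(data != 0, dim(data))
  }
  if (!is.logical(data)) stopf("mask data must be logical or 0/1")
  if (!is_len(spacing_mm, 3, min = 0)) {
    stopf("'spacing_mm' must be 3 positive lengths")
  }
  structure(list(data = data, spacing_mm = as.numeric(spacing_mm),
                 origin_mm = as.numeric(origin_mm)),
            class = "ct_mask")
}

#' @export
dim.ct_volume <- function(x) dim(x$data)

#' @export
dim.ct_mask <- function(x) dim(x$data)

#' @export
print.ct_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_volume> %d x %d x %d voxels, spacing %s mm\n",
              d[1], d[2], d[3], paste(format(x$spacing_mm), collapse = " x ")))
  cat(sprintf("  HU range [%.2f, %.2f]\n",
              min(x$data), max(x$data)))
  invisible(x)
}

#' @export
print.ct_mask <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<ct_mask> %d x %d x %d voxels, spacing %s mm, %d voxels set\n",
              d[1], d[2], d[3], paste(format(x$spacing_mm), collapse = " x "),
              sum(x$data)))
  invisible(x)
}

#' Grid geometry of a volume or mask
#'
#' @param x a `ct_volume`, `ct_mask` or `labeled_volume`.
#' @return list with `shape` (voxel counts, x/y/z), `spacing_mm`, `origin_mm`.
#' @export
grid_info <- function(x) {
  if (inherits(x, "labeled_volume")) x <- x$image
  list(shape = dim(x$data), spacing_mm = x$spacing_mm,
       origin_mm = x$origin_mm)
}

#' Test whether two objects share a voxel grid
#'
#' Grids match when shape, spacing and origin agree (spacing and origin to
#' within 1e-6 mm). All multi-input operations in the package reject
#' mismatched grids through [assert_same_grid()]; there is no implicit
#' resampling.
#'
#' @param a,b volumes or masks.
#' @return logical.
#' @export
same_grid <- function(a, b) {
  ga <- grid_info(a)
  gb <- grid_info(b)
  identical(ga$shape, gb$shape) &&
    all(abs(ga$spacing_mm - gb$spacing_mm) < 1e-6) &&
    all(abs(ga$origin_mm - gb$origin_mm) < 1e-6)
}

#' @rdname same_grid
#' @param what label used in the error message.
#' @export
assert_same_grid <- function(a, b, what = "inputs") {
  if (!same_grid(a, b)) {
    ga <- grid_info(a)
    gb <- grid_info(b)
    stopf(paste0("grid mismatch between %s: shape %s vs %s, ",
                 "spacing %s vs %s"),
          what,
          paste(ga$shape, collapse = "x"), paste(gb$shape, collapse = "x"),
          paste(format(ga$spacing_mm), collapse = "x"),
          paste(format(gb$spacing_mm), collapse = "x"))
  }
  invisible(TRUE)
}
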