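#' Image volume on a regular 3-D grid
#'
#' The common spatial container for ADC maps, dose grids and label volumes.
#' Voxels are stored in a 1-based `(i, j, k)` array (NIfTI axis order, `k` the
#' slice axis); the physical position of voxel centre `(i, j, k)` is
#' `origin + (c(i, j, k) - 1) * spacing`, all in millimetres. ADC values are
#' kept on the scanner's printed scale (10^-6 mm^2/s, i.e. the 0--5000 range),
#' dose in Gy after any header scaling.
#'
#' @param voxels Numeric 3-D array of voxel values.
#' @param spacing Numeric length-3, voxel size in mm per axis; all > 0.
#' @param origin Numeric length-3, physical position (mm) of voxel (1,1,1).
#' @param kind One of `"adc"`, `"dose"`, `"label"`.
#' @return An object of class `image_volume`.
#' @examples
#' vol <- image_volume(array(0, c(4, 4, 2)), spacing = c(1.64, 1.64, 3))
#' dim(vol$voxels)
#' @export
image_volume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                         kind = c("adc", "dose", "label")) {
  kind <- match.arg(kind)
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("`voxels` must be a 3-D array")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("`spacing` must be 3 finite positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be 3 finite values (mm)")
  if (any(!is.finite(voxels)))
    stop("voxel values must all be finite")
  structure(
    list(voxels = voxels, spacing = spacing, origin = origin, kind = kind),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<image_volume [%s]> %d x %d x %d voxels, spacing %.3g x %.3g x %.3g mm\n",
              x$kind, d[1], d[2], d[3], x$spacing[1], x$spacing[2], x$spacing[3]))
  cat(sprintf("  origin (%.3g, %.3g, %.3g) mm; value range [%.4g, %.4g]\n",
              x$origin[1], x$origin[2], x$origin[3],
              min(x$voxels), max(x$voxels)))
  invisible(x)
}

#' Named boolean structure mask on a reference grid
#'
#' @param name Structure name (e.g. `"CTV_70Gy"`, `"rectum"`).
#' @param mask Logical 3-D array, congruent with the reference grid.
#' @param reference An [image_volume()] supplying spacing/origin, or `NULL`
#'   if `spacing`/`origin` are given directly.
#' @param spacing,origin Grid geometry (mm); taken from `reference` when given.
#' @return An object of class `structure_mask`.
#' @export
structure_mask <- function(name, mask, reference = NULL,
                           spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.null(reference)) {
    stopifnot(inherits(reference, "image_volume"))
    if (!identical(dim(mask), dim(reference$voxels)))
      stop("mask shape does not match the reference grid")
    spacing <- reference$spacing
    origin <- reference$origin
  }
  if (!is.logical(mask) || length(dim(mask)) != 3L)
    stop("`mask` must be a logical 3-D array")
  if (anyNA(mask)) stop("mask must not contain NA")
  structure(
    list(name = as.character(name), mask = mask,
         spacing = as.numeric(spacing), origin = as.numeric(origin)),
    class = "structure_mask"
  )
}

#' Structure volume in cubic centimetres
#'
#' Voxel count times voxel volume; exact by construction.
#'
#' @param x A `structure_mask`.
#' @return Volume in cc.
#' @export
volume_cc <- function(x) {
  stopifnot(inherits(x, "structure_mask"))
  sum(x$mask) * prod(x$spacing) / 1000
}

#' @export
print.structure_mask <- function(x, ...) {
  cat(sprintf("<structure_mask> %s: %d voxels, %.3f cc\n",
              x$name, sum(x$mask), volume_cc(x)))
  invisible(x)
}

#' Ordered, uniquely named collection of structure masks
#'
#' All members share one reference grid (shape, spacing, origin).
#'
#' @param masks List of [structure_mask()] objects.
#' @return An object of class `structure_set`; members accessible by name
#'   with `$masks[[name]]` or [get_structure()].
#' @export
structure_set <- function(masks) {
  if (!length(masks)) stop("a structure_set needs at least one structure")
  if (!all(vapply(masks, inherits, logical(1), "structure_mask")))
    stop("all members must be structure_mask objects")
  nm <- vapply(masks, function(m) m$name, character(1))
  if (anyDuplicated(nm)) stop("structure names must be unique")
  ref <- masks[[1]]
  for (m in masks[-1]) {
    if (!identical(dim(m$mask), dim(ref$mask)) ||
        !isTRUE(all.equal(m$spacing, ref$spacing, tolerance = 1e-6)) ||
        !isTRUE(all.equal(m$origin, ref$origin, tolerance = 1e-6)))
      stop("all structures must share one reference grid")
  }
  names(masks) <- nm
  structure(
    list(masks = masks, spacing = ref$spacing, origin = ref$origin,
         dim = dim(ref$mask)),
    class = "structure_set"
  )
}

#' @export
print.structure_set <- function(x, ...) {
  cat(sprintf("<structure_set> %d structures on %d x %d x %d grid\n",
              length(x$masks), x$dim[1], x$dim[2], x$dim[3]))
  for (m in x$masks)
    cat(sprintf("  %-18s %8d voxels  %9.3f cc\n", m$name, sum(m$mask), volume_cc(m)))
  invisible(x)
}

#' @rdname structure_set
#' @param set A `structure_set`.
#' @param name Structure name to extract.
#' @export
get_structure <- function(set, name) {
  stopifnot(inherits(set, "structure_set"))
  m <- set$masks[[name]]
  if (is.null(m)) stop(sprintf("structure '%s' not found", name))
  m
}

#' @rdname structure_set
#' @export
structure_names <- function(set) {
  stopifnot(inherits(set, "structure_set"))
  names(set$masks)
}

# Shared-grid congruence check used across modules.
same_grid <- function(a, b) {
  da <- if (inherits(a, "image_volume")) dim(a$voxels) else dim(a$mask)
  db <- if (inherits(b, "image_volume")) dim(b$voxels) else dim(b$mask)
  identical(da, db) &&
    isTRUE(all.equal(a$spacing, b$spacing, tolerance = 1e-6)) &&
    isTRUE(all.equal(a$origin, b$origin, tolerance = 1e-6))
}

stop_if_grid_mismatch <- function(a, b, what = "inputs") {
  if (!same_grid(a, b))
    stop(sprintf("%s must share one voxel grid (shape, spacing, origin)", what))
  invisible(TRUE)
}

# Physical voxel-centre coordinates along one axis.
axis_coords <- function(n, spacing, origin) origin + (seq_len(n) - 1) * spacing
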