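#' Read an image volume from a NIfTI-1 file
#'
#' Spacing is taken from the header `pixdim`, origin from the sform/qform
#' translation. Header value scaling (`scl_slope`/`scl_inter`, the NIfTI
#' analogue of a dose-grid scaling factor) is applied by the reader, so dose
#' grids come back in Gy and never as raw stored integers.
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @param kind Value kind of the volume: `"adc"`, `"dose"` or `"label"`.
#' @return An [image_volume()].
#' @export
read_image_volume <- function(path, kind = c("adc", "dose", "label")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("unsupported or corrupt image file '%s': %s",
                                                   path, conditionMessage(e))))
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  if (length(dim(arr)) != 3L)
    stop("only 3-D volumes are supported")
  sp <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(sp)) || any(sp <= 0))
    stop("header has invalid (non-positive) voxel spacing")
  xf <- RNifti::xform(img)
  org <- as.numeric(xf[1:3, 4])
  storage.mode(arr) <- "double"
  if (any(!is.finite(arr))) stop("volume contains non-finite voxels")
  if (kind == "dose" && any(arr < 0))
    stop("dose grid contains negative values")
  image_volume(arr, spacing = sp, origin = org, kind = kind)
}

#' Write an image volume to NIfTI-1
#'
#' Values are written as float64 after any scaling has been applied, so a
#' round-trip through [read_image_volume()] is voxel-identical.
#'
#' @param volume An [image_volume()].
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_image_volume <- function(volume, path) {
  stopifnot(inherits(volume, "image_volume"))
  sp <- volume$spacing
  org <- volume$origin
  hdr <- RNifti::niftiHeader(list(
    pixdim = c(1, sp, 1, 1, 1, 1),
    srow_x = c(sp[1], 0, 0, org[1]),
    srow_y = c(0, sp[2], 0, org[2]),
    srow_z = c(0, 0, sp[3], org[3]),
    sform_code = 2
  ))
  img <- RNifti::asNifti(volume$voxels, reference = hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a structure set
#'
#' Two on-disk layouts are supported: a directory written by
#' [write_structure_set()] (one binary label volume per structure plus a
#' `structures.json` index, which preserves overlapping structures), or a
#' single integer label volume whose positive labels each become one mask.
#'
#' @param path Directory or label-volume file.
#' @param reference [image_volume()] defining the expected grid; masks that
#'   disagree with it in shape or geometry raise an error.
#' @return A [structure_set()].
#' @export
read_structure_set <- function(path, reference) {
  stopifnot(inherits(reference, "image_volume"))
  if (dir.exists(path)) {
    index_file <- file.path(path, "structures.json")
    if (!file.exists(index_file))
      stop(sprintf("no structures.json index in '%s'", path))
    index <- jsonlite::fromJSON(index_file, simplifyVector = TRUE)
    masks <- lapply(seq_along(index$name), function(i) {
      vol <- read_image_volume(file.path(path, index$file[i]), kind = "label")
      stop_if_grid_mismatch(vol, reference, sprintf("structure '%s' and reference", index$name[i]))
      structure_mask(index$name[i], vol$voxels > 0.5, reference = reference)
    })
  } else {
    vol <- read_image_volume(path, kind = "label")
    stop_if_grid_mismatch(vol, reference, "label volume and reference")
    labs <- sort(unique(round(vol$voxels[vol$voxels > 0.5])))
    if (!length(labs)) stop("label volume contains no positive labels")
    masks <- lapply(labs, function(l)
      structure_mask(sprintf("label_%d", as.integer(l)),
                     abs(vol$voxels - l) < 0.5, reference = reference))
  }
  empty <- vapply(masks, function(m) sum(m$mask) == 0L, logical(1))
  if (any(empty))
    warning(sprintf("empty structure(s): %s",
                    paste(vapply(masks[empty], function(m) m$name, character(1)),
                          collapse = ", ")))
  structure_set(masks)
}

#' Write a structure set
#'
#' One binary NIfTI label volume per structure plus a JSON index; overlapping
#' structures are preserved independently (no shared label map).
#'
#' @param structures A [structure_set()].
#' @param path Output directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_structure_set <- function(structures, path) {
  stopifnot(inherits(structures, "structure_set"))
  if (!length(structures$masks)) stop("refusing to write an empty structure set")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (m in structures$masks) {
    f <- paste0(gsub("[^A-Za-z0-9_.-]", "_", m$name), ".nii.gz")
    vol <- image_volume(array(as.double(m$mask), dim(m$mask)),
                        spacing = m$spacing, origin = m$origin, kind = "label")
    write_image_volume(vol, file.path(path, f))
    files <- c(files, f)
  }
  jsonlite::write_json(
    list(name = vapply(structures$masks, function(m) m$name, character(1)),
         file = files),
    file.path(path, "structures.json")
  )
  invisible(path)
}

#' Rasterize planar contours to a structure mask
#'
#' Each contour is a closed polygon in physical mm on one slice; a voxel
#' belongs to the structure when its centre falls inside the polygon
#' (even-odd rule, ray casting). This is the documented rasterization
#' convention for every contour input.
#'
#' @param name Structure name.
#' @param contours List of contours; each a list with `slice` (1-based k
#'   index) and `xy` (n x 2 matrix of vertex positions in mm, closed
#'   implicitly).
#' @param reference [image_volume()] defining the output grid.
#' @return A [structure_mask()].
#' @export
structure_from_contours <- function(name, contours, reference) {
  stopifnot(inherits(reference, "image_volume"))
  d <- dim(reference$voxels)
  mask <- array(FALSE, d)
  xs <- axis_coords(d[1], reference$spacing[1], reference$origin[1])
  ys <- axis_coords(d[2], reference$spacing[2], reference$origin[2])
  for (ct in contours) {
    k <- ct$slice
    if (k < 1 || k > d[3]) stop("contour slice index outside the grid")
    poly <- ct$xy
    if (!is.matrix(poly) || ncol(poly) != 2 || nrow(poly) < 3)
      stop("each contour needs an n x 2 vertex matrix with n >= 3")
    if (anyNA(poly)) stop("contour has missing vertices (unclosed contour?)")
    inside <- point_in_polygon(rep(xs, times = d[2]),
                               rep(ys, each = d[1]), poly)
    mask[, , k] <- mask[, , k] | matrix(inside, d[1], d[2])
  }
  if (!any(mask)) warning(sprintf("structure '%s' rasterized to an empty mask", name))
  structure_mask(name, mask, reference = reference)
}

# Even-odd ray-casting point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- poly[i, 1]; yi <- poly[i, 2]
    xj <- poly[j, 1]; yj <- poly[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
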