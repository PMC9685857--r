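#' Resample a volume onto a reference grid
#'
#' Maps every reference voxel centre into the source volume's physical frame
#' and interpolates. Use `mode = "nearest"` for label volumes and
#' `mode = "trilinear"` for scalar volumes (ADC, dose); trilinear never
#' overshoots the local value bounds. Reference voxel centres outside the
#' source extent receive `fill`.
#'
#' @param volume Source [image_volume()].
#' @param reference [image_volume()] whose grid the output is produced on.
#' @param mode `"trilinear"` or `"nearest"`.
#' @param fill Value for voxels outside the source extent (default 0).
#' @return An [image_volume()] on the reference grid, same `kind` as `volume`.
#' @export
resample_to_grid <- function(volume, reference, mode = c("trilinear", "nearest"),
                             fill = 0) {
  mode <- match.arg(mode)
  stopifnot(inherits(volume, "image_volume"), inherits(reference, "image_volume"))
  if (same_grid(volume, reference)) return(volume)

  dsrc <- dim(volume$voxels)
  dref <- dim(reference$voxels)
  # fractional (1-based) source index of each reference voxel centre, per axis
  fx <- (axis_coords(dref[1], reference$spacing[1], reference$origin[1]) -
           volume$origin[1]) / volume$spacing[1] + 1
  fy <- (axis_coords(dref[2], reference$spacing[2], reference$origin[2]) -
           volume$origin[2]) / volume$spacing[2] + 1
  fz <- (axis_coords(dref[3], reference$spacing[3], reference$origin[3]) -
           volume$origin[3]) / volume$spacing[3] + 1

  inx <- fx >= 1 & fx <= dsrc[1]
  iny <- fy >= 1 & fy <= dsrc[2]
  inz <- fz >= 1 & fz <= dsrc[3]
  if (!any(inx) || !any(iny) || !any(inz))
    stop("source and reference grids have disjoint physical extents")

  FX <- array(rep(fx, times = dref[2] * dref[3]), dref)
  FY <- array(rep(rep(fy, each = dref[1]), times = dref[3]), dref)
  FZ <- array(rep(fz, each = dref[1] * dref[2]), dref)
  inside <- array(rep(inx, times = dref[2] * dref[3]), dref) &
    array(rep(rep(iny, each = dref[1]), times = dref[3]), dref) &
    array(rep(inz, each = dref[1] * dref[2]), dref)

  out <- array(fill, dref)
  xf <- FX[inside]; yf <- FY[inside]; zf <- FZ[inside]

  if (mode == "nearest") {
    li <- cbind(pmin(pmax(round(xf), 1), dsrc[1]),
                pmin(pmax(round(yf), 1), dsrc[2]),
                pmin(pmax(round(zf), 1), dsrc[3]))
    out[inside] <- volume$voxels[li]
  } else {
    x0 <- pmin(floor(xf), dsrc[1] - 1); y0 <- pmin(floor(yf), dsrc[2] - 1)
    z0 <- pmin(floor(zf), dsrc[3] - 1)
    x0 <- pmax(x0, 1); y0 <- pmax(y0, 1); z0 <- pmax(z0, 1)
    tx <- xf - x0; ty <- yf - y0; tz <- zf - z0
    v <- volume$voxels
    g <- function(dx, dy, dz) v[cbind(x0 + dx, y0 + dy, z0 + dz)]
    out[inside] <-
      g(0, 0, 0) * (1 - tx) * (1 - ty) * (1 - tz) +
      g(1, 0, 0) * tx       * (1 - ty) * (1 - tz) +
      g(0, 1, 0) * (1 - tx) * ty       * (1 - tz) +
      g(1, 1, 0) * tx       * ty       * (1 - tz) +
      g(0, 0, 1) * (1 - tx) * (1 - ty) * tz +
      g(1, 0, 1) * tx       * (1 - ty) * tz +
      g(0, 1, 1) * (1 - tx) * ty       * tz +
      g(1, 1, 1) * tx       * ty       * tz
  }
  image_volume(out, spacing = reference$spacing, origin = reference$origin,
               kind = volume$kind)
}
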