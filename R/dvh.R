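#' Dose-volume histogram of a structure
#'
#' Fixed-width binning of the voxel doses inside a mask. Bins are
#' left-closed, right-open intervals `[bin_lo, bin_hi)` starting at 0 Gy.
#' The differential histogram is reported in cc and as a fraction of the
#' structure volume; the cumulative curve gives the volume receiving at
#' least each bin's lower edge, so it starts at the total volume and is
#' monotone non-increasing.
#'
#' If the dose grid and mask disagree, the dose is first resampled to the
#' mask's grid by trilinear interpolation (declared convention).
#'
#' @param dose Dose [image_volume()] in Gy.
#' @param mask Non-empty [structure_mask()].
#' @param bin_width Bin width in Gy (default 0.05).
#' @return An object of class `dvh`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.05) {
  stopifnot(inherits(dose, "image_volume"), inherits(mask, "structure_mask"))
  if (bin_width <= 0) stop("bin_width must be positive")
  if (!any(mask$mask)) stop(sprintf("mask '%s' is empty", mask$name))
  if (!same_grid(dose, mask)) {
    ref <- image_volume(array(0, dim(mask$mask)), spacing = mask$spacing,
                        origin = mask$origin, kind = "dose")
    dose <- resample_to_grid(dose, ref, mode = "trilinear")
  }
  d <- dose$voxels[mask$mask]
  if (any(d < 0)) stop("negative doses inside the structure")
  voxel_cc <- prod(mask$spacing) / 1000
  nbins <- max(1L, floor(max(d) / bin_width) + 1L)
  idx <- pmin(floor(d / bin_width) + 1L, nbins)
  counts <- tabulate(idx, nbins)
  bin_lo <- (seq_len(nbins) - 1) * bin_width
  diff_cc <- counts * voxel_cc
  total_cc <- sum(diff_cc)
  cum_cc <- rev(cumsum(rev(diff_cc)))  # volume with dose >= bin_lo
  structure(list(
    structure = mask$name, bin_width = bin_width,
    bin_lo = bin_lo, bin_hi = bin_lo + bin_width,
    counts = counts, diff_cc = diff_cc, diff_fraction = diff_cc / total_cc,
    cum_cc = cum_cc, cum_fraction = cum_cc / total_cc,
    total_cc = total_cc, voxel_cc = voxel_cc,
    min_dose = min(d), max_dose = max(d), mean_dose = mean(d)
  ), class = "dvh")
}

#' @export
print.dvh <- function(x, ...) {
  cat(sprintf("<dvh> %s: %.2f cc, dose %.2f-%.2f Gy (mean %.2f), %d bins of %g Gy\n",
              x$structure, x$total_cc, x$min_dose, x$max_dose, x$mean_dose,
              length(x$counts), x$bin_width))
  invisible(x)
}

#' Convert a DVH to a data frame
#'
#' Stable CSV schema: `structure, bin_lo, bin_hi, diff_cc, cum_pct`.
#'
#' @param x A `dvh`.
#' @param ... Unused.
#' @return A data frame, one row per bin.
#' @export
as.data.frame.dvh <- function(x, ...) {
  data.frame(structure = x$structure, bin_lo = x$bin_lo, bin_hi = x$bin_hi,
             diff_cc = x$diff_cc, cum_pct = 100 * x$cum_fraction)
}

#' Rebuild a DVH from its tabular form
#'
#' Inverse of [as.data.frame.dvh()] (up to voxel-level summaries): accepts
#' the stable CSV schema `structure, bin_lo, bin_hi, diff_cc` and
#' reconstructs the cumulative curve. Used by the command-line front end to
#' feed exported DVH tables to the TCP model.
#'
#' @param df Data frame with one structure's bins, ascending `bin_lo`.
#' @return An object of class `dvh`.
#' @export
dvh_from_table <- function(df) {
  df <- as.data.frame(df)
  need <- c("structure", "bin_lo", "bin_hi", "diff_cc")
  if (!all(need %in% names(df)))
    stop("DVH table needs columns: ", paste(need, collapse = ", "))
  if (length(unique(df$structure)) != 1L)
    stop("one structure per table; split the input first")
  df <- df[order(df$bin_lo), ]
  bw <- unique(round(df$bin_hi - df$bin_lo, 9))
  if (length(bw) != 1L) stop("bins must have one common width")
  total_cc <- sum(df$diff_cc)
  if (total_cc <= 0) stop("empty DVH")
  cum_cc <- rev(cumsum(rev(df$diff_cc)))
  centers <- (df$bin_lo + df$bin_hi) / 2
  w <- df$diff_cc / total_cc
  structure(list(
    structure = df$structure[1], bin_width = bw,
    bin_lo = df$bin_lo, bin_hi = df$bin_hi,
    counts = NA_integer_, diff_cc = df$diff_cc,
    diff_fraction = df$diff_cc / total_cc,
    cum_cc = cum_cc, cum_fraction = cum_cc / total_cc,
    total_cc = total_cc, voxel_cc = NA_real_,
    min_dose = min(df$bin_lo[df$diff_cc > 0]),
    max_dose = max(df$bin_hi[df$diff_cc > 0]),
    mean_dose = sum(w * centers)
  ), class = "dvh")
}

#' Dose received by the hottest p percent of a structure (Dp%)
#'
#' The smallest dose `d` such that the volume fraction receiving at least
#' `d` is `p/100` or less, linearly interpolated between bin edges of the
#' cumulative curve.
#'
#' @param dvh A [compute_dvh()] result.
#' @param p Percent in (0, 100); e.g. `2` for D2%.
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, p) {
  stopifnot(inherits(dvh, "dvh"))
  if (!is.finite(p) || p <= 0 || p >= 100)
    stop("p must lie strictly between 0 and 100")
  f <- p / 100
  edges <- c(dvh$bin_lo, dvh$bin_hi[length(dvh$bin_hi)])
  frac <- c(dvh$cum_fraction, 0)  # fraction with dose >= edge
  above <- which(frac > f)
  if (!length(above)) return(edges[1])
  j <- max(above)
  if (j == length(edges)) return(edges[j])
  # unique crossing between edges j and j+1
  edges[j] + (frac[j] - f) / (frac[j] - frac[j + 1]) * dvh$bin_width
}

#' Homogeneity index of a target dose distribution
#'
#' Default is the ICRU-83 form `(D2% - D98%) / D50%`: 0 for a perfectly
#' uniform dose, growing with within-target spread, and invariant under
#' uniform dose scaling. The alternative `d5d95` form
#' `(D5% - D95%) / prescription` is provided for sensitivity analyses.
#'
#' @param dvh A [compute_dvh()] result.
#' @param definition `"icru83"` (default) or `"d5d95"`.
#' @param prescription Prescription dose in Gy (required for `d5d95`).
#' @return Non-negative scalar.
#' @export
homogeneity_index <- function(dvh, definition = c("icru83", "d5d95"),
                              prescription = NULL) {
  definition <- match.arg(definition)
  if (definition == "icru83") {
    d50 <- dose_at_volume(dvh, 50)
    if (d50 <= 0) stop("D50% is zero; homogeneity index undefined")
    (dose_at_volume(dvh, 2) - dose_at_volume(dvh, 98)) / d50
  } else {
    if (is.null(prescription) || prescription <= 0)
      stop("d5d95 definition needs a positive prescription dose")
    (dose_at_volume(dvh, 5) - dose_at_volume(dvh, 95)) / prescription
  }
}

#' Conformity index of a target
#'
#' Default `"coverage"`: the fraction of the target receiving at least the
#' prescription, in `[0, 1]` with 1 ideal. `"paddick"` additionally
#' penalizes prescription isodose spilling outside the target:
#' `TV_RI^2 / (TV * V_RI)` with `TV` the target volume, `V_RI` the total
#' volume at or above the prescription and `TV_RI` their intersection.
#'
#' @param dose Dose [image_volume()] in Gy, on the target's grid.
#' @param target Non-empty [structure_mask()].
#' @param rx Prescription dose in Gy.
#' @param definition `"coverage"` (default) or `"paddick"`.
#' @return Scalar index.
#' @export
conformity_index <- function(dose, target, rx,
                             definition = c("coverage", "paddick")) {
  definition <- match.arg(definition)
  stopifnot(inherits(dose, "image_volume"), inherits(target, "structure_mask"))
  if (rx <= 0) stop("prescription must be positive")
  if (!any(target$mask)) stop(sprintf("target '%s' is empty", target$name))
  stop_if_grid_mismatch(dose, target, "dose grid and target")
  hot <- dose$voxels >= rx
  tv <- sum(target$mask)
  tv_ri <- sum(hot & target$mask)
  if (definition == "coverage") return(tv_ri / tv)
  v_ri <- sum(hot)
  if (v_ri == 0) return(0)
  tv_ri^2 / (tv * v_ri)
}
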