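#' ADC to relative cell density mapping
#'
#' ADC is inversely related to cellularity in prostate tumours, but no
#' calibrated functional form is universally agreed. Three monotone
#' non-increasing mappings are offered; because only the ratios
#' `CD_i / CD_p` enter the IOE formulas, any positive global scale of the
#' mapping cancels.
#'
#' * `inverse_linear` (default): `CD = (adc_ref - ADC) / (adc_ref - adc_min)`
#' * `reciprocal`: `CD = adc_ref / ADC`
#' * `user_table`: monotone linear interpolation of supplied `(ADC, CD)` pairs
#'
#' @param mapping_kind One of `"inverse_linear"`, `"reciprocal"`, `"user_table"`.
#' @param adc_min,adc_ref Domain of the mapping (defaults 0 and 5000, the
#'   ADC ceiling).
#' @param table For `user_table`: data frame or 2-column matrix of
#'   `(adc, cd)` pairs with non-increasing `cd`.
#' @return An object of class `density_model`.
#' @export
density_model <- function(mapping_kind = c("inverse_linear", "reciprocal", "user_table"),
                          adc_min = 0, adc_ref = 5000, table = NULL) {
  mapping_kind <- match.arg(mapping_kind)
  if (!(adc_ref > adc_min)) stop("adc_ref must exceed adc_min")
  if (mapping_kind == "user_table") {
    if (is.null(table)) stop("user_table mapping needs a (adc, cd) table")
    table <- as.data.frame(table)
    names(table)[1:2] <- c("adc", "cd")
    table <- table[order(table$adc), ]
    if (any(diff(table$cd) > 1e-12))
      stop("user table must be monotone non-increasing in ADC")
    if (any(table$cd <= 0)) stop("user table densities must be positive")
  }
  if (mapping_kind == "reciprocal" && adc_min <= 0)
    adc_min <- 1  # reciprocal is singular at 0; smallest physical ADC
  structure(list(mapping_kind = mapping_kind, adc_min = adc_min,
                 adc_ref = adc_ref, table = table),
            class = "density_model")
}

#' Mean ADC over a structure
#'
#' @param adc ADC [image_volume()].
#' @param mask Non-empty [structure_mask()] on the same grid.
#' @param statistic Summary statistic: `"mean"` (default) or `"median"`.
#' @return Scalar ADC summary.
#' @export
region_mean_adc <- function(adc, mask, statistic = c("mean", "median")) {
  statistic <- match.arg(statistic)
  stopifnot(inherits(adc, "image_volume"), inherits(mask, "structure_mask"))
  stop_if_grid_mismatch(adc, mask, "ADC map and mask")
  if (!any(mask$mask)) stop(sprintf("mask '%s' is empty", mask$name))
  v <- adc$voxels[mask$mask]
  if (statistic == "mean") mean(v) else stats::median(v)
}

#' Map a summary ADC value to relative cell density
#'
#' @param mean_adc Scalar ADC within `[adc_min, adc_ref]`.
#' @param model A [density_model()].
#' @return Positive relative density (dimensionless).
#' @export
adc_to_density <- function(mean_adc, model = density_model()) {
  stopifnot(inherits(model, "density_model"))
  if (!is.finite(mean_adc) || mean_adc < model$adc_min || mean_adc > model$adc_ref)
    stop(sprintf("ADC %g outside the model domain [%g, %g]",
                 mean_adc, model$adc_min, model$adc_ref))
  cd <- switch(model$mapping_kind,
    inverse_linear = (model$adc_ref - mean_adc) / (model$adc_ref - model$adc_min),
    reciprocal = model$adc_ref / mean_adc,
    user_table = stats::approx(model$table$adc, model$table$cd, xout = mean_adc,
                               rule = 2, ties = "ordered")$y
  )
  if (cd <= 0) cd <- .Machine$double.eps  # ADC exactly at adc_ref
  cd
}

#' Relative cell-density weights for a set of targets
#'
#' Per-target densities `CD_i` come from the summary ADC of each target;
#' the pooled density `CD_p` is by default the volume-weighted mean
#' `sum(V_i * CD_i) / sum(V_i)` over all targets (reading "the whole CTV" as
#' the pooled volume), under which the identity
#' `sum((V_i / V_T) * CD_i / CD_p) = 1` holds exactly. An unweighted mean of
#' the `CD_i` is available via `cd_p = "unweighted"`.
#'
#' @param adc ADC [image_volume()].
#' @param targets [structure_set()] or named list of [structure_mask()]s;
#'   empty targets are dropped with a warning.
#' @param model A [density_model()].
#' @param statistic Passed to [region_mean_adc()].
#' @param cd_p `"volume_weighted"` (default) or `"unweighted"`.
#' @return An object of class `density_weights`: per-target `cd`, `ratio`
#'   (`CD_i / CD_p`), `volume_cc`, `mean_adc`, plus scalars `cd_p`, `v_t_cc`.
#' @export
compute_density_weights <- function(adc, targets, model = density_model(),
                                    statistic = "mean",
                                    cd_p = c("volume_weighted", "unweighted")) {
  cd_p <- match.arg(cd_p)
  masks <- if (inherits(targets, "structure_set")) targets$masks else targets
  if (!length(masks)) stop("no targets supplied")
  nonempty <- vapply(masks, function(m) any(m$mask), logical(1))
  if (!any(nonempty)) stop("all targets are empty")
  if (any(!nonempty))
    warning(sprintf("dropping empty target(s): %s",
                    paste(names(masks)[!nonempty], collapse = ", ")))
  masks <- masks[nonempty]
  madc <- vapply(masks, function(m) region_mean_adc(adc, m, statistic), numeric(1))
  cd <- vapply(madc, adc_to_density, numeric(1), model = model)
  vol <- vapply(masks, volume_cc, numeric(1))
  cdp <- if (cd_p == "volume_weighted") sum(vol * cd) / sum(vol) else mean(cd)
  structure(list(
    target = names(masks), mean_adc = madc, cd = cd, volume_cc = vol,
    cd_p = cdp, ratio = cd / cdp, v_t_cc = sum(vol), cd_p_kind = cd_p
  ), class = "density_weights")
}

#' @export
print.density_weights <- function(x, ...) {
  cat(sprintf("<density_weights> CD_p = %.4f (%s), V_T = %.2f cc\n",
              x$cd_p, x$cd_p_kind, x$v_t_cc))
  for (i in seq_along(x$target))
    cat(sprintf("  %-18s ADC %7.1f  CD %.4f  CD/CD_p %.4f  V %8.2f cc\n",
                x$target[i], x$mean_adc[i], x$cd[i], x$ratio[i], x$volume_cc[i]))
  invisible(x)
}
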