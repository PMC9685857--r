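#' Index of effectiveness (IOE) for a dose-painting plan
#'
#' The composite plan index: a volume-weighted — and optionally
#' cell-density-weighted — sum of per-target scalar indices,
#'
#' \deqn{IOE = \sum_i x_i \cdot \frac{CD_i}{CD_p} \cdot \frac{V_i}{V_T},
#'       \qquad V_T = \sum_i V_i,}
#'
#' with `x_i` a per-target homogeneity index (IOE(H), closer to zero is
#' better) or conformity index (IOE(C), closer to one is better). With
#' `density_ratios = NULL` every ratio is 1 and the index reduces to the
#' plain volume-weighted form. Any number of targets is supported; the
#' three-level prostate evaluation (CTV 70/66/60 Gy) is the canonical case.
#' When `CD_p` is the volume-weighted pooled density the weights
#' `(CD_i/CD_p)(V_i/V_T)` sum to one, so the IOE is a weighted average
#' bounded by the smallest and largest `x_i`.
#'
#' @param index_values Per-target indices `x_i` (finite).
#' @param volumes Per-target volumes `V_i` in any common unit; all > 0.
#' @param density_ratios Per-target `CD_i / CD_p`, or `NULL` for the plain
#'   (unweighted-density) form.
#' @return Scalar IOE.
#' @export
ioe <- function(index_values, volumes, density_ratios = NULL) {
  n <- length(index_values)
  if (n < 1L) stop("need at least one target")
  if (length(volumes) != n) stop("index_values and volumes lengths differ")
  if (any(!is.finite(index_values))) stop("index values must be finite")
  if (any(!is.finite(volumes)) || any(volumes <= 0))
    stop("volumes must be positive and finite")
  if (is.null(density_ratios)) density_ratios <- rep(1, n)
  if (length(density_ratios) != n) stop("density_ratios length differs")
  if (any(!is.finite(density_ratios)) || any(density_ratios <= 0))
    stop("density ratios must be positive and finite")
  v_t <- sum(volumes)
  if (v_t <= 0) stop("total volume is zero")
  sum(index_values * density_ratios * volumes / v_t)
}

#' Unweighted mean of per-target conventional indices
#'
#' The conventional comparator to the IOE: the arithmetic mean of the
#' per-target HI or CI values.
#'
#' @param index_values Per-target indices; at least one.
#' @return Scalar mean.
#' @export
mean_index <- function(index_values) {
  if (!length(index_values)) stop("no index values supplied")
  if (any(!is.finite(index_values))) stop("index values must be finite")
  mean(index_values)
}

#' Evaluate a dose-painting plan
#'
#' Computes, per evaluation target: DVH, homogeneity index, conformity
#' index and volume; then the six plan-level indices — IOE(H) and IOE(C)
#' with and without cell-density weighting, and the mean conventional HI
#' and CI. By default the IOE covers the boosted levels and the prostate
#' level (70/66/60 Gy); the 53 Gy seminal-vesicle level is excluded from the
#' composite. Empty targets are dropped with a warning and the total volume
#' shrinks accordingly.
#'
#' @param dose Dose [image_volume()] in Gy.
#' @param targets [structure_set()] containing the evaluation CTVs.
#' @param prescriptions Named numeric vector of prescriptions (Gy) for every
#'   evaluated target.
#' @param adc Optional ADC [image_volume()]; with `density_model` it yields
#'   the cell-density weights. Omit both to evaluate the plain indices only
#'   (density variants then equal the plain ones).
#' @param density_model A [density_model()] used when `adc` is given.
#' @param evaluate Character vector of target names entering the indices;
#'   defaults to the intersection of `names(prescriptions)` with the set.
#' @param hi_definition,ci_definition Passed to [homogeneity_index()] /
#'   [conformity_index()].
#' @param bin_width DVH bin width in Gy.
#' @return An object of class `plan_evaluation`: `$targets` (per-target
#'   table), the six indices, and the DVHs.
#' @export
evaluate_plan <- function(dose, targets, prescriptions,
                          adc = NULL, density_model = dpeval::density_model(),
                          evaluate = NULL,
                          hi_definition = "icru83", ci_definition = "coverage",
                          bin_width = 0.05) {
  stopifnot(inherits(dose, "image_volume"), inherits(targets, "structure_set"))
  if (is.null(evaluate))
    evaluate <- intersect(names(prescriptions), structure_names(targets))
  if (!length(evaluate)) stop("no evaluation targets")
  masks <- lapply(evaluate, get_structure, set = targets)
  names(masks) <- evaluate
  nonempty <- vapply(masks, function(m) any(m$mask), logical(1))
  if (!any(nonempty)) stop("all evaluation targets are empty")
  if (any(!nonempty)) {
    warning(sprintf("dropping empty target(s) from the evaluation: %s",
                    paste(evaluate[!nonempty], collapse = ", ")))
    masks <- masks[nonempty]
    evaluate <- evaluate[nonempty]
  }

  dvhs <- lapply(masks, compute_dvh, dose = dose, bin_width = bin_width)
  rx <- prescriptions[evaluate]
  hi <- mapply(function(dv, r) homogeneity_index(dv, hi_definition, prescription = r),
               dvhs, rx)
  ci <- mapply(function(m, r) conformity_index(dose, m, r, ci_definition), masks, rx)
  vol <- vapply(masks, volume_cc, numeric(1))

  if (!is.null(adc)) {
    dw <- compute_density_weights(adc, masks, model = density_model)
    ratio <- dw$ratio[match(evaluate, dw$target)]
    cd <- dw$cd[match(evaluate, dw$target)]
  } else {
    dw <- NULL
    ratio <- rep(1, length(evaluate))
    cd <- rep(NA_real_, length(evaluate))
  }

  structure(list(
    targets = data.frame(name = evaluate, prescription_gy = as.numeric(rx),
                         volume_cc = vol, hi = as.numeric(hi),
                         ci = as.numeric(ci), cd = cd, density_ratio = ratio,
                         row.names = NULL),
    ioe_h_density = ioe(hi, vol, ratio),
    ioe_h_plain = ioe(hi, vol),
    ioe_c_density = ioe(ci, vol, ratio),
    ioe_c_plain = ioe(ci, vol),
    hi_mean = mean_index(hi),
    ci_mean = mean_index(ci),
    density = dw, dvhs = dvhs,
    hi_definition = hi_definition, ci_definition = ci_definition
  ), class = "plan_evaluation")
}

#' @export
print.plan_evaluation <- function(x, ...) {
  cat("<plan_evaluation>\n")
  print(x$targets, digits = 4)
  cat(sprintf("  IOE(H) with density %.4f | without %.4f | HI mean %.4f  (closer to 0 = better)\n",
              x$ioe_h_density, x$ioe_h_plain, x$hi_mean))
  cat(sprintf("  IOE(C) with density %.4f | without %.4f | CI mean %.4f  (closer to 1 = better)\n",
              x$ioe_c_density, x$ioe_c_plain, x$ci_mean))
  invisible(x)
}
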