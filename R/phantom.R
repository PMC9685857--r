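#' Synthetic ADC phantom specification
#'
#' A prostate-sized ellipsoid containing 1--3 spherical lesions with
#' Gaussian-noised ADC, surrounded by higher-ADC background, on a grid
#' echoing diffusion-MRI geometry (default 96 x 96 x 48 at
#' 1.64 x 1.64 x 3 mm). Default lesion ADC bands sit well inside the
#' high-risk (< 750) and lower-risk (750--1500) classification windows, and
#' default lesion radii give components comfortably above the 400-voxel
#' filter at this voxel size. All randomness is fixed by `seed`.
#'
#' @param grid_dim Integer length-3 grid shape.
#' @param spacing Voxel size in mm.
#' @param prostate_radii_mm Ellipsoid semi-axes of the prostate (mm).
#' @param lesions List of lesions, each a list with `class` ("high" or
#'   "lower"), `center_offset_mm` (length-3, relative to the prostate
#'   centre), `radius_mm`, `adc_mean`, `adc_sd`.
#' @param normal_adc_mean,normal_adc_sd Normal prostate tissue ADC.
#' @param outside_adc_mean,outside_adc_sd Extra-prostatic background ADC.
#' @param seed Integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_dim = c(96, 96, 48), spacing = c(1.64, 1.64, 3),
                         prostate_radii_mm = c(24, 20, 19),
                         lesions = list(
                           list(class = "high", center_offset_mm = c(10, 0, 0),
                                radius_mm = 10.2, adc_mean = 600, adc_sd = 50),
                           list(class = "lower", center_offset_mm = c(-11, 3, 2),
                                radius_mm = 9.8, adc_mean = 1100, adc_sd = 80)
                         ),
                         normal_adc_mean = 2000, normal_adc_sd = 150,
                         outside_adc_mean = 2600, outside_adc_sd = 250,
                         seed = 1L) {
  stopifnot(length(grid_dim) == 3, all(grid_dim >= 1),
            length(spacing) == 3, all(spacing > 0),
            length(prostate_radii_mm) == 3, all(prostate_radii_mm > 0))
  for (l in lesions) {
    if (!l$class %in% c("high", "lower")) stop("lesion class must be 'high' or 'lower'")
    if (l$adc_mean < 0 || l$adc_mean > 5000) stop("lesion ADC mean outside [0, 5000]")
    if (l$radius_mm <= 0) stop("lesion radius must be positive")
  }
  structure(list(grid_dim = as.integer(grid_dim), spacing = as.numeric(spacing),
                 prostate_radii_mm = prostate_radii_mm, lesions = lesions,
                 normal_adc_mean = normal_adc_mean, normal_adc_sd = normal_adc_sd,
                 outside_adc_mean = outside_adc_mean, outside_adc_sd = outside_adc_sd,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Boolean ellipsoid mask; centre and semi-axes in physical mm.
ellipsoid_mask <- function(grid_dim, spacing, origin, center_mm, radii_mm) {
  xs <- (axis_coords(grid_dim[1], spacing[1], origin[1]) - center_mm[1]) / radii_mm[1]
  ys <- (axis_coords(grid_dim[2], spacing[2], origin[2]) - center_mm[2]) / radii_mm[2]
  zs <- (axis_coords(grid_dim[3], spacing[3], origin[3]) - center_mm[3]) / radii_mm[3]
  X2 <- array(rep(xs^2, times = grid_dim[2] * grid_dim[3]), grid_dim)
  Y2 <- array(rep(rep(ys^2, each = grid_dim[1]), times = grid_dim[3]), grid_dim)
  Z2 <- array(rep(zs^2, each = grid_dim[1] * grid_dim[2]), grid_dim)
  X2 + Y2 + Z2 <= 1
}

#' Generate a synthetic ADC phantom with ground truth
#'
#' Draws the ADC volume region by region in a fixed order (background, then
#' normal prostate, then each lesion in list order) from the Mersenne
#' Twister seeded with `spec$seed`, so equal seeds give identical volumes.
#' Values are clamped to [0, 5000]. Also constructs geometric organ masks
#' (rectum, bladder, urethra, femoral heads, bowel) and a seminal-vesicle
#' base adjacent to the prostate, for margin exclusion and objective checks.
#'
#' @param spec A [phantom_spec()].
#' @return List with `adc` ([image_volume()]), `truth` ([structure_set()]:
#'   `prostate`, `lesion_high_risk`, `lesion_lower_risk`), `organs`
#'   ([structure_set()]: `sv_base`, `rectum`, `bladder`, `urethra`,
#'   `femoral_heads`, `bowel`) and `spec`.
#' @export
generate_adc_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  d <- spec$grid_dim; sp <- spec$spacing; org <- c(0, 0, 0)
  centre <- (d - 1) / 2 * sp
  set.seed(spec$seed)

  prostate <- ellipsoid_mask(d, sp, org, centre, spec$prostate_radii_mm)
  lesion_masks <- lapply(spec$lesions, function(l)
    ellipsoid_mask(d, sp, org, centre + l$center_offset_mm, rep(l$radius_mm, 3)))
  taken <- array(FALSE, d)
  for (i in seq_along(lesion_masks)) {
    if (any(lesion_masks[[i]] & !prostate))
      stop(sprintf("lesion %d extends outside the prostate", i))
    if (any(lesion_masks[[i]] & taken))
      stop(sprintf("lesion %d overlaps an earlier lesion", i))
    taken <- taken | lesion_masks[[i]]
  }

  adc <- array(0, d)
  n_out <- sum(!prostate)
  adc[!prostate] <- stats::rnorm(n_out, spec$outside_adc_mean, spec$outside_adc_sd)
  normal <- prostate & !taken
  adc[normal] <- stats::rnorm(sum(normal), spec$normal_adc_mean, spec$normal_adc_sd)
  for (i in seq_along(lesion_masks)) {
    l <- spec$lesions[[i]]
    adc[lesion_masks[[i]]] <- stats::rnorm(sum(lesion_masks[[i]]), l$adc_mean, l$adc_sd)
  }
  adc <- pmin(pmax(adc, 0), 5000)

  high <- array(FALSE, d); lower <- array(FALSE, d)
  for (i in seq_along(lesion_masks)) {
    if (spec$lesions[[i]]$class == "high") high <- high | lesion_masks[[i]]
    else lower <- lower | lesion_masks[[i]]
  }

  vol <- image_volume(adc, spacing = sp, origin = org, kind = "adc")
  truth <- structure_set(list(
    structure_mask("prostate", prostate, reference = vol),
    structure_mask("lesion_high_risk", high, reference = vol),
    structure_mask("lesion_lower_risk", lower, reference = vol)
  ))

  mk <- function(name, center_off, radii)
    structure_mask(name, ellipsoid_mask(d, sp, org, centre + center_off, radii),
                   reference = vol)
  fem <- ellipsoid_mask(d, sp, org, centre + c(45, 5, 0), rep(16, 3)) |
    ellipsoid_mask(d, sp, org, centre + c(-45, 5, 0), rep(16, 3))
  organs <- structure_set(list(
    mk("sv_base", c(0, 9, 25), c(13, 8, 6)),
    mk("rectum", c(0, 34, 0), c(14, 13, 45)),
    mk("bladder", c(0, -27, 14), c(20, 15, 14)),
    mk("urethra", c(0, 0, 0), c(3, 3, 21)),
    structure_mask("femoral_heads", fem, reference = vol),
    mk("bowel", c(0, -5, 40), c(26, 16, 12))
  ))
  list(adc = vol, truth = truth, organs = organs, spec = spec)
}

#' Dose-distribution specification for the phantom planner
#'
#' One row per dose level: target structure name, prescription (Gy),
#' engineered homogeneity (`hi`, the intended (D2%-D98%)/D50%) and
#' engineered coverage (intended fraction of the target at or above the
#' prescription). Nested targets are resolved by containment: a voxel gets
#' the level of the highest prescription covering it.
#'
#' @param levels Data frame with columns `name`, `rx`, `hi`, `coverage`.
#' @param falloff_mm Exponential dose falloff length outside the targets.
#' @return An object of class `dose_spec`.
#' @export
dose_spec <- function(levels = data.frame(
                        name = c("CTV_70Gy", "CTV_66Gy", "CTV_60Gy", "CTV_53Gy"),
                        rx = c(70, 66, 60, 53),
                        hi = c(0.086, 0.078, 0.151, 0.105),
                        coverage = c(0.995, 0.998, 0.992, 0.994)),
                      falloff_mm = 10) {
  levels <- as.data.frame(levels)
  stopifnot(all(c("name", "rx", "hi", "coverage") %in% names(levels)))
  if (any(levels$rx <= 0)) stop("prescriptions must be positive")
  if (any(levels$coverage < 0 | levels$coverage > 1)) stop("coverage must be in [0, 1]")
  if (any(levels$hi < 0)) stop("engineered spread must be >= 0")
  if (anyDuplicated(levels$name)) stop("duplicate level names")
  structure(list(levels = levels, falloff_mm = falloff_mm), class = "dose_spec")
}

# Sorted (ascending) voxel doses realizing the requested prescription,
# homogeneity and coverage: a piecewise-linear quantile function through
# control points pinning Q(1-coverage)=rx, Q(0.02)=D98, Q(0.5)=D50,
# Q(0.98)=D2 with (D2-D98)/D50 = hi.
engineer_region_dose <- function(n, rx, hi, coverage) {
  if (n < 1) return(numeric(0))
  if (hi <= 0 && coverage >= 1) return(rep(rx, n))
  p_cold <- min(max(1 - coverage, 0), 0.999)
  if (p_cold <= 0.02) {
    d98 <- rx * 1.002
    d50 <- d98 / (1 - hi / 2)
    d2 <- d50 * (1 + hi / 2)
    p <- c(0, if (p_cold > 0) p_cold, 0.02, 0.5, 0.98, 1)
    v <- c(if (p_cold > 0) rx * 0.95 else rx, if (p_cold > 0) rx,
           d98, d50, d2, d2 * 1.002)
  } else {
    # D98 sits inside the cold tail; pin it with an explicit knot and keep
    # the bottom 2% shallow (3% below D98) rather than extrapolating deep
    d50 <- rx * 1.01
    d2 <- d50 * (1 + hi / 2)
    d98 <- min(d50 * (1 - hi / 2), rx * 0.999)
    p <- c(0, 0.02, p_cold, 0.5, 0.98, 1)
    v <- c(d98 * 0.97, d98, rx, d50, d2, d2 * 1.002)
  }
  ord <- order(p)
  p <- p[ord]
  v <- cummax(v[ord])  # guard monotonicity in degenerate corners
  stats::approx(p, v, xout = (seq_len(n) - 0.5) / n, rule = 2, ties = "ordered")$y
}

# One-voxel 26-neighbourhood dilation.
dilate1 <- function(mask) {
  out <- mask
  for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
    if (di == 0 && dj == 0 && dk == 0) next
    out <- shift_or(out, mask, c(di, dj, dk))
  }
  out
}

#' Generate a dose grid with engineered per-target quality
#'
#' Each dose level's voxels (resolved by containment: highest prescription
#' wins on overlap) receive doses drawn from an engineered piecewise-linear
#' quantile function realizing the requested homogeneity and coverage;
#' within a region, doses are assigned deterministically by distance from
#' the region centroid (hot core, cooler rim). Outside all targets the dose
#' decays in one-voxel shells with length `falloff_mm`.
#'
#' @param targets [structure_set()] holding every structure named in `spec`.
#' @param spec A [dose_spec()]; levels naming structures absent from
#'   `targets` are an error, and overlapping same-prescription levels are
#'   rejected as unordered.
#' @return A dose [image_volume()] on the targets' grid.
#' @export
generate_dose_distribution <- function(targets, spec = dose_spec()) {
  stopifnot(inherits(targets, "structure_set"), inherits(spec, "dose_spec"))
  lv <- spec$levels[spec$levels$name %in% structure_names(targets), , drop = FALSE]
  missing <- setdiff(spec$levels$name, structure_names(targets))
  if (nrow(lv) == 0) stop("no dose level names a structure in `targets`")
  if (length(missing))
    message(sprintf("dose level(s) without a structure skipped: %s",
                    paste(missing, collapse = ", ")))
  lv <- lv[order(lv$rx, decreasing = TRUE), , drop = FALSE]
  d <- targets$dim; sp <- targets$spacing
  dose <- array(0, d)
  claimed <- array(FALSE, d)
  xs <- axis_coords(d[1], sp[1], targets$origin[1])
  ys <- axis_coords(d[2], sp[2], targets$origin[2])
  zs <- axis_coords(d[3], sp[3], targets$origin[3])
  for (r in seq_len(nrow(lv))) {
    m <- get_structure(targets, lv$name[r])$mask
    if (r > 1 && lv$rx[r] == lv$rx[r - 1]) {
      prev <- get_structure(targets, lv$name[r - 1])$mask
      if (any(m & prev))
        stop("overlapping targets with equal prescriptions are unordered by containment")
    }
    region <- m & !claimed
    claimed <- claimed | m
    n <- sum(region)
    if (n == 0L) next
    ci <- arrayInd(which(region), d)
    pos <- cbind(xs[ci[, 1]], ys[ci[, 2]], zs[ci[, 3]])
    centroid <- colMeans(pos)
    dist <- sqrt(rowSums((pos - rep(centroid, each = n))^2))
    ord <- order(dist, seq_len(n), decreasing = TRUE)  # far voxels first
    vals <- engineer_region_dose(n, lv$rx[r], lv$hi[r], lv$coverage[r])
    dose[which(region)[ord]] <- vals
  }
  # exponential shell falloff outside the targets
  edge_dose <- min(lv$rx) * 0.9
  step <- mean(sp)
  n_shell <- max(3L, ceiling(3 * spec$falloff_mm / step))
  covered <- claimed
  for (k in seq_len(n_shell)) {
    grown <- dilate1(covered)
    shell <- grown & !covered
    if (!any(shell)) break
    dose[shell] <- edge_dose * exp(-k * step / spec$falloff_mm)
    covered <- grown
  }
  image_volume(dose, spacing = sp, origin = targets$origin, kind = "dose")
}
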