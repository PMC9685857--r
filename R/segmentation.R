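#' ADC segmentation configuration
#'
#' Thresholds for classifying prostate voxels into dose-painting classes.
#' High-risk lesion tissue has ADC below `t_high_risk`; lower-risk lesion
#' tissue lies in `[t_high_risk, t_tumor_max)`; normal prostate tissue spans
#' `[t_tumor_max, adc_ceiling]`. Both comparisons at the band edges are
#' strict on the upper side, so an ADC exactly at `t_tumor_max` is normal
#' tissue. Components smaller than `min_component_voxels` under the chosen
#' neighbourhood connectivity are discarded as noise.
#'
#' @param t_high_risk Upper ADC bound (exclusive) for high-risk lesions.
#' @param t_tumor_max Upper ADC bound (exclusive) for lower-risk lesions.
#' @param adc_ceiling Largest valid ADC value.
#' @param min_component_voxels Minimum connected-component size kept.
#' @param connectivity 6, 18 or 26 (face / face+edge / full neighbourhood).
#' @return An object of class `segmentation_config`.
#' @export
segmentation_config <- function(t_high_risk = 750, t_tumor_max = 1500,
                                adc_ceiling = 5000, min_component_voxels = 400,
                                connectivity = 26) {
  if (!(t_high_risk > 0 && t_high_risk < t_tumor_max && t_tumor_max <= adc_ceiling))
    stop("need 0 < t_high_risk < t_tumor_max <= adc_ceiling")
  if (min_component_voxels < 1) stop("min_component_voxels must be >= 1")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  structure(list(t_high_risk = t_high_risk, t_tumor_max = t_tumor_max,
                 adc_ceiling = adc_ceiling,
                 min_component_voxels = as.integer(min_component_voxels),
                 connectivity = as.integer(connectivity)),
            class = "segmentation_config")
}

#' Classify prostate voxels by ADC band
#'
#' Partitions the prostate mask into three disjoint classes whose union is
#' exactly the prostate: `lesion_high_risk` (ADC < `t_high_risk`),
#' `lesion_lower_risk` (ADC in `[t_high_risk, t_tumor_max)`) and
#' `normal_prostate` (the rest). Voxels above `adc_ceiling` are assigned to
#' normal prostate with a warning.
#'
#' @param adc ADC [image_volume()].
#' @param prostate Prostate [structure_mask()] on the same grid.
#' @param cfg A [segmentation_config()].
#' @return A [structure_set()] with the three class masks.
#' @export
classify_adc_voxels <- function(adc, prostate, cfg = segmentation_config()) {
  stopifnot(inherits(adc, "image_volume"), inherits(prostate, "structure_mask"),
            inherits(cfg, "segmentation_config"))
  stop_if_grid_mismatch(adc, prostate, "ADC map and prostate mask")
  p <- prostate$mask
  if (!any(p)) stop("prostate mask is empty")
  v <- adc$voxels
  over <- p & v > cfg$adc_ceiling
  if (any(over))
    warning(sprintf("%d prostate voxel(s) above the ADC ceiling (%g); assigned to normal prostate",
                    sum(over), cfg$adc_ceiling))
  high <- p & v < cfg$t_high_risk
  lower <- p & v >= cfg$t_high_risk & v < cfg$t_tumor_max
  normal <- p & !high & !lower
  structure_set(list(
    structure_mask("lesion_high_risk", high, spacing = prostate$spacing,
                   origin = prostate$origin),
    structure_mask("lesion_lower_risk", lower, spacing = prostate$spacing,
                   origin = prostate$origin),
    structure_mask("normal_prostate", normal, spacing = prostate$spacing,
                   origin = prostate$origin)
  ))
}

# Neighbourhood offsets (K x 3 integer matrix) for 6/18/26 connectivity.
connectivity_offsets <- function(connectivity) {
  g <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  g <- g[rowSums(abs(g)) > 0, , drop = FALSE]
  ord <- rowSums(abs(g))
  keep <- switch(as.character(connectivity),
                 "6" = ord == 1, "18" = ord <= 2, "26" = ord <= 3,
                 stop("connectivity must be 6, 18 or 26"))
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

#' Label connected components of a boolean mask
#'
#' Breadth-first labelling under 6/18/26 connectivity; labels are assigned in
#' ascending linear-index order of each component's first voxel, so the
#' result is deterministic.
#'
#' @param mask Logical 3-D array.
#' @param connectivity 6, 18 or 26.
#' @return Integer array of the same shape; 0 = background, 1..n = components.
#' @export
label_components <- function(mask, connectivity = 26) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  dims <- dim(mask)
  labels <- array(0L, dims)
  if (!any(mask)) return(labels)
  off <- connectivity_offsets(connectivity)
  k <- nrow(off)
  unvisited <- mask
  seeds <- which(mask)
  s12 <- dims[1] * dims[2]
  current <- 0L
  for (seed in seeds) {
    if (!unvisited[seed]) next
    current <- current + 1L
    labels[seed] <- current
    unvisited[seed] <- FALSE
    frontier <- arrayInd(seed, dims)
    while (nrow(frontier)) {
      n <- nrow(frontier)
      nb <- frontier[rep(seq_len(n), each = k), , drop = FALSE] +
        off[rep(seq_len(k), times = n), , drop = FALSE]
      ok <- nb[, 1] >= 1L & nb[, 1] <= dims[1] &
        nb[, 2] >= 1L & nb[, 2] <= dims[2] &
        nb[, 3] >= 1L & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) break
      li <- nb[, 1] + (nb[, 2] - 1L) * dims[1] + (nb[, 3] - 1L) * s12
      li <- unique(li[unvisited[li]])
      if (!length(li)) break
      labels[li] <- current
      unvisited[li] <- FALSE
      frontier <- arrayInd(li, dims)
    }
  }
  labels
}

#' Remove small connected components
#'
#' Keeps only components with at least `cfg$min_component_voxels` voxels
#' under `cfg$connectivity`; idempotent and never adds voxels. An empty mask
#' passes through unchanged.
#'
#' @param mask A [structure_mask()].
#' @param cfg A [segmentation_config()].
#' @return A [structure_mask()] of the same name.
#' @export
filter_components <- function(mask, cfg = segmentation_config()) {
  stopifnot(inherits(mask, "structure_mask"), inherits(cfg, "segmentation_config"))
  lab <- label_components(mask$mask, cfg$connectivity)
  ncomp <- max(lab)
  if (ncomp == 0L) return(mask)
  sizes <- tabulate(lab[lab > 0L], nbins = ncomp)
  keep <- sizes >= cfg$min_component_voxels
  out <- array(FALSE, dim(mask$mask))
  out[lab > 0L] <- keep[lab[lab > 0L]]
  structure_mask(mask$name, out, spacing = mask$spacing, origin = mask$origin)
}

#' Margin expansion rule
#'
#' Margins are physical distances in mm. `margin_mm` is either one isotropic
#' value or six per-direction values in the order
#' `(x-, x+, y-, y+, z-, z+)` (axis sign = direction of increasing index).
#' The clinical "posterior margin reduced to zero" rule is expressed by zeroing
#' the component of the declared posterior direction with
#' [margin_vector()] — the anatomical posterior axis is configuration, never
#' inferred from the image.
#'
#' @param base_structure Name of the structure to expand.
#' @param margin_mm Length-1 or length-6 non-negative numeric (mm).
#' @param exclude Character vector of structure names subtracted from the
#'   expansion (e.g. rectum, bladder, urethra).
#' @param bound Optional name of a structure the expansion may not exceed.
#' @return An object of class `margin_rule`.
#' @export
margin_rule <- function(base_structure, margin_mm, exclude = character(0),
                        bound = NULL) {
  m <- as.numeric(margin_mm)
  if (length(m) == 1L) m <- rep(m, 6L)
  if (length(m) != 6L || any(!is.finite(m)) || any(m < 0))
    stop("margin_mm must be 1 or 6 non-negative values (mm)")
  structure(list(base_structure = base_structure, margin_mm = m,
                 exclude = as.character(exclude), bound = bound),
            class = "margin_rule")
}

#' Per-direction margin vector with selected directions zeroed
#'
#' @param iso_mm Isotropic margin (mm).
#' @param zero Character vector of directions set to zero, from
#'   `c("x-","x+","y-","y+","z-","z+")`.
#' @return Length-6 margin vector for [margin_rule()].
#' @export
margin_vector <- function(iso_mm, zero = character(0)) {
  dirs <- c("x-", "x+", "y-", "y+", "z-", "z+")
  if (!all(zero %in% dirs)) stop("unknown direction in `zero`")
  m <- rep(iso_mm, 6L)
  m[match(zero, dirs)] <- 0
  m
}

# Structuring-element offsets for an (aniso)tropic physical margin: offset o
# is included when sum_a (o_a * spacing_a / m_dir(a))^2 <= 1, using the
# margin of the direction matching the sign of o_a; a zero margin forbids any
# motion in that direction.
margin_offsets <- function(margin6, spacing) {
  lo <- floor(c(margin6[1] / spacing[1], margin6[3] / spacing[2], margin6[5] / spacing[3]))
  hi <- floor(c(margin6[2] / spacing[1], margin6[4] / spacing[2], margin6[6] / spacing[3]))
  g <- as.matrix(expand.grid(di = -lo[1]:hi[1], dj = -lo[2]:hi[2], dk = -lo[3]:hi[3]))
  keep <- logical(nrow(g))
  for (r in seq_len(nrow(g))) {
    s <- 0
    ok <- TRUE
    for (a in 1:3) {
      o <- g[r, a]
      if (o == 0) next
      m <- margin6[2 * a - if (o > 0) 0L else 1L]
      if (m == 0) { ok <- FALSE; break }
      s <- s + (o * spacing[a] / m)^2
    }
    keep[r] <- ok && s <= 1 + 1e-9
  }
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

# In-place shift-OR of `mask` translated by integer offset `o` into `acc`.
shift_or <- function(acc, mask, o) {
  d <- dim(mask)
  if (any(abs(o) >= d)) return(acc)
  ix <- if (o[1] >= 0) list((1 + o[1]):d[1], 1:(d[1] - o[1])) else list(1:(d[1] + o[1]), (1 - o[1]):d[1])
  iy <- if (o[2] >= 0) list((1 + o[2]):d[2], 1:(d[2] - o[2])) else list(1:(d[2] + o[2]), (1 - o[2]):d[2])
  iz <- if (o[3] >= 0) list((1 + o[3]):d[3], 1:(d[3] - o[3])) else list(1:(d[3] + o[3]), (1 - o[3]):d[3])
  acc[ix[[1]], iy[[1]], iz[[1]]] <- acc[ix[[1]], iy[[1]], iz[[1]]] |
    mask[ix[[2]], iy[[2]], iz[[2]]]
  acc
}

#' Expand a structure by a physical margin
#'
#' Morphological dilation with a physical-distance structuring element
#' honouring per-direction margins, followed by intersection with the
#' bounding structure (if any) and subtraction of the exclusion structures.
#' With zero margins and no exclusions the base passes through unchanged.
#'
#' @param base [structure_mask()] to expand.
#' @param rule A [margin_rule()] (its `base_structure` name is informative
#'   only; `base` is what gets expanded).
#' @param structures [structure_set()] resolving `rule$exclude`/`rule$bound`,
#'   or `NULL` when the rule references none.
#' @param name Name for the result (default `rule$base_structure`).
#' @return A [structure_mask()].
#' @export
expand_margin <- function(base, rule, structures = NULL, name = NULL) {
  stopifnot(inherits(base, "structure_mask"), inherits(rule, "margin_rule"))
  need <- c(rule$exclude, rule$bound)
  if (length(need)) {
    if (is.null(structures)) stop("rule references structures but none were supplied")
    missing <- setdiff(need, structure_names(structures))
    if (length(missing))
      stop(sprintf("unknown structure name(s): %s", paste(missing, collapse = ", ")))
  }
  off <- margin_offsets(rule$margin_mm, base$spacing)
  out <- base$mask
  for (r in seq_len(nrow(off))) {
    o <- off[r, ]
    if (all(o == 0L)) next
    out <- shift_or(out, base$mask, o)
  }
  if (!is.null(rule$bound))
    out <- out & get_structure(structures, rule$bound)$mask
  for (ex in rule$exclude)
    out <- out & !get_structure(structures, ex)$mask
  structure_mask(if (is.null(name)) rule$base_structure else name, out,
                 spacing = base$spacing, origin = base$origin)
}

#' Build the full set of dose-painting targets
#'
#' Implements the four-level target recipe: dominant intraprostatic lesions
#' (DILs) come from ADC classification plus component filtering; the
#' high-risk class becomes `CTV_70Gy` and the lower-risk class `CTV_66Gy`
#' (overridable via `risk_assignment`); `CTV_60Gy` is the prostate minus the
#' detected DILs; `CTV_53Gy` is the seminal-vesicle base. PTVs are produced
#' by margin expansion: 8 mm isotropic for `PTV_53Gy`, 5 mm with a zero
#' posterior component for `PTV_60Gy`, and 2 mm for `PTV_66Gy`/`PTV_70Gy`
#' bounded by the whole prostate (the CTV_60 union) and excluding rectum,
#' bladder and urethra. A risk class with no surviving component is omitted
#' with a message; evaluation proceeds on the remaining targets.
#'
#' @param adc ADC [image_volume()].
#' @param prostate Prostate [structure_mask()].
#' @param seminal_vesicle_base [structure_mask()] for `CTV_53Gy`, or `NULL`
#'   to omit the 53 Gy level.
#' @param oars [structure_set()] holding the exclusion organs named in
#'   `boost_exclude` (and anything else); may be `NULL` if no exclusions.
#' @param cfg A [segmentation_config()].
#' @param margins Named list of PTV margins in mm:
#'   `list(ptv70 = 2, ptv66 = 2, ptv60 = 5, ptv53 = 8)`.
#' @param posterior Direction string (see [margin_vector()]) zeroed in the
#'   `PTV_60Gy` expansion; default `"y+"`.
#' @param boost_exclude OAR names excluded from the boost PTVs.
#' @param risk_assignment Named character vector mapping class to dose level,
#'   default `c(high = "70", lower = "66")`.
#' @return A [structure_set()] with the constructed CTVs and PTVs.
#' @export
build_dose_painting_targets <- function(adc, prostate, seminal_vesicle_base = NULL,
                                        oars = NULL, cfg = segmentation_config(),
                                        margins = list(ptv70 = 2, ptv66 = 2,
                                                       ptv60 = 5, ptv53 = 8),
                                        posterior = "y+",
                                        boost_exclude = c("rectum", "bladder", "urethra"),
                                        risk_assignment = c(high = "70", lower = "66")) {
  classes <- classify_adc_voxels(adc, prostate, cfg)
  dil_high <- filter_components(get_structure(classes, "lesion_high_risk"), cfg)
  dil_lower <- filter_components(get_structure(classes, "lesion_lower_risk"), cfg)

  sp <- prostate$spacing; org <- prostate$origin
  ctvs <- list()
  add_ctv <- function(level, mask) {
    ctvs[[length(ctvs) + 1L]] <<- structure_mask(sprintf("CTV_%sGy", level), mask,
                                                 spacing = sp, origin = org)
  }
  dil_union <- array(FALSE, dim(prostate$mask))
  for (cls in c("high", "lower")) {
    m <- if (cls == "high") dil_high else dil_lower
    if (sum(m$mask) == 0L) {
      message(sprintf("no %s-risk DIL found; CTV_%sGy omitted", cls,
                      risk_assignment[[cls]]))
      next
    }
    add_ctv(risk_assignment[[cls]], m$mask)
    dil_union <- dil_union | m$mask
  }
  add_ctv("60", prostate$mask & !dil_union)
  if (!is.null(seminal_vesicle_base)) {
    stop_if_grid_mismatch(prostate, seminal_vesicle_base,
                          "prostate and seminal-vesicle base")
    add_ctv("53", seminal_vesicle_base$mask)
  }

  # resolution pool for bounds/exclusions: CTVs + prostate + any OARs
  pool <- ctvs
  pool[[length(pool) + 1L]] <- structure_mask("prostate", prostate$mask,
                                              spacing = sp, origin = org)
  if (!is.null(oars)) pool <- c(pool, unname(oars$masks))
  pool_set <- structure_set(pool)
  avail_excl <- intersect(boost_exclude, structure_names(pool_set))

  ptvs <- list()
  for (ctv in ctvs) {
    level <- sub("^CTV_(\\d+)Gy$", "\\1", ctv$name)
    ptv_name <- sprintf("PTV_%sGy", level)
    rule <- switch(level,
      "70" = margin_rule(ptv_name, margins$ptv70, exclude = avail_excl, bound = "prostate"),
      "66" = margin_rule(ptv_name, margins$ptv66, exclude = avail_excl, bound = "prostate"),
      "60" = margin_rule(ptv_name, margin_vector(margins$ptv60, zero = posterior),
                         exclude = intersect("rectum", avail_excl)),
      "53" = margin_rule(ptv_name, margins$ptv53)
    )
    ptvs[[length(ptvs) + 1L]] <- expand_margin(ctv, rule, pool_set)
  }
  structure_set(c(ctvs, ptvs))
}
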