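# Small in-code fixtures and independent oracles shared across test files.

# Unit-spacing volume from an array (defaults: 1 mm isotropic, origin 0).
vol3 <- function(arr, spacing = c(1, 1, 1), origin = c(0, 0, 0), kind = "adc") {
  image_volume(arr, spacing = spacing, origin = origin, kind = kind)
}

mask3 <- function(name, logical_arr, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  structure_mask(name, logical_arr, spacing = spacing, origin = origin)
}

# Small phantom spec for fast tests: 64 x 64 x 32 grid, lesions sized for a
# 100-voxel component floor.
small_phantom_spec <- function(seed = 1L, lesions = NULL) {
  if (is.null(lesions))
    lesions <- list(
      list(class = "high", center_offset_mm = c(8, 0, 0), radius_mm = 7,
           adc_mean = 600, adc_sd = 50),
      list(class = "lower", center_offset_mm = c(-9, 2, 1), radius_mm = 6.5,
           adc_mean = 1100, adc_sd = 80)
    )
  phantom_spec(grid_dim = c(64, 64, 32), spacing = c(1.64, 1.64, 3),
               prostate_radii_mm = c(22, 18, 17), lesions = lesions,
               seed = seed)
}

small_cfg <- function(min_component_voxels = 100, connectivity = 26)
  segmentation_config(min_component_voxels = min_component_voxels,
                      connectivity = connectivity)

# Independent flood-fill labeller: iterative minimum-label propagation over
# the neighbourhood until a fixed point. Deliberately different algorithm
# from the package's breadth-first search.
oracle_label_components <- function(mask, connectivity = 26) {
  d <- dim(mask)
  lab <- array(0, d)
  lab[mask] <- which(mask)  # seed with linear indices
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[rowSums(abs(offs)) > 0 & rowSums(abs(offs)) <= switch(
    as.character(connectivity), "6" = 1, "18" = 2, "26" = 3), , drop = FALSE]
  shift_min <- function(lab, o) {
    out <- lab
    src <- dst <- vector("list", 3)
    for (a in 1:3) {
      if (abs(o[a]) >= d[a]) return(lab)
      if (o[a] >= 0) { dst[[a]] <- (1 + o[a]):d[a]; src[[a]] <- 1:(d[a] - o[a]) }
      else { dst[[a]] <- 1:(d[a] + o[a]); src[[a]] <- (1 - o[a]):d[a] }
    }
    moved <- array(Inf, d)
    moved[dst[[1]], dst[[2]], dst[[3]]] <- lab[src[[1]], src[[2]], src[[3]]]
    moved[moved == 0] <- Inf
    cur <- out
    cur[cur == 0] <- Inf
    res <- pmin(cur, moved)
    res[!mask] <- 0
    res[is.infinite(res)] <- 0
    res
  }
  repeat {
    prev <- lab
    for (r in seq_len(nrow(offs))) lab <- shift_min(lab, offs[r, ])
    if (identical(lab, prev)) break
  }
  # canonicalize labels to 1..k in first-seen order
  ids <- unique(lab[lab > 0])
  out <- array(0L, d)
  for (i in seq_along(ids)) out[lab == ids[i]] <- i
  out
}

# Brute-force Euclidean dilation: voxel in output iff its centre lies within
# `margin_mm` of some base voxel centre (physical distances).
oracle_dilate <- function(base_mask, spacing, margin_mm) {
  d <- dim(base_mask)
  idx <- which(base_mask)
  ci <- arrayInd(idx, d)
  pts <- sweep(ci - 1, 2, spacing, "*")
  out <- array(FALSE, d)
  all_ci <- arrayInd(seq_len(prod(d)), d)
  all_pts <- sweep(all_ci - 1, 2, spacing, "*")
  for (v in seq_len(nrow(all_pts))) {
    dd <- sqrt(colSums((t(pts) - all_pts[v, ])^2))
    if (min(dd) <= margin_mm + 1e-9) out[v] <- TRUE
  }
  out
}

# Random logical blob field for property tests.
random_mask <- function(d, p = 0.2) array(stats::runif(prod(d)) < p, d)
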