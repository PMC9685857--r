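#' Planning objective rule
#'
#' One dose-volume or max-dose constraint on a structure. Metrics:
#' * `"V_Gy_pct"`: percent of the structure receiving at least `x` Gy
#' * `"V_pctRx_pct"`: percent receiving at least `x`% of the structure's
#'   prescription (needs a prescription at check time)
#' * `"Dmax"`: maximum dose in Gy (`x` unused)
#' * `"V_Gy_cc"`: absolute volume (cc) receiving at least `x` Gy
#'
#' @param structure Structure name.
#' @param metric One of the metric codes above.
#' @param x Metric argument (Gy or percent; ignored for `Dmax`).
#' @param threshold Finite constraint value (same units as the metric).
#' @param direction `"<"` or `">"`: the metric must compare this way to the
#'   threshold to pass.
#' @return An object of class `objective_rule`.
#' @export
objective_rule <- function(structure, metric = c("V_Gy_pct", "V_pctRx_pct",
                                                 "Dmax", "V_Gy_cc"),
                           x = NA_real_, threshold, direction = c("<", ">")) {
  metric <- match.arg(metric)
  direction <- match.arg(direction)
  if (!is.finite(threshold)) stop("threshold must be finite")
  if (metric != "Dmax" && !is.finite(x)) stop("metric needs a finite x")
  structure(list(structure = structure, metric = metric, x = x,
                 threshold = threshold, direction = direction),
            class = "objective_rule")
}

#' Standard prostate dose-painting optimization objectives
#'
#' The OAR and PTV objective battery used for the plans this package
#' evaluates: bladder/rectum dose-volume limits, femoral-head and bowel
#' maxima, and per-PTV coverage (`V_98% > 98%`) and hot-spot
#' (`V_105% < 2%`) constraints.
#'
#' @param ptv_names Character vector of PTV structure names the coverage and
#'   hot-spot rules are instantiated for.
#' @return List of [objective_rule()]s.
#' @export
default_planning_objectives <- function(ptv_names = c("PTV_70Gy", "PTV_66Gy",
                                                      "PTV_60Gy", "PTV_53Gy")) {
  rules <- list(
    objective_rule("bladder", "V_Gy_pct", 40.8, 50, "<"),
    objective_rule("bladder", "V_Gy_pct", 48.6, 25, "<"),
    objective_rule("bladder", "V_Gy_pct", 60, 5, "<"),
    objective_rule("bladder", "Dmax", threshold = 65, direction = "<"),
    objective_rule("rectum", "V_Gy_pct", 40.8, 50, "<"),
    objective_rule("rectum", "V_Gy_pct", 48.6, 35, "<"),
    objective_rule("rectum", "Dmax", threshold = 65, direction = "<"),
    objective_rule("rectum", "V_Gy_pct", 60, 3, "<"),
    objective_rule("femoral_heads", "Dmax", threshold = 40, direction = "<"),
    objective_rule("bowel", "V_Gy_cc", 50, 17, "<"),
    objective_rule("bowel", "Dmax", threshold = 60, direction = "<")
  )
  for (p in ptv_names) {
    rules[[length(rules) + 1L]] <- objective_rule(p, "V_pctRx_pct", 98, 98, ">")
    rules[[length(rules) + 1L]] <- objective_rule(p, "V_pctRx_pct", 105, 2, "<")
  }
  rules
}

#' Check planning objectives against a dose grid
#'
#' Evaluates each rule's metric on the named structure and reports the
#' computed value with a pass/fail flag. Rules whose structure is absent
#' raise an error (a mis-named constraint must never silently pass).
#'
#' @param dose Dose [image_volume()] in Gy.
#' @param structures [structure_set()] with every structure the rules name.
#' @param rules List of [objective_rule()]s.
#' @param prescriptions Named numeric vector of prescriptions in Gy for the
#'   structures addressed by `V_pctRx_pct` rules.
#' @return Data frame: structure, metric, x, value, threshold, direction, pass.
#' @export
check_objectives <- function(dose, structures, rules,
                             prescriptions = c(PTV_70Gy = 70, PTV_66Gy = 66,
                                               PTV_60Gy = 60, PTV_53Gy = 53)) {
  stopifnot(inherits(dose, "image_volume"), inherits(structures, "structure_set"))
  rows <- lapply(rules, function(r) {
    m <- get_structure(structures, r$structure)
    stop_if_grid_mismatch(dose, m, "dose grid and structure")
    d <- dose$voxels[m$mask]
    if (!length(d)) stop(sprintf("structure '%s' is empty", r$structure))
    value <- switch(r$metric,
      V_Gy_pct = 100 * mean(d >= r$x),
      V_Gy_cc = sum(d >= r$x) * prod(m$spacing) / 1000,
      Dmax = max(d),
      V_pctRx_pct = {
        rx <- prescriptions[[r$structure]]
        if (is.null(rx) || !is.finite(rx))
          stop(sprintf("no prescription for '%s'", r$structure))
        100 * mean(d >= r$x / 100 * rx)
      })
    pass <- if (r$direction == "<") value < r$threshold else value > r$threshold
    data.frame(structure = r$structure, metric = r$metric, x = r$x,
               value = value, threshold = r$threshold,
               direction = r$direction, pass = pass)
  })
  do.call(rbind, rows)
}
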