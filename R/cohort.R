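#' Run the full evaluation pipeline on one phantom case
#'
#' Segmentation (classify + component filter + margin expansion via
#' [build_dose_painting_targets()]), engineered dose generation, per-target
#' DVH/HI/CI, density weighting, the six plan indices and per-CTV Poisson
#' TCP — the complete chain a clinical case would follow.
#'
#' @param phantom Result of [generate_adc_phantom()].
#' @param dose_spec A [dose_spec()]; its levels address the constructed CTVs.
#' @param cfg A [segmentation_config()].
#' @param tcp_params A [tcp_parameters()].
#' @param density_model A [density_model()].
#' @return List with `targets` (the constructed [structure_set()]), `dose`,
#'   `evaluation` (a [evaluate_plan()] result), `tcp` (named list of
#'   [tcp_poisson()] results per CTV) and `row` (one cohort-table row).
#' @export
evaluate_dose_painting_case <- function(phantom, dose_spec = dpeval::dose_spec(),
                                        cfg = segmentation_config(),
                                        tcp_params = tcp_parameters(),
                                        density_model = dpeval::density_model()) {
  prostate <- get_structure(phantom$truth, "prostate")
  sv <- get_structure(phantom$organs, "sv_base")
  targets <- build_dose_painting_targets(phantom$adc, prostate,
                                         seminal_vesicle_base = sv,
                                         oars = phantom$organs, cfg = cfg)
  dose <- generate_dose_distribution(targets, dose_spec)
  rx_all <- c(CTV_70Gy = 70, CTV_66Gy = 66, CTV_60Gy = 60)
  ev <- evaluate_plan(dose, targets, rx_all, adc = phantom$adc,
                      density_model = density_model,
                      evaluate = intersect(names(rx_all), structure_names(targets)))
  tcp <- lapply(ev$dvhs, tcp_poisson, params = tcp_params)
  row <- data.frame(ioe_h_density = ev$ioe_h_density, ioe_h_plain = ev$ioe_h_plain,
                    ioe_c_density = ev$ioe_c_density, ioe_c_plain = ev$ioe_c_plain,
                    hi_mean = ev$hi_mean, ci_mean = ev$ci_mean)
  for (nm in names(tcp))
    row[[paste0("tcp_", tolower(gsub("_|Gy", "", nm)))]] <- tcp[[nm]]$tcp
  list(targets = targets, dose = dose, evaluation = ev, tcp = tcp, row = row)
}

#' Generate and evaluate a synthetic patient cohort
#'
#' Stands in for a multi-patient clinical cohort: `n` phantom + plan pairs
#' with randomized lesion geometry, lesion/normal ADC, per-target engineered
#' homogeneity, and per-target coverage. Coverage drives both the
#' conformity indices and (through DVH cold tails) the TCP, so the cohort
#' carries a built-in positive coverage-TCP relation. Every draw descends
#' from `seed` (one sub-seed per patient), so the cohort is fully
#' reproducible.
#'
#' @param n Number of patients (default 20).
#' @param seed Integer master seed.
#' @param coverage_range Per-target engineered coverage is drawn uniformly
#'   from this interval.
#' @param hi_means,hi_sds Engineered homogeneity draws for CTV 70/66/60 Gy
#'   (normal, truncated below at 0.03).
#' @param cfg,tcp_params,density_model Passed through the pipeline.
#' @param vary_geometry When `TRUE` (default), lesion radii and region ADC
#'   means are redrawn per patient and each phantom gets its own noise
#'   seed. When `FALSE`, every patient reuses the default geometry and the
#'   master seed, so with `hi_sds = 0` and a degenerate `coverage_range`
#'   all cohort rows are identical — the zero-variability control.
#' @param keep_cases Keep the per-patient pipeline outputs (memory-heavy).
#' @return An object of class `dp_cohort`: `$table` (one row per patient)
#'   plus the generation settings; with `keep_cases`, `$cases`.
#' @export
generate_cohort <- function(n = 20, seed = 1L,
                            coverage_range = c(0.92, 0.999),
                            hi_means = c(0.086, 0.078, 0.151),
                            hi_sds = c(0.011, 0.005, 0.016),
                            cfg = segmentation_config(),
                            tcp_params = tcp_parameters(),
                            density_model = dpeval::density_model(),
                            vary_geometry = TRUE, keep_cases = FALSE) {
  if (n < 1) stop("n must be >= 1")
  rows <- vector("list", n)
  cases <- if (keep_cases) vector("list", n) else NULL
  for (i in seq_len(n)) {
    sub_seed <- (as.integer(seed) + i * 1009L) %% .Machine$integer.max
    set.seed(sub_seed)
    spec <- if (vary_geometry) {
      phantom_spec(
        lesions = list(
          list(class = "high", center_offset_mm = c(10, 0, 0),
               radius_mm = stats::runif(1, 9.7, 10.8),
               adc_mean = stats::runif(1, 550, 680), adc_sd = 50),
          list(class = "lower", center_offset_mm = c(-11, 3, 2),
               radius_mm = stats::runif(1, 9.7, 10.4),
               adc_mean = stats::runif(1, 1000, 1250), adc_sd = 80)
        ),
        normal_adc_mean = stats::runif(1, 1900, 2200),
        seed = sub_seed
      )
    } else {
      phantom_spec(seed = as.integer(seed))
    }
    hi <- pmax(stats::rnorm(3, hi_means, hi_sds), 0.03)
    cov <- stats::runif(3, coverage_range[1], coverage_range[2])
    ds <- dose_spec(levels = data.frame(
      name = c("CTV_70Gy", "CTV_66Gy", "CTV_60Gy", "CTV_53Gy"),
      rx = c(70, 66, 60, 53),
      hi = c(hi, 0.105), coverage = c(cov, 0.994)
    ))
    case <- evaluate_dose_painting_case(generate_adc_phantom(spec), ds,
                                        cfg = cfg, tcp_params = tcp_params,
                                        density_model = density_model)
    case$row$patient <- i
    rows[[i]] <- case$row
    if (keep_cases) cases[[i]] <- case
  }
  tab <- do.call(rbind, rows)
  tab <- tab[, c("patient", setdiff(names(tab), "patient"))]
  structure(list(table = tab, n = n, seed = seed, cases = cases),
            class = "dp_cohort")
}

#' @export
print.dp_cohort <- function(x, ...) {
  cat(sprintf("<dp_cohort> %d synthetic patients (seed %d)\n", x$n, x$seed))
  print(utils::head(x$table, 5), digits = 4)
  if (x$n > 5) cat(sprintf("  ... %d more rows\n", x$n - 5))
  invisible(x)
}
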