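test_that("phantom generation is deterministic under a fixed seed", {
  a <- generate_adc_phantom(small_phantom_spec(seed = 7))
  b <- generate_adc_phantom(small_phantom_spec(seed = 7))
  expect_identical(a$adc$voxels, b$adc$voxels)
  expect_identical(get_structure(a$truth, "prostate")$mask,
                   get_structure(b$truth, "prostate")$mask)
  c <- generate_adc_phantom(small_phantom_spec(seed = 8))
  expect_false(identical(a$adc$voxels, c$adc$voxels))
})

test_that("segmentation recovers the engineered lesions (Dice >= 0.95)", {
  ph <- generate_adc_phantom(small_phantom_spec(seed = 13))
  cls <- classify_adc_voxels(ph$adc, get_structure(ph$truth, "prostate"),
                             small_cfg())
  for (class_name in c("lesion_high_risk", "lesion_lower_risk")) {
    seg <- filter_components(get_structure(cls, class_name), small_cfg())
    truth <- get_structure(ph$truth, class_name)
    dice <- 2 * sum(seg$mask & truth$mask) / (sum(seg$mask) + sum(truth$mask))
    expect_gte(dice, 0.95)
  }
})

test_that("a lesion-free phantom classifies as pure normal tissue", {
  spec <- small_phantom_spec(seed = 17, lesions = list())
  ph <- generate_adc_phantom(spec)
  cls <- classify_adc_voxels(ph$adc, get_structure(ph$truth, "prostate"),
                             small_cfg())
  seg_high <- filter_components(get_structure(cls, "lesion_high_risk"), small_cfg())
  seg_lower <- filter_components(get_structure(cls, "lesion_lower_risk"), small_cfg())
  expect_false(any(seg_high$mask))
  expect_false(any(seg_lower$mask))
})

test_that("lesions outside the prostate or overlapping each other are rejected", {
  bad <- small_phantom_spec(lesions = list(
    list(class = "high", center_offset_mm = c(30, 0, 0), radius_mm = 7,
         adc_mean = 600, adc_sd = 50)))
  expect_error(generate_adc_phantom(bad), "outside the prostate")
  overlap <- small_phantom_spec(lesions = list(
    list(class = "high", center_offset_mm = c(2, 0, 0), radius_mm = 7,
         adc_mean = 600, adc_sd = 50),
    list(class = "lower", center_offset_mm = c(-2, 0, 0), radius_mm = 7,
         adc_mean = 1100, adc_sd = 80)))
  expect_error(generate_adc_phantom(overlap), "overlaps")
})

test_that("engineered perfection yields HI = 0 and coverage CI = 1", {
  ph <- generate_adc_phantom(small_phantom_spec(seed = 19))
  tg <- structure_set(list(
    structure_mask("CTV_70Gy", get_structure(ph$truth, "lesion_high_risk")$mask,
                   reference = ph$adc),
    structure_mask("CTV_60Gy",
                   get_structure(ph$truth, "prostate")$mask &
                     !get_structure(ph$truth, "lesion_high_risk")$mask &
                     !get_structure(ph$truth, "lesion_lower_risk")$mask,
                   reference = ph$adc)))
  ds <- dose_spec(levels = data.frame(name = c("CTV_70Gy", "CTV_60Gy"),
                                      rx = c(70, 60), hi = c(0, 0),
                                      coverage = c(1, 1)))
  dose <- generate_dose_distribution(tg, ds)
  for (nm in c("CTV_70Gy", "CTV_60Gy")) {
    m <- get_structure(tg, nm)
    dv <- compute_dvh(dose, m)
    rx <- if (nm == "CTV_70Gy") 70 else 60
    expect_lt(homogeneity_index(dv), 2 * dv$bin_width / rx)
    expect_equal(conformity_index(dose, m, rx), 1)
  }
})

test_that("engineered homogeneity and coverage are recovered from the dose grid", {
  ph <- generate_adc_phantom(small_phantom_spec(seed = 23))
  dils <- get_structure(ph$truth, "lesion_high_risk")$mask |
    get_structure(ph$truth, "lesion_lower_risk")$mask
  tg <- structure_set(list(
    structure_mask("CTV_70Gy", get_structure(ph$truth, "lesion_high_risk")$mask,
                   reference = ph$adc),
    structure_mask("CTV_60Gy", get_structure(ph$truth, "prostate")$mask & !dils,
                   reference = ph$adc)))
  ds <- dose_spec(levels = data.frame(name = c("CTV_70Gy", "CTV_60Gy"),
                                      rx = c(70, 60), hi = c(0.10, 0.151),
                                      coverage = c(0.95, 0.992)))
  dose <- generate_dose_distribution(tg, ds)
  hi70 <- homogeneity_index(compute_dvh(dose, get_structure(tg, "CTV_70Gy")))
  hi60 <- homogeneity_index(compute_dvh(dose, get_structure(tg, "CTV_60Gy")))
  ci70 <- conformity_index(dose, get_structure(tg, "CTV_70Gy"), 70)
  ci60 <- conformity_index(dose, get_structure(tg, "CTV_60Gy"), 60)
  expect_lt(abs(hi70 - 0.10), 0.01)
  expect_lt(abs(hi60 - 0.151), 0.01)
  expect_lt(abs(ci70 - 0.95), 0.01)
  expect_lt(abs(ci60 - 0.992), 0.01)
})

test_that("overlapping equal prescriptions are rejected as unordered", {
  d <- c(10, 10, 4)
  m1 <- array(FALSE, d); m1[2:6, 2:6, 2:3] <- TRUE
  m2 <- array(FALSE, d); m2[4:8, 4:8, 2:3] <- TRUE
  tg <- structure_set(list(mask3("a", m1), mask3("b", m2)))
  ds <- dose_spec(levels = data.frame(name = c("a", "b"), rx = c(60, 60),
                                      hi = c(0.1, 0.1), coverage = c(1, 1)))
  expect_error(generate_dose_distribution(tg, ds), "unordered")
  # nested prescriptions resolve by containment: inner boost overrides
  ds2 <- dose_spec(levels = data.frame(name = c("a", "b"), rx = c(70, 60),
                                       hi = c(0, 0), coverage = c(1, 1)))
  dose <- generate_dose_distribution(tg, ds2)
  expect_true(all(dose$voxels[m1] >= 70))
  expect_true(all(dose$voxels[m2 & !m1] >= 60 & dose$voxels[m2 & !m1] < 70))
})

test_that("zero-variability cohorts collapse to identical rows", {
  coh <- generate_cohort(n = 2, seed = 5, coverage_range = c(0.97, 0.97),
                         hi_sds = c(0, 0, 0), vary_geometry = FALSE,
                         cfg = segmentation_config())
  expect_equal(nrow(coh$table), 2)
  expect_equal(unlist(coh$table[1, -1]), unlist(coh$table[2, -1]),
               tolerance = 1e-12)
})
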