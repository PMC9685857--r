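test_that("ADC classification partitions the prostate with strict band edges", {
  d <- c(12, 12, 6)
  prostate <- array(FALSE, d); prostate[2:11, 2:11, 2:5] <- TRUE
  adc <- array(2000, d)
  blob <- array(FALSE, d); blob[3:5, 3:5, 2:3] <- TRUE
  adc[blob] <- 600
  cls <- classify_adc_voxels(vol3(adc), mask3("prostate", prostate))
  expect_identical(get_structure(cls, "lesion_high_risk")$mask, blob)
  expect_identical(get_structure(cls, "normal_prostate")$mask, prostate & !blob)
  expect_false(any(get_structure(cls, "lesion_lower_risk")$mask))

  # pairwise disjoint and union exactly the prostate
  h <- get_structure(cls, "lesion_high_risk")$mask
  l <- get_structure(cls, "lesion_lower_risk")$mask
  n <- get_structure(cls, "normal_prostate")$mask
  expect_false(any(h & l) || any(h & n) || any(l & n))
  expect_identical(h | l | n, prostate)

  # boundary values: 750 is lower-risk, 1500 is normal
  adc2 <- array(1500, d); adc2[3, 3, 3] <- 750; adc2[4, 4, 4] <- 749.99
  cls2 <- classify_adc_voxels(vol3(adc2), mask3("prostate", prostate))
  expect_false(any(get_structure(cls2, "normal_prostate")$mask[3, 3, 3]))
  expect_true(get_structure(cls2, "lesion_lower_risk")$mask[3, 3, 3])
  expect_true(get_structure(cls2, "lesion_high_risk")$mask[4, 4, 4])
  expect_equal(sum(get_structure(cls2, "normal_prostate")$mask),
               sum(prostate) - 2)

  # above-ceiling voxels go to normal tissue with a warning
  adc3 <- array(2000, d); adc3[5, 5, 3] <- 5400
  expect_warning(cls3 <- classify_adc_voxels(vol3(adc3), mask3("prostate", prostate)),
                 "ceiling")
  expect_true(get_structure(cls3, "normal_prostate")$mask[5, 5, 3])

  expect_error(classify_adc_voxels(vol3(adc), mask3("p", array(FALSE, d))), "empty")
})

test_that("component filter keeps exactly the components at or above the floor", {
  d <- c(30, 30, 10)
  m <- array(FALSE, d)
  m[1:10, 1:10, 1:5] <- TRUE                # 500 voxels
  cfg <- segmentation_config(min_component_voxels = 400)
  kept <- filter_components(mask3("m", m), cfg)
  expect_identical(kept$mask, m)

  m399 <- array(FALSE, d); m399[1:399] <- TRUE  # contiguous run along x-col
  m399 <- array(FALSE, d)
  m399[1:10, 1:10, 1:4] <- TRUE; m399[1, 1, 1] <- FALSE  # 399 voxels
  expect_false(any(filter_components(mask3("m", m399), cfg)$mask))
})

test_that("component filter agrees with an independent flood-fill labeller", {
  d <- c(24, 24, 12)
  m <- array(FALSE, d)
  m[2:6, 2:6, 2:3] <- TRUE                   # 50
  m[10:19, 10:17, 2:6] <- TRUE               # 400 exactly at the floor
  m[2:11, 14:23, 8:12] <- TRUE               # 500, k-gap of 2 from the others
  for (conn in c(6, 26)) {
    lab_pkg <- label_components(m, conn)
    lab_or <- oracle_label_components(m, conn)
    expect_equal(max(lab_pkg), max(lab_or))
    # same partition: component memberships agree voxel-for-voxel
    expect_true(all(tapply(lab_or[m], lab_pkg[m], function(x) length(unique(x))) == 1))
    cfg <- segmentation_config(min_component_voxels = 400, connectivity = conn)
    kept <- filter_components(mask3("m", m), cfg)$mask
    sizes <- tabulate(lab_or[lab_or > 0])
    oracle_kept <- array(FALSE, d)
    oracle_kept[lab_or > 0] <- sizes[lab_or[lab_or > 0]] >= 400
    expect_identical(kept, oracle_kept)
  }
})

test_that("component filter is idempotent and never adds voxels", {
  set.seed(42)
  cfg <- segmentation_config(min_component_voxels = 5)
  for (i in 1:5) {
    m <- random_mask(c(15, 15, 8), p = 0.25)
    once <- filter_components(mask3("m", m), cfg)
    twice <- filter_components(once, cfg)
    expect_identical(once$mask, twice$mask)
    expect_true(all(!once$mask | m))
  }
  empty <- mask3("e", array(FALSE, c(4, 4, 4)))
  expect_false(any(filter_components(empty, cfg)$mask))
})

test_that("margin expansion matches a brute-force Euclidean-distance oracle", {
  d <- c(15, 15, 15)
  base <- array(FALSE, d); base[8, 8, 8] <- TRUE
  bm <- mask3("seed", base)
  out <- expand_margin(bm, margin_rule("ball", 5))
  expect_identical(out$mask, oracle_dilate(base, c(1, 1, 1), 5))

  # anisotropic spacing honoured as physical distance
  bm2 <- mask3("seed", base, spacing = c(1, 1, 2.5))
  out2 <- expand_margin(bm2, margin_rule("ball", 5))
  expect_identical(out2$mask, oracle_dilate(base, c(1, 1, 2.5), 5))
})

test_that("margin expansion: identity, monotonicity, exclusion and bounds", {
  d <- c(20, 20, 10)
  base <- array(FALSE, d); base[8:12, 8:12, 4:6] <- TRUE
  bm <- mask3("CTV", base)
  expect_identical(expand_margin(bm, margin_rule("x", 0))$mask, base)

  m2 <- expand_margin(bm, margin_rule("x", 2))$mask
  m5 <- expand_margin(bm, margin_rule("x", 5))$mask
  expect_true(all(!m2 | m5))  # larger margin is a superset
  expect_true(all(!base | m2))

  rectum <- array(FALSE, d); rectum[8:12, 14:20, ] <- TRUE
  ss <- structure_set(list(bm, mask3("rectum", rectum)))
  excl <- expand_margin(bm, margin_rule("PTV", 3, exclude = "rectum"), ss)
  expect_false(any(excl$mask & rectum))
  expect_true(all(!(base & !rectum) | excl$mask))  # base minus exclusion kept

  bound <- array(FALSE, d); bound[6:14, 6:14, 3:7] <- TRUE
  bnd <- expand_margin(bm, margin_rule("PTV", 4, bound = "bnd"),
                       structure_set(list(bm, mask3("bnd", bound))))
  expect_true(all(!bnd$mask | bound))

  # zeroed posterior direction: no growth toward +y
  v <- margin_vector(3, zero = "y+")
  post <- expand_margin(bm, margin_rule("PTV60", v))$mask
  expect_false(any(post[, 13:20, ]))   # base ends at j = 12
  expect_true(any(post[, 5:7, ]))      # anterior growth present

  expect_error(expand_margin(bm, margin_rule("x", 2, exclude = "nope"), ss),
               "unknown structure")
})

test_that("target construction partitions the prostate and respects bounds", {
  ph <- generate_adc_phantom(small_phantom_spec(seed = 3))
  cfg <- small_cfg()
  tg <- build_dose_painting_targets(ph$adc, get_structure(ph$truth, "prostate"),
                                    seminal_vesicle_base = get_structure(ph$organs, "sv_base"),
                                    oars = ph$organs, cfg = cfg)
  nm <- structure_names(tg)
  expect_true(all(c("CTV_70Gy", "CTV_66Gy", "CTV_60Gy", "CTV_53Gy",
                    "PTV_70Gy", "PTV_66Gy", "PTV_60Gy", "PTV_53Gy") %in% nm))
  p <- get_structure(ph$truth, "prostate")$mask
  c70 <- get_structure(tg, "CTV_70Gy")$mask
  c66 <- get_structure(tg, "CTV_66Gy")$mask
  c60 <- get_structure(tg, "CTV_60Gy")$mask
  expect_false(any(c70 & c60) || any(c66 & c60) || any(c70 & c66))
  expect_identical(c70 | c66 | c60, p)
  # boost PTVs bounded by the prostate and clear of the OAR exclusions
  for (ptv in c("PTV_70Gy", "PTV_66Gy")) {
    pm <- get_structure(tg, ptv)$mask
    expect_true(all(!pm | p))
    for (oar in c("rectum", "bladder", "urethra"))
      expect_false(any(pm & get_structure(ph$organs, oar)$mask))
  }
  # construction counts: CTVs recover the ground-truth lesion classes
  expect_gt(sum(c70 & get_structure(ph$truth, "lesion_high_risk")$mask) /
              sum(c70 | get_structure(ph$truth, "lesion_high_risk")$mask), 0.9)
})

test_that("a missing risk class drops its CTV and evaluation proceeds", {
  spec <- small_phantom_spec(seed = 5, lesions = list(
    list(class = "lower", center_offset_mm = c(-9, 2, 1), radius_mm = 6.5,
         adc_mean = 1100, adc_sd = 80)))
  ph <- generate_adc_phantom(spec)
  expect_message(
    tg <- build_dose_painting_targets(ph$adc, get_structure(ph$truth, "prostate"),
                                      oars = ph$organs, cfg = small_cfg()),
    "CTV_70Gy omitted")
  expect_false("CTV_70Gy" %in% structure_names(tg))
  expect_true(all(c("CTV_66Gy", "CTV_60Gy") %in% structure_names(tg)))
})
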