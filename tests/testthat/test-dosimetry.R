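test_that("DVH conservation: fractions sum to 1, cumulative non-increasing", {
  set.seed(31)
  d <- c(12, 12, 6)
  dose <- vol3(array(runif(prod(d), 40, 75), d), kind = "dose")
  m <- mask3("t", random_mask(d, 0.4))
  dv <- compute_dvh(dose, m)
  expect_equal(sum(dv$diff_fraction), 1, tolerance = 1e-9)
  expect_true(all(diff(dv$cum_cc) <= 1e-12))
  expect_equal(dv$cum_cc[1], volume_cc(m))
  expect_equal(dv$total_cc, volume_cc(m))
})

test_that("uniform and two-voxel DVHs behave analytically", {
  d <- c(4, 4, 2)
  uni <- vol3(array(70, d), kind = "dose")
  m <- mask3("t", array(TRUE, d))
  dv <- compute_dvh(uni, m)
  expect_equal(sum(dv$counts > 0), 1)          # one occupied bin
  expect_equal(dv$cum_fraction[dv$bin_lo <= 70], rep(1, sum(dv$bin_lo <= 70)))

  two <- array(0, c(2, 1, 1)); two[1] <- 60; two[2] <- 70
  dv2 <- compute_dvh(vol3(two, kind = "dose"), mask3("t", array(TRUE, c(2, 1, 1))))
  v65 <- dv2$cum_fraction[max(which(dv2$bin_lo <= 65))]
  expect_equal(v65, 0.5)                       # V_65Gy = 50%

  expect_error(compute_dvh(uni, mask3("e", array(FALSE, d))), "empty")
  neg <- vol3(array(-1, d), kind = "adc")
  expect_error(compute_dvh(neg, m), "negative")
})

test_that("cumulative DVH matches brute-force voxel counting at 20 thresholds", {
  set.seed(33)
  d <- c(16, 16, 8)
  doses <- array(runif(prod(d), 0, 80), d)
  m <- random_mask(d, 0.5)
  dv <- compute_dvh(vol3(doses, kind = "dose"), mask3("t", m), bin_width = 0.05)
  sel <- doses[m]
  for (thr in seq(2, 78, length.out = 20)) {
    # counting oracle: fraction of voxels at or above the bin edge <= thr
    edge_idx <- max(which(dv$bin_lo <= thr))
    oracle <- mean(sel >= dv$bin_lo[edge_idx])
    expect_equal(dv$cum_fraction[edge_idx], oracle, tolerance = 1e-12)
  }
})

test_that("percentile doses interpolate correctly and converge with bin width", {
  d <- c(10, 10, 10)
  uni <- compute_dvh(vol3(array(70, d), kind = "dose"), mask3("t", array(TRUE, d)))
  for (p in c(2, 50, 98))
    expect_equal(dose_at_volume(uni, p), 70, tolerance = uni$bin_width)

  # linear ramp of doses 0..100 over equal volumes
  ramp <- array(seq(0, 100, length.out = 1000), c(10, 10, 10))
  dvr <- compute_dvh(vol3(ramp, kind = "dose"), mask3("t", array(TRUE, d)))
  expect_equal(dose_at_volume(dvr, 50), 50, tolerance = 2 * dvr$bin_width)
  expect_equal(dose_at_volume(dvr, 2), 98, tolerance = 2 * dvr$bin_width)

  dvr2 <- compute_dvh(vol3(ramp, kind = "dose"), mask3("t", array(TRUE, d)),
                      bin_width = 0.025)
  for (p in c(2, 50, 98))
    expect_lt(abs(dose_at_volume(dvr, p) - dose_at_volume(dvr2, p)), 0.05)

  expect_error(dose_at_volume(dvr, 0), "between")
  expect_error(dose_at_volume(dvr, 100), "between")
  expect_true(dose_at_volume(dvr, 2) >= dose_at_volume(dvr, 50))
  expect_true(dose_at_volume(dvr, 50) >= dose_at_volume(dvr, 98))
})

test_that("homogeneity index follows its defining ratio and monotonicity", {
  # hand-built distribution with D2 = 74.2, D98 = 68.2, D50 = 70:
  # (74.2 - 68.2) / 70 = 0.0857...
  doses <- c(rep(74.2, 20),                       # exactly 2% at D2
             seq(74.19, 70.01, length.out = 480),
             seq(69.99, 68.21, length.out = 480),
             rep(68.2, 20))                       # bottom 2% at D98
  dv <- compute_dvh(vol3(array(doses, c(10, 10, 10)), kind = "dose"),
                    mask3("t", array(TRUE, c(10, 10, 10))), bin_width = 0.01)
  expect_equal(homogeneity_index(dv), 6 / 70, tolerance = 0.003)

  # uniform dose -> HI ~ 0 (within binning resolution)
  uni <- compute_dvh(vol3(array(70, c(5, 5, 5)), kind = "dose"),
                     mask3("t", array(TRUE, c(5, 5, 5))))
  expect_lt(homogeneity_index(uni), 2 * uni$bin_width / 70)

  # widening the spread at fixed centre strictly increases HI;
  # uniform scaling leaves the icru83 ratio unchanged
  mk <- function(spread, scale = 1) {
    x <- scale * seq(70 - spread, 70 + spread, length.out = 512)
    compute_dvh(vol3(array(x, c(8, 8, 8)), kind = "dose"),
                mask3("t", array(TRUE, c(8, 8, 8))), bin_width = 0.01)
  }
  his <- vapply(c(1, 2, 4), function(s) homogeneity_index(mk(s)), numeric(1))
  expect_true(all(diff(his) > 0))
  expect_equal(homogeneity_index(mk(2, scale = 1.3)), homogeneity_index(mk(2)),
               tolerance = 1e-2)

  expect_equal(homogeneity_index(mk(2), "d5d95", prescription = 70),
               (dose_at_volume(mk(2), 5) - dose_at_volume(mk(2), 95)) / 70)
})

test_that("conformity index counts coverage and penalizes spill (Paddick)", {
  d <- c(10, 10, 4)
  m <- array(FALSE, d); m[3:8, 3:8, 2:3] <- TRUE
  tgt <- mask3("t", m)
  hot_all <- vol3(array(71, d), kind = "dose")
  expect_equal(conformity_index(hot_all, tgt, 70), 1)

  half <- array(80, d); half[3:5, 3:8, 2:3] <- 60  # half the target cold
  expect_equal(conformity_index(vol3(half, kind = "dose"), tgt, 70), 0.5)

  set.seed(35)
  rnd <- array(runif(prod(d), 60, 80), d)
  ci <- conformity_index(vol3(rnd, kind = "dose"), tgt, 70)
  expect_equal(ci, mean(rnd[m] >= 70))  # counting oracle
  expect_true(ci >= 0 && ci <= 1)

  # coverage CI non-decreasing as the prescription drops
  cis <- vapply(c(78, 74, 70, 66), function(rx)
    conformity_index(vol3(rnd, kind = "dose"), tgt, rx), numeric(1))
  expect_true(all(diff(cis) >= 0))

  # Paddick: perfect conformity only when hot region == target
  exact <- array(0, d); exact[m] <- 71
  expect_equal(conformity_index(vol3(exact, kind = "dose"), tgt, 70, "paddick"), 1)
  expect_lt(conformity_index(hot_all, tgt, 70, "paddick"), 1)
})

test_that("objective checks evaluate metric values against their rules", {
  d <- c(10, 10, 4)
  dose <- array(30, d)
  bl <- array(FALSE, d); bl[1:5, , ] <- TRUE
  rc <- array(FALSE, d); rc[6:10, , ] <- TRUE
  dose[6, 1, 1] <- 66  # rectum hot spot
  ptv <- array(FALSE, d); ptv[2:5, 2:9, 2:3] <- TRUE  # inside the bladder half
  dose[ptv] <- 70; dose[2, 2, 2] <- 50  # one cold PTV voxel out of 64
  ss <- structure_set(list(mask3("bladder", bl), mask3("rectum", rc),
                           mask3("PTV_70Gy", ptv)))
  rules <- list(objective_rule("bladder", "V_Gy_pct", 40.8, 50, "<"),
                objective_rule("rectum", "Dmax", threshold = 65, direction = "<"),
                objective_rule("PTV_70Gy", "V_pctRx_pct", 98, 98, ">"))
  rep <- check_objectives(vol3(dose, kind = "dose"), ss, rules,
                          prescriptions = c(PTV_70Gy = 70))
  expect_true(rep$pass[1])                  # bladder mostly 30 Gy: V40.8 = 32%
  expect_false(rep$pass[2]); expect_equal(rep$value[2], 66)
  expect_true(rep$pass[3])                  # 63/64 = 98.4% >= 98% of 70
  expect_equal(rep$value[3], 100 * 63 / 64)
  expect_error(check_objectives(vol3(dose, kind = "dose"), ss,
                                list(objective_rule("spleen", "Dmax",
                                                    threshold = 1, direction = "<"))),
               "not found")
})
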