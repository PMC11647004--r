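test_that("discretization follows the fixed-bin-width contract", {
  v <- tiny_volume(array(c(0, 0.4, 0.5, 1.2, 0, 0, 0, 0), c(2, 2, 2)),
                   mask = array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2)))
  d <- discretize(v, "whole_heart", bin_width = 0.5)
  expect_equal(d$n_levels, 3L)
  expect_equal(sort(d$levels[!is.na(d$levels)]), c(1L, 1L, 2L, 3L))

  # uniform region: one level
  u <- tiny_volume(array(4.2, c(3, 3, 1)))
  expect_equal(discretize(u, "whole_heart")$n_levels, 1L)

  # doubling the bin width never increases the level count
  withr::with_seed(3, {
    for (r in 1:10) {
      vol <- random_masked_volume(c(5, 5, 4), n_levels = 7)
      n1 <- discretize(vol, "whole_heart", 0.5)$n_levels
      n2 <- discretize(vol, "whole_heart", 1.0)$n_levels
      expect_lte(n2, n1)
    }
  })

  expect_error(discretize(u, "whole_heart", bin_width = 0), "positive")
})

test_that("mean dose and dose-volume indicators match hand computation", {
  expect_equal(mean_dose(tiny_volume(array(5, c(2, 2, 2)))), 5)
  half <- tiny_volume(array(c(rep(0, 4), rep(10, 4)), c(2, 2, 2)))
  expect_equal(mean_dose(half), 5)

  dv <- dose_volume_indicators(tiny_volume(array(5, c(2, 2, 2))))
  expect_length(dv, 24)
  expect_true(all(dv[paste0("D_", c(2, 50, 98))] == 5))
  expect_equal(unname(dv["V_2"]), 100)
  expect_equal(unname(dv["V_10"]), 0)
  expect_equal(unname(dose_volume_indicators(half)["V_2"]), 50)

  # 10 listed voxel doses: all 24 values against a brute-force sort oracle
  doses <- c(0.3, 1.1, 2.4, 2.4, 3.7, 5.0, 8.2, 12.5, 20.1, 33.3)
  v10 <- tiny_volume(array(doses, c(10, 1, 1)))
  dv10 <- dose_volume_indicators(v10)
  for (x in c(2, 5, 10, 20, 30, 40, 50, 60, 70, 80, 90, 98))
    expect_equal(unname(dv10[paste0("D_", x)]),
                 quantile(doses, 1 - x / 100, names = FALSE, type = 7))
  for (d in c(1, 2, 5, 10, 15, 20, 25, 30, 35, 40, 45, 50))
    expect_equal(unname(dv10[paste0("V_", d)]), 100 * mean(doses >= d))
})

test_that("D_x and V_d are monotone and mean dose is bracketed by subparts", {
  withr::with_seed(7, {
    for (r in 1:8) {
      v <- random_masked_volume(c(6, 6, 6), n_levels = 8)
      dv <- dose_volume_indicators(v)
      expect_true(all(diff(dv[paste0("D_", dx_grid <- c(2, 5, 10, 20, 30,
        40, 50, 60, 70, 80, 90, 98))]) <= 1e-12))
      expect_true(all(diff(dv[paste0("V_", c(1, 2, 5, 10, 15, 20, 25, 30,
        35, 40, 45, 50))]) <= 1e-12))
      expect_true(all(dv[13:24] >= 0 & dv[13:24] <= 100))
    }
  })
  # subparts tile the heart: whole-heart mean within subpart mean range
  cfg <- cohort_config(n_patients = 2, seed = 21)
  course <- generate_dose_course(cfg, 1)
  vol <- aggregate_sessions(course)
  sub <- setdiff(heart_regions(), "whole_heart")
  mds <- vapply(sub, function(r) mean_dose(vol, r), numeric(1))
  wh <- mean_dose(vol, "whole_heart")
  expect_gte(wh, min(mds))
  expect_lte(wh, max(mds))
})

test_that("first-order features handle the constant region exactly", {
  v <- tiny_volume(array(5, c(2, 2, 2)))
  f <- first_order_features(v)
  expect_length(f, 18)
  expect_equal(unname(f["Mean"]), 5)
  expect_equal(unname(f["Variance"]), 0)
  expect_equal(unname(f["Energy"]), 200)
  expect_equal(unname(f["TotalEnergy"]), 200 * 8) # 2 mm isotropic voxels
  expect_equal(unname(f["Entropy"]), 0)
  expect_equal(unname(f["Uniformity"]), 1)
  expect_equal(unname(f["Skewness"]), 0)
})

test_that("texture feature groups have the documented cardinalities", {
  v <- random_masked_volume(c(5, 5, 5), n_levels = 4)
  d <- discretize(v, "whole_heart")
  expect_length(glcm_features(d), 24)
  expect_length(texture_matrix_features(d, "GLRLM"), 16)
  expect_length(texture_matrix_features(d, "GLSZM"), 16)
  expect_length(texture_matrix_features(d, "NGTDM"), 5)
  expect_length(texture_matrix_features(d, "GLDM"), 14)
  # 18 + 24 + 16 + 16 + 5 + 14 = 93
  full <- extract_region_features(v, "whole_heart", "dosiomics_full")
  expect_length(full, 93)
  expect_error(texture_matrix_features(d, "XYZ"))
})

test_that("constant regions give the degenerate texture conventions", {
  v <- tiny_volume(array(2, c(3, 3, 2)))
  d <- discretize(v, "whole_heart")
  g <- glcm_features(d)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["JointEnergy"]), 1)
  expect_equal(unname(g["Correlation"]), 1)
  z <- texture_matrix_features(d, "GLSZM")
  expect_equal(unname(z["ZonePercentage"]), 1 / 18) # one zone of size 18
})

test_that("2x2x1 GLCM pairs match hand enumeration", {
  lev_vol <- tiny_volume(array(c(0, 0.5, 0, 0.5), c(2, 2, 1)))
  d <- discretize(lev_vol, "whole_heart")
  expect_equal(d$n_levels, 2L)
  mats <- dosurv:::cpp_glcm(d$levels, dim(d$levels), 2L)
  # direction (1,0,0): both columns give the pair (1,2) -> symmetric counts
  expect_equal(mats[[1]], matrix(c(0, 2, 2, 0), 2))
  # direction (0,1,0): pairs (1,1) and (2,2)
  expect_equal(mats[[2]], matrix(c(2, 0, 0, 2), 2))
  # diagonals in-plane: one (1,2) pair each
  expect_equal(mats[[4]], matrix(c(0, 1, 1, 0), 2))
  expect_equal(mats[[5]], matrix(c(0, 1, 1, 0), 2))
  # hand-averaged features over the four non-empty directions
  g <- glcm_features(d)
  expect_equal(unname(g["Contrast"]), mean(c(1, 0, 1, 1)))
  expect_equal(unname(g["JointEnergy"]), 0.5)
})

test_that("3x1x1 run lengths match hand enumeration", {
  v <- tiny_volume(array(c(0, 0, 0.5), c(3, 1, 1)))
  d <- discretize(v, "whole_heart")
  mats <- dosurv:::cpp_glrlm(d$levels, dim(d$levels), 2L)
  # along x: a run of level 1 with length 2, one of level 2 with length 1
  expect_equal(mats[[1]], matrix(c(0, 1, 1, 0, 0, 0), 2, 3))
  # along y: three runs of length 1
  expect_equal(mats[[2]], matrix(c(2, 1, 0, 0, 0, 0), 2, 3))
})

test_that("texture features are invariant to adding a constant dose", {
  withr::with_seed(5, {
    v <- random_masked_volume(c(6, 5, 4), n_levels = 5)
    v2 <- dose_volume(v$values + 7.3, spacing = v$spacing, masks = v$masks)
    d1 <- discretize(v, "whole_heart")
    d2 <- discretize(v2, "whole_heart")
    expect_equal(d1$levels, d2$levels)
    expect_equal(glcm_features(d1), glcm_features(d2))
    expect_equal(texture_matrix_features(d1, "GLSZM"),
                 texture_matrix_features(d2, "GLSZM"))
  })
})

test_that("feature tables have the documented column counts per spec", {
  cfg <- cohort_config(n_patients = 4, seed = 13)
  co <- generate_cohort(cfg)
  tab_m <- extract_feature_table(co$records, co$courses, "mean_dose",
                                 "subparts")
  expect_length(grep("__", names(tab_m)), 5)
  tab_f <- extract_feature_table(co$records, co$courses, "dosiomics_full",
                                 "whole_heart")
  expect_length(grep("__", names(tab_f)), 93)
  # two identical patients give identical rows
  courses2 <- co$courses
  courses2[[2]] <- courses2[[1]]
  tab2 <- extract_feature_table(co$records, courses2, "firstorder",
                                "whole_heart")
  expect_equal(as.numeric(tab2[1, grep("__", names(tab2))]),
               as.numeric(tab2[2, grep("__", names(tab2))]))
  # missing course is an error
  expect_error(extract_feature_table(co$records, co$courses[1:2],
                                     "mean_dose", "whole_heart"),
               "no course")
  md <- feature_metadata(tab_f)
  expect_setequal(unique(md$family),
                  c("clinical", "firstorder", "glcm", "glrlm", "glszm",
                    "ngtdm", "gldm"))
})
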