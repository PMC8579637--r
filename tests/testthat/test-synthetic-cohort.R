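test_that("default cohort has the study's size and consistent labels", {
  cohort <- generate_cohort(cohort_config(seed = 42))
  expect_equal(nrow(cohort), 56)
  expect_equal(as.vector(table(cohort$group)[c("RG", "NRG")]), c(36, 20))
  # labels are derived from the simulated diameter changes
  rec <- recist_classify(cohort$delta_d_pct, cohort$diameter_pre_cm)
  expect_identical(as.character(rec$group), as.character(cohort$group))
  expect_true(all(cohort$diameter_pre_cm > 0 & cohort$volume_pre_cm3 > 0))
  # the pharmacokinetic identity holds per patient (1e-3 scales)
  expect_equal(cohort$ktrans_pre, cohort$ve_pre / 1000 * cohort$kep_pre)
})

test_that("the cohort is byte-identical under the same seed", {
  c1 <- generate_cohort(cohort_config(seed = 9))
  c2 <- generate_cohort(cohort_config(seed = 9))
  expect_identical(c1, c2)
  c3 <- generate_cohort(cohort_config(seed = 10))
  expect_false(identical(c1, c3))
})

test_that("large-sample group means converge to the configured moments", {
  cfg <- cohort_config(n_responders = 1e4, n_nonresponders = 1e4, seed = 77)
  cohort <- generate_cohort(cfg)
  isR <- cohort$group == "RG"
  expect_lt(abs(mean(cohort$adc_pre[isR]) - 1119.58) / 1119.58, 0.01)
  expect_lt(abs(mean(cohort$adc_pre[!isR]) - 1386.25) / 1386.25, 0.01)
  expect_lt(abs(mean(cohort$mk_pre[isR]) - 1052.25) / 1052.25, 0.01)
  expect_lt(abs(mean(cohort$dslow_pre[!isR]) - 933.85) / 933.85, 0.015)
})

test_that("noiseless rendering round-trips each patient's ground truth", {
  cfg <- small_config(seed = 3)
  cohort <- generate_cohort(cfg)
  rec <- cohort[1, ]
  img <- render_patient_images(rec, cfg, "pre", noise = FALSE)
  # ROI means deviate from the patient value only via the 5% within-tumour
  # variability; with tens of ROI voxels that is a ~1-2% standard error
  fa <- fit_adc(img$dwi, mask = img$lesion_mask)
  expect_lt(abs(roi_summary(fa$adc, img$roi_mask)$mean - rec$adc_pre) / rec$adc_pre, 0.05)
  fk <- fit_dki(img$dki, mask = img$lesion_mask)
  expect_lt(abs(roi_summary(fk$md, img$roi_mask)$mean - rec$md_pre) / rec$md_pre, 0.05)
  expect_lt(abs(roi_summary(fk$mk, img$roi_mask)$mean - rec$mk_pre) / rec$mk_pre, 0.05)
  fi <- fit_ivim_segmented(img$ivim, mask = img$lesion_mask)
  expect_lt(abs(roi_summary(fi$dslow, img$roi_mask)$mean - rec$dslow_pre) / rec$dslow_pre, 0.05)
  ft <- fit_tofts(img$dce, img$aif, mask = img$lesion_mask)
  expect_lt(abs(roi_summary(ft$ktrans, img$roi_mask)$mean - rec$ktrans_pre) / rec$ktrans_pre, 0.06)
  expect_lt(abs(roi_summary(ft$kep, img$roi_mask)$mean - rec$kep_pre) / rec$kep_pre, 0.06)
})

test_that("mask-derived volume approaches the recorded volume as voxels shrink", {
  cohort <- generate_cohort(small_config(seed = 21))
  rec <- cohort[5, ]
  vol_err <- function(voxel) {
    cfg <- cohort_config(seed = 21, voxel_mm = voxel, fov_mm = 72, n_slices = 12)
    img <- render_patient_images(rec, cfg, "pre", noise = FALSE, modalities = "dwi")
    areas <- apply(img$lesion_mask, 3, sum) * voxel^2 / 100   # cm^2 per slice
    v <- tumor_volume(areas, cfg$slice_thickness_cm, cfg$slice_gap_cm)
    abs(v - rec$volume_pre_cm3) / rec$volume_pre_cm3
  }
  e4 <- vol_err(4); e1 <- vol_err(1)
  expect_lt(e1, 0.04)
  expect_lt(e1, e4 + 1e-9)
})

test_that("noise realizations are independent across patients and repeatable", {
  cfg <- tiny_config(seed = 13)
  cohort <- generate_cohort(cfg)
  i1 <- render_patient_images(cohort[1, ], cfg, "pre", modalities = "dwi")
  i1b <- render_patient_images(cohort[1, ], cfg, "pre", modalities = "dwi")
  i2 <- render_patient_images(cohort[2, ], cfg, "pre", modalities = "dwi")
  expect_identical(i1$dwi$data, i1b$dwi$data)
  # different patients share geometry code but not noise
  expect_false(identical(as.vector(i1$dwi$data[1:50]), as.vector(i2$dwi$data[1:50])))
  # pre and post noise streams differ too
  ipost <- render_patient_images(cohort[1, ], cfg, "post", modalities = "dwi")
  expect_false(identical(i1$dwi$data, ipost$dwi$data))
})

test_that("marker directions in the generated cohort match the published signs", {
  cohort <- generate_cohort(cohort_config(seed = 15))
  isR <- cohort$group == "RG"
  expect_lt(mean(cohort$adc_pre[isR]), mean(cohort$adc_pre[!isR]))
  expect_lt(mean(cohort$md_pre[isR]), mean(cohort$md_pre[!isR]))
  expect_lt(mean(cohort$dslow_pre[isR]), mean(cohort$dslow_pre[!isR]))
  expect_gt(mean(cohort$mk_pre[isR]), mean(cohort$mk_pre[!isR]))
  # treatment shifts: ADC/MD rise, MK falls
  expect_gt(mean(cohort$adc_post - cohort$adc_pre), 0)
  expect_gt(mean(cohort$md_post - cohort$md_pre), 0)
  expect_lt(mean(cohort$mk_post - cohort$mk_pre), 0)
})
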