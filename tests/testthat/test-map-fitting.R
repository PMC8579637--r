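# Round-trip and consistency checks for the voxel-wise fitters. Forward
# models generate the data, so recovery of the generating parameters is the
# ground-truth oracle throughout.

rel_err <- function(est, truth) abs(est - truth) / abs(truth)

test_that("two-point ADC fit inverts the forward model", {
  vol <- series_volume(c(100, 47.56), acq_dwi)
  fit <- fit_adc(vol)
  # closed-form inversion oracle
  expect_equal(map_values(fit$adc, masked_only = TRUE),
               log(100 / 47.56) / 600 / 1e-6, tolerance = 1e-10)
  expect_equal(map_values(fit$adc, masked_only = TRUE), 1238, tolerance = 1e-3)
  expect_equal(map_values(fit$s0, masked_only = TRUE), 100, tolerance = 1e-10)
  # constant signal -> zero diffusivity
  flat <- fit_adc(series_volume(rep(80, 2), acq_dwi))
  expect_equal(map_values(flat$adc, masked_only = TRUE), 0)
})

test_that("non-positive signals flag the voxel unfit without aborting", {
  Y <- rbind(c(100, 47), c(100, 0))
  fit <- fit_adc(series_volume(Y, acq_dwi))
  expect_true(fit$adc$mask[1, 1, 1])
  expect_false(fit$adc$mask[2, 1, 1])
  expect_true(is.na(fit$adc$values[2, 1, 1]))
})

test_that("noise-free round trips recover the generating parameters", {
  set.seed(101)
  n <- 100

  # ADC
  adc <- runif(n, 3e-4, 2.5e-3); s0 <- runif(n, 40, 200)
  Y <- t(sapply(seq_len(n), function(i)
    dwi_signal(tissue_params(s0 = s0[i], adc = adc[i]), acq_dwi$b_values)))
  fit <- fit_adc(series_volume(Y, acq_dwi))
  expect_lt(max(rel_err(map_values(fit$adc, FALSE, TRUE), adc)), 1e-8)
  expect_lt(max(rel_err(map_values(fit$s0, FALSE, TRUE), s0)), 1e-8)

  # DKI within its fitting bounds
  D <- runif(n, 4e-4, 2.5e-3); K <- runif(n, 0.1, 2.5)
  Y <- t(sapply(seq_len(n), function(i)
    dki_signal(tissue_params(s0 = s0[i], d = D[i], k = K[i]), acq_dki$b_values)))
  fit <- fit_dki(series_volume(Y, acq_dki))
  expect_lt(max(rel_err(map_values(fit$md, FALSE, TRUE), D)), 1e-4)
  expect_lt(max(rel_err(map_values(fit$mk, FALSE, TRUE), K)), 1e-4)

  # segmented IVIM at tissue-like parameters
  f <- runif(n, 0.01, 0.25); ds <- runif(n, 4e-4, 1.5e-3)
  # pseudo-diffusion fast enough to have decayed by the b = 200 split,
  # the segmented algorithm's validity condition
  df <- runif(n, 25e-3, 80e-3)
  Y <- t(sapply(seq_len(n), function(i)
    ivim_signal(tissue_params(s0 = s0[i], f = f[i], dslow = ds[i], dfast = df[i]),
                acq_ivim$b_values)))
  fit <- fit_ivim_segmented(series_volume(Y, acq_ivim))
  expect_lt(max(rel_err(map_values(fit$dslow, FALSE, TRUE), ds)), 0.02)
  expect_lt(max(abs(map_values(fit$pf, FALSE, TRUE) - f)), 0.01)

  # Tofts under the population AIF
  kt <- runif(n, 0.1, 2); kep <- runif(n, 0.3, 3)
  aif <- aif_parker(onset_s = dce_onset(acq_dce))
  C <- t(sapply(seq_len(n), function(i)
    tofts_concentration(tissue_params(ktrans = kt[i], kep = kep[i]), aif, acq_dce)))
  fit <- fit_tofts(C, aif, acq_dce)
  expect_lt(max(rel_err(map_values(fit$ktrans, FALSE, TRUE), kt)), 1e-3)
  expect_lt(max(rel_err(map_values(fit$kep, FALSE, TRUE), kep)), 1e-3)
  expect_equal(map_values(fit$ve, FALSE, TRUE),
               map_values(fit$ktrans, FALSE, TRUE) / map_values(fit$kep, FALSE, TRUE))
})

test_that("kurtosis fit recovers tumour-like values and nests the ADC fit", {
  p <- tissue_params(s0 = 100, d = 1.0125e-3, k = 1.02)
  y <- dki_signal(p, acq_dki$b_values)
  fit <- fit_dki(series_volume(y, acq_dki))
  expect_lt(rel_err(map_values(fit$md, FALSE, TRUE), 1.0125e-3), 1e-4)
  expect_lt(rel_err(map_values(fit$mk, FALSE, TRUE), 1.02), 1e-4)
  # reporting scales: MD in 1e-6 mm^2/s, MK in 1e-3
  expect_equal(map_values(fit$md, masked_only = TRUE), 1012.5, tolerance = 1e-4)
  expect_equal(map_values(fit$mk, masked_only = TRUE), 1020, tolerance = 1e-4)

  # K = 0 data: fitted MK ~ 0 and MD matches the mono-exponential fit
  y0 <- dki_signal(tissue_params(s0 = 100, d = 1.2e-3, k = 0), acq_dki$b_values)
  f0 <- fit_dki(series_volume(y0, acq_dki))
  expect_lt(map_values(f0$mk, FALSE, TRUE), 1e-3)
  fadc <- fit_adc(series_volume(y0, acq_dki), acq_dki)
  expect_equal(map_values(f0$md, FALSE, TRUE),
               map_values(fadc$adc, FALSE, TRUE), tolerance = 1e-6)
})

test_that("kurtosis MD is nearly unbiased under Rician noise at SNR 50", {
  p <- tissue_params(s0 = 100, d = 1.0125e-3, k = 1.02)
  y <- dki_signal(p, acq_dki$b_values)
  Y <- add_noise(matrix(rep(y, each = 200), nrow = 200), sigma = 2,
                 model = "rician", seed = 202)
  fit <- fit_dki(series_volume(Y, acq_dki))
  md <- map_values(fit$md, FALSE, TRUE)
  expect_lt(abs(median(md) - 1.0125e-3) / 1.0125e-3, 0.03)
})

test_that("segmented IVIM handles the tumour-like example and the f = 0 limit", {
  p <- tissue_params(s0 = 100, f = 0.02, dslow = 0.778e-3, dfast = 41e-3)
  y <- ivim_signal(p, acq_ivim$b_values)
  fit <- fit_ivim_segmented(series_volume(y, acq_ivim), b_threshold = 200)
  expect_lt(rel_err(map_values(fit$dslow, FALSE, TRUE), 0.778e-3), 0.02)
  expect_lt(abs(map_values(fit$pf, FALSE, TRUE) - 0.02), 0.01)

  y0 <- ivim_signal(tissue_params(s0 = 100, f = 0, dslow = 0.9e-3, dfast = 30e-3),
                    acq_ivim$b_values)
  f0 <- fit_ivim_segmented(series_volume(y0, acq_ivim))
  expect_lt(map_values(f0$pf, FALSE, TRUE), 1e-6)
  fadc <- fit_adc(series_volume(y0, acq_ivim), acq_ivim)
  expect_equal(map_values(f0$dslow, FALSE, TRUE), 0.9e-3, tolerance = 1e-3)
  expect_equal(map_values(fadc$adc, FALSE, TRUE), 0.9e-3, tolerance = 1e-3)
  # perfusion-free voxel: Dfast unidentifiable, flagged unfit
  expect_false(any(f0$dfast$mask))
})

test_that("segmented and joint IVIM fits agree on noise-free data", {
  p <- tissue_params(s0 = 100, f = 0.02, dslow = 0.778e-3, dfast = 41e-3)
  y <- ivim_signal(p, acq_ivim$b_values)
  vol <- series_volume(y, acq_ivim)
  seg <- fit_ivim_segmented(vol)
  jnt <- fit_ivim_joint(vol)
  for (nm in c("dslow", "dfast", "pf", "s0")) {
    expect_lt(rel_err(map_values(seg[[nm]], FALSE, TRUE),
                      map_values(jnt[[nm]], FALSE, TRUE)), 0.01)
  }
  # the joint fit is the exact oracle here
  expect_lt(rel_err(map_values(jnt$dfast, FALSE, TRUE), 41e-3), 1e-4)
})

test_that("Tofts fit recovers the tumour-like example and its identities", {
  acq <- dce_acquisition(seq(0, 300, by = 2), n_baseline = 2)
  aif <- aif_step(1, onset_s = dce_onset(acq))
  p <- tissue_params(ktrans = 0.92, kep = 1.24)
  ct <- tofts_concentration(p, aif, acq)
  fit <- fit_tofts(ct, aif, acq)
  expect_lt(rel_err(map_values(fit$ktrans, FALSE, TRUE), 0.92), 1e-3)
  expect_lt(rel_err(map_values(fit$kep, FALSE, TRUE), 1.24), 1e-3)
  expect_equal(map_values(fit$ve, FALSE, TRUE), 0.742, tolerance = 1e-3)
  # all-zero concentration -> Ktrans = 0, Kep/Ve unfit
  z <- fit_tofts(numeric(length(acq$frame_times)), aif, acq)
  expect_equal(map_values(z$ktrans, FALSE, TRUE), 0)
  expect_false(any(z$kep$mask))
})

test_that("masked-out voxels do not influence fitted voxels", {
  set.seed(11)
  Y <- rbind(dwi_signal(tissue_params(s0 = 100, adc = 1e-3), acq_dwi$b_values),
             c(5, 1))
  vol1 <- series_volume(Y, acq_dwi)
  Y2 <- Y; Y2[2, ] <- c(500, 400)
  vol2 <- series_volume(Y2, acq_dwi)
  mask <- array(c(TRUE, FALSE), c(2, 1, 1))
  f1 <- fit_adc(vol1, mask = mask)
  f2 <- fit_adc(vol2, mask = mask)
  expect_identical(map_values(f1$adc), map_values(f2$adc))
  expect_true(is.na(f1$adc$values[2, 1, 1]))
})

test_that("reporting scales round-trip exactly", {
  vol <- series_volume(c(100, 47.56), acq_dwi)
  fit <- fit_adc(vol)
  expect_identical(map_values(fit$adc, reported = TRUE) * fit$adc$scale,
                   map_values(fit$adc, reported = FALSE))
  expect_equal(report_scale("adc"), 1e-6)
  expect_equal(report_scale("dfast"), 1e-4)
  expect_equal(report_scale("kep"), 1e-3)
})
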