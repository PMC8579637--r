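# Seeded generator of a synthetic pre/post induction-chemotherapy cohort:
# per-patient ground-truth tissue parameters drawn from published group
# summaries, lesion geometry consistent with the recorded diameters and
# volumes, and forward-rendered signal volumes with magnitude noise.

#' Synthetic cohort configuration
#'
#' Defaults encode the study conditions the generator emulates: 36
#' responders (RG) and 20 non-responders (NRG); group-specific pre-treatment
#' distributions of ADC, MD, MK and Dslow from the published Table of group
#' summaries (mean +/- SD, or median/IQR-matched log-normal for skewed
#' parameters); shared distributions for the perfusion and pharmacokinetic
#' parameters; group-specific percent-change distributions for diameter
#' (RG -49.24 +/- 15, NRG -18.62 +/- 10), volume (RG -64.98 +/- 17.77,
#' NRG -30.35 +/- 14.94) and the MRI parameters where published. A single
#' latent "response aggressiveness" factor (loading 0.5) induces
#' cross-marker correlation. Values in `markers_pre`/`deltas_pct` are on
#' the reporting scales.
#'
#' @param n_responders,n_nonresponders Group sizes.
#' @param seed Integer seed; the cohort is reproducible given the seed.
#' @param snr Signal-to-noise ratio S0/sigma of the rendered diffusion
#'   series (Rician noise).
#' @param sigma_dce Gaussian noise SD of the rendered concentration series
#'   (mM).
#' @param voxel_mm In-plane voxel size of rendered volumes (mm).
#' @param fov_mm In-plane field of view (mm).
#' @param n_slices Number of axial slices rendered.
#' @param slice_thickness_cm,slice_gap_cm Slice geometry (cm); their sum is
#'   the slice-to-slice distance used by the volume formula.
#' @param latent_loading Loading of the latent response factor on
#'   response-linked markers (0..1).
#' @param within_tumor_cv Within-lesion coefficient of variation of the
#'   voxel parameters.
#' @param acquisitions Acquisition set, see [default_acquisitions()].
#' @param ... Overrides for the distribution tables (`markers_pre`,
#'   `deltas_pct`, `diameter_cm`, `background`, `axis_ratios`,
#'   `demographics`).
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_responders = 36, n_nonresponders = 20, seed = 42,
                          snr = 50, sigma_dce = 0.03,
                          voxel_mm = 2, fov_mm = 72, n_slices = 12,
                          slice_thickness_cm = 0.4, slice_gap_cm = 0.1,
                          latent_loading = 0.5, within_tumor_cv = 0.05,
                          acquisitions = default_acquisitions(), ...) {
  if (n_responders < 2 || n_nonresponders < 2) stop("group sizes must be >= 2")
  cfg <- list(
    n_responders = as.integer(n_responders),
    n_nonresponders = as.integer(n_nonresponders),
    seed = as.integer(seed), snr = snr, sigma_dce = sigma_dce,
    voxel_mm = voxel_mm, fov_mm = fov_mm, n_slices = as.integer(n_slices),
    slice_thickness_cm = slice_thickness_cm, slice_gap_cm = slice_gap_cm,
    latent_loading = latent_loading, within_tumor_cv = within_tumor_cv,
    acquisitions = acquisitions,
    # pre-treatment marker distributions on reporting scales.
    # type "normal": c(mean, sd); type "lognormal": c(median, iqr).
    # direction: sign linking the latent response factor to the marker
    # (-1: lower value in responders), 0: not response-linked.
    markers_pre = list(
      adc   = list(type = "normal",    rg = c(1119.58, 144.06), nrg = c(1386.25, 198.23),
                   lo = 300, hi = 2500, direction = -1),
      md    = list(type = "lognormal", rg = c(902, 150), nrg = c(1121, 331),
                   lo = 300, hi = 2600, direction = -1),
      mk    = list(type = "normal",    rg = c(1052.25, 122.02), nrg = c(935.10, 185.34),
                   lo = 200, hi = 2900, direction = 1),
      dslow = list(type = "normal",    rg = c(724.50, 235.92), nrg = c(933.85, 219.95),
                   lo = 150, hi = 2400, direction = -1),
      dfast = list(type = "normal",    rg = c(410.59, 181.51), nrg = c(410.59, 181.51),
                   lo = 60, hi = 1500, direction = 0),
      pf    = list(type = "lognormal", rg = c(198.5, 103), nrg = c(198.5, 103),
                   lo = 20, hi = 1800, direction = 0),
      kep   = list(type = "lognormal", rg = c(1239.5, 945), nrg = c(1239.5, 945),
                   lo = 100, hi = 9000, direction = 0),
      ve    = list(type = "normal",    rg = c(686.18, 242.58), nrg = c(686.18, 242.58),
                   lo = 50, hi = 980, direction = 0)
    ),
    # percent-change (post vs pre) distributions: c(mean, sd) per group
    deltas_pct = list(
      diameter = list(rg = c(-49.24, 15), nrg = c(-18.62, 10),
                      rg_range = c(-95, -30), nrg_range = c(-29.9, 40), direction = -1),
      volume   = list(rg = c(-64.98, 17.77), nrg = c(-30.35, 14.94),
                      rg_range = c(-98, -2), nrg_range = c(-90, 15), direction = -1),
      adc   = list(rg = c(33.81, 22.2), nrg = c(18.14, 22.2), range = c(-60, 160), direction = 1),
      md    = list(rg = c(58.56, 20.49), nrg = c(28.61, 21.77), range = c(-60, 180), direction = 1),
      mk    = list(rg = c(-60.92, 14.8), nrg = c(-28.17, 10.4), range = c(-90, 60), direction = -1),
      dslow = list(rg = c(20.4, 15), nrg = c(20.4, 15), range = c(-60, 130), direction = 0),
      dfast = list(rg = c(-11.6, 20), nrg = c(-11.6, 20), range = c(-80, 120), direction = 0),
      pf    = list(rg = c(22.4, 25), nrg = c(22.4, 25), range = c(-70, 160), direction = 0),
      kep   = list(rg = c(-35.1, 25), nrg = c(-35.1, 25), range = c(-85, 90), direction = 0),
      ve    = list(rg = c(22.1, 25), nrg = c(22.1, 25), range = c(-70, 42), direction = 0)
    ),
    diameter_cm = list(median = 2.4, iqr = 0.9, lo = 1.2, hi = 6),
    axis_ratios = c(b = 0.8, c = 0.7),   # in-plane minor / through-plane vs a
    # healthy-tissue background rendered outside the lesion (natural units)
    background = list(s0 = 80, adc = 1.5e-3, d = 1.3e-3, k = 0.5, f = 0.05,
                      dslow = 1.3e-3, dfast = 10e-3, ktrans = 0.15, kep = 0.5),
    lesion_s0 = 100,
    demographics = list(
      age = list(rg = c(43.75, 13.14), nrg = c(48.75, 11.92), lo = 18, hi = 70),
      p_male = c(rg = 29 / 36, nrg = 17 / 20),
      t_stage = list(rg = c(2, 18, 10, 6), nrg = c(0, 7, 7, 6)),
      n_stage = list(rg = c(1, 5, 16, 14), nrg = c(1, 6, 6, 7)),
      pathology = list(rg = c(19, 15, 2), nrg = c(7, 9, 4)),
      p_docetaxel = c(rg = 27 / 36, nrg = 12 / 20)
    )
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "cohort_config")
}

lognormal_sdlog <- function(median, iqr) {
  asinh(iqr / (2 * median)) / stats::qnorm(0.75)
}

# Correlated truncated draw: standard normal deviate built from the shared
# latent factor z (loading lam, signed by direction) plus independent noise;
# out-of-range independent components are redrawn.
draw_deviate <- function(n, z, loading, direction, in_range, max_iter = 200) {
  lam <- if (direction == 0) 0 else loading * direction
  mix <- sqrt(1 - lam^2)
  dev <- lam * z + mix * stats::rnorm(n)
  for (i in seq_len(max_iter)) {
    bad <- !in_range(dev)
    if (!any(bad)) break
    dev[bad] <- (lam * z + mix * stats::rnorm(n))[bad]
  }
  dev
}

draw_trunc_normal <- function(mean, sd, lo, hi, z, loading = 0, direction = 0) {
  n <- length(z)
  dev <- draw_deviate(n, z, loading, direction,
                      function(d) { v <- mean + sd * d; v >= lo & v <= hi })
  clamp(mean + sd * dev, lo, hi)
}

draw_trunc_lognormal <- function(median, iqr, lo, hi, z, loading = 0, direction = 0) {
  n <- length(z)
  sdlog <- lognormal_sdlog(median, iqr)
  dev <- draw_deviate(n, z, loading, direction,
                      function(d) { v <- exp(log(median) + sdlog * d); v >= lo & v <= hi })
  clamp(exp(log(median) + sdlog * dev), lo, hi)
}

# Slice-summed ellipsoid volume (cm^3): analytic cross-section areas at
# slice centers tiling [-c, c], each weighted by the slice-to-slice
# distance -- the same convention as tumor_volume().
ellipsoid_slice_volume <- function(a, b, c, slab) {
  n <- max(1, ceiling(2 * c / slab))
  zc <- -c + (seq_len(n) - 0.5) * slab
  areas <- pi * a * b * pmax(0, 1 - (zc / c)^2)
  tumor_volume(areas, slab)   # slab already = thickness + gap
}

.cohort_params <- c("adc", "md", "mk", "dslow", "dfast", "pf", "ktrans", "kep", "ve")

#' Generate a synthetic patient cohort
#'
#' Draws per-patient ground-truth tissue parameters, lesion geometry and
#' response labels under the configured group distributions. Responder
#' labels are assigned by applying [recist_classify()] to the simulated
#' diameter changes, so labels, diameters and RECIST categories are
#' mutually consistent (the percent-change draws are truncated to their
#' group's RECIST range). `Ktrans` is derived as `Ve * Kep` per patient so
#' the pharmacokinetic identity holds exactly.
#'
#' @param config A [cohort_config()].
#' @return A data.frame, one row per patient, with demographics, RECIST
#'   category and group, diameters/volumes (pre/post, cm / cm^3), realized
#'   percent changes, and ground-truth marker values `<param>_pre` /
#'   `<param>_post` on the reporting scales. The config is attached as
#'   attribute `"config"`.
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' table(cohort$group)
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  local_seed(config$seed, {
    nR <- config$n_responders; nN <- config$n_nonresponders
    n <- nR + nN
    group <- rep(c("RG", "NRG"), c(nR, nN))
    isR <- group == "RG"
    z <- stats::rnorm(n)
    lam <- config$latent_loading

    pick <- function(spec_rg, spec_nrg) {
      # build per-patient (mean, sd) rows from group-specific params
      cbind(ifelse(isR, spec_rg[1], spec_nrg[1]),
            ifelse(isR, spec_rg[2], spec_nrg[2]))
    }

    # diameter change, truncated to each group's RECIST-consistent range
    dd <- config$deltas_pct$diameter
    ms <- pick(dd$rg, dd$nrg)
    lo <- ifelse(isR, dd$rg_range[1], dd$nrg_range[1])
    hi <- ifelse(isR, dd$rg_range[2], dd$nrg_range[2])
    delta_d_pct <- draw_trunc_normal(ms[, 1], ms[, 2], lo, hi, z, lam, dd$direction)

    dgeo <- config$diameter_cm
    diameter_pre <- draw_trunc_lognormal(dgeo$median, dgeo$iqr, dgeo$lo, dgeo$hi,
                                         z, 0, 0)
    diameter_post <- diameter_pre * (1 + delta_d_pct / 100)

    rec <- recist_classify(delta_d_pct, pre_diameter_cm = diameter_pre)
    stopifnot(identical(as.character(rec$group), group))

    dv <- config$deltas_pct$volume
    ms <- pick(dv$rg, dv$nrg)
    lo <- ifelse(isR, dv$rg_range[1], dv$nrg_range[1])
    hi <- ifelse(isR, dv$rg_range[2], dv$nrg_range[2])
    delta_v_target <- draw_trunc_normal(ms[, 1], ms[, 2], lo, hi, z, lam, dv$direction)

    # lesion geometry: in-plane axes follow the diameter; the through-plane
    # axis absorbs the remaining volume change
    slab <- config$slice_thickness_cm + config$slice_gap_cm
    a_pre <- diameter_pre / 2
    b_pre <- config$axis_ratios[["b"]] * a_pre
    c_pre <- config$axis_ratios[["c"]] * a_pre
    sxy <- 1 + delta_d_pct / 100
    a_post <- a_pre * sxy; b_post <- b_pre * sxy
    c_post <- c_pre * (1 + delta_v_target / 100) / sxy^2
    volume_pre <- mapply(ellipsoid_slice_volume, a_pre, b_pre, c_pre, slab)
    volume_post <- mapply(ellipsoid_slice_volume, a_post, b_post, c_post, slab)
    delta_v_pct <- (volume_post - volume_pre) / volume_pre * 100

    # pre-treatment markers (reporting scale)
    pre <- list()
    for (nm in setdiff(names(config$markers_pre), "ve")) {
      mp <- config$markers_pre[[nm]]
      ms <- pick(mp$rg, mp$nrg)
      pre[[nm]] <- if (mp$type == "normal")
        draw_trunc_normal(ms[, 1], ms[, 2], mp$lo, mp$hi, z, lam, mp$direction)
      else
        draw_trunc_lognormal(ms[, 1], ms[, 2], mp$lo, mp$hi, z, lam, mp$direction)
    }
    mv <- config$markers_pre$ve
    pre$ve <- draw_trunc_normal(mv$rg[1], mv$rg[2], mv$lo, mv$hi, z, lam, mv$direction)
    pre$ktrans <- (pre$ve / 1000) * pre$kep    # both on 1e-3 scales

    # post-treatment markers via percent changes, kept inside marker bounds
    post <- list()
    for (nm in c("adc", "md", "mk", "dslow", "dfast", "pf", "kep", "ve")) {
      dl <- config$deltas_pct[[nm]]
      ms <- pick(dl$rg, dl$nrg)
      bounds <- config$markers_pre[[nm]]
      base <- pre[[nm]]
      dev <- draw_deviate(n, z, lam, dl$direction, function(d) {
        v <- base * (1 + (ms[, 1] + ms[, 2] * d) / 100)
        v >= bounds$lo & v <= bounds$hi
      })
      post[[nm]] <- clamp(base * (1 + (ms[, 1] + ms[, 2] * dev) / 100),
                          bounds$lo, bounds$hi)
    }
    post$ktrans <- (post$ve / 1000) * post$kep

    # demographics matched to the published margins
    dem <- config$demographics
    age <- round(draw_trunc_normal(ifelse(isR, dem$age$rg[1], dem$age$nrg[1]),
                                   ifelse(isR, dem$age$rg[2], dem$age$nrg[2]),
                                   dem$age$lo, dem$age$hi, z, 0, 0))
    sex <- ifelse(stats::runif(n) < ifelse(isR, dem$p_male[["rg"]], dem$p_male[["nrg"]]),
                  "M", "F")
    sample_cat <- function(levels, w) {
      out <- character(n)
      out[isR] <- sample(levels, nR, replace = TRUE, prob = w$rg / sum(w$rg))
      out[!isR] <- sample(levels, nN, replace = TRUE, prob = w$nrg / sum(w$nrg))
      out
    }
    t_stage <- sample_cat(c("T1", "T2", "T3", "T4"), dem$t_stage)
    n_stage <- sample_cat(c("N0", "N1", "N2", "N3"), dem$n_stage)
    pathology <- sample_cat(c("undifferentiated", "low", "moderate"), dem$pathology)
    regimen <- ifelse(stats::runif(n) < ifelse(isR, dem$p_docetaxel[["rg"]],
                                               dem$p_docetaxel[["nrg"]]),
                      "TP-docetaxel", "TP-paclitaxel")

    out <- data.frame(
      patient_id = sprintf("P%03d", seq_len(n)),
      group = factor(group, levels = c("RG", "NRG")),
      category = rec$category,
      age = age, sex = sex, t_stage = t_stage, n_stage = n_stage,
      pathology = pathology, regimen = regimen,
      diameter_pre_cm = diameter_pre, diameter_post_cm = diameter_post,
      delta_d_pct = delta_d_pct,
      volume_pre_cm3 = volume_pre, volume_post_cm3 = volume_post,
      delta_v_pct = delta_v_pct,
      stringsAsFactors = FALSE
    )
    for (nm in .cohort_params) {
      out[[paste0(nm, "_pre")]] <- pre[[nm]]
      out[[paste0(nm, "_post")]] <- post[[nm]]
    }
    attr(out, "config") <- config
    out
  })
}

# Per-patient tissue parameters in natural units for one timepoint.
record_params <- function(record, timepoint) {
  sfx <- paste0("_", timepoint)
  get1 <- function(nm) record[[paste0(nm, sfx)]] * report_scale(nm)
  list(adc = get1("adc"), d = get1("md"), k = get1("mk"),
       dslow = get1("dslow"), dfast = get1("dfast"), f = get1("pf"),
       ktrans = get1("ktrans"), kep = get1("kep"), ve = get1("ve"))
}

#' Render signal volumes for one synthetic patient
#'
#' Forward-models the patient's ground-truth parameters through the four
#' signal models on a voxel grid: lesion voxels carry the patient's
#' parameters with mild within-tumor variability (log-normal, CV
#' `within_tumor_cv`), background voxels a fixed healthy-tissue parameter
#' set. Diffusion series receive Rician noise at `S0/snr`, the DCE
#' concentration series Gaussian noise of SD `sigma_dce`. The noise seed is
#' derived deterministically from the cohort seed and the patient index,
#' so different patients get independent realizations.
#'
#' @param record One row of a [generate_cohort()] data.frame.
#' @param config The matching [cohort_config()].
#' @param timepoint `"pre"` or `"post"`.
#' @param noise Logical; `FALSE` renders noiseless volumes.
#' @param modalities Subset of `c("dwi", "dki", "ivim", "dce")` to render.
#' @return A list: `dwi`, `dki`, `ivim` ([signal_volume()]s), `dce`
#'   (concentration volume, mM), `lesion_mask` (all slices), `roi_mask`
#'   (largest axial slice), `aif`, `spacing`, `patient_id`, `timepoint`.
#' @export
render_patient_images <- function(record, config, timepoint = c("pre", "post"),
                                  noise = TRUE,
                                  modalities = c("dwi", "dki", "ivim", "dce")) {
  timepoint <- match.arg(timepoint)
  modalities <- match.arg(modalities, several.ok = TRUE)
  stopifnot(nrow(as.data.frame(record)) == 1)
  idx <- as.integer(sub("^P", "", record$patient_id))
  seed <- derive_seed(config$seed, 2L * idx + (timepoint == "post"))
  local_seed(seed, {
    vx <- config$voxel_mm
    slab_mm <- 10 * (config$slice_thickness_cm + config$slice_gap_cm)
    nx <- ny <- ceiling(config$fov_mm / vx)
    nz <- config$n_slices
    xs <- (seq_len(nx) - (nx + 1) / 2) * vx
    zs <- (seq_len(nz) - (nz + 1) / 2) * slab_mm
    # lesion ellipsoid axes in mm for this timepoint
    sxy <- if (timepoint == "post") 1 + record$delta_d_pct / 100 else 1
    a <- 10 * record$diameter_pre_cm / 2 * sxy
    b <- config$axis_ratios[["b"]] * 10 * record$diameter_pre_cm / 2 * sxy
    cc <- config$axis_ratios[["c"]] * 10 * record$diameter_pre_cm / 2
    if (timepoint == "post")
      cc <- cc * (1 + record$delta_v_pct / 100) / sxy^2
    q <- outer(outer((xs / a)^2, (xs / b)^2, `+`), (zs / cc)^2, `+`)
    mask <- q <= 1
    # sub-voxel lesion at coarse resolution: keep the nearest voxel so the
    # lesion never vanishes from the rendered volume
    if (!any(mask)) mask[which.min(q)] <- TRUE
    slice_counts <- apply(mask, 3, sum)
    roi_mask <- array(FALSE, dim(mask))
    kbest <- which.max(slice_counts)
    roi_mask[, , kbest] <- mask[, , kbest]

    # per-voxel parameters: background everywhere, lesion values inside
    truth <- record_params(record, timepoint)
    bg <- config$background
    nles <- sum(mask)
    cv <- config$within_tumor_cv
    sdlog <- sqrt(log(1 + cv^2))
    jitter <- function() exp(stats::rnorm(nles, -sdlog^2 / 2, sdlog))
    pm <- list()
    for (nm in c("adc", "d", "k", "dslow", "dfast", "f", "ktrans", "kep")) {
      bg_nm <- switch(nm, d = "d", k = "k", nm)
      arr <- array(bg[[bg_nm]], dim(mask))
      arr[mask] <- truth[[nm]] * jitter()
      pm[[nm]] <- arr
    }
    pm$f <- clamp(pm$f, 0, 1)
    s0 <- array(bg$s0, dim(mask))
    s0[mask] <- config$lesion_s0 * jitter()

    acq <- config$acquisitions
    dims <- dim(mask)
    mk_series <- function(bvals, fun) {
      arr <- array(0, c(dims, length(bvals)))
      for (j in seq_along(bvals)) arr[, , , j] <- fun(bvals[j])
      arr
    }
    sig <- config$lesion_s0 / config$snr
    spacing <- c(vx, vx, slab_mm)
    out <- list(lesion_mask = mask, roi_mask = roi_mask, spacing = spacing,
                patient_id = record$patient_id, timepoint = timepoint)
    if ("dwi" %in% modalities) {
      dwi <- mk_series(acq$dwi$b_values, function(bb) s0 * exp(-bb * pm$adc))
      if (noise) dwi <- add_noise(dwi, sig, "rician")
      out$dwi <- signal_volume(dwi, spacing, acq$dwi)
    }
    if ("dki" %in% modalities) {
      dki <- mk_series(acq$dki$b_values, function(bb)
        s0 * exp(-bb * pm$d + bb^2 * pm$d^2 * pm$k / 6))
      if (noise) dki <- add_noise(dki, sig, "rician")
      out$dki <- signal_volume(dki, spacing, acq$dki)
    }
    if ("ivim" %in% modalities) {
      ivim <- mk_series(acq$ivim$b_values, function(bb)
        s0 * ((1 - pm$f) * exp(-bb * pm$dslow) +
                pm$f * exp(-bb * (pm$dslow + pm$dfast))))
      if (noise) ivim <- add_noise(ivim, sig, "rician")
      out$ivim <- signal_volume(ivim, spacing, acq$ivim)
    }
    if ("dce" %in% modalities) {
      aif <- aif_parker(onset_s = dce_onset(acq$dce))
      cp <- aif_eval(aif, acq$dce$frame_times)
      G <- exp_conv_grid(cp, acq$dce$frame_times / 60, as.vector(pm$kep))
      dce <- array(as.vector(pm$ktrans) * G, c(dims, length(acq$dce$frame_times)))
      if (noise) dce <- add_noise(dce, config$sigma_dce, "gaussian")
      out$dce <- signal_volume(dce, spacing, acq$dce, nonneg = FALSE)
      out$aif <- aif
    }
    out
  })
}

#' Fit rendered volumes for a whole cohort in memory
#'
#' Renders each patient at the configured resolution, fits the requested
#' models voxel-wise, and summarizes each fitted parameter map over the
#' largest-axial-slice ROI (mean on the reporting scale). This is the
#' end-to-end path from ground truth to an analysis-ready marker table.
#'
#' @param cohort A [generate_cohort()] data.frame.
#' @param config The matching [cohort_config()].
#' @param models Subset of `c("adc", "dki", "ivim", "dce")`.
#' @param timepoints Subset of `c("pre", "post")`.
#' @param noise Render with noise (default TRUE).
#' @return A data.frame with `patient_id`, `group`, diameters/volumes and
#'   fitted marker columns (`adc_pre`, `md_pre`, ... for the requested
#'   models/timepoints).
#' @export
fit_cohort <- function(cohort, config = attr(cohort, "config"),
                       models = c("adc", "dki", "ivim", "dce"),
                       timepoints = c("pre", "post"), noise = TRUE) {
  models <- match.arg(models, several.ok = TRUE)
  out <- cohort[, c("patient_id", "group", "category",
                    "diameter_pre_cm", "diameter_post_cm", "delta_d_pct",
                    "volume_pre_cm3", "volume_post_cm3", "delta_v_pct")]
  for (tp in timepoints) {
    cols <- list()
    mods <- c(adc = "dwi", dki = "dki", ivim = "ivim", dce = "dce")[models]
    for (i in seq_len(nrow(cohort))) {
      img <- render_patient_images(cohort[i, ], config, tp, noise = noise,
                                   modalities = unname(mods))
      vals <- c()
      if ("adc" %in% models) {
        fa <- fit_adc(img$dwi)
        vals["adc"] <- roi_summary(fa$adc, img$roi_mask)$mean
      }
      if ("dki" %in% models) {
        fk <- fit_dki(img$dki)
        vals["md"] <- roi_summary(fk$md, img$roi_mask)$mean
        vals["mk"] <- roi_summary(fk$mk, img$roi_mask)$mean
      }
      if ("ivim" %in% models) {
        fi <- fit_ivim_segmented(img$ivim)
        vals["dslow"] <- roi_summary(fi$dslow, img$roi_mask)$mean
        vals["dfast"] <- tryCatch(roi_summary(fi$dfast, img$roi_mask)$mean,
                                  error = function(e) NA_real_)
        vals["pf"] <- roi_summary(fi$pf, img$roi_mask)$mean
      }
      if ("dce" %in% models) {
        ft <- fit_tofts(img$dce, img$aif)
        vals["ktrans"] <- roi_summary(ft$ktrans, img$roi_mask)$mean
        vals["kep"] <- roi_summary(ft$kep, img$roi_mask)$mean
        vals["ve"] <- roi_summary(ft$ve, img$roi_mask)$mean
      }
      cols[[i]] <- vals
    }
    tab <- do.call(rbind, cols)
    colnames(tab) <- paste0(colnames(tab), "_", tp)
    out <- cbind(out, as.data.frame(tab))
  }
  out
}
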