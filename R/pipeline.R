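# Stagewise orchestration: simulate a cohort fixture to disk, fit parameter
# maps from NIfTI inputs, and produce the statistical report bundle.
# Every stage is deterministic given (config, seed) and writes a manifest
# whose hash makes reruns verifiable.

write_json_file <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
}

config_hash <- function(config) {
  rlang::hash(config)
}

# Serializable form of a cohort config (acquisitions flattened).
config_to_list <- function(config) {
  cfg <- unclass(config)
  cfg$acquisitions <- list(
    dwi_b = config$acquisitions$dwi$b_values,
    dki_b = config$acquisitions$dki$b_values,
    ivim_b = config$acquisitions$ivim$b_values,
    dce_times = config$acquisitions$dce$frame_times,
    dce_n_baseline = config$acquisitions$dce$n_baseline
  )
  cfg
}

write_map_nifti <- function(map, path, spacing) {
  img <- RNifti::asNifti(map$values, pixdim = spacing)
  RNifti::writeNifti(img, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  write_json_file(list(parameter = map$parameter, reporting_scale = map$scale,
                       n_fitted = sum(map$mask), spacing_mm = spacing), sidecar)
  invisible(path)
}

#' Simulate a cohort fixture directory
#'
#' Generates the synthetic cohort and writes the full fixture set: one
#' NIfTI signal volume per patient/timepoint/modality plus lesion and ROI
#' masks, the ground-truth cohort table (CSV), the configuration (YAML) and
#' a manifest (JSON) recording the seed and a config hash.
#'
#' @param config A [cohort_config()].
#' @param out_dir Output directory (created if missing; parent must exist).
#' @param write_images Write per-patient NIfTI volumes (default TRUE; the
#'   cohort table alone is enough for summary-level statistics).
#' @return The manifest, invisibly.
#' @export
run_simulate <- function(config = cohort_config(), out_dir,
                         write_images = TRUE) {
  if (missing(out_dir)) stop("out_dir is required")
  if (!dir.exists(dirname(out_dir)))
    stop(sprintf("parent directory does not exist: %s", dirname(out_dir)))
  dir.create(out_dir, showWarnings = FALSE)
  cohort <- generate_cohort(config)
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  yaml::write_yaml(config_to_list(config), file.path(out_dir, "config.yaml"))
  files <- c("cohort.csv", "config.yaml")
  if (write_images) {
    img_dir <- file.path(out_dir, "images")
    dir.create(img_dir, showWarnings = FALSE)
    for (i in seq_len(nrow(cohort))) {
      for (tp in c("pre", "post")) {
        img <- render_patient_images(cohort[i, ], config, tp)
        stem <- file.path(img_dir, paste0(cohort$patient_id[i], "_", tp))
        for (mod in c("dwi", "dki", "ivim", "dce")) {
          RNifti::writeNifti(RNifti::asNifti(img[[mod]]$data,
                                             pixdim = c(img$spacing, 1)),
                             paste0(stem, "_", mod, ".nii.gz"))
        }
        RNifti::writeNifti(RNifti::asNifti(img$lesion_mask + 0,
                                           pixdim = img$spacing),
                           paste0(stem, "_mask.nii.gz"))
        RNifti::writeNifti(RNifti::asNifti(img$roi_mask + 0,
                                           pixdim = img$spacing),
                           paste0(stem, "_roi.nii.gz"))
      }
    }
    files <- c(files, "images")
  }
  manifest <- list(stage = "simulate", seed = config$seed,
                   config_hash = config_hash(config),
                   n_patients = nrow(cohort), files = files)
  write_json_file(manifest, file.path(out_dir, "manifest.json"))
  invisible(manifest)
}

read_fixture_config <- function(in_dir) {
  y <- yaml::read_yaml(file.path(in_dir, "config.yaml"))
  acq <- list(
    dwi = diffusion_acquisition(y$acquisitions$dwi_b),
    dki = diffusion_acquisition(y$acquisitions$dki_b),
    ivim = diffusion_acquisition(y$acquisitions$ivim_b),
    dce = dce_acquisition(y$acquisitions$dce_times, y$acquisitions$dce_n_baseline)
  )
  y$acquisitions <- acq
  do.call(cohort_config, y)
}

read_signal_nifti <- function(path, acq, nonneg = TRUE) {
  if (!file.exists(path)) stop(sprintf("missing NIfTI input: %s", path))
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop(sprintf("corrupt NIfTI file: %s", path)))
  arr <- array(as.numeric(img), dim(img))
  pd <- attr(img, "pixdim") %||% c(1, 1, 1, 1)
  signal_volume(arr, pd[1:3], acq, nonneg = nonneg)
}

#' Fit parameter maps for a simulated fixture directory
#'
#' Reads the per-patient NIfTI volumes written by [run_simulate()], fits
#' the requested models voxel-wise, writes one NIfTI map per parameter
#' (float values, reporting scale recorded in a JSON sidecar), and builds
#' the fitted-marker cohort table used by [run_stats()].
#'
#' @param in_dir Fixture directory from [run_simulate()].
#' @param out_dir Output directory for maps and the fitted cohort table.
#' @param models Subset of `c("adc", "dki", "ivim", "dce")`.
#' @return The fitted cohort table, invisibly.
#' @export
run_fit <- function(in_dir, out_dir,
                    models = c("adc", "dki", "ivim", "dce")) {
  models <- match.arg(models, several.ok = TRUE)
  cohort <- utils::read.csv(file.path(in_dir, "cohort.csv"))
  config <- read_fixture_config(in_dir)
  dir.create(out_dir, showWarnings = FALSE)
  map_dir <- file.path(out_dir, "maps")
  dir.create(map_dir, showWarnings = FALSE)
  acq <- config$acquisitions
  aif <- aif_parker(onset_s = dce_onset(acq$dce))
  spacing <- c(config$voxel_mm, config$voxel_mm,
               10 * (config$slice_thickness_cm + config$slice_gap_cm))
  by_tp <- list()
  for (tp in c("pre", "post")) {
    rows <- list()
    for (i in seq_len(nrow(cohort))) {
      pid <- cohort$patient_id[i]
      stem <- file.path(in_dir, "images", paste0(pid, "_", tp))
      roi <- RNifti::readNifti(paste0(stem, "_roi.nii.gz")) > 0
      lesion <- RNifti::readNifti(paste0(stem, "_mask.nii.gz")) > 0
      if (!any(lesion)) { warning(sprintf("empty mask for %s %s; skipped", pid, tp)); next }
      vals <- c()
      fit_one <- function(maps) {
        for (nm in names(maps)) {
          if (nm == "s0") next
          write_map_nifti(maps[[nm]],
                          file.path(map_dir, paste0(pid, "_", tp, "_", nm, ".nii.gz")),
                          spacing = spacing)
          # a parameter can be unfit across the whole ROI (e.g. Dfast in a
          # voxel set with no detectable perfusion); record NA, keep going
          vals[nm] <<- tryCatch(roi_summary(maps[[nm]], roi)$mean,
                                error = function(e) NA_real_)
        }
      }
      if ("adc" %in% models)
        fit_one(fit_adc(read_signal_nifti(paste0(stem, "_dwi.nii.gz"), acq$dwi),
                        acq$dwi, mask = lesion))
      if ("dki" %in% models)
        fit_one(fit_dki(read_signal_nifti(paste0(stem, "_dki.nii.gz"), acq$dki),
                        acq$dki, mask = lesion))
      if ("ivim" %in% models)
        fit_one(fit_ivim_segmented(read_signal_nifti(paste0(stem, "_ivim.nii.gz"), acq$ivim),
                                   acq$ivim, mask = lesion))
      if ("dce" %in% models)
        fit_one(fit_tofts(read_signal_nifti(paste0(stem, "_dce.nii.gz"), acq$dce,
                                            nonneg = FALSE),
                          aif, acq$dce, mask = lesion))
      names(vals) <- paste0(names(vals), "_", tp)
      rows[[pid]] <- data.frame(patient_id = pid, t(vals))
    }
    by_tp[[tp]] <- do.call(rbind, rows)
  }
  fitted <- merge(by_tp$pre, by_tp$post, by = "patient_id")
  keep <- c("patient_id", "group", "category", "diameter_pre_cm",
            "diameter_post_cm", "delta_d_pct", "volume_pre_cm3",
            "volume_post_cm3", "delta_v_pct")
  fitted <- merge(cohort[, keep], fitted, by = "patient_id")
  utils::write.csv(fitted, file.path(out_dir, "cohort_fitted.csv"),
                   row.names = FALSE)
  write_json_file(list(stage = "fit", models = models,
                       config_hash = config_hash(config),
                       n_patients = nrow(cohort)),
                  file.path(out_dir, "manifest.json"))
  invisible(fitted)
}

#' Statistical report bundle for a cohort table
#'
#' Runs the full statistics layer on a cohort table (ground-truth or
#' fitted): paired pre/post comparisons per MRI parameter, responder vs
#' non-responder comparisons (numeric with the normality gate, categorical
#' demographics), logistic combination of the significant pre-treatment
#' markers into a predictive score, ROC analysis of each significant
#' marker and of the combined score, and pairwise DeLong comparisons.
#' Writes CSV tables and a JSON bundle; identical inputs give identical
#' outputs.
#'
#' @param cohort Cohort data.frame (e.g. from [generate_cohort()] or
#'   [run_fit()]), or a path to its CSV.
#' @param out_dir Optional output directory; when NULL nothing is written.
#' @param alpha Significance level for marker selection (default 0.05).
#' @return A list of class `cohort_report`: `pre_post`, `group_numeric`,
#'   `group_categorical`, `roc` (list of `roc_result`), `pre_score`
#'   (logistic combination), `delong` (pairwise comparisons), `markers`
#'   (selected marker names).
#' @export
run_stats <- function(cohort, out_dir = NULL, alpha = 0.05) {
  if (is.character(cohort)) cohort <- utils::read.csv(cohort)
  if (length(unique(cohort$group)) < 2)
    stop("both responder groups must be present")
  isR <- cohort$group == "RG"
  params <- intersect(.cohort_params,
                      sub("_pre$", "", grep("_pre$", names(cohort), value = TRUE)))

  # pre vs post, whole cohort (complete pairs only)
  pre_post <- list()
  for (p in params) {
    pre <- cohort[[paste0(p, "_pre")]]; post <- cohort[[paste0(p, "_post")]]
    keep <- stats::complete.cases(pre, post)
    if (sum(keep) >= 3)
      pre_post[[p]] <- compare_paired(pre[keep], post[keep], variable = p)
  }

  # RG vs NRG on every numeric endpoint (pre, post, delta, delta%)
  endpoints <- list()
  for (p in params) {
    pre <- cohort[[paste0(p, "_pre")]]; post <- cohort[[paste0(p, "_post")]]
    endpoints[[paste0(p, "_pre")]] <- pre
    endpoints[[paste0(p, "_post")]] <- post
    endpoints[[paste0("delta_", p)]] <- post - pre
    endpoints[[paste0("delta_", p, "_pct")]] <- (post - pre) / pre * 100
  }
  endpoints$diameter_post <- cohort$diameter_post_cm
  endpoints$delta_d_pct <- cohort$delta_d_pct
  endpoints$volume_post <- cohort$volume_post_cm3
  endpoints$delta_v_pct <- cohort$delta_v_pct
  endpoints$age <- cohort$age
  group_numeric <- list()
  for (nm in names(endpoints)) {
    g1 <- endpoints[[nm]][isR]; g2 <- endpoints[[nm]][!isR]
    g1 <- g1[!is.na(g1)]; g2 <- g2[!is.na(g2)]
    if (length(g1) >= 3 && length(g2) >= 3)
      group_numeric[[nm]] <- compare_unpaired(g1, g2, variable = nm)
  }

  group_categorical <- list()
  for (nm in intersect(c("sex", "t_stage", "n_stage", "pathology", "regimen"),
                       names(cohort))) {
    tab <- table(cohort$group, cohort[[nm]])
    if (ncol(tab) > 1)
      group_categorical[[nm]] <- compare_categorical(as.matrix(tab), variable = nm)
  }

  # significant pre-treatment markers -> logistic PRE score -> ROC
  pre_markers <- intersect(paste0(params, "_pre"), names(group_numeric))
  sig <- pre_markers[vapply(pre_markers,
                            function(nm) group_numeric[[nm]]$p_value < alpha, TRUE)]
  sig <- sig[colSums(is.na(cohort[, sig, drop = FALSE])) == 0]
  roc <- list()
  for (nm in sig)
    roc[[nm]] <- roc_analysis(endpoints[[nm]], isR, marker = nm)
  pre_score <- NULL
  if (length(sig) >= 1) {
    pre_score <- logistic_combine(cohort[, sig, drop = FALSE], isR)
    roc[["pre_score"]] <- roc_analysis(pre_score$score, isR, marker = "pre_score")
  }
  delong <- list()
  nms <- names(roc)
  if (length(nms) >= 2) {
    for (i in seq_len(length(nms) - 1)) for (j in (i + 1):length(nms)) {
      s1 <- if (nms[i] == "pre_score") pre_score$score else endpoints[[nms[i]]]
      s2 <- if (nms[j] == "pre_score") pre_score$score else endpoints[[nms[j]]]
      delong[[paste(nms[i], "vs", nms[j])]] <- delong_compare(s1, s2, isR)
    }
  }

  report <- structure(list(pre_post = pre_post, group_numeric = group_numeric,
                           group_categorical = group_categorical,
                           roc = roc, pre_score = pre_score, delong = delong,
                           markers = sig),
                      class = "cohort_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE)
    utils::write.csv(comparison_table(pre_post),
                     file.path(out_dir, "pre_post.csv"), row.names = FALSE)
    utils::write.csv(comparison_table(group_numeric),
                     file.path(out_dir, "group_numeric.csv"), row.names = FALSE)
    utils::write.csv(comparison_table(group_categorical),
                     file.path(out_dir, "group_categorical.csv"), row.names = FALSE)
    utils::write.csv(roc_table(roc), file.path(out_dir, "diagnostic.csv"),
                     row.names = FALSE)
    write_json_file(report_to_list(report), file.path(out_dir, "report.json"))
  }
  report
}

comparison_table <- function(comps) {
  do.call(rbind, lapply(comps, function(x) {
    data.frame(variable = x$variable, test = x$test,
               statistic = x$statistic, p_value = x$p_value)
  }))
}

roc_table <- function(roc) {
  do.call(rbind, lapply(roc, function(x) {
    data.frame(marker = x$marker, orientation = x$orientation, auc = x$auc,
               ci_lo = x$ci[1], ci_hi = x$ci[2], youden = x$youden,
               cutoff = x$cutoff, sensitivity = x$sensitivity,
               specificity = x$specificity, plr = x$plr, nlr = x$nlr,
               ppv = x$ppv, npv = x$npv)
  }))
}

report_to_list <- function(report) {
  list(
    pre_post = lapply(report$pre_post, function(x)
      list(test = x$test, statistic = x$statistic, p_value = x$p_value)),
    group_numeric = lapply(report$group_numeric, function(x)
      list(test = x$test, statistic = x$statistic, p_value = x$p_value)),
    group_categorical = lapply(report$group_categorical, function(x)
      list(test = x$test, statistic = x$statistic, p_value = x$p_value)),
    markers = report$markers,
    roc = lapply(report$roc, function(x)
      list(orientation = x$orientation, auc = x$auc, ci = x$ci,
           youden = x$youden, cutoff = x$cutoff, sensitivity = x$sensitivity,
           specificity = x$specificity, plr = x$plr, nlr = x$nlr,
           ppv = x$ppv, npv = x$npv)),
    delong = report$delong
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat(sprintf("  significant pre-treatment markers: %s\n",
              paste(x$markers, collapse = ", ")))
  for (r in x$roc)
    cat(sprintf("  %-12s AUC %.3f (%.3f, %.3f) cutoff %.4g sens %.1f%% spec %.1f%%\n",
                r$marker, r$auc, r$ci[1], r$ci[2], r$cutoff,
                100 * r$sensitivity, 100 * r$specificity))
  invisible(x)
}
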