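# ROI summarization, change metrics, tumor size formulas and RECIST labels.

#' Summarize a parameter map over an ROI
#'
#' Statistics are computed over the intersection of the ROI with the map's
#' fitted-voxel mask, on the reporting scale. Quartiles use linear
#' interpolation between order statistics (R's default type-7 convention),
#' which matters when comparing IQRs across software.
#'
#' @param map A [parameter_map()].
#' @param roi 3-D logical array (same grid as the map).
#' @return An object of class `roi_stats`: parameter, `n_voxels`, `mean`,
#'   `sd`, `median`, `iqr` on the reporting scale.
#' @export
roi_summary <- function(map, roi) {
  stopifnot(inherits(map, "parameter_map"))
  if (!identical(dim(roi), dim(map$values)))
    stop("ROI grid does not match the map grid")
  sel <- roi & map$mask
  if (!any(sel)) stop("ROI does not intersect any fitted voxel")
  v <- map$values[sel] / map$scale
  q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(list(parameter = map$parameter, n_voxels = length(v),
                 mean = mean(v), sd = stats::sd(v),
                 median = q[2], iqr = q[3] - q[1]),
            class = "roi_stats")
}

#' @export
print.roi_stats <- function(x, ...) {
  cat(sprintf("<roi_stats> %s: n=%d mean=%.4g median=%.4g IQR=%.4g\n",
              x$parameter, x$n_voxels, x$mean, x$median, x$iqr))
  invisible(x)
}

#' Pre/post change metrics
#'
#' `delta = post - pre` and `delta_pct = delta / pre * 100`. ROI summaries
#' are compared on their means.
#'
#' @param pre,post Scalars or `roi_stats` objects; `pre` must be non-zero.
#' @return A list `(pre, post, delta, delta_pct)` of class `delta_metrics`.
#' @examples
#' change_metrics(1238.43, 1549.84)
#' @export
change_metrics <- function(pre, post) {
  val <- function(x) if (inherits(x, "roi_stats")) x$mean else as.numeric(x)
  pre <- val(pre); post <- val(post)
  if (any(pre == 0)) stop("pre value must be non-zero")
  structure(list(pre = pre, post = post, delta = post - pre,
                 delta_pct = (post - pre) / pre * 100),
            class = "delta_metrics")
}

#' Tumor volume from slice areas
#'
#' `Volume = area * (slice thickness + interstice gap)`, summed over
#' slices for multi-slice lesions.
#'
#' @param area Lesion cross-section area(s) per slice, cm^2.
#' @param slice_thickness Slice thickness, cm (> 0).
#' @param gap Interslice gap, cm (>= 0).
#' @return Volume in cm^3.
#' @examples
#' tumor_volume(5, 0.4, 0.1)          # 2.5
#' tumor_volume(c(3, 4), 0.4, 0.1)    # 3.5
#' @export
tumor_volume <- function(area, slice_thickness, gap = 0) {
  if (any(area < 0)) stop("areas must be non-negative")
  if (slice_thickness <= 0) stop("slice thickness must be positive")
  if (gap < 0) stop("gap must be non-negative")
  sum(area) * (slice_thickness + gap)
}

#' RECIST 1.1 classification of a single target lesion
#'
#' Categories from the diameter change of the (single) target lesion:
#' partial response (PR) for a decrease of at least 30%, progressive
#' disease (PD) for an increase of at least 20% that is also at least 5 mm
#' in absolute terms, complete response (CR) when the lesion disappears,
#' stable disease (SD) otherwise. Responders (RG) are CR/PR; non-responders
#' (NRG) are SD/PD. When `pre_diameter_cm` is not supplied the 5 mm PD
#' guard cannot be evaluated and is assumed satisfied.
#'
#' @param delta_diameter_pct Percent diameter change (post vs pre), may be
#'   a vector.
#' @param pre_diameter_cm Optional pre-treatment diameter(s), cm.
#' @return A data.frame with columns `category` (factor CR/PR/SD/PD) and
#'   `group` (factor RG/NRG).
#' @examples
#' recist_classify(c(-49.24, -18.62, -30, -100, 25), pre_diameter_cm = 2.4)
#' @export
recist_classify <- function(delta_diameter_pct, pre_diameter_cm = NULL) {
  pct <- as.numeric(delta_diameter_pct)
  if (any(pct < -100)) stop("diameter cannot shrink by more than 100%")
  guard <- if (is.null(pre_diameter_cm)) rep(TRUE, length(pct))
           else pre_diameter_cm * pct / 100 >= 0.5
  category <- ifelse(pct <= -100, "CR",
               ifelse(pct <= -30, "PR",
                ifelse(pct >= 20 & guard, "PD", "SD")))
  category <- factor(category, levels = c("CR", "PR", "SD", "PD"))
  group <- factor(ifelse(category %in% c("CR", "PR"), "RG", "NRG"),
                  levels = c("RG", "NRG"))
  data.frame(category = category, group = group)
}
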