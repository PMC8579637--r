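#' Reference NPC induction-chemotherapy cohort summaries
#'
#' Published summary statistics from a prospective cohort of 56 patients
#' with locoregionally advanced nasopharyngeal carcinoma imaged before and
#' after two cycles of induction chemotherapy (36 responders, 20
#' non-responders by RECIST 1.1). These printed group summaries and
#' operating points are the calibration targets of the synthetic-cohort
#' generator and the inputs to the summary-level verification helpers
#' ([t_from_summary()], [diagnostic_metrics()]).
#'
#' @return A list with elements:
#' \describe{
#'   \item{n_rg, n_nrg}{group sizes (36 responders / 20 non-responders).}
#'   \item{markers}{data.frame of ROC operating points per marker
#'     (`marker`, `auc`, `ci_lo`, `ci_hi`, `cutoff`, `sensitivity`,
#'     `specificity`), sensitivities/specificities as fractions.}
#'   \item{group_summaries}{data.frame of mean +/- SD group summaries used
#'     for pooled-t verification (`variable`, `mean_rg`, `sd_rg`,
#'     `mean_nrg`, `sd_nrg`).}
#'   \item{pre_post}{data.frame of whole-cohort pre/post-treatment
#'     summaries per MRI parameter on the reporting scale (`parameter`,
#'     `pre`, `post`, either means or medians as published).}
#' }
#' @export
reference_cohort <- function() {
  list(
    n_rg = 36L,
    n_nrg = 20L,
    markers = data.frame(
      marker = c("adc_pre", "md_pre", "mk_pre", "dslow_pre", "pre_score"),
      auc = c(0.885, 0.855, 0.692, 0.742, 0.912),
      ci_lo = c(0.772, 0.735, 0.555, 0.608, 0.806),
      ci_hi = c(0.955, 0.935, 0.809, 0.850, 0.971),
      cutoff = c(1210, 1010, 832, 835, 0.799),
      sensitivity = c(0.75, 0.806, 0.944, 0.75, 0.7222),
      specificity = c(0.90, 0.75, 0.45, 0.70, 0.95),
      stringsAsFactors = FALSE
    ),
    group_summaries = data.frame(
      variable = c("delta_volume_pct", "adc_pre", "age"),
      mean_rg = c(-64.98, 1119.58, 43.75),
      sd_rg = c(17.77, 144.06, 13.14),
      mean_nrg = c(-30.35, 1386.25, 48.75),
      sd_nrg = c(14.94, 198.23, 11.92),
      stringsAsFactors = FALSE
    ),
    pre_post = data.frame(
      parameter = c("adc", "md", "mk", "dslow", "dfast", "pf", "ktrans", "ve", "kep"),
      pre = c(1238.43, 1012.50, 1020.00, 778.00, 410.59, 198.50, 920.43, 686.18, 1239.50),
      post = c(1549.84, 1432.61, 779.00, 937.00, 363.16, 243.00, 790.48, 838.14, 805.00),
      summary = c("mean", "mean", "median", "median", "mean", "median",
                  "mean", "mean", "median"),
      stringsAsFactors = FALSE
    )
  )
}
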