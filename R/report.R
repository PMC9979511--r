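# Per-feature discrimination summary across the whole registry.

#' Univariate discrimination report over all scored features
#'
#' For every registry feature (and the cell density when present) this runs
#' [univariate_auc()], [youden_threshold()] and [chi_square_feature()] on
#' per-feature complete cases and assembles the conventional summary table:
#' AUC, orientation, optimal Youden partition with its sensitivity and
#' specificity, and the chi-square p-value of the disease-by-category
#' comparison (categorical features only).
#'
#' @param cohort A `synovial_cohort`.
#' @param include_density Also report the continuous density score when any
#'   densities are present (default `TRUE`).
#' @return data.frame with one row per feature: `feature`, `auc`,
#'   `direction` (`"RA"`/`"OA"`: the disease indicated by higher scores),
#'   `cutoff` (oriented units), `partition`, `sensitivity`, `specificity`,
#'   `youden_j`, `chisq_p`, `n_missing`.
#' @examples
#' head(feature_report(reference_cohort()), 4)
#' @export
feature_report <- function(cohort, include_density = TRUE) {
  stopifnot(inherits(cohort, "synovial_cohort"))
  reg <- attr(cohort, "registry")
  feats <- names(reg)
  rows <- lapply(feats, function(f) {
    roc <- univariate_auc(cohort[[f]], cohort$disease, f)
    thr <- youden_threshold(roc)
    part <- describe_partition(thr, f)
    chi <- tryCatch(chi_square_feature(crosstab(cohort, f)),
                    error = function(e) list(p_value = NA_real_))
    data.frame(
      feature = f, auc = roc$auc,
      direction = if (roc$orientation == 1) "RA" else "OA",
      cutoff = thr$cutoff, partition = part$label,
      sensitivity = thr$sensitivity, specificity = thr$specificity,
      youden_j = thr$J, chisq_p = chi$p_value,
      n_missing = roc$n_missing, stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (include_density && any(!is.na(cohort$density))) {
    roc <- univariate_auc(cohort$density, cohort$disease, "density")
    thr <- youden_threshold(roc)
    cut_raw <- roc$orientation * thr$cutoff
    out <- rbind(out, data.frame(
      feature = "density", auc = roc$auc,
      direction = if (roc$orientation == 1) "RA" else "OA",
      cutoff = thr$cutoff,
      partition = sprintf("%s %.0f cells/mm^2 (RA)",
                          if (roc$orientation == 1) ">=" else "<=", cut_raw),
      sensitivity = thr$sensitivity, specificity = thr$specificity,
      youden_j = thr$J, chisq_p = NA_real_,
      n_missing = roc$n_missing, stringsAsFactors = FALSE
    ))
  }
  out[order(-out$auc), ]
}
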