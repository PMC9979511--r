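# Univariate ROC/AUC with ties, Youden optimal cut-points, chi-square group
# comparison and covariate-adjusted logistic regression.

# Tie-aware Mann-Whitney AUC for the convention "higher score favours RA":
# P(score_RA > score_OA) + 0.5 P(tie), computed from midranks.
mw_auc <- function(scores, is_ra) {
  r <- rank(scores)                      # midranks handle ties
  n1 <- as.numeric(sum(is_ra))
  n0 <- as.numeric(sum(!is_ra))
  (sum(r[is_ra]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Univariate ROC and AUC of one scalar feature against disease
#'
#' Treats the feature values themselves as prediction scores for the OA/RA
#' label and computes the tie-aware Mann-Whitney AUC
#' \deqn{AUC = (\#\{RA > OA\} + 0.5\,\#\{ties\}) / (n_{RA} n_{OA}),}
#' which equals the trapezoidal area under the ROC curve through every
#' distinct cut. The curve is oriented so that the reported AUC is at least
#' 0.5: `orientation = +1` means higher scores indicate RA, `-1` means
#' higher scores indicate OA (e.g. fibrosis). Missing scores are dropped
#' pairwise and the number dropped is reported.
#'
#' @param scores Numeric vector of per-patient scores (ordinal codes, cell
#'   densities, or any scalar).
#' @param labels Disease labels, coercible to a factor with levels OA/RA.
#' @param feature Optional feature name carried into the result.
#' @return A `roc_result`: list with `feature`, `orientation`, `auc`,
#'   `points` (data.frame with `cutoff`, `fpr`, `tpr`; cut rule "oriented
#'   score >= cutoff predicts RA"), `n_oa`, `n_ra`, `n_missing`.
#' @examples
#' coh <- reference_cohort()
#' univariate_auc(coh$fibrosis, coh$disease, "fibrosis")
#' @export
univariate_auc <- function(scores, labels, feature = NULL) {
  lab <- toupper(as.character(labels))
  keep <- !is.na(scores) & !is.na(lab)
  n_missing <- sum(!keep)
  scores <- as.numeric(scores[keep])
  lab <- lab[keep]
  if (!all(lab %in% c("OA", "RA"))) stop("labels must be OA or RA")
  is_ra <- lab == "RA"
  if (!any(is_ra) || all(is_ra)) stop("both disease classes must be present")
  if (!length(scores)) stop("all scores missing")

  auc_ra <- mw_auc(scores, is_ra)
  orientation <- if (auc_ra >= 0.5) 1L else -1L
  auc <- max(auc_ra, 1 - auc_ra)

  s <- orientation * scores               # higher oriented score => RA
  ord <- order(s, decreasing = TRUE)
  sv <- s[ord]
  ra <- is_ra[ord]
  last <- c(sv[-1] != sv[-length(sv)], TRUE)   # end of each tie block
  tpr <- cumsum(ra)[last] / sum(is_ra)
  fpr <- cumsum(!ra)[last] / sum(!is_ra)
  points <- data.frame(cutoff = c(Inf, sv[last]), fpr = c(0, fpr),
                       tpr = c(0, tpr))
  structure(
    list(feature = feature, orientation = orientation, auc = auc,
         points = points, n_oa = sum(!is_ra), n_ra = sum(is_ra),
         n_missing = n_missing),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("<roc_result>%s AUC = %.3f (higher score => %s; %d OA, %d RA%s)\n",
              if (is.null(x$feature)) "" else paste0(" ", x$feature),
              x$auc, if (x$orientation == 1) "RA" else "OA",
              x$n_oa, x$n_ra,
              if (x$n_missing) sprintf(", %d missing", x$n_missing) else ""))
  invisible(x)
}

#' Youden J optimal cut-point on a ROC curve
#'
#' Scans every ROC point and returns the cut maximizing Youden's
#' J = sensitivity + specificity - 1. Ties in J are broken toward the more
#' specific cut (the higher oriented cutoff). The rule is "oriented score >=
#' cutoff predicts RA"; for orientation -1 this means raw scores at or above
#' `-cutoff` predict OA.
#'
#' @param roc A `roc_result` from [univariate_auc()].
#' @return A `threshold_result`: list with `cutoff` (oriented score units),
#'   `J`, `sensitivity`, `specificity` and the `orientation` echoed from the
#'   curve. A degenerate (single-valued) score yields J = 0 at the trivial
#'   all-RA cut.
#' @examples
#' coh <- reference_cohort()
#' youden_threshold(univariate_auc(coh$lining_hyperplasia, coh$disease))
#' @export
youden_threshold <- function(roc) {
  stopifnot(inherits(roc, "roc_result"))
  p <- roc$points[is.finite(roc$points$cutoff), , drop = FALSE]
  j <- p$tpr - p$fpr
  best <- which.max(j)   # points are ordered by decreasing cutoff,
                         # so which.max takes the most specific tie
  structure(
    list(cutoff = p$cutoff[best], J = j[best],
         sensitivity = p$tpr[best], specificity = 1 - p$fpr[best],
         orientation = roc$orientation, feature = roc$feature),
    class = "threshold_result"
  )
}

#' @export
print.threshold_result <- function(x, ...) {
  cat(sprintf(
    "<threshold_result>%s cut >= %g (oriented): J = %.3f, sens = %.3f, spec = %.3f\n",
    if (is.null(x$feature)) "" else paste0(" ", x$feature),
    x$cutoff, x$J, x$sensitivity, x$specificity))
  invisible(x)
}

#' Render an optimal cut as a category partition
#'
#' Translates a [youden_threshold()] result on an ordinal/binary feature into
#' the two groups of category labels it separates, phrased as "RA-side vs
#' OA-side" categories.
#'
#' @param thr A `threshold_result` for a registry feature.
#' @param feature Feature name (defaults to the one carried in `thr`).
#' @return List with `ra_categories`, `oa_categories` and a human-readable
#'   `label`.
#' @export
describe_partition <- function(thr, feature = thr$feature) {
  reg <- feature_registry()
  if (is.null(feature) || !feature %in% names(reg)) {
    stop("feature must name a registry feature")
  }
  def <- reg[[feature]]
  oriented <- thr$orientation * def$codes
  ra_side <- oriented >= thr$cutoff
  list(
    ra_categories = def$labels[ra_side],
    oa_categories = def$labels[!ra_side],
    label = paste0(paste(def$labels[ra_side], collapse = " or "),
                   " (RA) vs ",
                   paste(def$labels[!ra_side], collapse = " or "), " (OA)")
  )
}

#' Pearson chi-square comparison of a disease-by-category table
#'
#' Pearson's chi-square test without continuity correction on a 2 x k count
#' table (missing scores excluded beforehand; see [crosstab()]), with
#' k - 1 degrees of freedom.
#'
#' @param tab A `synovial_crosstab` or a 2 x k count matrix.
#' @return List with `statistic`, `df`, `p_value`.
#' @examples
#' chi_square_feature(crosstab(reference_cohort(), "fibrosis"))
#' @export
chi_square_feature <- function(tab) {
  counts <- if (inherits(tab, "synovial_crosstab")) tab$counts else as.matrix(tab)
  if (nrow(counts) != 2) stop("expected a 2 x k table of counts")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0)) {
    stop("zero-margin row or column; collapse categories before testing")
  }
  ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = unname(ht$p.value))
}

#' Covariate-adjusted logistic regression of disease on a feature
#'
#' Fits a maximum-likelihood binary logistic regression of disease (RA = 1)
#' on an exposure feature adjusted for one or more other features, on
#' complete cases. Categorical features enter as indicator contrasts against
#' their lowest category. The exposure's overall contribution is summarized
#' by a likelihood-ratio test alongside per-coefficient Wald statistics.
#'
#' @param cohort A `synovial_cohort`.
#' @param exposure Feature whose adjusted association is of interest.
#' @param adjust Character vector of adjustment features.
#' @param ordinal_as_numeric Enter ordinal features as a single linear score
#'   rather than indicators (default `FALSE`).
#' @return List with `coefficients` (data.frame: term, estimate, std_error,
#'   z, p_value), `exposure_lrt_p`, `n_used`, `separation` (TRUE when the
#'   fit shows signs of complete separation).
#' @export
adjusted_logistic <- function(cohort, exposure, adjust,
                              ordinal_as_numeric = FALSE) {
  stopifnot(inherits(cohort, "synovial_cohort"))
  reg <- attr(cohort, "registry")
  vars <- c(exposure, adjust)
  bad <- setdiff(vars, c(names(reg), "density"))
  if (length(bad)) stop("unknown feature(s): ", paste(bad, collapse = ", "))

  d <- data.frame(y = as.integer(cohort$disease == "RA"))
  for (v in vars) {
    x <- cohort[[v]]
    if (v != "density" && !ordinal_as_numeric && length(reg[[v]]$codes) > 2) {
      d[[v]] <- factor(x, levels = reg[[v]]$codes)
    } else {
      d[[v]] <- as.numeric(x)
    }
  }
  d <- d[stats::complete.cases(d), , drop = FALSE]
  form <- stats::as.formula(paste("y ~", paste(vars, collapse = " + ")))
  fit <- stats::glm(form, family = stats::binomial(), data = d)
  n_par <- length(stats::coef(fit))
  if (nrow(d) < 10 * n_par) {
    warning(sprintf("only %d complete cases for %d parameters", nrow(d), n_par))
  }
  separation <- any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
    !fit$converged
  if (separation) warning("fit shows signs of complete separation")
  sm <- summary(fit)$coefficients
  coefs <- data.frame(term = rownames(sm), estimate = sm[, 1],
                      std_error = sm[, 2], z = sm[, 3], p_value = sm[, 4],
                      row.names = NULL, stringsAsFactors = FALSE)
  reduced <- stats::glm(
    stats::as.formula(paste("y ~", paste(adjust, collapse = " + "))),
    family = stats::binomial(), data = d)
  lrt <- stats::anova(reduced, fit, test = "LRT")
  list(coefficients = coefs,
       exposure_lrt_p = lrt[["Pr(>Chi)"]][2],
       n_used = nrow(d), separation = separation)
}
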