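# Canonical definitions of the fourteen pathologist-scored synovial features
# and the bundled OA/RA reference cross-tabulation.

#' Registry of the fourteen scored synovial histology features
#'
#' Returns the canonical feature definitions used throughout the package:
#' five semi-quantitative ordinal features (lymphocytic inflammation, lining
#' hyperplasia, fibrosis, plasma cells, mucoid change) and nine binary
#' absent/present features. Each definition carries the ordered category
#' labels and their contiguous integer codes `0..k-1`; for ordinal features
#' the code order is the severity order used when feature scores are treated
#' as ROC prediction scores.
#'
#' Band-like lymphocytic inflammation ranks above "marked" (code 4), and
#' "widespread or band-like" fibrosis is a single top category (code 2),
#' matching how optimal thresholds on these features are conventionally
#' reported.
#'
#' @return A named list of 14 `feature_def` objects, each with elements
#'   `name`, `kind` (`"ordinal"` or `"binary"`), `labels` (ordered category
#'   labels) and `codes` (integer codes `0..k-1`).
#' @examples
#' reg <- feature_registry()
#' length(reg)
#' reg$fibrosis$labels
#' @export
feature_registry <- function() {
  def <- function(name, kind, labels) {
    structure(
      list(name = name, kind = kind, labels = labels,
           codes = seq_along(labels) - 1L),
      class = "feature_def"
    )
  }
  binary <- c("Absent", "Present")
  defs <- list(
    def("lymphocytic_inflammation", "ordinal",
        c("None", "Mild", "Moderate", "Marked", "Band-like")),
    def("lining_hyperplasia", "ordinal",
        c("Normal lining", "2-3 cells thick", "3-4 cells thick",
          ">4 cells thick")),
    def("fibrosis", "ordinal", c("None", "Focal", "Widespread or band-like")),
    def("plasma_cells", "ordinal",
        c("<10% plasma cells", "<50% plasma cells", ">50% plasma cells")),
    def("mucoid_change", "ordinal",
        c("None", "Slight", "Moderate", "Marked", "Myxomatous")),
    def("neutrophils", "binary", binary),
    def("binucleate_plasma_cells", "binary", binary),
    def("russell_bodies", "binary", binary),
    def("sub_lining_giant_cells", "binary", binary),
    def("synovial_lining_giant_cells", "binary", binary),
    def("fibrin", "binary", binary),
    def("detritus", "binary", binary),
    def("mast_cells", "binary", binary),
    def("germinal_centers", "binary", binary)
  )
  names(defs) <- vapply(defs, `[[`, character(1), "name")
  defs
}

#' @export
print.feature_def <- function(x, ...) {
  cat(sprintf("<feature_def> %s (%s): %s\n", x$name, x$kind,
              paste(sprintf("%d=%s", x$codes, x$labels), collapse = " < ")))
  invisible(x)
}

#' Reference OA/RA category counts for every scored feature
#'
#' Per-disease category counts for the fourteen histology features in a
#' published reference cohort of 147 osteoarthritis (OA) and 60 rheumatoid
#' arthritis (RA) total-knee-replacement explants, together with the number
#' of patients missing each score. These counts are the package's built-in
#' worked example: expanding them with [reference_cohort()] reproduces the
#' published per-feature discrimination statistics.
#'
#' @return A named list, one element per registry feature, each a list with
#'   `counts` (2 x k integer matrix, rows `OA`/`RA`, columns the category
#'   labels) and `missing` (length-2 integer vector of unscored patients).
#' @seealso [reference_cohort()], [feature_registry()]
#' @export
synovial_reference_counts <- function() {
  reg <- feature_registry()
  mk <- function(name, oa, ra, miss = c(0L, 0L)) {
    m <- rbind(OA = as.integer(oa), RA = as.integer(ra))
    colnames(m) <- reg[[name]]$labels
    list(counts = m, missing = c(OA = miss[1], RA = miss[2]))
  }
  list(
    lymphocytic_inflammation = mk("lymphocytic_inflammation",
                                  c(43, 64, 30, 9, 1), c(7, 20, 14, 15, 4)),
    lining_hyperplasia = mk("lining_hyperplasia",
                            c(10, 97, 38, 2), c(0, 16, 26, 18)),
    fibrosis = mk("fibrosis", c(7, 85, 55), c(40, 16, 4)),
    plasma_cells = mk("plasma_cells", c(125, 18, 4), c(33, 17, 10)),
    mucoid_change = mk("mucoid_change",
                       c(6, 63, 50, 17, 11), c(5, 22, 22, 6, 4),
                       miss = c(0L, 1L)),
    neutrophils = mk("neutrophils", c(146, 1), c(47, 13)),
    binucleate_plasma_cells = mk("binucleate_plasma_cells",
                                 c(131, 16), c(41, 19)),
    russell_bodies = mk("russell_bodies", c(134, 13), c(47, 13)),
    sub_lining_giant_cells = mk("sub_lining_giant_cells",
                                c(145, 2), c(51, 9)),
    synovial_lining_giant_cells = mk("synovial_lining_giant_cells",
                                     c(122, 25), c(36, 22), miss = c(0L, 2L)),
    fibrin = mk("fibrin", c(134, 13), c(33, 27)),
    detritus = mk("detritus", c(85, 62), c(18, 42)),
    mast_cells = mk("mast_cells", c(1, 146), c(37, 22), miss = c(0L, 1L)),
    germinal_centers = mk("germinal_centers", c(146, 1), c(58, 2))
  )
}

#' Mean reference cell densities (cells per mm^2 of tissue)
#'
#' Group means of computer-vision-quantified nuclei density in the reference
#' cohort: 2900 cells/mm^2 in OA and 4196 cells/mm^2 in RA.
#' @return Named numeric vector with elements `OA` and `RA`.
#' @export
reference_density_means <- function() c(OA = 2900, RA = 4196)

#' Expand the reference counts into a patient-level cohort
#'
#' Builds a cohort of 147 OA and 60 RA records whose per-feature category
#' counts equal [synovial_reference_counts()] exactly, including the recorded
#' missing scores (stored as `NA`). Only the per-feature marginal
#' distributions of the reference cohort are published, so the joint
#' assignment across features is arbitrary: each feature column is filled
#' independently and shuffled within disease group under a fixed internal
#' seed, which leaves every marginal statistic — per-feature ROC/AUC, Youden
#' thresholds, chi-square comparisons — identical to the real cohort while
#' carrying no information about cross-feature dependence.
#'
#' @return A `synovial_cohort` (see [as_synovial_cohort()]) with 207 rows and
#'   no density column values.
#' @examples
#' coh <- reference_cohort()
#' table(coh$disease)
#' @export
reference_cohort <- function() {
  cnt <- synovial_reference_counts()
  reg <- feature_registry()
  n <- c(OA = 147L, RA = 60L)
  cols <- lapply(names(reg), function(f) {
    x <- cnt[[f]]
    unlist(lapply(c("OA", "RA"), function(g) {
      v <- c(rep(reg[[f]]$codes, times = x$counts[g, ]),
             rep(NA_integer_, x$missing[g]))
      with_seed(derive_seed(20260101L, "reference", f, g), sample(v))
    }), use.names = FALSE)
  })
  names(cols) <- names(reg)
  df <- data.frame(
    patient_id = c(sprintf("OA-%03d", seq_len(n["OA"])),
                   sprintf("RA-%03d", seq_len(n["RA"]))),
    disease = factor(rep(c("OA", "RA"), n), levels = c("OA", "RA")),
    cols,
    density = NA_real_,
    stringsAsFactors = FALSE
  )
  as_synovial_cohort(df)
}
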