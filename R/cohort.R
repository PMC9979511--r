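# Patient-level cohort container, validation, CSV dialect and crosstabs.

#' Construct a validated synovial cohort
#'
#' A `synovial_cohort` is a `data.frame` with one row per patient and columns
#' `patient_id` (unique), `disease` (factor with levels `OA`, `RA`), one
#' integer-coded column per registry feature (missing scores as `NA`), and an
#' optional numeric `density` column (cells per mm^2 of tissue, `NA` when not
#' measured).
#'
#' @param df A data.frame with the columns described above. Feature columns
#'   may hold either integer codes or category label strings; labels are
#'   converted to codes against [feature_registry()].
#' @return The validated cohort (class `synovial_cohort`).
#' @export
as_synovial_cohort <- function(df) {
  reg <- feature_registry()
  stopifnot(is.data.frame(df))
  names(df) <- tolower(names(df))
  need <- c("patient_id", "disease")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("cohort lacks required column(s): ",
                         paste(miss, collapse = ", "))
  df$patient_id <- as.character(df$patient_id)
  if (anyDuplicated(df$patient_id)) {
    stop("duplicate patient_id: ",
         paste(unique(df$patient_id[duplicated(df$patient_id)]),
               collapse = ", "))
  }
  dis <- toupper(trimws(as.character(df$disease)))
  bad <- setdiff(unique(dis), c("OA", "RA"))
  if (length(bad)) stop("unknown disease label(s): ",
                        paste(bad, collapse = ", "))
  df$disease <- factor(dis, levels = c("OA", "RA"))

  for (f in names(reg)) {
    if (!f %in% names(df)) stop("cohort lacks feature column: ", f)
    df[[f]] <- decode_feature(df[[f]], reg[[f]])
  }
  if (!"density" %in% names(df)) df$density <- NA_real_
  if (is.character(df$density)) {
    d <- trimws(df$density)
    d[d == ""] <- NA_character_
    num <- suppressWarnings(as.numeric(d))
    bad <- which(!is.na(d) & is.na(num))
    if (length(bad)) stop(sprintf("invalid density '%s' (row %d)",
                                  d[bad[1]], bad[1]))
    df$density <- num
  }
  df$density <- as.numeric(df$density)
  if (any(df$density < 0, na.rm = TRUE)) stop("negative density values")

  df <- df[, c("patient_id", "disease", names(reg), "density")]
  structure(df, registry = reg,
            class = c("synovial_cohort", "data.frame"))
}

# Map a vector of codes or label strings onto a feature's integer codes.
decode_feature <- function(x, def) {
  if (is.numeric(x)) {
    v <- as.integer(x)
    bad <- which(!is.na(v) & !(v %in% def$codes))
    if (length(bad)) {
      stop(sprintf("invalid code '%s' for feature '%s' (row %d)",
                   v[bad[1]], def$name, bad[1]))
    }
    return(v)
  }
  s <- trimws(as.character(x))
  s[s == ""] <- NA_character_
  v <- rep(NA_integer_, length(s))
  known <- !is.na(s)
  # accept labels (case-insensitive) or stringified codes
  idx <- match(tolower(s[known]), tolower(def$labels))
  num <- suppressWarnings(as.integer(s[known]))
  use_num <- is.na(idx) & !is.na(num) & num %in% def$codes
  idx[use_num] <- num[use_num] + 1L
  if (anyNA(idx)) {
    bad <- which(known)[which(is.na(idx))[1]]
    stop(sprintf("unknown category '%s' for feature '%s' (row %d)",
                 s[bad], def$name, bad))
  }
  v[known] <- def$codes[idx]
  v
}

#' Read a cohort from CSV
#'
#' The CSV dialect is UTF-8, comma-separated, one header row, one row per
#' patient. Feature cells may contain category labels (e.g. `"Focal"`) or
#' integer codes; empty cells are missing scores. Column-name matching is
#' case-insensitive.
#'
#' @param path Path to the CSV file.
#' @return A `synovial_cohort`.
#' @seealso [write_cohort()]
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", na.strings = NULL)
  as_synovial_cohort(df)
}

#' Write a cohort to CSV
#'
#' Feature scores are written as their category labels and missing scores as
#' empty cells, so files remain readable without the code book.
#' `write_cohort()` then `read_cohort()` is the identity on valid cohorts.
#'
#' @param cohort A `synovial_cohort`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "synovial_cohort"))
  reg <- attr(cohort, "registry")
  out <- data.frame(patient_id = cohort$patient_id,
                    disease = as.character(cohort$disease),
                    stringsAsFactors = FALSE)
  for (f in names(reg)) {
    lab <- reg[[f]]$labels[cohort[[f]] + 1L]
    lab[is.na(lab)] <- ""
    out[[f]] <- lab
  }
  dens <- cohort$density
  out$density <- ifelse(is.na(dens), "", format(dens, digits = 12,
                                                scientific = FALSE,
                                                trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' Cross-tabulate one feature by disease
#'
#' Counts patients by disease group and feature category, the form in which
#' semi-quantitative synovitis scores are conventionally reported and the
#' input expected by [chi_square_feature()]. Missing scores are tallied
#' separately, never as a category.
#'
#' @param cohort A `synovial_cohort`.
#' @param feature Feature name from [feature_registry()].
#' @return A `synovial_crosstab`: list with `feature`, `counts` (2 x k
#'   matrix, rows OA/RA, columns category labels) and `missing` (per-disease
#'   count of unscored patients).
#' @examples
#' crosstab(reference_cohort(), "neutrophils")
#' @export
crosstab <- function(cohort, feature) {
  stopifnot(inherits(cohort, "synovial_cohort"))
  reg <- attr(cohort, "registry")
  if (!feature %in% names(reg)) stop("unknown feature: ", feature)
  def <- reg[[feature]]
  x <- cohort[[feature]]
  g <- cohort$disease
  counts <- t(vapply(c("OA", "RA"), function(d) {
    tabulate(x[g == d] + 1L, nbins = length(def$codes))
  }, integer(length(def$codes))))
  colnames(counts) <- def$labels
  rownames(counts) <- c("OA", "RA")
  missing <- vapply(c("OA", "RA"), function(d) sum(is.na(x[g == d])),
                    integer(1))
  structure(list(feature = feature, counts = counts, missing = missing),
            class = "synovial_crosstab")
}

#' @export
print.synovial_crosstab <- function(x, ...) {
  cat("<synovial_crosstab>", x$feature, "\n")
  print(x$counts)
  if (any(x$missing > 0)) {
    cat("missing:", paste(names(x$missing), x$missing, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
print.synovial_cohort <- function(x, ...) {
  cat(sprintf("<synovial_cohort> %d patients (%d OA, %d RA); %d features; %s\n",
              nrow(x), sum(x$disease == "OA"), sum(x$disease == "RA"),
              length(attr(x, "registry")),
              if (all(is.na(x$density))) "no density" else "with density"))
  NextMethod()
}

# data.frame subsetting drops attributes; keep the registry alive
#' @export
`[.synovial_cohort` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("patient_id", "disease") %in% names(out))) {
    attr(out, "registry") <- attr(x, "registry")
    class(out) <- c("synovial_cohort", "data.frame")
  }
  out
}
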