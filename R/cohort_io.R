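#' Read a cohort table
#'
#' Reads a per-subject CSV with required columns `subject_id` and `label`
#' (0 = encapsulated, 1 = invasive). Optional clinical columns (`age`,
#' `symptoms`, `myasthenia`, `cystic_change`, `calcification`, `diameter`)
#' and shape-feature columns are typed when present; unknown columns are
#' passed through untouched. Missing optional columns are recorded in the
#' `missing_optional` attribute.
#'
#' @param path CSV path (UTF-8, comma-separated, header row).
#' @return a `data.frame` of class `cohort_table`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("cohort file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_cohort(df)
}

#' Validate a data frame as a cohort table
#'
#' @param df data frame with at least `subject_id` and `label` columns.
#' @return the validated `cohort_table`.
#' @export
as_cohort <- function(df) {
  required <- c("subject_id", "label")
  miss <- setdiff(required, names(df))
  if (length(miss))
    stop("cohort table missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  df$subject_id <- as.character(df$subject_id)
  if (anyDuplicated(df$subject_id))
    stop("duplicated subject_id: ",
         paste(unique(df$subject_id[duplicated(df$subject_id)]),
               collapse = ", "), call. = FALSE)
  lab <- suppressWarnings(as.numeric(df$label))
  if (anyNA(lab) || !all(lab %in% c(0, 1)))
    stop("label must be binary 0 (encapsulated) / 1 (invasive)", call. = FALSE)
  df$label <- as.integer(lab)
  optional <- c("age", "symptoms", "myasthenia", "cystic_change",
                "calcification", "diameter", "log_volume",
                "surface_area_cm2", "sphericity", "discrete_compactness",
                "roundness")
  for (col in intersect(optional, names(df)))
    df[[col]] <- as.numeric(df[[col]])
  attr(df, "missing_optional") <- setdiff(optional, names(df))
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Write a shape-feature table
#'
#' One row per subject, full float precision, columns fixed as
#' `subject_id`, `n_voxels`, `volume_ml`, `log_volume`, `surface_area_cm2`,
#' `sphericity`, `discrete_compactness`, `roundness`.
#'
#' @param features data frame with a `subject_id` column plus the feature
#'   columns produced by [extract_features()]; may have zero rows.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_feature_table <- function(features, path) {
  cols <- c("subject_id", "n_voxels", "volume_ml", "log_volume",
            "surface_area_cm2", "sphericity", "discrete_compactness",
            "roundness")
  out <- features[, intersect(cols, names(features)), drop = FALSE]
  for (col in setdiff(cols, names(out))) out[[col]] <- numeric(nrow(out))
  out <- out[, cols, drop = FALSE]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(x) format(x, digits = 17, trim = TRUE))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a shape-feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return data frame with typed feature columns.
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$subject_id <- as.character(df$subject_id)
  df
}
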