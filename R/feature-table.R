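#' Per-recording feature table
#'
#' The unit all detectors consume: a numeric feature matrix with one row per
#' recording, together with recording metadata. Class labels follow the
#' 1 = healthy control (HC), 2 = Parkinson's disease (PD) convention.
#'
#' @param matrix numeric matrix, one row per recording, no missing values.
#'   Missingness is modeled by absent rows/tables, never by `NA` cells.
#' @param records data frame with columns `subject_id`, `recording_id`,
#'   `class` (integer, 1 = HC, 2 = PD), `gender` (`"male"`/`"female"`),
#'   `channel` (`"AC"`/`"SP"`) and `modality` (`"P"`, `"S"`, `"V"`, `"U"`).
#' @param feature_set name of the feature set the columns come from.
#' @param feature_names optional character vector of column names.
#' @return an object of class `feature_table`.
#' @export
feature_table <- function(matrix, records, feature_set = "features",
                          feature_names = colnames(matrix)) {
  matrix <- as.matrix(matrix)
  storage.mode(matrix) <- "double"
  if (is.null(feature_names)) {
    feature_names <- sprintf("f%04d", seq_len(ncol(matrix)))
  }
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("subject_id", "recording_id", "class", "gender",
                "channel", "modality")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0) {
    stop("records is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(matrix) != nrow(records)) {
    stop("matrix row count (", nrow(matrix), ") must equal record count (",
         nrow(records), ")")
  }
  if (ncol(matrix) < 1) stop("feature table needs at least one feature")
  if (anyNA(matrix) || any(!is.finite(matrix))) {
    stop("feature table must not contain missing or non-finite values")
  }
  if (!all(records$class %in% c(1L, 2L))) {
    stop("class labels must be 1 (HC) or 2 (PD)")
  }
  if (anyDuplicated(records$recording_id)) {
    stop("recording ids must be unique within a table")
  }
  per_subj <- unique(records[, c("subject_id", "class", "gender")])
  if (anyDuplicated(per_subj$subject_id)) {
    stop("class and gender must be constant within subject")
  }
  colnames(matrix) <- feature_names
  structure(
    list(matrix = matrix, records = records,
         feature_set = feature_set, feature_names = feature_names),
    class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf(
    "<feature_table> set '%s': %d recordings x %d features, %d subjects (%d HC / %d PD)\n",
    x$feature_set, nrow(x$matrix), ncol(x$matrix),
    length(unique(x$records$subject_id)),
    length(unique(x$records$subject_id[x$records$class == 1L])),
    length(unique(x$records$subject_id[x$records$class == 2L]))))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$matrix)

metadata_columns <- c("subject_id", "recording_id", "class", "gender",
                      "channel", "modality")

#' Write a feature table to delimited text
#'
#' Emits a CSV with the metadata columns (`subject_id`, `recording_id`,
#' `class`, `gender`, `channel`, `modality`) followed by the feature columns.
#'
#' @param table a [feature_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- cbind(table$records[, metadata_columns], as.data.frame(table$matrix))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV file path.
#' @param feature_set feature-set label; defaults to the file name stem.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, feature_set = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(feature_set)) {
    feature_set <- sub("\\.[^.]*$", "", basename(path))
  }
  records <- df[, metadata_columns]
  records$class <- as.integer(records$class)
  mat <- as.matrix(df[, setdiff(names(df), metadata_columns), drop = FALSE])
  feature_table(mat, records, feature_set = feature_set,
                feature_names = colnames(mat))
}
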