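#' Names of the 13 statistical functionals, in output order
#' @export
functional_names <- function() {
  c("min", "max", "mean", "median", "q_lo", "q_up", "trimean", "sd",
    "iqr", "lower_range", "upper_range", "skewness", "kurtosis")
}

#' Compress frame-based descriptor trajectories into 13 statistical functionals
#'
#' Maps each column (low-level descriptor trajectory) of a frame matrix to
#' 13 summary statistics: minimum, maximum, mean, median, lower quartile,
#' upper quartile, trimean `(2*median + Q_lo + Q_up) / 4`, standard
#' deviation, inter-quartile range, lower range `median - Q_lo`, upper range
#' `Q_up - median`, skewness and excess kurtosis. Quartiles use linear
#' interpolation of the empirical CDF (quantile type 7). Skewness and
#' kurtosis of a zero-variance column are defined as 0 so degenerate
#' trajectories do not propagate `NaN`s.
#'
#' @param frames numeric matrix (or data frame), one row per frame, one
#'   column per descriptor; at least one frame.
#' @return named numeric vector of length `13 * ncol(frames)`, ordered
#'   descriptor-major with names `"<descriptor>_<functional>"`.
#' @export
summarize_functionals <- function(frames) {
  frames <- as.matrix(frames)
  if (nrow(frames) < 1 || length(frames) == 0) {
    stop("frame matrix must contain at least one frame")
  }
  if (anyNA(frames)) stop("frame matrix must not contain missing values")
  if (is.null(colnames(frames))) {
    colnames(frames) <- sprintf("lld%03d", seq_len(ncol(frames)))
  }
  out <- vapply(seq_len(ncol(frames)), function(j) {
    column_functionals(frames[, j])
  }, numeric(13L))
  stats_names <- functional_names()
  names_out <- as.vector(outer(stats_names, colnames(frames),
                               function(s, d) paste(d, s, sep = "_")))
  out <- as.vector(out)
  names(out) <- names_out
  out
}

column_functionals <- function(x) {
  n <- length(x)
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  q_lo <- qs[1]; med <- qs[2]; q_up <- qs[3]
  m <- mean(x)
  sdev <- if (n > 1) stats::sd(x) else 0
  m2 <- mean((x - m)^2)
  if (m2 > 0) {
    skew <- mean((x - m)^3) / m2^1.5
    kurt <- mean((x - m)^4) / m2^2 - 3
  } else {
    skew <- 0
    kurt <- 0
  }
  c(min(x), max(x), m, med, q_lo, q_up,
    (2 * med + q_lo + q_up) / 4, sdev, q_up - q_lo,
    med - q_lo, q_up - med, skew, kurt)
}

#' Summarize a frame matrix stored as delimited text
#'
#' Reads a CSV of frame-based descriptors (one row per frame) and returns the
#' single summarized feature row, compatible with [feature_table()] columns.
#'
#' @param path CSV file of frames.
#' @return named numeric vector as from [summarize_functionals()].
#' @export
summarize_frames_file <- function(path) {
  frames <- utils::read.csv(path, stringsAsFactors = FALSE)
  summarize_functionals(as.matrix(frames))
}
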