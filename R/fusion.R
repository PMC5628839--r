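#' Construct a score table (helper for assembling fusion inputs)
#'
#' Wraps per-recording scores with their metadata into the `score_table`
#' shape produced by [oob_scores()], e.g. when reading scores back from CSV.
#'
#' @param records recording metadata (see [feature_table()]).
#' @param d numeric OOB score differences in `[-1, 1]`.
#' @param b OOB multiplicities.
#' @param feature_set feature-set label carried as an attribute.
#' @return a `score_table` data frame.
#' @export
score_table <- function(records, d, b = rep(1L, length(d)),
                        feature_set = "features") {
  stopifnot(nrow(records) == length(d), length(d) == length(b))
  if (any(d[!is.na(d)] < -1 | d[!is.na(d)] > 1)) {
    stop("scores d must lie in [-1, 1]")
  }
  out <- cbind(records[, c("recording_id", "subject_id", "class", "gender",
                           "channel", "modality")],
               data.frame(d = d, b = b))
  class(out) <- c("score_table", "data.frame")
  attr(out, "feature_set") <- feature_set
  out
}

#' Assemble base-detector scores into a meta-feature table
#'
#' Decision-level stacking input: one column per (feature set, modality)
#' score table, restricted to the requested modality combination. Only
#' subjects present (with defined scores) in every fused table are kept;
#' dropped subjects are reported. When phonation (`P`) is part of the
#' combination, the fusion unit is the phonation recording and the
#' subject-level speech/voiced/unvoiced scores are broadcast to each of the
#' subject's phonation recordings; otherwise there is one row per
#' subject-level recording.
#'
#' @param score_tables list of `score_table`s (each carrying its
#'   `feature_set` attribute and a single modality).
#' @param combo character vector of modalities to fuse, e.g. `c("P", "S")`.
#' @return object of class `meta_feature_table` with fields `records`,
#'   `matrix` (columns named `<set>.<modality>`) and `combo`.
#' @export
assemble_meta <- function(score_tables, combo) {
  combo <- intersect(c("P", "S", "V", "U"), combo)
  if (length(combo) == 0) stop("combo must name at least one modality")
  keys <- vapply(score_tables, function(s) {
    mods <- unique(s$modality)
    if (length(mods) != 1) stop("each score table must hold one modality")
    paste(attr(s, "feature_set"), mods, sep = ".")
  }, character(1))
  names(score_tables) <- keys
  mods <- sub("^.*\\.", "", keys)
  used <- score_tables[mods %in% combo]
  if (length(used) == 0) stop("no score tables for the requested modalities")
  missing_mod <- setdiff(combo, sub("^.*\\.", "", names(used)))
  if (length(missing_mod) > 0) {
    stop("no base scores for modality/modalities: ",
         paste(missing_mod, collapse = ", "))
  }

  defined_subjects <- lapply(used, function(s) unique(s$subject_id[!is.na(s$d)]))
  keep <- Reduce(intersect, defined_subjects)
  if (length(keep) == 0) stop("no subject is present in all fused modalities")
  all_subj <- unique(unlist(lapply(used, function(s) s$subject_id)))
  dropped <- setdiff(all_subj, keep)
  if (length(dropped) > 0) {
    message(length(dropped),
            " subject(s) dropped from fusion (missing a fused modality): ",
            paste(dropped, collapse = ", "))
  }

  # anchor rows: phonation recordings if P fused, else the (single)
  # recordings of the first fused modality
  anchor_mod <- if ("P" %in% combo) "P" else combo[1]
  anchor <- used[[which(sub("^.*\\.", "", names(used)) == anchor_mod)[1]]]
  anchor <- anchor[anchor$subject_id %in% keep & !is.na(anchor$d), ]
  records <- anchor[, c("recording_id", "subject_id", "class", "gender",
                        "channel", "modality")]

  cols <- lapply(names(used), function(key) {
    s <- used[[key]]
    mod <- unique(s$modality)
    if (mod == anchor_mod) {
      s$d[match(records$recording_id, s$recording_id)]
    } else if (mod == "P") {
      stop("phonation tables cannot be broadcast onto another anchor")
    } else {
      per_subject <- s$d[match(records$subject_id, s$subject_id)]
      per_subject
    }
  })
  mat <- do.call(cbind, cols)
  colnames(mat) <- names(used)
  if (anyNA(mat)) stop("undefined OOB scores remain after subject filtering")
  structure(list(records = records, matrix = mat,
                 combo = paste(combo, collapse = "+"),
                 column_keys = names(used)),
            class = "meta_feature_table")
}

#' @export
print.meta_feature_table <- function(x, ...) {
  cat(sprintf("<meta_feature_table> combo %s: %d rows x %d score columns, %d subjects\n",
              x$combo, nrow(x$matrix), ncol(x$matrix),
              length(unique(x$records$subject_id))))
  invisible(x)
}

#' Convert a meta-feature table to a feature table for the meta-forest
#'
#' @param meta an [assemble_meta()] result.
#' @return a [feature_table()] whose features are the base-detector scores.
#' @export
as_feature_table <- function(meta) {
  stopifnot(inherits(meta, "meta_feature_table"))
  feature_table(meta$matrix, meta$records, feature_set = meta$combo,
                feature_names = colnames(meta$matrix))
}

#' Fit the stacking meta-forest with repetitions
#'
#' Trains a grouped-OOB meta random forest on the concatenated base scores,
#' repeating the fit `R` times with fresh seeds (the base scores stay
#' fixed; only the meta-forest is re-randomized) to estimate the mean and
#' standard deviation of the fused EER and minimum Cllr.
#'
#' @param meta an [assemble_meta()] result.
#' @param config a [forest_config()]; repetition `r` uses seed
#'   `config$seed + r - 1`.
#' @param R number of repetitions (the study-scale protocol uses 99).
#' @return object of class `fusion_result`: per-repetition metrics, their
#'   mean/sd (sd `NA` for `R = 1`) and the detector of the first repetition
#'   (used downstream for the proximity matrix).
#' @export
fuse <- function(meta, config = forest_config(), R = 99L) {
  stopifnot(inherits(meta, "meta_feature_table"), R >= 1)
  tbl <- as_feature_table(meta)
  reps <- vector("list", R)
  first <- NULL
  for (r in seq_len(R)) {
    cfg <- config
    cfg$seed <- config$seed + r - 1L
    det <- fit_detector(tbl, cfg)
    sc <- as_detection_scores(det$scores)
    reps[[r]] <- data.frame(rep = r, seed = cfg$seed, q = det$q,
                            cllr = min_cllr(sc), eer = eer(sc))
    if (r == 1) first <- det
  }
  reps <- do.call(rbind, reps)
  structure(list(
    combo = meta$combo, R = R, reps = reps,
    mean_cllr = mean(reps$cllr),
    sd_cllr = if (R >= 2) stats::sd(reps$cllr) else NA_real_,
    mean_eer = mean(reps$eer),
    sd_eer = if (R >= 2) stats::sd(reps$eer) else NA_real_,
    detector = first),
    class = "fusion_result")
}

#' @export
print.fusion_result <- function(x, ...) {
  cat(sprintf("<fusion_result> %s over %d repetition(s): Cllr %.3f (%s), EER %.2f%% (%s)\n",
              x$combo, x$R, x$mean_cllr,
              if (is.na(x$sd_cllr)) "-" else sprintf("%.3f", x$sd_cllr),
              x$mean_eer,
              if (is.na(x$sd_eer)) "-" else sprintf("%.2f", x$sd_eer)))
  invisible(x)
}
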