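#' The ten modality combinations of the fusion experiment
#'
#' Four unimodal and six multimodal decision-level fusions.
#' @return list of character vectors.
#' @export
fusion_combos <- function() {
  list(c("P"), c("S"), c("V"), c("U"),
       c("P", "S"), c("S", "V"), c("S", "U"), c("V", "U"),
       c("S", "V", "U"), c("P", "S", "V", "U"))
}

#' Fit a grouped-OOB detector on every individual feature table
#'
#' The per-table experiment: for each (channel, modality, feature set)
#' table, fits [fit_detector()] and records the out-of-bag minimum Cllr and
#' EER, flagging the best feature set per channel-by-modality column by each
#' metric. Deterministic given the seed: table `i` (in sorted name order)
#' uses seed `config$seed + i`.
#'
#' @param tables named list of [feature_table()]s (e.g. from
#'   [simulate_cohort()] or read from CSV).
#' @param config a [forest_config()].
#' @return list with `metrics` (one row per table: `feature_set`, `channel`,
#'   `modality`, `q`, `cllr`, `eer`, best-in-column flags) and `scores`
#'   (the per-table OOB `score_table`s, input to [run_fusion()]).
#' @export
run_individual <- function(tables, config = forest_config()) {
  keys <- sort(names(tables))
  rows <- vector("list", length(keys))
  scores <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    tbl <- tables[[keys[i]]]
    cfg <- config
    cfg$seed <- config$seed + i
    det <- fit_detector(tbl, cfg)
    sc <- suppressWarnings(as_detection_scores(det$scores))
    rows[[i]] <- data.frame(
      table = keys[i], feature_set = tbl$feature_set,
      channel = tbl$records$channel[1], modality = tbl$records$modality[1],
      q = det$q, cllr = min_cllr(sc), eer = eer(sc),
      stringsAsFactors = FALSE)
    scores[[i]] <- det$scores
  }
  metrics <- do.call(rbind, rows)
  col_key <- paste(metrics$channel, metrics$modality)
  metrics$best_cllr <- stats::ave(metrics$cllr, col_key,
                                  FUN = function(v) v == min(v)) == 1
  metrics$best_eer <- stats::ave(metrics$eer, col_key,
                                 FUN = function(v) v == min(v)) == 1
  names(scores) <- keys
  list(metrics = metrics, scores = scores)
}

#' Run the decision-level fusion experiment
#'
#' For every channel present in the base scores and every requested modality
#' combination, assembles the meta-feature table and fits the repeated
#' meta-forest, reporting mean (sd) Cllr and EER over `R` repetitions.
#'
#' @param scores named list of `score_table`s from [run_individual()]
#'   (names `<channel>_<modality>_<set>`).
#' @param config a [forest_config()] for the meta-forests.
#' @param R repetitions per combination (study-scale protocol: 99).
#' @param combos list of modality combinations; defaults to the ten
#'   standard ones from [fusion_combos()].
#' @return data frame with one row per channel and combination: mean/sd
#'   Cllr and EER, subject count and the combination label.
#' @export
run_fusion <- function(scores, config = forest_config(), R = 9L,
                       combos = fusion_combos()) {
  channels <- unique(vapply(scores, function(s) s$channel[1], character(1)))
  out <- list()
  for (ch in sort(channels)) {
    ch_scores <- Filter(function(s) s$channel[1] == ch, scores)
    for (combo in combos) {
      meta <- suppressMessages(assemble_meta(ch_scores, combo))
      res <- fuse(meta, config, R = R)
      out[[length(out) + 1]] <- data.frame(
        channel = ch, combo = res$combo,
        n_subjects = length(unique(meta$records$subject_id)),
        n_meta_features = ncol(meta$matrix), R = R,
        mean_cllr = res$mean_cllr, sd_cllr = res$sd_cllr,
        mean_eer = res$mean_eer, sd_eer = res$sd_eer,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
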