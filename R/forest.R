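#' Random-forest configuration
#'
#' @param B number of trees (the study-scale value is 5000; desk-scale runs
#'   use 500).
#' @param q_candidates per-node candidate-feature counts to try; `NULL`
#'   selects the default grid `{floor(sqrt(p)), floor(2*sqrt(p)),
#'   floor(p/2)}` at fit time.
#' @param min_leaf minimum leaf size; trees are unpruned (1).
#' @param seed master seed; per-tree generators are derived by the counter
#'   scheme `seed * 1e6 + q_index * 1e5 + tree_index`, so any tree is
#'   reproducible in isolation.
#' @return a `forest_config` object.
#' @export
forest_config <- function(B = 5000L, q_candidates = NULL, min_leaf = 1L,
                          seed = 1L) {
  if (B < 1) stop("B must be >= 1")
  if (!is.null(q_candidates) && any(q_candidates < 1)) {
    stop("every q must be >= 1")
  }
  structure(list(B = as.integer(B), q_candidates = q_candidates,
                 min_leaf = as.integer(min_leaf), seed = as.integer(seed)),
            class = "forest_config")
}

default_q_grid <- function(p) {
  q <- unique(pmin(pmax(c(floor(sqrt(p)), floor(2 * sqrt(p)), floor(p / 2)),
                        1L), p))
  sort(as.integer(q))
}

#' Draw a subject-grouped, stratified bootstrap plan
#'
#' For every tree, independently within each class-by-gender stratum, draws
#' with replacement as many sampling units as the stratum contains, so each
#' bootstrap sample preserves the class and gender balance of the full
#' dataset exactly. With `unit = "subject"` (the grouped scheme) the unit is
#' the subject: all recordings of a subject are jointly in-bag or
#' out-of-bag, which prevents pathology detection from degenerating into
#' speaker identification when subjects contribute repeated recordings.
#' `unit = "recording"` is the naive per-recording bootstrap, provided only
#' to demonstrate the leakage bias it induces.
#'
#' @param records recording metadata (the `records` of a [feature_table()]).
#' @param B number of trees.
#' @param seed integer seed; the plan is deterministic given the seed.
#' @param unit bootstrap unit, `"subject"` (grouped) or `"recording"`.
#' @return a `bootstrap_plan`: the sampling units with their strata, an
#'   in-bag count matrix (units x trees) and the out-of-bag indicator.
#' @export
draw_plan <- function(records, B = 5000L, seed = 1L,
                      unit = c("subject", "recording")) {
  unit <- match.arg(unit)
  if (nrow(records) == 0) stop("no recordings")
  if (unit == "subject") {
    groups <- unique(records[, c("subject_id", "class", "gender")])
    group_id <- groups$subject_id
  } else {
    groups <- records[, c("recording_id", "class", "gender")]
    group_id <- groups$recording_id
  }
  n_g <- nrow(groups)
  stratum <- interaction(groups$class, groups$gender, drop = TRUE)
  singletons <- names(which(table(stratum) == 1L))
  if (length(singletons) > 0) {
    warning("stratum/strata with a single unit (always in-bag, never OOB): ",
            paste(singletons, collapse = ", "))
  }
  counts <- matrix(0L, nrow = n_g, ncol = B)
  set.seed(seed)
  for (lev in levels(stratum)) {
    idx <- which(stratum == lev)
    S <- length(idx)
    draws <- matrix(idx[sample.int(S, S * B, replace = TRUE)], nrow = S)
    for (b in seq_len(B)) {
      tab <- tabulate(draws[, b], nbins = n_g)
      counts[idx, b] <- counts[idx, b] + tab[idx]
    }
  }
  structure(list(group_id = group_id, class = groups$class,
                 gender = groups$gender, counts = counts, B = B,
                 unit = unit, seed = as.integer(seed)),
            class = "bootstrap_plan")
}

# map each recording row to its sampling-unit index in the plan
plan_row_groups <- function(plan, records) {
  key <- if (plan$unit == "subject") records$subject_id else records$recording_id
  idx <- match(key, plan$group_id)
  if (anyNA(idx)) stop("records contain units absent from the plan")
  idx
}

#' In-bag recording rows for one tree
#'
#' Expands the plan's unit multiset into recording row indices: a unit drawn
#' `k` times contributes every one of its recordings `k` times.
#'
#' @param plan a [draw_plan()] result.
#' @param records recording metadata aligned with the table rows.
#' @param tree tree index in `1:B`.
#' @return integer vector of (possibly repeated) row indices.
#' @export
inbag_rows <- function(plan, records, tree) {
  g <- plan_row_groups(plan, records)
  mult <- plan$counts[g, tree]
  rep(seq_along(g), times = mult)
}

# n_recordings x B logical matrix: TRUE where the recording is OOB
oob_mask <- function(plan, records) {
  g <- plan_row_groups(plan, records)
  plan$counts[g, , drop = FALSE] == 0L
}

#' Grow a grouped-bootstrap random forest
#'
#' Grows `B` unpruned CART trees on the per-tree in-bag recording multisets
#' of a bootstrap plan. At every node, `q` candidate features are freshly
#' sampled and the best Gini-impurity binary split among them is taken;
#' nodes are split until pure or unsplittable. Leaves store the in-bag
#' class counts `n(t, ., c)` from which leaf class frequencies (and hence
#' all scores) are computed.
#'
#' @param table a [feature_table()].
#' @param plan a [draw_plan()] for the same records.
#' @param q per-node candidate feature count, `1 <= q <= p`.
#' @param seed base seed for the per-tree generators.
#' @return object of class `grouped_rf`.
#' @export
grow_forest <- function(table, plan, q, seed = plan$seed) {
  stopifnot(inherits(table, "feature_table"), inherits(plan, "bootstrap_plan"))
  p <- ncol(table$matrix)
  if (q < 1 || q > p) stop("q must be in [1, p]")
  B <- plan$B
  inbag <- lapply(seq_len(B), function(b) inbag_rows(plan, table$records, b))
  if (any(vapply(inbag, length, integer(1)) == 0)) {
    stop("a tree has an empty in-bag sample")
  }
  seeds <- as.numeric(seed) * 1e6 + seq_len(B)
  trees <- cpp_grow_forest(table$matrix, as.integer(table$records$class),
                           inbag, as.integer(q), seeds)
  structure(list(trees = trees, plan = plan, q = as.integer(q),
                 seed = seed, feature_names = table$feature_names,
                 feature_set = table$feature_set),
            class = "grouped_rf")
}

#' @export
print.grouped_rf <- function(x, ...) {
  cat(sprintf("<grouped_rf> %d trees, q = %d, %s-level bootstrap\n",
              length(x$trees), x$q, x$plan$unit))
  invisible(x)
}

#' Leaf class frequencies for a recording
#'
#' `f(t, x, c) = n(t, x, c) / sum_j n(t, x, c_j)` for the leaf that `x`
#' falls into in each tree; the frequencies of the two classes sum to 1 at
#' every leaf.
#'
#' @param forest a [grow_forest()] result.
#' @param x numeric feature vector (length p) or matrix of rows.
#' @return matrix with one row per input recording and one column per tree,
#'   holding the PD (class 2) leaf frequency; the HC frequency is its
#'   complement.
#' @export
leaf_frequency <- function(forest, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  cpp_leaf_freq2(forest$trees, as.matrix(x))
}

#' Out-of-bag score table
#'
#' For each recording, averages the leaf class-frequency difference over the
#' trees for which the recording is out-of-bag:
#' `d = mean_t f(t, x, PD) - mean_t f(t, x, HC)`, a soft score in
#' `[-1, 1]` (equivalently `2 * mean OOB PD-frequency - 1`). Recordings that
#' are never out-of-bag get `d = NA` with a warning.
#'
#' @param forest a [grow_forest()] result.
#' @param table the [feature_table()] the forest was grown on.
#' @return a `score_table` data frame: recording metadata plus the score `d`
#'   and the OOB multiplicity `b`.
#' @export
oob_scores <- function(forest, table) {
  stopifnot(inherits(forest, "grouped_rf"))
  f2 <- cpp_leaf_freq2(forest$trees, table$matrix)
  m <- oob_mask(forest$plan, table$records)
  b <- rowSums(m)
  d <- ifelse(b > 0, rowSums((2 * f2 - 1) * m) / pmax(b, 1), NA_real_)
  if (any(b == 0)) {
    warning(sum(b == 0), " recording(s) never out-of-bag; score undefined")
  }
  out <- cbind(table$records[, c("recording_id", "subject_id", "class",
                                 "gender", "channel", "modality")],
               data.frame(d = d, b = b))
  class(out) <- c("score_table", "data.frame")
  attr(out, "feature_set") <- table$feature_set
  out
}

#' Fit the grouped-OOB detector with selection of q
#'
#' Draws one grouped bootstrap plan, grows one forest per candidate `q`,
#' scores each by its out-of-bag minimum Cllr, and keeps the forest with the
#' lowest Cllr (ties broken by the smallest `q`).
#'
#' @param table a [feature_table()].
#' @param config a [forest_config()].
#' @param unit bootstrap unit (see [draw_plan()]); `"subject"` for the
#'   grouped scheme.
#' @return object of class `pd_detector`: the selected `forest`, its
#'   `plan`, OOB `scores`, chosen `q` and the per-q Cllr grid.
#' @export
fit_detector <- function(table, config = forest_config(),
                         unit = c("subject", "recording")) {
  unit <- match.arg(unit)
  q_grid <- config$q_candidates
  p <- ncol(table$matrix)
  if (is.null(q_grid)) q_grid <- default_q_grid(p)
  if (any(q_grid > p)) stop("q candidates must not exceed p = ", p)
  q_grid <- sort(unique(as.integer(q_grid)))
  plan <- draw_plan(table$records, B = config$B, seed = config$seed,
                    unit = unit)
  fits <- vector("list", length(q_grid))
  cllrs <- numeric(length(q_grid))
  for (i in seq_along(q_grid)) {
    forest <- grow_forest(table, plan, q_grid[i],
                          seed = config$seed * 100 + i)
    scores <- oob_scores(forest, table)
    if (all(is.na(scores$d))) stop("all OOB scores undefined")
    cllrs[i] <- min_cllr(as_detection_scores(scores))
    fits[[i]] <- list(forest = forest, scores = scores)
  }
  best <- which.min(cllrs) # ties: first (smallest q)
  structure(list(forest = fits[[best]]$forest, plan = plan,
                 scores = fits[[best]]$scores, q = q_grid[best],
                 per_q = data.frame(q = q_grid, cllr = cllrs),
                 config = config, unit = unit,
                 feature_set = table$feature_set),
            class = "pd_detector")
}

#' @export
print.pd_detector <- function(x, ...) {
  sc <- as_detection_scores(suppressWarnings(x$scores))
  cat(sprintf(
    "<pd_detector> set '%s': B = %d, chosen q = %d, OOB EER = %.2f%%, min Cllr = %.3f\n",
    x$feature_set, x$config$B, x$q, eer(sc), min_cllr(sc)))
  invisible(x)
}

#' Permutation variable importance (mean decrease in OOB accuracy)
#'
#' For each feature and tree, permutes the feature's values among that
#' tree's out-of-bag recordings, re-classifies them (hard vote: the sign of
#' the leaf class-frequency difference) and reports the mean drop in OOB
#' accuracy across trees. Irrelevant features score near zero; the
#' informative features of the synthetic generator should rank above noise.
#'
#' @param detector a [fit_detector()] result (or pass `forest` + `table`).
#' @param table the feature table the forest was grown on.
#' @param seed seed for the permutations (reproducible).
#' @return data frame with `feature` and `importance`, in column order.
#' @export
permutation_importance <- function(detector, table, seed = 1L) {
  forest <- if (inherits(detector, "pd_detector")) detector$forest else detector
  stopifnot(inherits(forest, "grouped_rf"))
  m <- oob_mask(forest$plan, table$records)
  oob <- lapply(seq_len(ncol(m)), function(b) which(m[, b]))
  seeds <- as.numeric(seed) * 1e6 + seq_along(oob)
  imp <- cpp_perm_importance(forest$trees, table$matrix,
                             as.integer(table$records$class), oob, seeds)
  data.frame(feature = table$feature_names, importance = imp)
}

#' Write an OOB score table and its JSON sidecar
#'
#' The CSV holds the recording metadata plus the score `d` and OOB
#' multiplicity `b`; the sidecar records the feature set, chosen q, B, seed
#' and the per-q Cllr grid.
#'
#' @param detector a [fit_detector()] result (or a bare `score_table`, in
#'   which case no sidecar fields beyond the feature set are available).
#' @param path CSV output path; the sidecar is `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_scores <- function(detector, path) {
  if (inherits(detector, "pd_detector")) {
    scores <- detector$scores
    sidecar <- list(feature_set = attr(scores, "feature_set"),
                    q = detector$q, B = detector$config$B,
                    seed = detector$config$seed,
                    per_q_cllr = detector$per_q)
  } else {
    stopifnot(inherits(detector, "score_table"))
    scores <- detector
    sidecar <- list(feature_set = attr(scores, "feature_set"))
  }
  utils::write.csv(as.data.frame(scores), path, row.names = FALSE)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an OOB score table written by [write_scores()]
#'
#' Restores the `score_table` (and its feature-set attribute from the JSON
#' sidecar when present), ready for [as_detection_scores()] or
#' [assemble_meta()].
#'
#' @param path CSV file path.
#' @param feature_set feature-set label; defaults to the sidecar's value,
#'   falling back to the file name stem.
#' @return a `score_table` data frame.
#' @export
read_scores <- function(path, feature_set = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(feature_set)) {
    sidecar <- paste0(path, ".json")
    feature_set <- if (file.exists(sidecar)) {
      jsonlite::read_json(sidecar)$feature_set
    }
    if (is.null(feature_set)) feature_set <- sub("\\.[^.]*$", "", basename(path))
  }
  df$class <- as.integer(df$class)
  score_table(df[, metadata_columns],
              d = ifelse(df$b > 0, df$d, NA_real_), b = df$b,
              feature_set = feature_set)
}
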