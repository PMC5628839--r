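#' Pools of target and non-target detection scores
#'
#' The detection metrics operate on two score pools: `tar` holds scores of
#' PD (target) recordings, `non` of HC (non-target) recordings. Higher
#' scores must indicate stronger support for PD.
#'
#' @param tar numeric vector of target (PD) scores.
#' @param non numeric vector of non-target (HC) scores.
#' @return object of class `detection_scores`.
#' @export
detection_scores <- function(tar, non) {
  tar <- as.numeric(tar)
  non <- as.numeric(non)
  if (length(tar) == 0 || length(non) == 0) {
    stop("both target and non-target score pools must be nonempty")
  }
  if (anyNA(tar) || anyNA(non) || any(!is.finite(c(tar, non)))) {
    stop("scores must be finite")
  }
  structure(list(tar = tar, non = non), class = "detection_scores")
}

#' Extract detection score pools from an out-of-bag score table
#'
#' Drops recordings whose score is undefined (never out-of-bag) with a
#' warning.
#'
#' @param x a `score_table` as produced by [oob_scores()].
#' @return a [detection_scores()] object.
#' @export
as_detection_scores <- function(x) {
  stopifnot(inherits(x, "score_table"))
  undef <- is.na(x$d)
  if (any(undef)) {
    warning(sum(undef), " recording(s) with undefined OOB score dropped")
    x <- x[!undef, ]
  }
  detection_scores(tar = x$d[x$class == 2L], non = x$d[x$class == 1L])
}

# Empirical ROC operating points for the rule "accept PD iff score >= t",
# over all distinct thresholds plus the two trivial rules.
# Returns a data.frame with columns p_miss, p_fa.
roc_points <- function(scores) {
  th <- sort(unique(c(scores$tar, scores$non)))
  n_tar <- length(scores$tar)
  n_non <- length(scores$non)
  p_fa <- vapply(th, function(t) sum(scores$non >= t) / n_non, numeric(1))
  p_miss <- vapply(th, function(t) sum(scores$tar < t) / n_tar, numeric(1))
  data.frame(p_miss = c(0, p_miss, 1), p_fa = c(1, p_fa, 0))
}

#' ROC convex hull of a score set
#'
#' Computes the empirical ROC over all score thresholds and returns the
#' vertices of its convex hull, ordered from (`p_miss` = 0, `p_fa` = 1) to
#' (`p_miss` = 1, `p_fa` = 0). The hull is the basis for the equal error
#' rate and equals the operating points reachable by thresholding the
#' PAV-calibrated scores.
#'
#' @param scores a [detection_scores()] object.
#' @return data frame of hull vertices (`p_miss`, `p_fa`), class
#'   `rocch_curve`.
#' @export
rocch <- function(scores) {
  stopifnot(inherits(scores, "detection_scores"))
  pts <- roc_points(scores)
  # work in ROC space: x = p_fa, y = 1 - p_miss; keep the upper hull
  x <- pts$p_fa
  y <- 1 - pts$p_miss
  ord <- order(x, y)
  x <- x[ord]; y <- y[ord]
  hx <- numeric(0); hy <- numeric(0)
  cross <- function(ox, oy, ax, ay, bx, by) {
    (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  }
  for (i in seq_along(x)) {
    while (length(hx) >= 2 &&
           cross(hx[length(hx) - 1], hy[length(hy) - 1],
                 hx[length(hx)], hy[length(hy)], x[i], y[i]) >= 0) {
      hx <- hx[-length(hx)]; hy <- hy[-length(hy)]
    }
    hx <- c(hx, x[i]); hy <- c(hy, y[i])
  }
  out <- data.frame(p_miss = rev(1 - hy), p_fa = rev(hx))
  class(out) <- c("rocch_curve", "data.frame")
  out
}

#' Equal error rate from the ROC convex hull
#'
#' The operating point where the convexified DET curve crosses the diagonal
#' (`p_miss` = `p_fa`), with linear interpolation inside the crossing
#' segment. 50% marks a useless detector.
#'
#' @param scores a [detection_scores()] object.
#' @return EER in percent.
#' @export
eer <- function(scores) {
  hull <- rocch(scores)
  g <- hull$p_miss - hull$p_fa # increases from -1 to +1 along the hull
  k <- max(which(g <= 0))
  if (g[k] == 0) return(100 * hull$p_miss[k])
  t <- -g[k] / (g[k + 1] - g[k])
  100 * (hull$p_miss[k] + t * (hull$p_miss[k + 1] - hull$p_miss[k]))
}

# Weighted PAV over score-tied blocks. Returns per-block target/non-target
# counts in score-ascending order after pooling adjacent violators of
# monotonicity in the target fraction. Integer arithmetic keeps the
# violation test exact.
pav_blocks <- function(scores) {
  s <- c(scores$non, scores$tar)
  z <- c(rep(0L, length(scores$non)), rep(1L, length(scores$tar)))
  ord <- order(s)
  s <- s[ord]; z <- z[ord]
  uniq <- !duplicated(s)
  grp <- cumsum(uniq)
  t_cnt <- as.numeric(tapply(z, grp, sum))
  n_cnt <- as.numeric(tapply(1 - z, grp, sum))
  scr <- s[uniq]
  # stack-based pooling: fraction t/(t+n) must be nondecreasing in score
  Tb <- numeric(0); Nb <- numeric(0); lo <- numeric(0); hi <- numeric(0)
  for (i in seq_along(t_cnt)) {
    Tb <- c(Tb, t_cnt[i]); Nb <- c(Nb, n_cnt[i])
    lo <- c(lo, scr[i]); hi <- c(hi, scr[i])
    k <- length(Tb)
    while (k > 1 &&
           Tb[k - 1] * (Tb[k] + Nb[k]) >= Tb[k] * (Tb[k - 1] + Nb[k - 1])) {
      Tb[k - 1] <- Tb[k - 1] + Tb[k]
      Nb[k - 1] <- Nb[k - 1] + Nb[k]
      hi[k - 1] <- hi[k]
      Tb <- Tb[-k]; Nb <- Nb[-k]; lo <- lo[-k]; hi <- hi[-k]
      k <- k - 1
    }
  }
  data.frame(tar = Tb, non = Nb, score_lo = lo, score_hi = hi)
}

#' Minimum cost of the log-likelihood ratio (Cllr), in bits
#'
#' `Cllr = 1/(2 N_tar) * sum_tar log2(1 + 1/LR) +
#'         1/(2 N_non) * sum_non log2(1 + LR)`,
#' minimized over all monotone score-to-LLR mappings. The minimizer is the
#' PAV (isotonic) calibration of the ideal posteriors; tied scores are
#' merged into weighted blocks so equal scores receive equal LLRs. Blocks
#' containing a single class are allowed the limiting LLR of plus/minus
#' infinity, whose cost contribution is 0; consequently perfect separation
#' yields 0 and an uninformative (all-equal) score set yields exactly 1.
#' A useful, well-calibrated detector has `Cllr < 1`.
#'
#' @param scores a [detection_scores()] object.
#' @return minimum Cllr in bits.
#' @export
min_cllr <- function(scores) {
  stopifnot(inherits(scores, "detection_scores"))
  blocks <- pav_blocks(scores)
  n_tar <- length(scores$tar)
  n_non <- length(scores$non)
  total <- 0
  for (i in seq_len(nrow(blocks))) {
    a <- blocks$tar[i]; b <- blocks$non[i]
    if (a > 0 && b > 0) {
      llr <- log(a / n_tar) - log(b / n_non) # optimal LLR for the block
      total <- total + a / (2 * n_tar) * log2(1 + exp(-llr)) +
        b / (2 * n_non) * log2(1 + exp(llr))
    }
    # pure blocks: LLR -> +-Inf, cost contribution -> 0
  }
  total
}

#' Cost of the log-likelihood ratio for given LLRs (bits)
#'
#' Evaluates Cllr for an explicit calibration: natural-log LLRs of the
#' target and non-target trials. Used to verify that no fixed monotone
#' calibration beats [min_cllr()].
#'
#' @param tar_llr natural-log LLRs of target trials.
#' @param non_llr natural-log LLRs of non-target trials.
#' @return Cllr in bits.
#' @export
cllr <- function(tar_llr, non_llr) {
  mean(log2(1 + exp(-tar_llr))) / 2 + mean(log2(1 + exp(non_llr))) / 2
}

#' Optimal PAV score-to-LLR calibration
#'
#' Returns the monotone LLR (natural log) assigned to each input score by
#' the PAV calibration underlying [min_cllr()]. Infinite block LLRs are
#' clamped to `llr_cap` for reporting.
#'
#' @param scores a [detection_scores()] object.
#' @param llr_cap magnitude used in place of infinite LLRs of pure blocks.
#' @return list with `tar_llr` and `non_llr` aligned with the input pools.
#' @export
pav_llrs <- function(scores, llr_cap = 40) {
  blocks <- pav_blocks(scores)
  n_tar <- length(scores$tar)
  n_non <- length(scores$non)
  block_llr <- ifelse(
    blocks$tar == 0, -llr_cap,
    ifelse(blocks$non == 0, llr_cap,
           log(blocks$tar / n_tar) - log(blocks$non / n_non)))
  assign_llr <- function(s) {
    idx <- vapply(s, function(v) {
      which(v >= blocks$score_lo & v <= blocks$score_hi)[1]
    }, integer(1))
    block_llr[idx]
  }
  list(tar_llr = assign_llr(scores$tar), non_llr = assign_llr(scores$non))
}

#' Summarize a score table's detection performance as JSON
#'
#' Computes the ROCCH equal error rate and the minimum Cllr of an OOB score
#' table and writes `{"eer_percent": ..., "min_cllr_bits": ...}`, with the
#' DET coordinates in an optional side CSV.
#'
#' @param scores a `score_table` (see [oob_scores()], [read_scores()]) or a
#'   [detection_scores()] object.
#' @param path JSON output path.
#' @param det_path optional CSV path for the DET-curve coordinates.
#' @return the metric list, invisibly.
#' @export
write_metrics <- function(scores, path, det_path = NULL) {
  if (inherits(scores, "score_table")) {
    scores <- suppressWarnings(as_detection_scores(scores))
  }
  stopifnot(inherits(scores, "detection_scores"))
  metrics <- list(eer_percent = eer(scores), min_cllr_bits = min_cllr(scores))
  jsonlite::write_json(metrics, path, auto_unbox = TRUE, digits = NA)
  if (!is.null(det_path)) {
    utils::write.csv(det_points(scores), det_path, row.names = FALSE)
  }
  invisible(metrics)
}

#' DET-curve coordinates on probit axes
#'
#' Maps the ROC convex hull vertices through the standard-normal quantile
#' function, yielding the coordinates of the detection error trade-off
#' curve. Probabilities of exactly 0 or 1 are clipped to `eps` / `1 - eps`
#' before the probit transform.
#'
#' @param scores a [detection_scores()] object.
#' @param eps clipping bound applied before `qnorm`.
#' @return data frame with `probit_fa`, `probit_miss` and the underlying
#'   `p_miss`, `p_fa` vertices.
#' @export
det_points <- function(scores, eps = 1e-6) {
  hull <- rocch(scores)
  clip <- function(p) pmin(pmax(p, eps), 1 - eps)
  data.frame(probit_fa = stats::qnorm(clip(hull$p_fa)),
             probit_miss = stats::qnorm(clip(hull$p_miss)),
             p_miss = hull$p_miss, p_fa = hull$p_fa)
}
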