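# Independent brute-force oracles and small fixture builders.

# Single-table synthetic cohort (one channel, phonation only by default).
make_table <- function(n_subjects = 40, delta = 1, sigma_s = 1, sigma_e = 1,
                       reps = 3L, p = 30L, n_informative = 10L, seed = 1L,
                       prop_pd = 0.5, prop_female = 0.5) {
  cfg <- simulation_config(
    n_subjects = n_subjects, prop_pd = prop_pd, prop_female = prop_female,
    recordings_per_modality = c(P = reps),
    feature_set_sizes = c(acoustic = p), n_informative = n_informative,
    class_effect = delta, subject_sd = sigma_s, noise_sd = sigma_e,
    channels = "AC", seed = seed)
  simulate_cohort(cfg)[[1]]
}

# Brute-force ROCCH EER: threshold sweep, convexification via chull(),
# then exhaustive search of the diagonal crossing over hull edges.
oracle_eer <- function(tar, non) {
  th <- sort(unique(c(tar, non)))
  pf <- vapply(th, function(t) mean(non >= t), numeric(1))
  pm <- vapply(th, function(t) mean(tar < t), numeric(1))
  x <- c(0, pf, 1, 1)         # ROC x = P_fa, plus corners (0,0), (1,1), (1,0)
  y <- c(0, 1 - pm, 1, 0)
  pts <- unique(cbind(x, y))
  h <- chull(pts)
  hull <- pts[h, , drop = FALSE]
  hull <- hull[!(hull[, 1] == 1 & hull[, 2] == 0), , drop = FALSE]
  hull <- hull[order(hull[, 1], hull[, 2]), , drop = FALSE]
  # walk edges; find where p_miss - p_fa = (1 - y) - x crosses zero
  g <- (1 - hull[, 2]) - hull[, 1]
  for (i in seq_len(nrow(hull) - 1)) {
    if (g[i] >= 0 && g[i + 1] <= 0) {
      if (g[i] == g[i + 1]) return(unname(100 * (1 - hull[i, 2])))
      t <- g[i] / (g[i] - g[i + 1])
      pmV <- (1 - hull[i, 2]) + t * ((1 - hull[i + 1, 2]) - (1 - hull[i, 2]))
      return(unname(100 * pmV))
    }
  }
  stop("no diagonal crossing found")
}

# Brute-force minimum Cllr: PAV level sets recovered from the greatest
# convex minorant of the cumulative-sum diagram (via chull), then 1-D
# numeric minimization of each level set's cost contribution.
oracle_min_cllr <- function(tar, non) {
  s <- c(non, tar)
  z <- c(rep(0, length(non)), rep(1, length(tar)))
  ord <- order(s)
  s <- s[ord]; z <- z[ord]
  grp <- cumsum(!duplicated(s))
  t_cnt <- as.numeric(tapply(z, grp, sum))
  w_cnt <- as.numeric(tapply(rep(1, length(z)), grp, sum))
  W <- c(0, cumsum(w_cnt))
  Tc <- c(0, cumsum(t_cnt))
  # lower hull of the CSD: add a sentinel far above so chull's remaining
  # boundary is exactly the greatest convex minorant
  px <- c(W, max(W) / 2)
  py <- c(Tc, max(Tc) + 10 * max(W) + 10)
  h <- chull(px, py)
  keep <- sort(h[h != length(px)])
  vx <- px[keep]; vy <- py[keep]
  n_tar <- length(tar); n_non <- length(non)
  total <- 0
  for (i in seq_len(length(vx) - 1)) {
    a <- vy[i + 1] - vy[i]              # targets in the level set
    b <- (vx[i + 1] - vx[i]) - a        # non-targets
    contrib <- function(v) {
      a / (2 * n_tar) * log2(1 + exp(-v)) + b / (2 * n_non) * log2(1 + exp(v))
    }
    opt <- stats::optimize(contrib, interval = c(-45, 45), tol = 1e-12)
    total <- total + opt$objective
  }
  total
}

# R-side tree traversal, independent of the compiled predictor.
r_tree_leaf <- function(tree, x) {
  node <- 1L
  while (tree$feature[node] >= 0L) {
    f <- tree$feature[node] + 1L
    node <- if (x[f] <= tree$threshold[node]) {
      tree$left[node] + 1L
    } else {
      tree$right[node] + 1L
    }
  }
  node
}

r_forest_leaves <- function(forest, X) {
  vapply(forest$trees, function(tr) {
    vapply(seq_len(nrow(X)), function(i) r_tree_leaf(tr, X[i, ]), integer(1))
  }, integer(nrow(X)))
}

# dummy per-recording scores for assembly-structure tests
dummy_scores <- function(table, seed = 1L) {
  set.seed(seed)
  score_table(table$records, d = stats::runif(nrow(table$records), -1, 1),
              b = rep(10L, nrow(table$records)),
              feature_set = table$feature_set)
}
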