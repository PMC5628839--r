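#' Random-forest proximity matrix
#'
#' Runs every row of the (meta-)feature table down every tree of the forest
#' and counts, for each pair of rows, the fraction of trees in which the two
#' rows share a terminal node. All trees are counted (the rows being
#' compared need not be out-of-bag). The result is symmetric with unit
#' diagonal and entries in `[0, 1]`; `1 - phi` serves as a dissimilarity
#' (zero self-distance and symmetric, but not necessarily metric).
#'
#' @param forest a [grow_forest()] result or a `pd_detector`.
#' @param table the [feature_table()] whose rows are compared.
#' @return a `proximity_matrix` (base matrix with recording ids as
#'   dimnames).
#' @export
proximity <- function(forest, table) {
  if (inherits(forest, "pd_detector")) forest <- forest$forest
  stopifnot(inherits(forest, "grouped_rf"))
  ids <- cpp_leaf_ids(forest$trees, table$matrix)
  phi <- cpp_proximity(ids)
  dimnames(phi) <- list(table$records$recording_id,
                        table$records$recording_id)
  class(phi) <- c("proximity_matrix", class(phi))
  phi
}

validate_proximity <- function(phi) {
  if (!is.matrix(phi) || nrow(phi) != ncol(phi)) {
    stop("proximity matrix must be square")
  }
  if (max(abs(phi - t(phi))) > 1e-12) stop("proximity matrix must be symmetric")
  if (any(phi < -1e-12 | phi > 1 + 1e-12)) stop("proximities must lie in [0, 1]")
  if (max(abs(diag(phi) - 1)) > 1e-12) stop("proximity diagonal must be 1")
  invisible(phi)
}

#' Embed a proximity matrix into 2D by t-SNE on 1 - phi
#'
#' Converts the proximity matrix into the distance matrix `1 - phi` and
#' minimizes the Kullback-Leibler divergence between the high-dimensional
#' neighbor distribution (Gaussian kernel on squared distances, bandwidths
#' chosen per point to match the configured perplexity) and the
#' low-dimensional Student-t neighbor distribution, by gradient descent
#' with momentum and early exaggeration. Deterministic given the seed.
#'
#' @param phi a [proximity()] matrix (or any symmetric unit-diagonal
#'   proximity).
#' @param records optional recording metadata to attach class labels to the
#'   coordinates.
#' @param perplexity effective neighborhood size (default 60; a warning is
#'   issued unless `1 <= perplexity < n/3`).
#' @param iterations gradient-descent iterations (default 1000).
#' @param seed seed for the random initial layout.
#' @return object of class `rf_embedding`: `coords` data frame (`x`, `y`,
#'   plus `recording_id`/`class` when `records` is given), the final KL
#'   divergence `kl`, and the post-exaggeration KL trace `kl_trace`.
#' @export
embed_proximity <- function(phi, records = NULL, perplexity = 60,
                            iterations = 1000L, seed = 1L) {
  validate_proximity(unclass(phi))
  n <- nrow(phi)
  if (perplexity < 1 || perplexity >= n / 3) {
    warning("perplexity ", perplexity, " outside [1, n/3) for n = ", n)
  }
  d <- 1 - unclass(phi)
  fit <- tsne_from_distances(d, perplexity = perplexity,
                             max_iter = iterations, seed = seed)
  coords <- data.frame(x = fit$Y[, 1], y = fit$Y[, 2])
  if (!is.null(rownames(phi))) coords$recording_id <- rownames(phi)
  if (!is.null(records) && !is.null(coords$recording_id)) {
    idx <- match(coords$recording_id, records$recording_id)
    coords$class <- records$class[idx]
    coords$subject_id <- records$subject_id[idx]
  }
  structure(list(coords = coords, kl = fit$kl, kl_trace = fit$kl_trace,
                 perplexity = perplexity, iterations = iterations,
                 seed = seed),
            class = "rf_embedding")
}

# Exact (O(n^2)) t-SNE on a precomputed distance matrix.
tsne_from_distances <- function(d, perplexity = 30, max_iter = 1000L,
                                seed = 1L, eta = 200,
                                exaggeration = 12, exaggeration_iter = 250L) {
  n <- nrow(d)
  P <- cond_probs(d, perplexity)
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  P <- P / sum(P)

  set.seed(seed)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), nrow = n)
  inc <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  kl_trace <- numeric(0)
  Pe <- P * exaggeration
  for (it in seq_len(max_iter)) {
    if (it == exaggeration_iter + 1L) Pe <- P
    sq <- rowSums(Y^2)
    num <- 1 / (1 + outer(sq, sq, "+") - 2 * tcrossprod(Y))
    diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    L <- (Pe - Q) * num
    G <- 4 * (diag(rowSums(L)) - L) %*% Y
    gains <- pmax(ifelse(sign(G) != sign(inc), gains + 0.2, gains * 0.8), 0.01)
    mom <- if (it < 250) 0.5 else 0.8
    inc <- mom * inc - eta * gains * G
    Y <- Y + inc
    Y <- sweep(Y, 2, colMeans(Y))
    if (it > exaggeration_iter && (it %% 50 == 0 || it == max_iter)) {
      kl_trace <- c(kl_trace, sum(P * log(P / Q)))
    }
  }
  list(Y = Y, kl = kl_trace[length(kl_trace)], kl_trace = kl_trace)
}

# Per-row Gaussian conditional probabilities matching log(perplexity)
# entropy, via bisection on the precision beta.
cond_probs <- function(d, perplexity, tol = 1e-5, max_tries = 50L) {
  n <- nrow(d)
  d2 <- d^2
  target <- log(perplexity)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    beta <- 1
    beta_lo <- -Inf
    beta_hi <- Inf
    for (k in seq_len(max_tries)) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw < 1e-300) {
        h <- 0
      } else {
        p <- w / sw
        h <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(h - target) < tol) break
      if (h > target) { # entropy too high: sharpen
        beta_lo <- beta
        beta <- if (is.finite(beta_hi)) (beta + beta_hi) / 2 else beta * 2
      } else {
        beta_hi <- beta
        beta <- if (is.finite(beta_lo)) (beta + beta_lo) / 2 else beta / 2
      }
    }
    w <- exp(-di * beta)
    if (sum(w) < 1e-300) w <- rep(1, length(di))
    P[i, -i] <- w / sum(w)
  }
  P
}

#' Plot a 2D embedding with class-coded markers
#'
#' PD recordings are drawn as squares, HC recordings as circles.
#'
#' @param x an [embed_proximity()] result (with class labels attached).
#' @param ... passed to [plot()].
#' @export
plot.rf_embedding <- function(x, ...) {
  co <- x$coords
  pch <- if (!is.null(co$class)) ifelse(co$class == 2L, 15, 1) else 19
  col <- if (!is.null(co$class)) ifelse(co$class == 2L, "firebrick", "navy") else "black"
  plot(co$x, co$y, pch = pch, col = col, xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  if (!is.null(co$class)) {
    graphics::legend("topright", legend = c("PD", "HC"), pch = c(15, 1),
                     col = c("firebrick", "navy"), bty = "n")
  }
  invisible(x)
}

#' Project a new, unlabelled case into an existing embedding
#'
#' Deployment-mode counterpart of the OOB score: the new recording is unseen
#' by every tree, so it is scored through every base forest using the
#' all-tree average of the leaf class-frequency difference. The resulting
#' meta-feature row is run down the meta-forest, its proximity to every
#' existing row is computed, the proximity matrix is augmented to
#' `(n+1) x (n+1)` and the embedding is re-run with the new case as a
#' distinct point.
#'
#' @param meta_detector the fitted meta-forest (`pd_detector`).
#' @param meta the [assemble_meta()] table the meta-forest was fitted on.
#' @param base_detectors named list of base `pd_detector`s; names must match
#'   the meta columns (`<set>.<modality>`).
#' @param new_features named list of numeric feature vectors, one per base
#'   detector, for the new recording.
#' @param ... passed to [embed_proximity()] (perplexity, iterations, seed).
#' @return list with the augmented `embedding` (new case last, class `NA`),
#'   the new case's `meta_row` of base scores and its `proximity_row`.
#' @export
project_new_case <- function(meta_detector, meta, base_detectors,
                             new_features, ...) {
  stopifnot(inherits(meta_detector, "pd_detector"),
            inherits(meta, "meta_feature_table"))
  needed <- colnames(meta$matrix)
  missing_sets <- setdiff(needed, names(new_features))
  if (length(missing_sets) > 0) {
    stop("new case lacks feature set(s): ", paste(missing_sets, collapse = ", "))
  }
  meta_row <- vapply(needed, function(key) {
    det <- base_detectors[[key]]
    if (is.null(det)) stop("no base detector for ", key)
    f2 <- leaf_frequency(det$forest, new_features[[key]])
    mean(2 * f2 - 1) # all trees: the case is OOB for every tree
  }, numeric(1))

  forest <- meta_detector$forest
  ids_old <- cpp_leaf_ids(forest$trees, meta$matrix)
  ids_new <- cpp_leaf_ids(forest$trees, matrix(meta_row, nrow = 1))
  prox_row <- rowMeans(ids_old == matrix(ids_new, nrow = nrow(ids_old),
                                         ncol = ncol(ids_old), byrow = TRUE))
  phi <- proximity(forest, as_feature_table(meta))
  phi_aug <- rbind(cbind(unclass(phi), prox_row), c(prox_row, 1))
  rn <- c(rownames(phi), "new_case")
  dimnames(phi_aug) <- list(rn, rn)
  records_aug <- rbind(
    meta$records,
    data.frame(recording_id = "new_case", subject_id = "new_case",
               class = NA_integer_, gender = NA_character_,
               channel = NA_character_, modality = NA_character_))
  emb <- embed_proximity(phi_aug, records = records_aug, ...)
  list(embedding = emb, meta_row = meta_row, proximity_row = prox_row)
}

#' Write embedding coordinates to CSV
#'
#' @param embedding an [embed_proximity()] result.
#' @param path output CSV path (`recording_id`, `class`, `x`, `y`).
#' @return `path`, invisibly.
#' @export
write_embedding <- function(embedding, path) {
  co <- embedding$coords
  cols <- intersect(c("recording_id", "class", "x", "y"), names(co))
  utils::write.csv(co[, cols], path, row.names = FALSE)
  invisible(path)
}
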