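test_that("proximity matches direct leaf-membership enumeration", {
  tbl <- make_table(n_subjects = 10, reps = 1L, p = 5, n_informative = 2,
                    seed = 71)
  plan <- suppressWarnings(draw_plan(tbl$records, B = 50, seed = 3))
  forest <- grow_forest(tbl, plan, q = 2)
  phi <- proximity(forest, tbl)
  ids <- r_forest_leaves(forest, tbl$matrix) # independent R traversal
  n <- nrow(tbl$matrix)
  expected <- matrix(0, n, n)
  for (b in seq_len(ncol(ids))) {
    expected <- expected + outer(ids[, b], ids[, b], "==")
  }
  expected <- expected / ncol(ids)
  expect_equal(unclass(phi), expected, ignore_attr = TRUE, tolerance = 1e-12)
  expect_equal(diag(unclass(phi)), rep(1, n), ignore_attr = TRUE)
  expect_equal(unclass(phi), t(unclass(phi)), ignore_attr = TRUE)
})

test_that("identical feature rows have proximity 1", {
  tbl <- make_table(n_subjects = 8, reps = 1L, p = 4, n_informative = 2,
                    seed = 72)
  tbl$matrix[2, ] <- tbl$matrix[1, ]
  plan <- draw_plan(tbl$records, B = 40, seed = 5)
  forest <- grow_forest(tbl, plan, q = 2)
  phi <- proximity(forest, tbl)
  expect_equal(phi[1, 2], 1)
})

test_that("the 1 - phi distances are valid dissimilarities", {
  tbl <- make_table(n_subjects = 12, reps = 1L, p = 6, n_informative = 3,
                    seed = 73)
  plan <- draw_plan(tbl$records, B = 60, seed = 7)
  phi <- proximity(grow_forest(tbl, plan, q = 2), tbl)
  d <- 1 - unclass(phi)
  expect_true(all(diag(d) == 0))
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(d, t(d))
})

test_that("embedding is seed-deterministic and preserves tight pairs", {
  set.seed(81)
  n <- 10
  pts <- matrix(runif(n * 3), n)
  pts[2, ] <- pts[1, ] # identical pair
  d <- as.matrix(dist(pts)) / max(dist(pts))
  phi <- 1 - d
  e1 <- suppressWarnings(embed_proximity(phi, perplexity = 3,
                                         iterations = 400, seed = 4))
  e2 <- suppressWarnings(embed_proximity(phi, perplexity = 3,
                                         iterations = 400, seed = 4))
  expect_identical(e1$coords, e2$coords)
  co <- e1$coords
  pair <- sqrt((co$x[1] - co$x[2])^2 + (co$y[1] - co$y[2])^2)
  others <- sqrt((co$x[1] - co$x[-(1:2)])^2 + (co$y[1] - co$y[-(1:2)])^2)
  expect_true(all(pair < others))
})

test_that("embedding inputs are validated and perplexity bounds warned about", {
  phi <- diag(4)
  phi[1, 2] <- 0.5 # asymmetric
  expect_error(embed_proximity(phi, perplexity = 1, iterations = 10),
               "symmetric")
  phi_ok <- matrix(0.2, 4, 4)
  diag(phi_ok) <- 1
  expect_warning(embed_proximity(phi_ok, perplexity = 3, iterations = 10),
                 "perplexity")
})

test_that("KL divergence decreases over post-exaggeration checkpoints", {
  tbl <- make_table(n_subjects = 20, reps = 1L, delta = 2, p = 10,
                    n_informative = 5, seed = 74)
  plan <- draw_plan(tbl$records, B = 80, seed = 9)
  phi <- proximity(grow_forest(tbl, plan, q = 3), tbl)
  emb <- embed_proximity(phi, records = tbl$records, perplexity = 5,
                         iterations = 600, seed = 2)
  expect_true(all(diff(emb$kl_trace) <= 1e-3))
  expect_equal(emb$kl, emb$kl_trace[length(emb$kl_trace)])
})

test_that("projecting an existing row reproduces its proximity row", {
  tabs <- simulate_cohort(simulation_config(
    n_subjects = 14, prop_pd = 0.5, prop_female = 0.5,
    recordings_per_modality = c(P = 2L),
    feature_set_sizes = c(mfcc = 8), n_informative = 3, class_effect = 2,
    channels = "AC", seed = 75))
  tbl <- tabs[[1]]
  cfg <- forest_config(B = 60, q_candidates = 2, seed = 3)
  det <- suppressWarnings(fit_detector(tbl, cfg)) # tiny roster: muted warnings
  sc <- det$scores
  meta <- suppressWarnings(assemble_meta(list(sc), combo = "P"))
  mdet <- suppressWarnings(
    fit_detector(as_feature_table(meta),
                 forest_config(B = 60, q_candidates = 1, seed = 5)))
  phi <- proximity(mdet, as_feature_table(meta))
  # feed row 3's meta-features back through the meta-forest only
  row3 <- meta$matrix[3, , drop = TRUE]
  ids_old <- pdvoice:::cpp_leaf_ids(mdet$forest$trees, meta$matrix)
  ids_new <- pdvoice:::cpp_leaf_ids(mdet$forest$trees,
                                    matrix(row3, nrow = 1))
  prox_row <- rowMeans(ids_old == matrix(ids_new, nrow = nrow(ids_old),
                                         ncol = ncol(ids_old), byrow = TRUE))
  expect_equal(prox_row[-3], unclass(phi)[3, -3], ignore_attr = TRUE)
  expect_equal(prox_row[3], 1)
})

test_that("a new case lands near its own class and the matrix stays valid", {
  cfg <- simulation_config(
    n_subjects = 20, prop_pd = 0.5, prop_female = 0.5,
    recordings_per_modality = c(P = 2L),
    feature_set_sizes = c(mfcc = 10), n_informative = 4, class_effect = 2.5,
    subject_sd = 0.5, channels = "AC", seed = 76)
  tbl <- simulate_cohort(cfg)[[1]]
  det <- fit_detector(tbl, forest_config(B = 100, q_candidates = 3, seed = 7))
  meta <- assemble_meta(list(det$scores), combo = "P")
  mdet <- fit_detector(as_feature_table(meta),
                       forest_config(B = 100, q_candidates = 1, seed = 9))
  pd_row <- which(tbl$records$class == 2L)[1]
  out <- project_new_case(
    mdet, meta, base_detectors = setNames(list(det), colnames(meta$matrix)),
    new_features = setNames(list(tbl$matrix[pd_row, ]), colnames(meta$matrix)),
    perplexity = 5, iterations = 400, seed = 11)
  expect_gt(out$meta_row[[1]], 0) # scored towards PD
  co <- out$embedding$coords
  new_pt <- co[co$recording_id == "new_case", ]
  pd_cent <- colMeans(co[!is.na(co$class) & co$class == 2L, c("x", "y")])
  hc_cent <- colMeans(co[!is.na(co$class) & co$class == 1L, c("x", "y")])
  d_pd <- sqrt(sum((unlist(new_pt[, c("x", "y")]) - pd_cent)^2))
  d_hc <- sqrt(sum((unlist(new_pt[, c("x", "y")]) - hc_cent)^2))
  expect_lt(d_pd, d_hc)
  # augmented proximity row is a valid similarity profile
  expect_true(all(out$proximity_row >= 0 & out$proximity_row <= 1))
  expect_error(project_new_case(mdet, meta, base_detectors = list(),
                                new_features = list()),
               "lacks feature set")
})

test_that("embedding coordinates round-trip to CSV with class labels", {
  tbl <- make_table(n_subjects = 10, reps = 1L, p = 5, n_informative = 2,
                    seed = 77)
  plan <- suppressWarnings(draw_plan(tbl$records, B = 40, seed = 2))
  phi <- proximity(grow_forest(tbl, plan, q = 2), tbl)
  emb <- suppressWarnings(embed_proximity(phi, records = tbl$records,
                                          perplexity = 3, iterations = 100,
                                          seed = 1))
  path <- tempfile(fileext = ".csv")
  write_embedding(emb, path)
  back <- utils::read.csv(path)
  expect_equal(names(back), c("recording_id", "class", "x", "y"))
  expect_equal(nrow(back), 10)
})
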