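test_that("bootstrap plan partitions subjects and preserves stratum counts", {
  tbl <- make_table(n_subjects = 24, p = 5, n_informative = 2, seed = 4)
  plan <- draw_plan(tbl$records, B = 40, seed = 9)
  groups <- unique(tbl$records[, c("subject_id", "class", "gender")])
  stratum <- interaction(groups$class, groups$gender, drop = TRUE)
  for (b in c(1, 17, 40)) {
    cnt <- plan$counts[, b]
    # in-bag multiset and OOB set partition the subjects
    expect_true(all(cnt >= 0))
    expect_setequal(union(plan$group_id[cnt > 0], plan$group_id[cnt == 0]),
                    groups$subject_id)
    # stratified: draws per stratum equal the stratum's subject count
    for (lev in levels(stratum)) {
      idx <- which(stratum == lev)
      expect_equal(sum(cnt[idx]), length(idx))
    }
  }
})

test_that("grouping holds: all recordings of a subject are jointly in or out", {
  tbl <- make_table(n_subjects = 15, p = 5, n_informative = 2, seed = 6)
  plan <- draw_plan(tbl$records, B = 25, seed = 2)
  for (b in c(1, 13, 25)) {
    rows <- inbag_rows(plan, tbl$records, b)
    tab <- table(tbl$records$subject_id[rows])
    n_rec <- table(tbl$records$subject_id)
    for (s in names(tab)) {
      mult <- plan$counts[match(s, plan$group_id), b]
      expect_equal(unname(tab[s]), unname(mult * n_rec[s]))
    }
    oob_subj <- plan$group_id[plan$counts[, b] == 0]
    expect_length(intersect(tbl$records$subject_id[rows], oob_subj), 0)
  }
})

test_that("a single-subject stratum is always in-bag and triggers a warning", {
  rec <- data.frame(
    subject_id = c("s1", "s2", "s3"), recording_id = c("r1", "r2", "r3"),
    class = c(1L, 1L, 2L), gender = c("male", "male", "male"),
    channel = "AC", modality = "S")
  expect_warning(plan <- draw_plan(rec, B = 30, seed = 1), "single unit")
  expect_true(all(plan$counts[plan$group_id == "s3", ] >= 1))
})

test_that("per-tree OOB subject fraction approaches the bootstrap omission rate", {
  S <- 200
  rec <- data.frame(
    subject_id = sprintf("s%03d", 1:S), recording_id = sprintf("r%03d", 1:S),
    class = 2L, gender = "female", channel = "AC", modality = "S")
  plan <- draw_plan(rec, B = 2000, seed = 31)
  frac <- mean(colMeans(plan$counts == 0))
  expect_lt(abs(frac - (1 - 1 / S)^S), 0.01) # ~ exp(-1)
})

test_that("a perfectly separating feature yields a depth-1 pure tree", {
  rec <- data.frame(
    subject_id = sprintf("s%d", 1:6), recording_id = sprintf("r%d", 1:6),
    class = rep(c(1L, 2L), each = 3), gender = "female",
    channel = "AC", modality = "S")
  tbl <- feature_table(matrix(c(1, 2, 3, 10, 11, 12), ncol = 1), rec,
                       feature_names = "x")
  plan <- draw_plan(tbl$records, B = 20, seed = 3)
  forest <- grow_forest(tbl, plan, q = 1)
  for (tr in forest$trees) {
    leaves <- which(tr$feature == -1L)
    internal <- which(tr$feature != -1L)
    if (length(internal) > 0) { # mixed in-bag sample: exactly one split
      expect_equal(length(internal), 1L)
      expect_true(all(tr$n1[leaves] == 0 | tr$n2[leaves] == 0))
    }
  }
  # training error 0 on in-bag rows: all-tree frequencies are extreme
  f2 <- leaf_frequency(forest, tbl$matrix)
  expect_true(all(f2[rec$class == 2L, ] == 1))
  expect_true(all(f2[rec$class == 1L, ] == 0))
})

test_that("leaf class counts are conserved and frequencies normalize", {
  tbl <- make_table(n_subjects = 10, reps = 2L, p = 6, n_informative = 2,
                    seed = 12)
  plan <- suppressWarnings(draw_plan(tbl$records, B = 30, seed = 5))
  forest <- grow_forest(tbl, plan, q = 3)
  for (b in c(1, 15, 30)) {
    tr <- forest$trees[[b]]
    leaves <- which(tr$feature == -1L)
    expect_true(all(tr$n1[leaves] + tr$n2[leaves] > 0))
    expect_equal(sum(tr$n1[leaves] + tr$n2[leaves]),
                 length(inbag_rows(plan, tbl$records, b)))
  }
  # leaf frequency = n2/(n1+n2) at the leaf each row lands in (R traversal)
  f2 <- leaf_frequency(forest, tbl$matrix)
  ids <- r_forest_leaves(forest, tbl$matrix)
  for (b in c(1, 30)) {
    tr <- forest$trees[[b]]
    expected <- tr$n2[ids[, b]] / (tr$n1[ids[, b]] + tr$n2[ids[, b]])
    expect_equal(f2[, b], expected)
  }
  expect_true(all(f2 >= 0 & f2 <= 1))
})

test_that("q = p behaves as bagged CART and invalid q errors", {
  tbl <- make_table(n_subjects = 10, p = 4, n_informative = 2, seed = 13)
  plan <- draw_plan(tbl$records, B = 10, seed = 7)
  expect_s3_class(grow_forest(tbl, plan, q = 4), "grouped_rf")
  expect_error(grow_forest(tbl, plan, q = 5), "q must be")
  expect_error(grow_forest(tbl, plan, q = 0), "q must be")
})

test_that("OOB scores hit the +-1 extremes under perfect separation and obey Eq (1)", {
  tbl <- make_table(n_subjects = 16, delta = 8, sigma_s = 0.2, sigma_e = 0.5,
                    p = 5, n_informative = 5, seed = 14)
  plan <- draw_plan(tbl$records, B = 60, seed = 8)
  forest <- grow_forest(tbl, plan, q = 2)
  sc <- oob_scores(forest, tbl)
  expect_true(all(abs(sc$d) <= 1))
  expect_gt(mean(sc$d[sc$class == 2L]), 0.8)
  expect_lt(mean(sc$d[sc$class == 1L]), -0.8)
  # d = 2 * mean OOB PD-frequency - 1, to machine precision
  f2 <- leaf_frequency(forest, tbl$matrix)
  m <- pdvoice:::oob_mask(plan, tbl$records)
  pbar <- rowSums(f2 * m) / rowSums(m)
  expect_equal(sc$d, 2 * pbar - 1, tolerance = 1e-12)
})

test_that("recordings never out-of-bag are flagged", {
  tbl <- make_table(n_subjects = 12, p = 4, n_informative = 2, seed = 15)
  plan <- draw_plan(tbl$records, B = 1, seed = 3)
  forest <- grow_forest(tbl, plan, q = 2)
  expect_warning(sc <- oob_scores(forest, tbl), "never out-of-bag")
  expect_true(any(is.na(sc$d)))
  expect_true(all(sc$b[is.na(sc$d)] == 0))
})

test_that("forests are reproducible from the seed, tree by tree", {
  tbl <- make_table(n_subjects = 12, p = 6, n_informative = 3, seed = 16)
  plan <- draw_plan(tbl$records, B = 8, seed = 10)
  f1 <- grow_forest(tbl, plan, q = 2, seed = 77)
  f2 <- grow_forest(tbl, plan, q = 2, seed = 77)
  expect_identical(f1$trees, f2$trees)
  f3 <- grow_forest(tbl, plan, q = 2, seed = 78)
  expect_false(identical(f1$trees, f3$trees))
})

test_that("fit_detector selects q by minimum Cllr and respects a single candidate", {
  tbl <- make_table(n_subjects = 24, delta = 1.5, p = 12, n_informative = 4,
                    seed = 17)
  # the seed-17 roster has a singleton stratum: warnings expected and muted
  single <- suppressWarnings(
    fit_detector(tbl, forest_config(B = 60, q_candidates = 3, seed = 2)))
  expect_equal(single$q, 3L)
  expect_equal(nrow(single$per_q), 1L)
  multi <- suppressWarnings(
    fit_detector(tbl, forest_config(B = 60, q_candidates = c(2, 4, 6),
                                    seed = 2)))
  expect_equal(multi$q, multi$per_q$q[which.min(multi$per_q$cllr)])
})

test_that("a strong class effect is detected with near-zero OOB EER", {
  tbl <- make_table(n_subjects = 60, delta = 2, sigma_s = 1, sigma_e = 1,
                    p = 100, n_informative = 20, seed = 18)
  det <- fit_detector(tbl, forest_config(B = 500, seed = 4))
  expect_lte(eer(as_detection_scores(det$scores)), 5)
})

test_that("OOB accuracy is in line with an established forest implementation", {
  tbl <- make_table(n_subjects = 40, reps = 1L, delta = 1.5, sigma_s = 0,
                    p = 20, n_informative = 5, seed = 19)
  det <- fit_detector(tbl, forest_config(B = 300, q_candidates = 4, seed = 5))
  ours <- mean(sign(det$scores$d) == ifelse(tbl$records$class == 2L, 1, -1))
  rf <- randomForest::randomForest(tbl$matrix, factor(tbl$records$class),
                                   ntree = 300, mtry = 4)
  theirs <- 1 - rf$err.rate[300, "OOB"]
  expect_lt(abs(ours - theirs), 0.15)
})

test_that("permutation importance recovers informative features", {
  tbl <- make_table(n_subjects = 40, delta = 1.5, sigma_s = 0.5, sigma_e = 1,
                    p = 20, n_informative = 5, seed = 20)
  plan <- draw_plan(tbl$records, B = 150, seed = 6)
  forest <- grow_forest(tbl, plan, q = 4)
  imp <- permutation_importance(forest, tbl, seed = 3)
  expect_gt(median(imp$importance[1:5]), median(imp$importance[6:20]))
  expect_lt(abs(median(imp$importance[6:20])), 0.02) # noise features ~ 0
  imp2 <- permutation_importance(forest, tbl, seed = 3)
  expect_identical(imp, imp2)
})
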