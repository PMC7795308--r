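test_that("recall counts same-class retrievals against class size minus one", {
  act <- stats::setNames(rep(c("A", "B"), c(10, 10)), sprintf("m%02d", 1:20))
  others <- names(act)[act == "A" & names(act) != "m01"]
  expect_equal(recall_percent(others, "m01", act), 100)
  expect_equal(recall_percent(character(0), "m01", act), 0)
  expect_equal(recall_percent(c(others[1:3], "m15", "m16"), "m01", act),
               100 * 3 / 9, tolerance = 1e-12)
  solo <- c(act, solo = "C")
  expect_error(recall_percent(character(0), "solo", solo), "single member")
  expect_error(recall_percent(character(0), "nope", act), "unknown query_id")
})

test_that("class recall averages seeded reference searches", {
  # identical in-class vectors and a generous cutoff: perfect recall
  x <- rbind(matrix(rep(c(1, 1, 0, 0), each = 8), 8, 4),
             matrix(rep(c(0, 0, 1, 1), each = 8), 8, 4))
  fp <- fp_tbl(x, sprintf("m%02d", 1:16), rep(c("A", "B"), each = 8))
  expect_equal(class_recall(fp, "A", cutoff = 0.5, n_refs = 5, seed = 1,
                            mode = "binary"), 100)
  # seeded reference sampling is reproducible
  case <- synth_case(3, class_sizes = c(A = 40, B = 40))
  r1 <- class_recall(case$fp, "A", cutoff = 0.05, n_refs = 10, seed = 5,
                     mode = "binary")
  r2 <- class_recall(case$fp, "A", cutoff = 0.05, n_refs = 10, seed = 5,
                     mode = "binary")
  expect_identical(r1, r2)
  expect_warning(class_recall(fp, "A", cutoff = 0.5, n_refs = 50, seed = 1),
                 "fewer than")
  expect_error(class_recall(fp, "Z", cutoff = 0.5, seed = 1), "unknown class")
})

test_that("planted signal drives recall above a label-permuted control", {
  wins <- 0
  for (seed in 1:5) {
    case <- synth_case(seed * 7, class_sizes = c(A = 60, B = 60))
    real <- class_recall(case$fp, "A", cutoff = 0.05, n_refs = 10,
                         seed = seed, mode = "binary")
    perm_act <- withr::with_seed(seed + 100, sample(case$fp$activity))
    permuted <- fp_tbl(fp_values(case$fp), fp_ids(case$fp), perm_act)
    ctrl <- class_recall(permuted, "A", cutoff = 0.05, n_refs = 10,
                         seed = seed, mode = "binary")
    if (real > ctrl) wins <- wins + 1
  }
  expect_gte(wins, 3)
})

test_that("recall tables recompute published summary rows", {
  tab <- build_recall_table(mddr_recall_values("ds1", 1))
  expect_equal(round(tab$column_means[["SDBN"]], 2), 24.63)
  expect_equal(round(tab$column_means[["BIN"]], 2), 22.93)
  expect_equal(unname(tab$best_counts["SDBN"]), 8)
  tab3 <- build_recall_table(mddr_recall_values("ds3", 1))
  expect_equal(unname(tab3$best_counts["SDBN"]), 9)
  expect_equal(round(tab3$column_means[["SDBN"]], 2), 16.38)
  # every row credits at least one method; ties may credit several
  expect_gte(sum(tab$best_counts), nrow(tab$table))
  # single method: best everywhere
  solo <- build_recall_table(data.frame(class = c("a", "b"), method = "M",
                                        recall = c(10, 20)))
  expect_equal(unname(solo$best_counts), 2)
  expect_error(build_recall_table(data.frame(class = "a", method = "M",
                                             recall = 120)), "\\[0, 100\\]")
})

test_that("gains reproduce the published narrative values", {
  g1 <- recall_gains(build_recall_table(mddr_recall_values("ds1", 1)), "SDBN")
  gains <- stats::setNames(g1$gain, g1$method)
  expect_equal(unname(gains[c("BIN", "SQB", "ASMTP", "TAN")]),
               c(1.70, 2.62, 4.55, 4.77))
  expect_equal(unname(gains["SDBN"]), 0)
  g9 <- recall_gains(build_recall_table(mddr_recall_values("ds3", 5)), "SDBN")
  expect_equal(g9$gain[g9$method == "SQB"], 6.47)
  expect_error(recall_gains(build_recall_table(mddr_recall_values("ds1", 1)),
                            "XXX"), "not in table")
})

test_that("Kendall's W matches hand computations and the brute-force oracle", {
  # identical rankings across judges: complete agreement
  expect_equal(kendall_w(rbind(c(10, 20, 30), c(1, 2, 3), c(5, 6, 7)))$W, 1)
  # two judges with exactly reversed rankings of two objects: S = 0, W = 0
  rev2 <- kendall_w(rbind(c(1, 2), c(2, 1)))
  expect_equal(rev2$S, 0)
  expect_equal(rev2$W, 0)
  # random matrices against the independent transcription of the formulas
  for (seed in 1:5) {
    x <- withr::with_seed(seed, matrix(runif(24), 6, 4))
    res <- kendall_w(x)
    expect_equal(res$W, brute_kendall_w(x), tolerance = 1e-12)
    # each judge's ranks are a permutation; totals sum to m n (n + 1) / 2
    expect_equal(sort(res$rank_matrix[1, ]), 1:4)
    expect_equal(sum(res$totals), 6 * 4 * 5 / 2)
    expect_gte(res$W, 0); expect_lte(res$W, 1)
  }
  # invariance to relabeling judges and objects
  x <- withr::with_seed(9, matrix(runif(20), 5, 4))
  expect_equal(kendall_w(x[sample(5), sample(4)])$W, kendall_w(x)$W)
  # ties produce mid-ranks and a still-valid W
  tied <- kendall_w(rbind(c(1, 1, 2), c(3, 3, 3)))
  expect_equal(unname(tied$rank_matrix[1, ]), c(1.5, 1.5, 3))
  expect_gte(tied$W, 0); expect_lte(tied$W, 1)
  expect_error(kendall_w(matrix(1, 1, 3)), "at least 2")
})

test_that("concordance over published recall rows is significant where narrated", {
  res <- kendall_w(build_recall_table(mddr_recall_values("ds1", 1)))
  expect_equal(res$m, 11)
  expect_equal(res$n, 5)
  # SDBN attains the highest mean rank on the heterogeneous DS1 benchmark
  expect_equal(names(which.max(res$mean_ranks)), "SDBN")
  expect_lt(res$p_value, 0.05)
})

test_that("tidiers return the documented tabular shapes", {
  tab <- build_recall_table(mddr_recall_values("ds2", 1))
  expect_equal(dim(tidy(tab)), c(50, 3))
  expect_equal(nrow(glance(tab)), 5)
  kw <- kendall_w(tab)
  expect_equal(nrow(tidy(kw)), 5)
  expect_named(glance(kw), c("W", "chisq", "df", "p_value", "m", "n"))
  E <- matrix(runif(20), 5, 4)
  pca <- build_error_pca(E, k = 2)
  td <- tidy(pca)
  expect_equal(nrow(td), 4)
  expect_true(all(c("PCA1", "PCA2", "dist") %in% names(td)))
})
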