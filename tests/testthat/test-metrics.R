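# Simplex grid, confusion metrics, ROC/AUC, feature screen.

test_that("simplex grid enumerates exactly the stated candidate sets", {
  g1 <- simplex_grid(3, 1)
  expect_equal(nrow(g1), 3)           # just the vertices
  expect_true(all(rowSums(g1 == 1) == 1))
  expect_equal(nrow(simplex_grid(3, 0.5)), 6)
  expect_equal(nrow(simplex_grid(3, 0.05)), 231)
  expect_error(simplex_grid(3, 0.3), "1/k")
})

test_that("grid size follows the closed form and points are valid and unique", {
  for (M in 2:4) for (k in c(1, 2, 5, 11, 20, 40)) {
    g <- simplex_grid(M, 1 / k)
    expect_equal(nrow(g), choose(k + M - 1, M - 1))
    expect_true(all(abs(rowSums(g) - 1) < 1e-12))
    expect_true(all(g >= 0))
    expect_equal(anyDuplicated(g), 0)
    # lexicographic: first column non-decreasing (up to fp representation)
    expect_true(all(diff(g[, 1]) >= -1e-12))
  }
})

test_that("confusion metrics reproduce hand-computed percentages", {
  cm <- new_confusion_matrix(tp = 25, fn = 3, fp = 5, tn = 19)
  expect_equal(unname(confusion_metrics(cm)), c(84.6, 89.3, 79.2))
  perfect <- new_confusion_matrix(tp = 10, fn = 0, fp = 0, tn = 10)
  expect_equal(unname(confusion_metrics(perfect)), c(100, 100, 100))
  expect_error(confusion_metrics(new_confusion_matrix(0, 0, 2, 3)),
               "sensitivity undefined")
  expect_error(confusion_metrics(new_confusion_matrix(2, 3, 0, 0)),
               "specificity undefined")
  # construction from label vectors
  cm2 <- confusion_matrix(reference = c(1, 1, -1, -1),
                          predicted = c(1, -1, -1, 1))
  expect_equal(cm2$tp + cm2$fn + cm2$fp + cm2$tn, 4)
  expect_equal(cm2$tp, 1)
})

test_that("AUC equals Mann-Whitney pair enumeration, ties included", {
  ra <- roc_auc(c(1, 1, -1, -1), c(0.9, 0.4, 0.6, 0.2))
  expect_equal(ra$auc, 0.75)   # 3 of 4 concordant pairs
  expect_equal(roc_auc(c(1, 1, -1), c(5, 4, 1))$auc, 1.0)
  expect_equal(roc_auc(c(1, -1, 1, -1), rep(2, 4))$auc, 0.5)
  set.seed(201)
  for (r in 1:20) {
    n <- sample(4:12, 1)
    y <- random_labels(n)
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(y, s)$auc, oracle_auc_enum(y, s))
    expect_equal(roc_auc(y, s)$auc,
                 as.numeric(pROC::auc(pROC::roc(y, s, direction = "<",
                                                quiet = TRUE))))
  }
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(202)
  y <- random_labels(20)
  s <- rnorm(20)
  a0 <- roc_auc(y, s)$auc
  expect_equal(roc_auc(y, exp(s))$auc, a0)
  expect_equal(roc_auc(y, 3 * s - 100)$auc, a0)
  expect_equal(roc_auc(y, atan(s))$auc, a0)
})

test_that("ROC points step from (0,0) to (1,1)", {
  set.seed(203)
  y <- random_labels(14)
  ra <- roc_auc(y, rnorm(14))
  expect_equal(ra$roc$tpr[1], 0)
  expect_equal(ra$roc$fpr[1], 0)
  expect_equal(ra$roc$tpr[nrow(ra$roc)], 1)
  expect_equal(ra$roc$fpr[nrow(ra$roc)], 1)
  expect_true(all(diff(ra$roc$tpr) >= 0) && all(diff(ra$roc$fpr) >= 0))
})

test_that("feature screen reproduces Welch statistics and Bonferroni levels", {
  ids <- sprintf("S%03d", 1:6)
  blocks <- list(clinical = matrix(c(1, 2, 3, 4, 5, 6), 6, 1,
                                   dimnames = list(ids, "f")))
  d <- multimodal_dataset(blocks, labels = c(1, 1, 1, -1, -1, -1))
  sc <- feature_screen(d)
  expect_equal(sc$t, -3.674, tolerance = 1e-3)  # groups (1,2,3) vs (4,5,6)
  expect_equal(sc$p, t.test(1:3, 4:6)$p.value)
  # identical group distributions: t = 0, p = 1
  blocks2 <- list(m = matrix(c(1, 2, 1, 2), 4, 1,
                             dimnames = list(sprintf("S%03d", 1:4), "g")))
  d2 <- multimodal_dataset(blocks2, labels = c(1, 1, -1, -1))
  sc2 <- feature_screen(d2)
  expect_equal(sc2$t, 0)
  expect_equal(sc2$p, 1)
  # Bonferroni threshold: 0.05 / 266 for the default EEG family
  d3 <- simulate_cohort(cohort_spec(n_case = 4, n_control = 4), seed = 1)
  sc3 <- feature_screen(d3)
  expect_equal(unique(sc3$bonferroni[sc3$modality == "eeg"]), 0.05 / 266,
               tolerance = 1e-12)
  expect_equal(0.05 / 266, 1.8797e-4, tolerance = 1e-4)
})

test_that("zero-variance features are flagged, not fatal", {
  ids <- sprintf("S%03d", 1:6)
  blocks <- list(m = matrix(c(rep(1, 6), rnorm(6)), 6, 2,
                            dimnames = list(ids, c("flat", "ok"))))
  d <- multimodal_dataset(blocks, labels = rep(c(1, -1), 3))
  sc <- feature_screen(d)
  expect_true(sc$degenerate[sc$feature == "flat"])
  expect_true(is.na(sc$p[sc$feature == "flat"]))
  expect_false(sc$degenerate[sc$feature == "ok"])
})
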