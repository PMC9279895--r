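# Kernel PCA, two-component separation, heatmaps, contribution report.

test_that("kernel PCA matches an independent eigen-solve of the centered kernel", {
  K <- random_psd_kernel(4, seed = 41)
  kp <- kernel_pca(K)
  Kc <- oracle_center(unclass(K))
  e <- eigen((Kc + t(Kc)) / 2, symmetric = TRUE)
  for (c in seq_along(kp$eigenvalues)) {
    expected <- e$vectors[, c] * sqrt(e$values[c])
    got <- kp$scores[, c]
    expect_true(max(abs(got - expected)) < 1e-8 ||
                  max(abs(got + expected)) < 1e-8)
  }
  # centering: component scores sum to zero; eigenvalues sum to the trace
  expect_lt(max(abs(colSums(kp$scores))), 1e-8)
  expect_equal(kp$total_variance, sum(diag(Kc)), tolerance = 1e-10)
})

test_that("kernel PCA on a linear kernel reproduces ordinary PCA scores", {
  set.seed(42)
  X <- matrix(rnorm(9 * 5), 9)
  K <- compute_kernel(X, kernel_spec("linear", standardize = TRUE))
  kp <- kernel_pca(K)
  Z <- scale(X)
  pc <- prcomp(Z, center = TRUE)
  for (c in 1:4) {
    a <- kp$scores[, c]
    b <- pc$x[, c]
    expect_true(max(abs(a - b)) < 1e-6 || max(abs(a + b)) < 1e-6)
  }
})

test_that("full PC-score distances equal kernel-induced distances", {
  K <- random_psd_kernel(7, seed = 43)
  kp <- kernel_pca(K, n_components = 6)
  Kc <- unclass(center_kernel(K))
  D_kernel <- sqrt(outer(diag(Kc), diag(Kc), `+`) - 2 * Kc)
  D_scores <- as.matrix(dist(kp$scores))
  expect_equal(D_scores, D_kernel, tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("component signs are fixed and requests past the rank truncate", {
  K <- random_psd_kernel(6, seed = 44)
  kp1 <- kernel_pca(K)
  kp2 <- kernel_pca(K)
  expect_identical(kp1$scores, kp2$scores)
  for (c in seq_len(ncol(kp1$scores)))
    expect_gt(kp1$scores[which.max(abs(kp1$scores[, c])), c], 0)
  # rank-1 kernel: only one informative component
  v <- rnorm(6)
  K1 <- tcrossprod(v)
  expect_warning(kp3 <- kernel_pca(K1, n_components = 4), "rank")
  expect_lte(ncol(kp3$scores), 2)
  expect_error(kernel_pca(matrix(c(1, 2, 2, 1), 2)), "positive semidefinite")
})

test_that("logistic separation plane works and flags perfect separation", {
  set.seed(45)
  s <- cbind(PC1 = c(rnorm(20, 3), rnorm(20, -3)), PC2 = rnorm(40))
  y <- rep(c(1, -1), each = 20)
  sep <- pc_separation(s, y)
  expect_equal(sep$accuracy, 1)
  expect_true(sep$separated)
  expect_false(sep$boundary$vertical)
  # label swap flips the boundary orientation
  sep_sw <- pc_separation(s, -y)
  expect_lt(sum(sep$coefficients * sep_sw$coefficients), 0)
  # overlapping classes: finite logistic fit, moderate accuracy
  s2 <- cbind(PC1 = c(rnorm(50, 0.5), rnorm(50, -0.5)), PC2 = rnorm(100))
  y2 <- rep(c(1, -1), each = 50)
  sep2 <- pc_separation(s2, y2)
  expect_false(sep2$separated)
  expect_gt(sep2$accuracy, 0.5)
})

test_that("labels independent of the scores give chance-level accuracy", {
  set.seed(46)
  s <- matrix(rnorm(2000), 1000, 2, dimnames = list(NULL, c("PC1", "PC2")))
  y <- random_labels(1000)
  sep <- pc_separation(s, y)
  expect_lt(sep$accuracy, 0.6)
})

test_that("heatmap reordering forms class blocks and preserves the spectrum", {
  ids <- sprintf("S%03d", 1:6)
  y <- c(-1, 1, -1, 1, 1, -1)
  K <- outer(y, y, function(a, b) (a == b) * 1)  # within-class 1, between 0
  dimnames(K) <- list(ids, ids)
  path <- withr::local_tempfile(fileext = ".png")
  K2 <- kernel_heatmap(K, y, path = path)
  expect_true(file.exists(path))
  # positive class leads; blocks are exactly the expected pattern
  expect_equal(unclass(K2)[1:3, 1:3], matrix(1, 3, 3), ignore_attr = TRUE)
  expect_equal(unclass(K2)[4:6, 1:3], matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(eigen(K2, only.values = TRUE)$values,
               eigen(K, only.values = TRUE)$values, tolerance = 1e-12)
  # export path is deterministic: identical bytes for identical input
  path2 <- withr::local_tempfile(fileext = ".png")
  kernel_heatmap(K, y, path = path2)
  expect_identical(unname(tools::md5sum(path)), unname(tools::md5sum(path2)))
})

test_that("contribution report averages fold weights with sample SD", {
  cv <- list(fold_beta = rbind(c(1, 0, 0), c(0, 1, 0)))
  colnames(cv$fold_beta) <- c("pet", "clinical", "eeg")
  rep <- contribution_report(cv)
  expect_equal(rep$mean, c(0.5, 0.5, 0))
  expect_equal(rep$sd, c(0.7071068, 0.7071068, 0), tolerance = 1e-6)
  expect_equal(sum(rep$mean), 1)
  cv2 <- list(fold_beta = rbind(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3)))
  expect_equal(contribution_report(cv2)$sd, c(0, 0, 0))
})
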