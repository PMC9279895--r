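# SVM dual solver: hand-worked examples, KKT invariants, oracle agreement.

test_that("two-point identity-kernel problem is solved exactly", {
  fit <- mksvm(diag(2), c(1, -1), C = 10)
  expect_equal(fit$alpha, c(1, 1), tolerance = 1e-8)
  expect_equal(fit$b, 0, tolerance = 1e-8)
  expect_equal(fit$objective, 1, tolerance = 1e-8)
  expect_equal(fit$margin_sv, 1:2)
  # plug a test point with kernel row (1, 0) into the decision function
  expect_equal(unname(predict(fit, matrix(c(1, 0), 1))), 1, tolerance = 1e-8)
  # an all-zero kernel row scores exactly b
  expect_equal(unname(predict(fit, matrix(0, 1, 2))), fit$b)
})

test_that("dual solution satisfies the KKT conditions on random problems", {
  set.seed(101)
  for (r in 1:12) {
    n <- sample(6:14, 1)
    K <- random_psd_kernel(n)
    y <- random_labels(n)
    C <- sample(c(0.1, 1, 10), 1)
    fit <- mksvm(K, y, C = C)
    expect_lt(abs(sum(fit$alpha * y)), 1e-8)
    expect_true(all(fit$alpha >= -1e-12 & fit$alpha <= C + 1e-12))
    f <- drop(K %*% (fit$alpha * y)) + fit$b
    if (length(fit$margin_sv))
      expect_lt(max(abs(y[fit$margin_sv] * f[fit$margin_sv] - 1)), 1e-4)
    # complementary slackness at the solver tolerance
    expect_true(all(y[fit$alpha < 1e-8 * C] * f[fit$alpha < 1e-8 * C]
                    >= 1 - 1e-4))
  }
})

test_that("dual objective matches the independent LIBSVM oracle", {
  set.seed(102)
  for (r in 1:10) {
    n <- sample(8:12, 1)
    K <- random_psd_kernel(n)
    y <- random_labels(n)
    C <- sample(c(0.1, 1), 1)
    fit <- mksvm(K, y, C = C)
    orc <- oracle_svm_dual(unclass(K), y, C)
    expect_equal(fit$objective, orc$objective, tolerance = 1e-6)
  }
})

test_that("separable training data are classified perfectly", {
  set.seed(103)
  X <- rbind(matrix(rnorm(20, 4), 5), matrix(rnorm(20, -4), 5))
  y <- rep(c(1, -1), each = 5)
  fit <- mksvm(compute_kernel(X, kernel_spec("linear", standardize = FALSE)),
               y, C = 100)
  expect_equal(sign(fitted(fit)), y)
  # a decision score of exactly zero maps to the positive class
  f2 <- mksvm(diag(2), c(1, -1), C = 10)
  expect_equal(unname(predict(f2, matrix(c(0.5, 0.5), 1))), 0)
  expect_equal(unname(predict(f2, matrix(c(0.5, 0.5), 1), type = "class")), 1)
})

test_that("single-class labels and broken kernels are rejected", {
  expect_error(mksvm(diag(3), c(1, 1, 1)), "both classes")
  K <- matrix(c(1, 2, 0, 1), 2)
  expect_error(mksvm(K, c(1, -1)), "symmetric")
  K <- matrix(c(1, 2, 2, 1), 2)  # eigenvalues 3, -1
  expect_error(mksvm(K, c(1, -1)), "positive semidefinite")
})

test_that("beta at a simplex vertex reproduces the single-kernel fit", {
  set.seed(104)
  ids <- sprintf("S%03d", 1:10)
  Ks <- lapply(1:3, function(i) new_kernel_matrix(random_psd_kernel(10),
                                                  subject_ids = ids))
  y <- random_labels(10)
  for (m in 1:3) {
    beta <- rep(0, 3); beta[m] <- 1
    f1 <- mksvm(combine_kernels(Ks, kernel_weights(beta)), y, C = 1)
    f2 <- mksvm(Ks[[m]], y, C = 1)
    expect_equal(f1$alpha, f2$alpha, tolerance = 1e-6)
    expect_equal(f1$b, f2$b, tolerance = 1e-6)
  }
})

test_that("the number of bounded support vectors is non-increasing in C", {
  set.seed(105)
  K <- random_psd_kernel(14)
  y <- random_labels(14)
  bounded <- sapply(c(0.05, 0.2, 1, 5, 25), function(C)
    sum(mksvm(K, y, C = C)$alpha > C - 1e-8 * C))
  expect_true(all(diff(bounded) <= 0))
})

test_that("duplicating a subject at halved cost leaves predictions unchanged", {
  set.seed(106)
  n <- 8
  K <- random_psd_kernel(n) + 0.5 * diag(n)  # strictly PD: unique solution
  y <- random_labels(n)
  i <- 3
  fit1 <- mksvm(K, y, C = 1)
  idx <- c(seq_len(n), i)
  K2 <- K[idx, idx]
  y2 <- y[idx]
  C2 <- rep(1, n + 1)
  C2[c(i, n + 1)] <- 0.5
  fit2 <- mksvm(K2, y2, C = C2, check_psd = FALSE)
  # score a grid of held-out points through both models
  set.seed(107)
  Kt <- matrix(rnorm(5 * n), 5, n)
  s1 <- Kt %*% (fit1$alpha * y) + fit1$b
  s2 <- Kt[, c(seq_len(n), i), drop = FALSE] %*% (fit2$alpha * y2) + fit2$b
  expect_equal(unname(s1), unname(s2), tolerance = 1e-5)
})

test_that("dataset-fitted model serializes and predicts after reload", {
  d <- make_tiny_dataset(seed = 3)
  fit <- mksvm(d, beta = c(0.6, 0.2, 0.2), C = 1)
  expect_equal(sum(fit$beta), 1)
  path <- withr::local_tempfile(fileext = ".json")
  write_mksvm(fit, path)
  m2 <- read_mksvm(path, data = d)
  expect_equal(m2$alpha, fit$alpha, tolerance = 1e-12)
  expect_equal(m2$b, fit$b, tolerance = 1e-12)
  new <- make_tiny_dataset(n_case = 2, n_control = 2, seed = 4)
  expect_equal(predict(fit, new), predict(m2, new), tolerance = 1e-10)
  expect_length(predict(fit, new), 4)
})
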