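# Kernel engine: computation, normalization, combination, centering.

test_that("linear kernel reproduces direct inner products", {
  X <- matrix(c(1, 0, 0, 1, 1, 1), 3, 2, byrow = TRUE)
  K <- compute_kernel(X, kernel_spec("linear", standardize = FALSE))
  expect_equal(unclass(K), matrix(c(1, 0, 1, 0, 1, 1, 1, 1, 2), 3),
               ignore_attr = TRUE)
})

test_that("rbf kernel has unit diagonal and z-scoring removes scale", {
  set.seed(5)
  X <- matrix(rnorm(40), 8, 5)
  K <- compute_kernel(X, kernel_spec("rbf"))
  expect_equal(unname(diag(K)), rep(1, 8))
  expect_true(all(K > 0 & K <= 1 + 1e-12))
  K1 <- compute_kernel(X, kernel_spec("linear"))
  K2 <- compute_kernel(7.3 * X, kernel_spec("linear"))
  expect_equal(unclass(K1), unclass(K2), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("median-heuristic bandwidth depends on training rows only", {
  set.seed(6)
  X <- matrix(rnorm(60), 12, 5)
  K1 <- compute_kernel(X, kernel_spec("rbf"), train_rows = 1:8)
  K2 <- compute_kernel(X[1:10, ], kernel_spec("rbf"), train_rows = 1:8)
  expect_equal(attr(K1, "spec")$gamma, attr(K2, "spec")$gamma)
  expect_equal(unclass(K1)[1:10, 1:10], unclass(K2), ignore_attr = TRUE)
})

test_that("zero-variance features are dropped with a warning", {
  X <- cbind(a = rnorm(6), b = rep(2, 6))
  expect_warning(K <- compute_kernel(X, kernel_spec("linear")), "zero-variance")
  expect_equal(attr(K, "spec")$dropped_features, "b")
})

test_that("cosine normalization matches the closed form and is idempotent", {
  K <- new_kernel <- matrix(c(4, 2, 2, 9), 2)
  rownames(K) <- colnames(K) <- c("a", "b")
  Kn <- normalize_kernel(K)
  expect_equal(unclass(Kn), matrix(c(1, 1/3, 1/3, 1), 2), ignore_attr = TRUE)
  expect_equal(unclass(normalize_kernel(Kn)), unclass(Kn))
  # normalization preserves PSD (congruence by a positive diagonal)
  for (s in 1:5) {
    K <- random_psd_kernel(7, seed = s) + diag(7) * 0.1
    expect_gte(kernel_min_eigenvalue(normalize_kernel(K)), -1e-10)
  }
  K[1, 1] <- 0
  expect_error(normalize_kernel(K), "S001")
})

test_that("kernel weights live on the simplex", {
  expect_error(kernel_weights(c(0.5, 0.6)), "sum to 1")
  expect_error(kernel_weights(c(-0.1, 1.1)), "non-negative")
  w <- kernel_weights(c(0.25, 0.75), c("a", "b"))
  expect_equal(sum(w), 1)
})

test_that("combining kernels is the weighted elementwise sum", {
  K1 <- new_kernel_matrix(diag(2), subject_ids = c("a", "b"))
  K2 <- new_kernel_matrix(matrix(1, 2, 2), subject_ids = c("a", "b"))
  Kc <- combine_kernels(list(K1, K2), c(0.5, 0.5))
  expect_equal(unclass(Kc), matrix(c(1, .5, .5, 1), 2), ignore_attr = TRUE)
  # vertex recovers a single kernel; identical kernels are a fixed point
  expect_equal(unclass(combine_kernels(list(K1, K2), c(1, 0))), diag(2),
               ignore_attr = TRUE)
  expect_equal(unclass(combine_kernels(list(K2, K2, K2), c(.2, .3, .5))),
               unclass(K2), ignore_attr = TRUE)
  K3 <- new_kernel_matrix(diag(2), subject_ids = c("b", "a"))
  expect_error(combine_kernels(list(K1, K3), c(0.5, 0.5)), "subject order")
})

test_that("combination is linear in the weights and preserves PSD", {
  set.seed(7)
  Ks <- lapply(1:3, function(i)
    new_kernel_matrix(random_psd_kernel(6), subject_ids = sprintf("S%03d", 1:6)))
  for (r in 1:5) {
    b1 <- c(x <- runif(3)) / sum(x)
    b2 <- c(x <- runif(3)) / sum(x)
    a <- runif(1)
    lhs <- combine_kernels(Ks, kernel_weights(a * b1 + (1 - a) * b2))
    rhs <- a * unclass(combine_kernels(Ks, b1)) +
      (1 - a) * unclass(combine_kernels(Ks, b2))
    expect_equal(unclass(lhs), rhs, tolerance = 1e-12, ignore_attr = TRUE)
    expect_gte(kernel_min_eigenvalue(lhs), -1e-10)
  }
})

test_that("double centering matches the brute-force projection", {
  # constant kernel collapses to zero
  Kc <- center_kernel(matrix(3, 4, 4))
  expect_equal(unclass(Kc), matrix(0, 4, 4), ignore_attr = TRUE)
  set.seed(8)
  K <- random_psd_kernel(6)
  Kc <- center_kernel(K)
  expect_equal(unclass(Kc), oracle_center(K), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_lt(max(abs(rowSums(unclass(Kc)))), 1e-8)
  # explicit 3x3 arithmetic: 2*I centered
  Kc3 <- unclass(center_kernel(diag(c(2, 2, 2))))
  expect_equal(Kc3, oracle_center(diag(c(2, 2, 2))), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("training-row statistics make test-row kernel values reproducible", {
  set.seed(9)
  X <- matrix(rnorm(80), 16, 5)
  tr <- c(2, 5, 7, 8, 11, 13, 14, 16)
  o <- 3
  K1 <- compute_kernel(X, kernel_spec("linear"), train_rows = tr)
  K2 <- compute_kernel(X[c(tr, o), ], kernel_spec("linear"),
                       train_rows = seq_along(tr))
  expect_equal(unclass(K1)[c(tr, o), c(tr, o)], unclass(K2),
               tolerance = 1e-12, ignore_attr = TRUE)
})
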