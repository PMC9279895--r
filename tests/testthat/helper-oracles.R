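# Independent oracles and small fixtures shared across the suite.

# random symmetric PSD kernel (full rank almost surely)
random_psd_kernel <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(rnorm(n * n), n)
  K <- tcrossprod(A) / n
  rownames(K) <- colnames(K) <- sprintf("S%03d", seq_len(n))
  K
}

# balanced-ish +/-1 labels with both classes guaranteed
random_labels <- function(n) {
  y <- sample(c(rep(1, ceiling(n / 2)), rep(-1, floor(n / 2))))
  y
}

# Independent QP oracle for the SVM dual: LIBSVM (via e1071) run on an
# explicit square-root factor of K, so it solves the identical quadratic
# program through an unrelated code path. Returns alpha and the dual
# objective computed directly from that alpha.
oracle_svm_dual <- function(K, y, C) {
  e <- eigen(K, symmetric = TRUE)
  L <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(K))
  m <- e1071::svm(L, factor(y, levels = c(-1, 1)), kernel = "linear",
                  cost = C, scale = FALSE, tolerance = 1e-9)
  a <- rep(0, nrow(K))
  a[m$index] <- abs(m$coefs)
  Q <- (y %o% y) * K
  list(alpha = a, objective = sum(a) - 0.5 * drop(t(a) %*% Q %*% a))
}

# Mann-Whitney AUC by explicit pair enumeration (ties count 1/2)
oracle_auc_enum <- function(y, s) {
  pos <- s[y > 0]
  neg <- s[y < 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force double centering J K J with J = I - 11'/n
oracle_center <- function(K) {
  n <- nrow(K)
  J <- diag(n) - matrix(1 / n, n, n)
  J %*% K %*% J
}

# small multimodal dataset built directly from Gaussian blocks; modality 1
# ("clinical") carries a mean shift of `d` per feature, the rest are noise
make_tiny_dataset <- function(n_case = 8, n_control = 8, d = 2,
                              p = c(clinical = 4, eeg = 12, pet = 6),
                              seed = 1) {
  set.seed(seed)
  n <- n_case + n_control
  ids <- sprintf("S%03d", seq_len(n))
  shift <- rep(c(d, 0), c(n_case, n_control))
  blocks <- lapply(seq_along(p), function(i) {
    X <- matrix(rnorm(n * p[i]), n)
    if (i == 1L) X <- X + shift
    dimnames(X) <- list(ids, sprintf("%s%02d", names(p)[i], seq_len(p[i])))
    X
  })
  names(blocks) <- names(p)
  multimodal_dataset(blocks, labels = rep(c(1, -1), c(n_case, n_control)),
                     subject_ids = ids)
}
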