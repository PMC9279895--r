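#' Simplex grid of candidate kernel weights
#'
#' All vectors of length `M` whose components are non-negative multiples of
#' `step` summing to exactly 1 — the search space for the kernel-weight grid
#' search. `step` must be `1/k` for an integer `k`; the grid then has
#' `choose(k + M - 1, M - 1)` points, enumerated in deterministic
#' lexicographic order (first coordinate slowest, ascending).
#'
#' @param M number of modalities.
#' @param step grid resolution `1/k` (default 0.05, i.e. k = 20).
#' @return matrix (`grid size` x `M`); each row lies on the unit simplex.
#' @examples
#' nrow(simplex_grid(3, 0.05))  # 231 candidate weight vectors
#' @export
simplex_grid <- function(M, step = 0.05) {
  if (M < 1L) stop("'M' must be at least 1")
  k <- round(1 / step)
  if (abs(k - 1 / step) > 1e-8 || k < 1L)
    stop(sprintf("'step' must be 1/k for an integer k (got %g)", step))
  rows <- compositions_k(as.integer(k), as.integer(M))
  grid <- rows / k
  # guard against fp drift: each row sums to exactly 1 by construction in
  # integer arithmetic, renormalize the float representation
  grid / rowSums(grid)
}

# all length-M vectors of non-negative integers summing to k,
# lexicographic in the first coordinate (ascending), recursively
compositions_k <- function(k, M) {
  if (M == 1L) return(matrix(k, 1L, 1L))
  out <- vector("list", k + 1L)
  for (first in 0:k) {
    rest <- compositions_k(k - first, M - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}
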