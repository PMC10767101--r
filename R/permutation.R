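#' Permutation test for a mean shape difference between two groups
#'
#' Test statistic: the Euclidean distance between the two group mean
#' Procrustes coordinate vectors (both groups must come from one joint
#' superimposition). The null distribution is built by random relabelling;
#' the p-value uses the add-one convention `p = (b + 1) / (m + 1)` where `b`
#' counts permuted statistics >= the observed one.
#'
#' @param A,B Flattened aligned coordinate matrices (rows = specimens) of
#'   the two groups, or `aligned_sample`-derived matrices via
#'   [aligned_matrix()].
#' @param n_perm Number of permutations (the conventional full-analysis
#'   setting is 10000).
#' @param seed Integer RNG seed (mandatory for reproducibility).
#' @return Object of class `permutation_test`: `statistic`, `observed`,
#'   `n_perm`, `perm_values`, `p_value`, `seed`.
#' @export
permutation_test_shape <- function(A, B, n_perm = 10000L, seed) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(ncol(A) == ncol(B), nrow(A) >= 2, nrow(B) >= 2)
  perm_test_two_sample(
    rbind(A, B), nrow(A), n_perm, seed,
    stat_fun = function(X, idxA) {
      sqrt(sum((colMeans(X[idxA, , drop = FALSE]) -
                colMeans(X[-idxA, , drop = FALSE]))^2))
    },
    label = "mean shape distance"
  )
}

#' Permutation test for a mean size difference between two groups
#'
#' Test statistic: the absolute difference of group mean centroid sizes
#' (conventionally CEJ-ring centroid sizes, so anterior teeth can be
#' included). Null and p-value as in [permutation_test_shape()].
#'
#' @param sizes_a,sizes_b Numeric vectors of centroid sizes (mm).
#' @inheritParams permutation_test_shape
#' @return A `permutation_test` object.
#' @export
permutation_test_size <- function(sizes_a, sizes_b, n_perm = 10000L, seed) {
  stopifnot(length(sizes_a) >= 2, length(sizes_b) >= 2)
  perm_test_two_sample(
    matrix(c(sizes_a, sizes_b), ncol = 1), length(sizes_a), n_perm, seed,
    stat_fun = function(X, idxA) {
      abs(mean(X[idxA, 1]) - mean(X[-idxA, 1]))
    },
    label = "mean centroid-size difference"
  )
}

perm_test_two_sample <- function(X, nA, n_perm, seed, stat_fun, label) {
  n_perm <- as.integer(n_perm)
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (missing(seed) || is.null(seed)) stop("a seed is required")
  n <- nrow(X)
  observed <- stat_fun(X, seq_len(nA))
  perm_values <- numeric(n_perm)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  for (b in seq_len(n_perm)) {
    perm_values[b] <- stat_fun(X, sample.int(n, nA))
  }
  p <- (sum(perm_values >= observed) + 1) / (n_perm + 1)
  structure(
    list(
      statistic = label, observed = observed, n_perm = n_perm,
      perm_values = perm_values, p_value = p, seed = seed
    ),
    class = "permutation_test"
  )
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' @export
print.permutation_test <- function(x, ...) {
  cat(sprintf("<permutation_test> %s = %.6g, p = %.4g (%d permutations, seed %d)\n",
              x$statistic, x$observed, x$p_value, x$n_perm, x$seed))
  invisible(x)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with decisions at a
#' stated rate `q`.
#'
#' @param pvals Numeric p-values in `[0, 1]` (NAs propagate).
#' @param q FDR level for the decision vector (default 0.05).
#' @return List with `adjusted` (BH-adjusted p-values) and `reject` (logical
#'   decisions at `q`).
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  pv <- as.numeric(pvals)
  if (any(pv < 0 | pv > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  adj <- stats::p.adjust(pv, method = "BH")
  names(adj) <- names(pvals)
  list(adjusted = adj, reject = !is.na(adj) & adj <= q)
}
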