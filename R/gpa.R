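#' Centroid size of a landmark configuration
#'
#' Square root of the summed squared distances of the landmarks to their
#' centroid; the standard size variable of geometric morphometrics.
#'
#' @param coords Numeric matrix k x 3 (k >= 2).
#' @return Positive scalar (same units as the coordinates).
#' @examples
#' cube <- as.matrix(expand.grid(0:1, 0:1, 0:1))
#' centroid_size(cube) # sqrt(6)
#' @export
centroid_size <- function(coords) {
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) >= 2, ncol(coords) == 3)
  cs <- sqrt(sum(sweep(coords, 2, colMeans(coords))^2))
  if (cs < 1e-12) stop("degenerate configuration: centroid size is zero")
  cs
}

#' Optimal proper rotation between two centered configurations
#'
#' Least-squares (Kabsch) rotation `R` minimising `||A R - B||^2` with the
#' constraint `det(R) = +1`: reflections are disallowed, so mirrored shapes
#' are fitted by the best proper rotation rather than flipped.
#'
#' @param A,B Centered k x 3 matrices.
#' @return 3 x 3 rotation matrix with determinant +1.
#' @export
optimal_rotation <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(all(dim(A) == dim(B)), ncol(A) == 3)
  M <- crossprod(A, B)
  sv <- svd(M)
  d <- sign(det(sv$u %*% t(sv$v)))
  if (d == 0) d <- 1  # rank-deficient ambiguous case: canonical choice
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

# rotate whole sample so the mean shape sits in a canonical principal-axes
# orientation; makes GPA output unique (hence input-order invariant).
canonical_orientation <- function(mean_shape) {
  e <- eigen(crossprod(mean_shape), symmetric = TRUE)
  v1 <- e$vectors[, 1]; v2 <- e$vectors[, 2]
  fix_sign <- function(v) {
    proj <- mean_shape %*% v
    if (proj[which.max(abs(proj))] < 0) -v else v
  }
  v1 <- fix_sign(v1); v2 <- fix_sign(v2)
  v3 <- c(v1[2] * v2[3] - v1[3] * v2[2],
          v1[3] * v2[1] - v1[1] * v2[3],
          v1[1] * v2[2] - v1[2] * v2[1])
  cbind(v1, v2, v3)
}

#' Generalised Procrustes superimposition
#'
#' Iterative generalised least-squares superimposition: every configuration
#' is centred, scaled to unit centroid size, and rotated to the current mean
#' shape; the mean is updated (re-normalised to unit centroid size) until its
#' change falls below `tol` or `max_iter` is reached. Scale, location and
#' orientation information is thereby removed. The aligned sample is finally
#' rotated into a canonical principal-axes orientation of the mean so the
#' result does not depend on input order.
#'
#' @param configs List of k x 3 matrices (>= 2, equal k).
#' @param tol Convergence tolerance on the mean-shape change (default 1e-10).
#' @param max_iter Maximum iterations (default 100).
#' @return Object of class `aligned_sample`: `aligned` (list of unit-size
#'   aligned k x 3 matrices), `mean_shape` (unit centroid size),
#'   `centroid_sizes` (original sizes, mm), and per-specimen similarity
#'   transforms (`centers`, `scales`, `rotations`) mapping raw to aligned
#'   coordinates as `aligned = ((raw - center)/scale) %*% rotation`.
#' @export
gpa <- function(configs, tol = 1e-10, max_iter = 100L) {
  n <- length(configs)
  if (n < 2) stop("gpa: need >= 2 configurations")
  k <- nrow(configs[[1]])
  if (!all(vapply(configs, nrow, 1L) == k)) stop("gpa: unequal landmark counts")
  centers <- lapply(configs, function(m) colMeans(as.matrix(m)))
  sizes <- numeric(n)
  X <- vector("list", n)
  for (i in seq_len(n)) {
    m <- sweep(as.matrix(configs[[i]]), 2, centers[[i]])
    sizes[i] <- sqrt(sum(m^2))
    if (sizes[i] < 1e-12) stop("gpa: degenerate configuration ", i)
    X[[i]] <- m / sizes[i]
  }
  rots <- rep(list(diag(3)), n)
  mean_shape <- X[[1]]
  for (iter in seq_len(max_iter)) {
    for (i in seq_len(n)) {
      R <- optimal_rotation(X[[i]], mean_shape)
      X[[i]] <- X[[i]] %*% R
      rots[[i]] <- rots[[i]] %*% R
    }
    new_mean <- Reduce(`+`, X) / n
    new_mean <- new_mean / sqrt(sum(new_mean^2))
    delta <- sqrt(sum((new_mean - mean_shape)^2))
    mean_shape <- new_mean
    if (delta < tol) break
  }
  if (delta >= tol) {
    stop("gpa: no convergence after ", max_iter,
         " iterations (last mean change ", format(delta), ")")
  }
  Rc <- canonical_orientation(mean_shape)
  mean_shape <- mean_shape %*% Rc
  for (i in seq_len(n)) {
    X[[i]] <- X[[i]] %*% Rc
    rots[[i]] <- rots[[i]] %*% Rc
  }
  ids <- names(configs)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  structure(
    list(
      ids = ids, aligned = X, mean_shape = mean_shape,
      centroid_sizes = sizes, centers = centers, scales = sizes,
      rotations = rots, iterations = iter
    ),
    class = "aligned_sample"
  )
}

#' @export
print.aligned_sample <- function(x, ...) {
  cat(sprintf("<aligned_sample> n=%d, k=%d landmarks, %d GPA iterations\n",
              length(x$aligned), nrow(x$mean_shape), x$iterations))
  invisible(x)
}

#' Flatten an aligned sample to an n x 3k coordinate matrix
#'
#' Row i is specimen i's aligned coordinates in (x1, y1, z1, x2, ...) order.
#'
#' @param sample An `aligned_sample`.
#' @return Numeric matrix n x 3k with specimen ids as row names.
#' @export
aligned_matrix <- function(sample) {
  X <- t(vapply(sample$aligned, function(m) as.numeric(t(m)),
                numeric(3L * nrow(sample$mean_shape))))
  rownames(X) <- sample$ids
  X
}

# inverse of aligned_matrix for one row
unflatten_shape <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Total Procrustes variance of an aligned sample
#'
#' Sum of squared deviations of the aligned coordinates from their sample
#' mean, divided by n - 1 (the trace of the coordinate covariance matrix).
#'
#' @param sample An `aligned_sample`.
#' @return Non-negative scalar.
#' @export
procrustes_variance <- function(sample) {
  X <- aligned_matrix(sample)
  sum(sweep(X, 2, colMeans(X))^2) / (nrow(X) - 1)
}
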