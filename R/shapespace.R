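#' Principal component analysis of Procrustes shape coordinates
#'
#' Eigen-decomposition of the covariance of the flattened aligned
#' coordinates (n x 3k). Axis signs follow a deterministic convention: the
#' largest-magnitude loading of each axis is positive. With all components
#' retained, scores reconstruct the aligned coordinates exactly, and the
#' eigenvalues sum to the total Procrustes variance.
#'
#' @param sample An `aligned_sample` from [gpa()] or
#'   [run_sliding_protocol()].
#' @return Object of class `shape_space`: `center` (3k mean coordinate
#'   vector), `mean_shape` (k x 3), `axes` (3k x r orthonormal),
#'   `eigenvalues` (variances, non-increasing), `scores` (n x r),
#'   `k`, `ids`, plus pass-through `groups`/`taxa` when present.
#' @export
shape_pca <- function(sample) {
  X <- aligned_matrix(sample)
  n <- nrow(X)
  if (n < 3) stop("shape_pca: need >= 3 specimens")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  r <- sum(pc$sdev > max(pc$sdev) * 1e-10)
  axes <- pc$rotation[, seq_len(r), drop = FALSE]
  scores <- pc$x[, seq_len(r), drop = FALSE]
  for (j in seq_len(r)) {
    if (axes[which.max(abs(axes[, j])), j] < 0) {
      axes[, j] <- -axes[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(
      center = pc$center,
      mean_shape = unflatten_shape(pc$center),
      axes = axes,
      eigenvalues = pc$sdev[seq_len(r)]^2,
      scores = scores,
      k = nrow(sample$mean_shape),
      ids = sample$ids,
      groups = sample$groups,
      taxa = sample$taxa
    ),
    class = "shape_space"
  )
}

#' @export
print.shape_space <- function(x, ...) {
  pct <- 100 * x$eigenvalues / sum(x$eigenvalues)
  cat(sprintf("<shape_space> n=%d, k=%d, %d components (PC1 %.1f%%, PC2 %.1f%%)\n",
              nrow(x$scores), x$k, length(x$eigenvalues),
              pct[1], ifelse(length(pct) > 1, pct[2], NA)))
  invisible(x)
}

#' Shape at a signed multiple of an axis' standard deviation
#'
#' Returns the landmark configuration `mean + c * sqrt(eigenvalue) * axis`,
#' the geometry used for wireframe visualisations of shape change along a
#' principal component (conventionally at c = +/-1.5).
#'
#' @param space A [shape_pca()] result.
#' @param axis Component index.
#' @param c Standard-deviation multiplier.
#' @return k x 3 landmark matrix.
#' @export
pc_extreme_shape <- function(space, axis, c = 1.5) {
  if (axis < 1 || axis > length(space$eigenvalues)) {
    stop("axis out of range: ", axis)
  }
  v <- space$center + c * sqrt(space$eigenvalues[axis]) * space$axes[, axis]
  unflatten_shape(v)
}

#' Project new configurations into an existing shape space
#'
#' @param space A [shape_pca()] result.
#' @param coords A k x 3 aligned configuration (or list of them) on the same
#'   landmark layout, superimposed consistently with the space's sample.
#' @return Score matrix (rows = configurations).
#' @export
project_into_space <- function(space, coords) {
  if (!is.list(coords)) coords <- list(coords)
  X <- t(vapply(coords, function(m) as.numeric(t(m)), numeric(3L * space$k)))
  sweep(X, 2, space$center) %*% space$axes
}
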