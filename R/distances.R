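#' Pairwise Procrustes-distance distributions within and between groups
#'
#' Procrustes distance is operationalised as the Euclidean distance between
#' jointly superimposed coordinate vectors; all within-group pairs (and all
#' requested between-group pairs) are computed from one joint
#' superimposition. A group of size n yields n(n-1)/2 within-group pairs.
#'
#' @param sample An `aligned_sample`, or an n x 3k coordinate matrix.
#' @param labels Group label per specimen.
#' @param between Between-group pairs to include: `"all"`, `"none"`, or a
#'   list of 2-element character vectors.
#' @return Named list of `distance_distribution` objects (fields `label`,
#'   `type` within/between, `distances`, `n_pairs`, `limit95`).
#' @export
pairwise_distances <- function(sample, labels, between = "all") {
  X <- if (inherits(sample, "aligned_sample")) aligned_matrix(sample) else as.matrix(sample)
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(X))
  D <- as.matrix(stats::dist(X))
  gnames <- sort(unique(labels))
  out <- list()
  for (g in gnames) {
    idx <- which(labels == g)
    if (length(idx) < 2) {
      warning("group '", g, "' has a single member; empty within-group distribution")
      d <- numeric(0)
    } else {
      d <- D[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]
    }
    out[[paste0("within:", g)]] <- new_distance_distribution(g, "within", d)
  }
  pairs <- if (identical(between, "all")) {
    if (length(gnames) >= 2) utils::combn(gnames, 2, simplify = FALSE) else list()
  } else if (identical(between, "none")) list() else between
  for (pr in pairs) {
    idx1 <- which(labels == pr[1]); idx2 <- which(labels == pr[2])
    d <- as.numeric(D[idx1, idx2, drop = FALSE])
    out[[paste0("between:", pr[1], "|", pr[2])]] <-
      new_distance_distribution(paste(pr, collapse = " vs "), "between", d)
  }
  out
}

new_distance_distribution <- function(label, type, distances) {
  structure(
    list(
      label = label, type = type, distances = distances,
      n_pairs = length(distances),
      limit95 = if (length(distances)) limit95(distances) else NA_real_
    ),
    class = "distance_distribution"
  )
}

#' @export
print.distance_distribution <- function(x, ...) {
  cat(sprintf("<distance_distribution> %s (%s): %d pairs, 95%% limit %.6g\n",
              x$label, x$type, x$n_pairs, x$limit95))
  invisible(x)
}

#' 95% limit of a distance distribution
#'
#' Empirical 95th percentile with linear interpolation between closest order
#' statistics (the default quantile definition, type 7). Used as the
#' conspecificity limit: differences beyond a group's within-group limit
#' exceed the variation expected of a single species.
#'
#' @param dist A `distance_distribution` or numeric vector of distances.
#' @param warn_small Warn when fewer than 20 pairs are available.
#' @return The 95th percentile.
#' @export
limit95 <- function(dist, warn_small = TRUE) {
  d <- if (inherits(dist, "distance_distribution")) dist$distances else as.numeric(dist)
  if (!length(d)) stop("limit95: empty distribution")
  if (warn_small && length(d) < 20) {
    warning("limit95: only ", length(d), " pairs; percentile is unstable")
  }
  unname(stats::quantile(d, 0.95, type = 7))
}

#' Flag focal differences that exceed reference within-group limits
#'
#' For each focal value (e.g. the Procrustes distance or dentine-body-height
#' difference between a questioned specimen and each of its conspecifics)
#' and each reference within-group distribution, reports whether the value
#' exceeds the reference's 95% limit, with the margin.
#'
#' @param focal Named numeric vector of focal pairwise differences.
#' @param references List of `distance_distribution` objects (the reference
#'   within-group distributions).
#' @return Data frame with columns `focal`, `value`, `reference`, `limit95`,
#'   `exceeds`, `margin`.
#' @export
exceedance_report <- function(focal, references) {
  focal <- unlist(focal)
  if (is.null(names(focal))) names(focal) <- seq_along(focal)
  rows <- list()
  for (ref in references) {
    for (i in seq_along(focal)) {
      rows[[length(rows) + 1]] <- data.frame(
        focal = names(focal)[i], value = unname(focal[i]),
        reference = ref$label, limit95 = ref$limit95,
        exceeds = unname(focal[i] > ref$limit95),
        margin = unname(focal[i] - ref$limit95)
      )
    }
  }
  do.call(rbind, rows)
}
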