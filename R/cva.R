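#' Canonical variate analysis on a principal-component subset
#'
#' CVA on the first `n_pcs` PC scores of a shape space: canonical axes
#' maximise between-group relative to pooled within-group variance, scaled
#' so the pooled within-group variance per canonical axis is 1 (so Euclidean
#' distance in canonical space is Mahalanobis distance with the pooled
#' within-group covariance). The number of canonical axes is
#' `min(n_groups - 1, n_pcs)`. Working on a small PC subset (conventionally
#' 5-10) keeps the number of variables below the number of specimens.
#'
#' @param space A [shape_pca()] result.
#' @param groups Group label per specimen (factor or character).
#' @param n_pcs Number of leading PCs to use.
#' @param loo Also compute the leave-one-out classification table via
#'   [loo_cv_cva()] (default TRUE).
#' @return Object of class `cva_result`: `axes` (n_pcs x n_cv, in PC-score
#'   space), `scores` (n x n_cv canonical scores), `group_means` (canonical
#'   space), `grand_mean` (PC space), `within_cov` (pooled, PC space),
#'   `classification` (resubstitution table), `accuracy`, and when
#'   `loo = TRUE` the fields `loo_classification`, `loo_accuracy`,
#'   `loo_scores`.
#' @export
cva <- function(space, groups, n_pcs, loo = TRUE) {
  X <- space$scores[, seq_len(n_pcs), drop = FALSE]
  fit <- cva_core(X, groups)
  fit$n_pcs <- n_pcs
  fit$space <- space
  pred <- cva_classify(fit, fit$scores)
  fit$classification <- table(truth = fit$groups, predicted = pred)
  fit$accuracy <- mean(pred == fit$groups)
  if (loo) {
    cv <- loo_cv_cva(space, groups, n_pcs)
    fit$loo_classification <- cv$classification
    fit$loo_accuracy <- cv$accuracy
    fit$loo_scores <- cv$scores
  }
  class(fit) <- "cva_result"
  fit
}

# core CVA solve on an n x p score matrix
cva_core <- function(X, groups) {
  groups <- as.character(groups)
  n <- nrow(X); p <- ncol(X)
  tab <- table(groups)
  g <- length(tab)
  if (g < 2) stop("cva: need >= 2 groups")
  if (any(tab < 2)) stop("cva: every group needs >= 2 members")
  if (n <= p) stop("cva: number of specimens must exceed number of variables")
  grand <- colMeans(X)
  means <- rowsum(X, groups) / as.numeric(tab)
  W <- matrix(0, p, p)
  for (gn in names(tab)) {
    Xi <- X[groups == gn, , drop = FALSE]
    W <- W + crossprod(sweep(Xi, 2, colMeans(Xi)))
  }
  W <- W / (n - g)
  Mc <- sweep(means, 2, grand)
  B <- crossprod(Mc * sqrt(as.numeric(tab))) / (g - 1)
  eW <- eigen(W, symmetric = TRUE)
  if (min(eW$values) < max(eW$values) * 1e-10) {
    stop("cva: singular pooled within-group covariance; use fewer PCs")
  }
  Wih <- eW$vectors %*% (t(eW$vectors) / sqrt(eW$values))
  M <- t(Wih) %*% B %*% Wih
  M <- (M + t(M)) / 2
  eM <- eigen(M, symmetric = TRUE)
  ncv <- as.integer(min(g - 1, p))
  A <- Wih %*% eM$vectors[, seq_len(ncv), drop = FALSE]  # a' W a = 1 per axis
  # deterministic sign: largest-magnitude coefficient positive
  for (j in seq_len(ncv)) {
    if (A[which.max(abs(A[, j])), j] < 0) A[, j] <- -A[, j]
  }
  scores <- sweep(X, 2, grand) %*% A
  gm <- sweep(means, 2, grand) %*% A
  list(
    axes = A, eigenvalues = eM$values[seq_len(ncv)],
    scores = scores, group_means = gm, group_names = rownames(gm),
    group_sizes = as.numeric(tab),
    grand_mean = grand, within_cov = W, groups = groups, n_cv = ncv
  )
}

# nearest canonical-space group mean (Mahalanobis, pooled covariance)
cva_classify <- function(fit, cv_scores) {
  d2 <- vapply(seq_len(nrow(fit$group_means)), function(gi) {
    rowSums(sweep(cv_scores, 2, fit$group_means[gi, ])^2)
  }, numeric(nrow(cv_scores)))
  if (is.null(dim(d2))) d2 <- matrix(d2, nrow = 1)
  fit$group_names[apply(d2, 1, which.min)]
}

#' @export
print.cva_result <- function(x, ...) {
  cat(sprintf("<cva_result> %d groups, %d PCs, %d canonical axes, resub acc %.3f",
              length(x$group_names), x$n_pcs, x$n_cv, x$accuracy))
  if (!is.null(x$loo_accuracy)) cat(sprintf(", LOO acc %.3f", x$loo_accuracy))
  cat("\n")
  invisible(x)
}

#' Leave-one-out cross-validated CVA
#'
#' Each specimen is scored and classified by a CVA refitted without it,
#' exposing spurious group separation that resubstitution hides. Fully
#' deterministic.
#'
#' @inheritParams cva
#' @return List with `scores` (each specimen's canonical scores under its
#'   held-out fit), `predicted`, `classification` table and `accuracy`.
#' @export
loo_cv_cva <- function(space, groups, n_pcs) {
  groups <- as.character(groups)
  X <- space$scores[, seq_len(n_pcs), drop = FALSE]
  tab <- table(groups)
  if (length(tab) < 2) stop("loo_cv_cva: need >= 2 groups")
  if (any(tab < 3)) stop("loo_cv_cva: every group needs >= 3 members to refit")
  n <- nrow(X)
  ncv <- min(length(tab) - 1, n_pcs)
  scores <- matrix(NA_real_, n, ncv)
  pred <- character(n)
  for (i in seq_len(n)) {
    fit <- cva_core(X[-i, , drop = FALSE], groups[-i])
    sc <- matrix(X[i, ] - fit$grand_mean, 1) %*% fit$axes
    scores[i, ] <- sc[, seq_len(ncv)]
    pred[i] <- cva_classify(fit, sc)
  }
  list(
    scores = scores, predicted = pred,
    classification = table(truth = groups, predicted = pred),
    accuracy = mean(pred == groups)
  )
}

#' Select the PC-subset size by cross-validated accuracy
#'
#' Fits one CVA per candidate subset size (default 5-10, i.e. 6 fits) and
#' returns the candidate with the highest leave-one-out classification
#' accuracy; ties are broken towards fewer PCs. Infeasible candidates (too
#' few specimens, singular covariance) are skipped with a warning.
#'
#' @inheritParams cva
#' @param candidates Candidate numbers of PCs (default `5:10`).
#' @return List with `n_pcs` (selected), `accuracies` (named per candidate,
#'   NA when skipped) and `n_fits` (number of CVA fits performed).
#' @export
select_n_pcs <- function(space, groups, candidates = 5:10) {
  acc <- rep(NA_real_, length(candidates))
  names(acc) <- candidates
  n_fits <- 0L
  for (j in seq_along(candidates)) {
    p <- candidates[j]
    if (p > ncol(space$scores)) {
      warning("skipping infeasible candidate n_pcs = ", p)
      next
    }
    res <- tryCatch(loo_cv_cva(space, groups, p), error = function(e) NULL)
    n_fits <- n_fits + 1L
    if (is.null(res)) {
      warning("skipping infeasible candidate n_pcs = ", p)
      next
    }
    acc[j] <- res$accuracy
  }
  if (all(is.na(acc))) stop("select_n_pcs: no feasible candidate")
  best <- candidates[which.max(acc)]  # which.max: first max -> fewest PCs
  list(n_pcs = best, accuracies = acc, n_fits = n_fits)
}

#' Typicality probability of a point for each group
#'
#' Tail probability that a group member lies as far from the group mean
#' (Mahalanobis distance) as the query point: the upper tail of a chi-square
#' law with degrees of freedom equal to the dimensionality of the canonical
#' space. A point at a group mean has typicality 1; typicality decreases
#' monotonically with distance.
#'
#' @param cv_score Numeric vector, canonical scores of the query point.
#' @param group_means Matrix (groups x n_cv) of canonical group means.
#' @param within_cov Covariance of the canonical space (identity under the
#'   scaling used by [cva()]; supplied for generality).
#' @return Named numeric vector of typicality probabilities in `[0, 1]`.
#' @export
typicality_probability <- function(cv_score, group_means,
                                   within_cov = diag(length(cv_score))) {
  cv_score <- as.numeric(cv_score)
  p <- length(cv_score)
  ev <- eigen(within_cov, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < max(ev) * 1e-12) stop("typicality: singular covariance")
  Wi <- solve(within_cov)
  d2 <- apply(group_means, 1, function(m) {
    dv <- cv_score - m
    as.numeric(dv %*% Wi %*% dv)
  })
  out <- stats::pchisq(d2, df = p, lower.tail = FALSE)
  names(out) <- rownames(group_means)
  out
}

#' Classify an unknown specimen across candidate PC-subset CVAs
#'
#' Projects an aligned unknown configuration into the shape space, then into
#' a CVA fitted on the labelled sample for each candidate PC-subset size,
#' and computes typicality probabilities for every group. Per candidate, the
#' specimen is assigned the group of highest typicality if any typicality
#' reaches `threshold`, else "unclassified" (the conservative convention:
#' threshold 0.1). The summary label is the modal outcome across candidates.
#'
#' @param space A [shape_pca()] result for the labelled sample.
#' @param groups Group labels of the labelled sample.
#' @param unknown_coords k x 3 aligned configuration of the unknown (same
#'   layout and superimposition frame).
#' @param candidates Candidate PC-subset sizes (default `5:10`).
#' @param threshold Typicality threshold (default 0.1).
#' @return List with `label` (modal outcome), `detail` (one row per
#'   candidate: n_pcs, best group, its typicality, outcome) and
#'   `typicalities` (candidates x groups matrix).
#' @export
classify_unknown <- function(space, groups, unknown_coords, candidates = 5:10,
                             threshold = 0.1) {
  pc_all <- as.numeric(project_into_space(space, unknown_coords))
  groups <- as.character(groups)
  gnames <- sort(unique(groups))
  typ <- matrix(NA_real_, length(candidates), length(gnames),
                dimnames = list(candidates, gnames))
  outcome <- character(length(candidates))
  best_group <- character(length(candidates))
  best_typ <- numeric(length(candidates))
  for (j in seq_along(candidates)) {
    p <- candidates[j]
    if (p > length(pc_all)) { outcome[j] <- NA_character_; next }
    fit <- tryCatch(cva_core(space$scores[, seq_len(p), drop = FALSE], groups),
                    error = function(e) NULL)
    if (is.null(fit)) { outcome[j] <- NA_character_; next }
    sc <- matrix(pc_all[seq_len(p)] - fit$grand_mean, 1) %*% fit$axes
    tp <- typicality_probability(as.numeric(sc), fit$group_means)
    typ[j, names(tp)] <- tp
    bi <- which.max(tp)
    best_group[j] <- names(tp)[bi]
    best_typ[j] <- tp[bi]
    outcome[j] <- if (tp[bi] >= threshold) names(tp)[bi] else "unclassified"
  }
  valid <- outcome[!is.na(outcome)]
  label <- if (length(valid)) names(sort(table(valid), decreasing = TRUE))[1]
           else NA_character_
  list(
    label = label,
    detail = data.frame(
      n_pcs = candidates, best_group = best_group,
      best_typicality = best_typ, outcome = outcome
    ),
    typicalities = typ
  )
}
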