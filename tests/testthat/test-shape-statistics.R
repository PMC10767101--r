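test_that("PCA conserves variance and reconstructs coordinates", {
  cfgs <- noisy_p3_configs(8, seed = 61)
  al <- gpa(lapply(cfgs, `[[`, "coords"))
  space <- shape_pca(al)
  X <- aligned_matrix(al)
  total_var <- sum(apply(X, 2, var))
  expect_equal(sum(space$eigenvalues), total_var, tolerance = 1e-10)
  # full reconstruction from all retained components
  Xhat <- sweep(space$scores %*% t(space$axes), 2, space$center, `+`)
  expect_equal(Xhat, X, tolerance = 1e-8, ignore_attr = TRUE)
  # duplicating every specimen leaves axes and eigenvalue ratios unchanged
  al2 <- al
  al2$aligned <- c(al$aligned, al$aligned)
  al2$ids <- c(al$ids, paste0(al$ids, "b"))
  space2 <- shape_pca(al2)
  r <- length(space$eigenvalues)
  expect_equal(unname(abs(diag(crossprod(space$axes, space2$axes[, seq_len(r)])))),
               rep(1, r), tolerance = 1e-6)
})

test_that("PC extreme shapes obey linearity and score identities", {
  cfgs <- noisy_p3_configs(6, seed = 62)
  space <- shape_pca(gpa(lapply(cfgs, `[[`, "coords")))
  expect_equal(pc_extreme_shape(space, 1, 0), space$mean_shape)
  plus <- pc_extreme_shape(space, 1, 1.5)
  minus <- pc_extreme_shape(space, 1, -1.5)
  expect_equal((plus + minus) / 2, space$mean_shape, tolerance = 1e-12)
  sc <- project_into_space(space, plus)
  expect_equal(unname(sc[1, 1]), unname(1.5 * sqrt(space$eigenvalues[1])),
               tolerance = 1e-8)
  expect_lt(max(abs(sc[1, -1])), 1e-8)
  expect_error(pc_extreme_shape(space, 99, 1), "out of range")
})

test_that("groups differing in dentine body height separate on PC1", {
  tpl_a <- p3_template()
  tpl_b <- p3_template(body_height = tpl_a$body_height * 1.2)
  noise <- 0.02  # low-noise regime
  cfgs <- c(noisy_p3_configs(8, noise, seed = 63, group = "A", template = tpl_a),
            noisy_p3_configs(8, noise, seed = 64, group = "B", template = tpl_b))
  al <- gpa(lapply(cfgs, `[[`, "coords"))
  space <- shape_pca(al)
  g <- rep(c("A", "B"), each = 8)
  gap <- abs(mean(space$scores[g == "A", 1]) - mean(space$scores[g == "B", 1]))
  sd_within <- max(sd(space$scores[g == "A", 1]), sd(space$scores[g == "B", 1]))
  expect_gt(gap, 2 * sd_within)
})

test_that("CVA axis count and two-group axis match a direct discriminant solve", {
  set.seed(65)
  n <- 30
  X <- matrix(rnorm(n * 12), n, 12)
  g3 <- rep(c("a", "b", "c"), each = 10)
  X[g3 == "b", 1] <- X[g3 == "b", 1] + 3
  X[g3 == "c", 2] <- X[g3 == "c", 2] + 3
  space <- shape_pca(make_aligned(X, 4))
  fit3 <- cva(space, g3, n_pcs = 6, loo = FALSE)
  expect_identical(fit3$n_cv, 2L)  # min(3 - 1, 6)
  # two-group case: canonical axis collinear with W^{-1}(m1 - m2)
  g2 <- rep(c("a", "b"), each = 15)
  X2 <- matrix(rnorm(n * 12), n, 12)
  X2[g2 == "b", 3] <- X2[g2 == "b", 3] + 2
  space2 <- shape_pca(make_aligned(X2, 4))
  fit2 <- cva(space2, g2, n_pcs = 5, loo = FALSE)
  S <- space2$scores[, 1:5]
  m1 <- colMeans(S[g2 == "a", ]); m2 <- colMeans(S[g2 == "b", ])
  W <- (crossprod(sweep(S[g2 == "a", ], 2, m1)) +
        crossprod(sweep(S[g2 == "b", ], 2, m2))) / (n - 2)
  dir <- solve(W, m1 - m2)
  cosang <- abs(sum(dir * fit2$axes[, 1])) /
    sqrt(sum(dir^2) * sum(fit2$axes[, 1]^2))
  expect_gte(cosang, 1 - 1e-8)
})

test_that("CVA agrees with lda on group assignment of separated clusters", {
  skip_if_not_installed("MASS")
  set.seed(66)
  X <- matrix(rnorm(36 * 15), 36, 15)
  g <- rep(c("a", "b", "c"), each = 12)
  X[g == "b", 1] <- X[g == "b", 1] + 4
  X[g == "c", 2] <- X[g == "c", 2] + 4
  space <- shape_pca(make_aligned(X, 5))
  fit <- cva(space, g, n_pcs = 6, loo = FALSE)
  pred_pkg <- edjmorph:::cva_classify(fit, fit$scores)
  S <- space$scores[, 1:6]
  pred_lda <- as.character(predict(MASS::lda(S, grouping = g))$class)
  expect_gt(mean(pred_pkg == pred_lda), 0.97)
})

test_that("random labels give high resubstitution but chance-level LOO accuracy", {
  set.seed(67)
  X <- matrix(rnorm(30 * 30), 30, 30)  # isotropic noise, no real groups
  g <- rep(c("a", "b", "c"), each = 10)
  space <- shape_pca(make_aligned(X, 10))
  fit <- cva(space, g, n_pcs = 10)
  expect_gt(fit$accuracy, 1 / 3)  # resubstitution overfits
  # LOO accuracy within the binomial 95% interval around chance (1/3)
  ci <- qbinom(c(0.025, 0.975), 30, 1 / 3) / 30
  expect_gte(fit$loo_accuracy, ci[1])
  expect_lte(fit$loo_accuracy, ci[2])
  # determinism
  expect_identical(loo_cv_cva(space, g, 10)$accuracy, fit$loo_accuracy)
})

test_that("perfectly separated groups cross-validate at 100%", {
  set.seed(68)
  X <- matrix(rnorm(24 * 12, sd = 0.1), 24, 12)
  g <- rep(c("a", "b"), each = 12)
  X[g == "b", 1] <- X[g == "b", 1] + 10
  space <- shape_pca(make_aligned(X, 4))
  expect_identical(loo_cv_cva(space, g, 5)$accuracy, 1)
  expect_error(cva(space, rep("a", 24), 5), "2 groups")
})

test_that("the PC sweep performs 6 fits and breaks ties towards fewer PCs", {
  set.seed(69)
  X <- matrix(rnorm(40 * 15), 40, 15)
  g <- rep(c("a", "b"), each = 20)
  X[g == "b", 1] <- X[g == "b", 1] + 8  # signal entirely in PC1
  space <- shape_pca(make_aligned(X, 5))
  res <- select_n_pcs(space, g, candidates = 5:10)
  expect_identical(res$n_fits, 6L)
  # all candidates include PC1, so accuracies tie at 1 -> smallest wins
  expect_true(all(res$accuracies == 1))
  expect_identical(res$n_pcs, 5L)
})

test_that("the sweep finds the candidate that spans the signal subspace", {
  set.seed(70)
  n <- 48
  X <- matrix(rnorm(n * 15), n, 15)
  g <- rep(c("a", "b"), each = n / 2)
  # strong nuisance variance on 6 group-blind directions, group signal on the
  # 7th-largest variance direction: only candidates >= 7 can separate
  X[, 1:6] <- X[, 1:6] * 8
  X[g == "b", 7] <- X[g == "b", 7] + 8
  space <- shape_pca(make_aligned(X, 5))
  res <- select_n_pcs(space, g, candidates = 5:10)
  expect_identical(res$n_pcs, 7L)
  expect_gt(res$accuracies["7"], max(res$accuracies[c("5", "6")]))
})

test_that("typicality follows the chi-square tail law", {
  gm <- rbind(a = c(0, 0), b = c(5, 0))
  expect_equal(unname(typicality_probability(c(0, 0), gm)["a"]), 1)
  # monotone decrease with distance
  t1 <- typicality_probability(c(1, 0), gm)["a"]
  t2 <- typicality_probability(c(2, 0), gm)["a"]
  expect_gt(t1, t2)
  # chi-square quantile oracle: D = 2.4477 in 2 dimensions -> p ~ 0.05
  D <- sqrt(qchisq(0.95, df = 2))
  expect_equal(unname(typicality_probability(c(D, 0), gm)["a"]), 0.05,
               tolerance = 1e-6)
  expect_error(typicality_probability(c(0, 0), gm, matrix(0, 2, 2)), "singular")
})

test_that("unknown classification follows the 0.1 typicality rule", {
  set.seed(71)
  n <- 45
  X <- matrix(rnorm(n * 12), n, 12)
  g <- rep(c("a", "b", "c"), each = 15)
  X[g == "b", 1] <- X[g == "b", 1] + 6
  X[g == "c", 2] <- X[g == "c", 2] + 6
  k <- 4
  space <- shape_pca(make_aligned(X, k))
  # an unknown drawn from group b's distribution classifies as b throughout
  unknown_b <- matrix(colMeans(X[g == "b", ]) + rnorm(12, sd = 0.2), k, 3,
                      byrow = TRUE)
  res <- classify_unknown(space, g, unknown_b, candidates = 5:10)
  expect_identical(res$label, "b")
  expect_true(all(res$detail$outcome == "b"))
  expect_identical(nrow(res$detail), 6L)
  # an unknown far from every group is unclassified everywhere
  far <- matrix(colMeans(X) + 60 * apply(X, 2, sd), k, 3, byrow = TRUE)
  res2 <- classify_unknown(space, g, far, candidates = 5:10)
  expect_identical(res2$label, "unclassified")
  expect_true(all(res2$typicalities < 0.1, na.rm = TRUE))
})

test_that("permutation tests honour their boundary cases and conventions", {
  set.seed(72)
  A <- matrix(rnorm(5 * 9), 5, 9)
  # identical groups: observed statistic 0, p = 1
  t0 <- permutation_test_shape(A, A, n_perm = 99, seed = 1)
  expect_equal(t0$observed, 0)
  expect_equal(t0$p_value, 1)
  # overwhelming separation: only permutations recreating the original
  # split can tie the observed statistic, so p sits at the attainable floor
  B <- A + 50
  t1 <- permutation_test_shape(A, B, n_perm = 999, seed = 2)
  n_tie <- sum(t1$perm_values >= t1$observed)
  expect_equal(t1$p_value, (n_tie + 1) / 1000)
  expect_lte(t1$p_value, 0.02)
  sizes_a <- rnorm(8, 100, 1)
  t2 <- permutation_test_size(sizes_a, sizes_a + 30, n_perm = 999, seed = 3)
  expect_lte(t2$p_value, 0.01)
  t3 <- permutation_test_size(sizes_a, sizes_a, n_perm = 99, seed = 4)
  expect_equal(t3$p_value, 1)
  # reproducibility and p-convention invariant
  t4 <- permutation_test_shape(A, A + 0.5, n_perm = 199, seed = 5)
  t5 <- permutation_test_shape(A, A + 0.5, n_perm = 199, seed = 5)
  expect_identical(t4$p_value, t5$p_value)
  expect_equal(t4$p_value,
               (sum(t4$perm_values >= t4$observed) + 1) / (t4$n_perm + 1))
  expect_error(permutation_test_shape(A, B, n_perm = 99), "seed")
})

test_that("Benjamini-Hochberg adjustment matches the step-up formula", {
  expect_equal(benjamini_hochberg(0.03)$adjusted, 0.03)
  expect_equal(benjamini_hochberg(rep(0.2, 4))$adjusted, rep(0.2, 4))
  res <- benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04, 0.05), q = 0.05)
  expect_equal(res$adjusted, rep(0.05, 5))
  expect_true(all(res$reject))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})
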