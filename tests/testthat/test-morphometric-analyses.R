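test_that("pairwise distance distributions have the right pair counts", {
  set.seed(81)
  X <- matrix(rnorm(9 * 12), 9, 12)
  labels <- c(rep("g1", 5), rep("g2", 4))
  dd <- suppressWarnings(pairwise_distances(X, labels))
  expect_identical(dd[["within:g1"]]$n_pairs, 10L)  # 5 choose 2
  expect_identical(dd[["within:g2"]]$n_pairs, 6L)
  expect_identical(dd[["between:g1|g2"]]$n_pairs, 20L)
  # duplicate shapes give zero distances
  X2 <- X[rep(1, 4), ]
  dd2 <- suppressWarnings(pairwise_distances(X2, rep("g", 4)))
  expect_true(all(dd2[["within:g"]]$distances == 0))
  # single-member group warns and yields an empty distribution
  w <- capture_warnings(dd3 <- pairwise_distances(X, c("solo", labels[-1])))
  expect_true(any(grepl("single member", w)))
  expect_identical(dd3[["within:solo"]]$n_pairs, 0L)
})

test_that("joint-superimposition distances track per-pair Procrustes fits", {
  cfgs <- noisy_p3_configs(6, noise_sd = 0.04, seed = 82)
  al <- gpa(lapply(cfgs, `[[`, "coords"))
  X <- aligned_matrix(al)
  dd <- suppressWarnings(pairwise_distances(X, rep("g", 6)))
  d_joint <- dd[["within:g"]]$distances
  # oracle: ordinary Procrustes distance per pair (two-shape GPA)
  pair_idx <- which(upper.tri(matrix(0, 6, 6)), arr.ind = TRUE)
  # upper.tri indexing matches dist() ordering used by pairwise_distances
  d_opa <- apply(pair_idx, 1, function(ij) {
    a2 <- gpa(list(cfgs[[ij[1]]]$coords, cfgs[[ij[2]]]$coords))
    sqrt(sum((a2$aligned[[1]] - a2$aligned[[2]])^2))
  })
  expect_lt(max(abs(sort(d_joint) - sort(d_opa)) / sort(d_opa)), 0.01)
})

test_that("the 95% limit follows the interpolated-percentile definition", {
  d <- as.numeric(1:100)
  expect_equal(limit95(d, warn_small = FALSE),
               unname(quantile(d, 0.95, type = 7)))
  # sort-and-index oracle for type-7 interpolation
  h <- (100 - 1) * 0.95 + 1
  oracle <- d[floor(h)] + (h - floor(h)) * (d[ceiling(h)] - d[floor(h)])
  expect_equal(limit95(d, warn_small = FALSE), oracle)
  expect_equal(limit95(rep(3.5, 30)), 3.5)
  # monotonicity: appending a value above the limit never lowers it
  l0 <- limit95(d, warn_small = FALSE)
  expect_gte(limit95(c(d, 200), warn_small = FALSE), l0)
  expect_error(limit95(numeric(0)), "empty")
})

test_that("exceedance reports flag exactly the limit-crossing comparisons", {
  refs <- list(
    edjmorph:::new_distance_distribution("r1", "within", seq(0, 1, length.out = 50)),
    edjmorph:::new_distance_distribution("r2", "within", seq(0, 2, length.out = 50))
  )
  rep1 <- exceedance_report(c(pairA = 0.1), refs)
  expect_false(any(rep1$exceeds))
  rep2 <- exceedance_report(c(pairB = 1.5), refs)
  expect_identical(rep2$exceeds, c(TRUE, FALSE))
  expect_equal(rep2$margin, rep2$value - rep2$limit95)
})

test_that("dentine body height has its closed form and invariances", {
  layout <- landmark_layout(p3_class())
  spec <- default_dbh_spec(layout)
  # synthetic configuration: ridge subset at height h above cervix subset
  h <- 0.37
  coords <- matrix(rnorm(layout$n_total * 3, sd = 0.001), layout$n_total, 3)
  coords[spec$ridge_idx, ] <- matrix(c(0, 0, h), length(spec$ridge_idx), 3,
                                     byrow = TRUE)
  coords[spec$cej_idx, ] <- 0
  expect_equal(dentine_body_height(coords, spec), h)
  # rigid motion invariance, linear scaling
  set.seed(83)
  R <- rand_rotation()
  moved <- sweep(coords %*% R, 2, c(4, -7, 2), `+`)
  expect_equal(dentine_body_height(moved, spec),
               dentine_body_height(coords, spec), tolerance = 1e-12)
  expect_equal(dentine_body_height(coords * 2.5, spec), 2.5 * h)
  # validation
  expect_error(dbh_spec(layout, 3:7, 23:26, 50:54, 60:64), "unequal")
  expect_error(dbh_spec(layout, 3:7, 23:27, 500:504, 510:514), "out of layout")
})

test_that("lower-molar defaults split the distal subset around the hypoconulid", {
  layout <- landmark_layout(m1_class())
  spec <- default_dbh_spec(layout)
  im <- layout_index_map(layout)
  # distal subsets sit in ridge section 3 in two disjoint runs that skip the
  # central (hypoconulid) position
  expect_true(all(spec$ridge_distal %in% im$ridge3))
  mid <- im$ridge3[ceiling(length(im$ridge3) / 2)]
  expect_false(mid %in% spec$ridge_distal)
  runs <- split(spec$ridge_distal,
                cumsum(c(1, diff(spec$ridge_distal) != 1)))
  expect_length(runs, 2)
  expect_length(spec$ridge_mesial, length(spec$ridge_distal))
})

test_that("recovered DBH rises monotonically with the generator's body height", {
  base <- p3_template()
  deltas <- c(0, 0.1, 0.2, 0.4)
  vals <- vapply(deltas, function(d) {
    template_truth_dbh(p3_template(body_height = base$body_height * (1 + d)))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # noiseless specimen DBH within 2% of H/CS of the template
  sp <- realize_specimen(base, "t", pose = "identity")
  cfg <- build_homologous_configuration(sp)
  expect_equal(template_truth_dbh(base),
               base$body_height / centroid_size(cfg$coords),
               tolerance = 0.02)
})

test_that("DBH difference distributions mirror the distance machinery", {
  cfgs <- noisy_p3_configs(6, seed = 84)
  al <- run_sliding_protocol(cfgs)
  spec <- default_dbh_spec(cfgs[[1]]$layout)
  res <- suppressWarnings(
    dbh_distribution_analysis(al, rep("g", 6), spec, between = "none")
  )
  expect_identical(res$distributions[["within:g"]]$n_pairs, 15L)
  expect_true(all(res$distributions[["within:g"]]$distances >= 0))
  # identical specimens give all-zero differences
  al0 <- al
  al0$aligned <- rep(al$aligned[1], 4)
  al0$ids <- as.character(1:4)
  res0 <- suppressWarnings(
    dbh_distribution_analysis(al0, rep("g", 4), spec, between = "none")
  )
  expect_true(all(res0$distributions[["within:g"]]$distances == 0))
})

test_that("tooth-row size profiles shift, order and bound correctly", {
  sizes <- data.frame(
    specimen_id = rep(c("ind1", "ind2"), each = 3),
    group = "G",
    tooth = rep(c("P3", "M1", "M2"), 2),
    cs = c(10, 14, 12, 20, 28, 24)  # ind2 = doubled ind1
  )
  prof <- toothrow_size_profile(sizes)
  tr <- prof$traces
  expect_equal(unname(tr["ind2", c("P3", "M1", "M2")] -
                      tr["ind1", c("P3", "M1", "M2")]),
               rep(log(2), 3))
  expect_true(size_pattern(prof, "ind1", "M1", "M2"))
  expect_true(is.na(size_pattern(prof, "ind1", "I1", "M1")))
  env <- prof$envelopes$G
  for (pos in c("P3", "M1", "M2")) {
    vals <- tr[, pos]
    expect_gte(min(vals, na.rm = TRUE), env["min", pos])
    expect_lte(max(vals, na.rm = TRUE), env["max", pos])
  }
})
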