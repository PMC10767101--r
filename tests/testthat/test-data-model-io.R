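test_that("layouts fix the landmark counts per tooth class", {
  cases <- list(
    list(tooth_class("P3", "mandibular"), 2L, c(20L, 25L), 87L),
    list(tooth_class("P4", "maxillary"), 2L, c(20L, 25L), 87L),
    list(tooth_class("M1", "mandibular"), 4L, rep(20L, 4), 124L),
    list(tooth_class("M3", "maxillary"), 4L, rep(20L, 4), 124L),
    list(tooth_class("I1", "mandibular"), 0L, integer(0), 40L),
    list(tooth_class("C", "maxillary"), 0L, integer(0), 40L)
  )
  for (cs in cases) {
    ly <- landmark_layout(cs[[1]])
    expect_identical(ly$n_fixed, cs[[2]])
    expect_identical(ly$ridge_section_counts, cs[[3]])
    expect_identical(ly$n_cej, 40L)
    expect_identical(ly$n_total, cs[[4]])
    im <- layout_index_map(ly)
    all_idx <- sort(unlist(im, use.names = FALSE))
    expect_identical(all_idx, seq_len(ly$n_total))  # disjoint and covering
    expect_identical(length(ly$fixed_names), as.integer(ly$n_fixed))
  }
})

test_that("landmark files round-trip losslessly in both dialects", {
  sp <- realize_specimen(p3_template(), "rt1", noise_sd = 0.05, seed = 7,
                         taxon = "T", group = "G")
  for (fmt in c("tps", "csv")) {
    f <- tempfile(fileext = paste0(".", fmt))
    write_landmark_file(sp, f, format = fmt)
    back <- read_landmark_file(f, p3_class(), taxon = "T", group = "G")
    expect_equal(back$fixed_points, sp$fixed_points, tolerance = 1e-6)
    expect_equal(back$edj_ridge_points, sp$edj_ridge_points, tolerance = 1e-6)
    expect_equal(back$cej_points, sp$cej_points, tolerance = 1e-6)
    # second round-trip is exact (quantisation already applied)
    f2 <- tempfile(fileext = paste0(".", fmt))
    write_landmark_file(back, f2, format = fmt)
    back2 <- read_landmark_file(f2, p3_class())
    expect_identical(back2$cej_points, back$cej_points)
    unlink(c(f, f2))
  }
})

test_that("reader rejects malformed files and layout mismatches", {
  sp <- realize_specimen(p3_template(), "bad", seed = 8)
  f <- tempfile(fileext = ".tps")
  write_landmark_file(sp, f)
  # a premolar file read against a molar layout: fixed-point count mismatch
  expect_error(read_landmark_file(f, m1_class()), "fixed-point count mismatch")
  # corrupt a coordinate line
  lines <- readLines(f)
  lines[3] <- "1.0 not_a_number 2.0"
  writeLines(lines, f)
  expect_error(read_landmark_file(f, p3_class()), "line 3")
  unlink(f)
})

test_that("mirroring is an involution that preserves geometry", {
  right <- realize_specimen(p3_template(), "r1", noise_sd = 0.05, seed = 9)
  expect_identical(mirror_to_right(right), right)  # right stays unchanged
  left <- realize_specimen(p3_template(), "l1", noise_sd = 0.05, seed = 9,
                           side = "left")
  mirrored <- mirror_to_right(left)
  expect_identical(mirrored$side, "right")
  # involution: re-expressing as left and mirroring again is the identity
  twice <- mirror_to_right(
    raw_specimen("l1", p3_class(),
                 {m <- mirrored$fixed_points; m[, 1] <- -m[, 1]; m},
                 {m <- mirrored$edj_ridge_points; m[, 1] <- -m[, 1]
                  m[c(1, nrow(m):2), ]},
                 {m <- mirrored$cej_points; m[, 1] <- -m[, 1]
                  m[c(1, nrow(m):2), ]},
                 side = "left")
  )
  expect_equal(twice$cej_points, mirrored$cej_points, tolerance = 1e-12)
  # centroid size and inter-landmark distances are preserved exactly
  expect_equal(centroid_size(mirrored$cej_points), centroid_size(left$cej_points))
  expect_equal(sort(as.numeric(dist(mirrored$edj_ridge_points))),
               sort(as.numeric(dist(left$edj_ridge_points))))
})

test_that("a mirrored antimere superimposes on its right twin at noise level", {
  # bilaterally asymmetric template: reflection is not a rotation
  tpl <- p3_template(talonid_reduction = 0.25, horn_heights = c(2.2, 1.2),
                     cej_wave = 0.3)
  noise <- 0.05
  right <- realize_specimen(tpl, "twinR", noise_sd = noise, seed = 11)
  left <- realize_specimen(tpl, "twinL", noise_sd = noise, seed = 12,
                           side = "left")
  cfg_r <- build_homologous_configuration(right)
  cfg_m <- build_homologous_configuration(mirror_to_right(left))
  cfg_l_unmirrored <- build_homologous_configuration(
    raw_specimen("raw_left", p3_class(), left$fixed_points,
                 left$edj_ridge_points, left$cej_points, side = "right")
  )
  d_mirrored <- sqrt(sum((do.call(rbind, gpa(list(cfg_r$coords, cfg_m$coords))$aligned) |>
    (\(x) x[1:87, ] - x[88:174, ])())^2))
  d_raw <- sqrt(sum((do.call(rbind, gpa(list(cfg_r$coords, cfg_l_unmirrored$coords))$aligned) |>
    (\(x) x[1:87, ] - x[88:174, ])())^2))
  # mirrored distance is noise-scale; unmirrored reflection is much larger
  expect_lt(d_mirrored, 0.1)
  expect_gt(d_raw, 2 * d_mirrored)
})

test_that("manifest loading validates columns, keys and paths", {
  dir <- tempfile("man_")
  res <- generate_cohort(cohort_spec(list(
    group_spec("A", p3_template(), 3)
  ), seed = 21), dir)
  mf <- res$manifest
  expect_s3_class(mf, "edj_manifest")
  expect_identical(nrow(mf), 3L)
  # duplicate key rejected
  df <- utils::read.csv(res$manifest_path)
  dup <- rbind(df, df[1, ])
  f <- file.path(dir, "dup.csv")
  utils::write.csv(dup, f, row.names = FALSE)
  expect_error(load_manifest(f), "duplicate")
  # missing column rejected
  f2 <- file.path(dir, "short.csv")
  utils::write.csv(df[, -2], f2, row.names = FALSE)
  expect_error(load_manifest(f2), "missing column")
  # dangling path rejected
  df$path[1] <- "no_such_file.tps"
  f3 <- file.path(dir, "dangling.csv")
  utils::write.csv(df, f3, row.names = FALSE)
  expect_error(load_manifest(f3), "missing file")
  unlink(dir, recursive = TRUE)
})

test_that("reference class counts expand to a consistent 712-tooth manifest", {
  ref <- reference_sample_counts()
  expect_identical(sum(ref$counts$count), 712L)
  expect_identical(nrow(ref$manifest), 712L)
  expect_identical(sum(ref$counts$count[ref$counts$class == "incisor"]), 91L)
  expect_identical(sum(ref$counts$count[ref$counts$class == "premolar"]), 212L)
  key <- paste(ref$manifest$specimen_id, ref$manifest$tooth, ref$manifest$arcade)
  expect_false(anyDuplicated(key) > 0)
})
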