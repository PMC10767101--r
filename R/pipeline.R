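#' Analysis run configuration
#'
#' Collects the settings of a full per-tooth-position analysis run. The
#' defaults are the conventional full-analysis settings: PC candidate range
#' 5-10, 10,000 permutations, typicality threshold 0.1.
#'
#' @param manifest An `edj_manifest` (from [load_manifest()] or
#'   [generate_cohort()]).
#' @param positions Tooth position labels to analyse (default: all present).
#' @param test_pairs `"all"` (every pair of labelled groups) or a list of
#'   2-element character vectors.
#' @param pc_candidates Candidate PC-subset sizes for the CVA sweep.
#' @param n_perm Permutations per test.
#' @param typicality_threshold Classification threshold.
#' @param bh_q FDR level for the Benjamini-Hochberg pass.
#' @param seed Mandatory integer master seed; every stochastic step derives
#'   its own seed from it deterministically.
#' @param unknown_label Group label marking unknown specimens to classify
#'   (excluded from tests and CVA fitting).
#' @param output_dir Optional directory for JSON/CSV outputs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(manifest, positions = NULL, test_pairs = "all",
                       pc_candidates = 5:10, n_perm = 10000L,
                       typicality_threshold = 0.1, bh_q = 0.05, seed,
                       unknown_label = "unknown", output_dir = NULL) {
  if (missing(seed)) stop("run_config: a seed is mandatory")
  structure(
    list(
      manifest = manifest, positions = positions, test_pairs = test_pairs,
      pc_candidates = pc_candidates, n_perm = as.integer(n_perm),
      typicality_threshold = typicality_threshold, bh_q = bh_q,
      seed = as.integer(seed), unknown_label = unknown_label,
      output_dir = output_dir
    ),
    class = "run_config"
  )
}

#' Run the full analysis for every tooth position
#'
#' Per tooth position: derive homologous configurations, run the two-round
#' sliding superimposition protocol, PCA (with +/-1.5 SD extreme shapes on
#' PC1), permutation tests for mean shape (EDJ coordinates) and size (CEJ
#' centroid size) between every requested group pair, the CVA sweep over PC
#' candidates with leave-one-out validation, typicality classification of
#' unknown specimens, pairwise Procrustes-distance and dentine-body-height
#' difference distributions with 95% within-group limits. Afterwards a
#' single Benjamini-Hochberg pass is applied across tooth positions within
#' each test family (shape, size), and ln centroid-size tooth-row profiles
#' are assembled. A stage failure aborts that tooth position (recorded in
#' `errors`) and the others continue. Fully deterministic at fixed
#' config + seed.
#'
#' @param config A [run_config()].
#' @return Object of class `edj_report`; see the fields of each element of
#'   `$positions`, plus `$shape_tests`, `$size_tests` (BH-adjusted),
#'   `$size_profile` and `$errors`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  manifest <- config$manifest
  specimens <- read_manifest_specimens(manifest)
  pos_keys <- unique(paste(manifest$arcade, manifest$tooth))
  if (!is.null(config$positions)) {
    pos_keys <- pos_keys[sub("^\\S+ ", "", pos_keys) %in% config$positions]
  }
  report <- list(positions = list(), errors = list(),
                 config = config[c("pc_candidates", "n_perm",
                                   "typicality_threshold", "bh_q", "seed")])
  shape_p <- c(); size_p <- c()
  all_sizes <- list()
  for (pi in seq_along(pos_keys)) {
    key <- pos_keys[pi]
    rows <- which(paste(manifest$arcade, manifest$tooth) == key)
    res <- tryCatch(
      analyze_position(specimens[rows], config, pos_seed = config$seed + 1000L * pi),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      report$errors[[key]] <- conditionMessage(res)
      next
    }
    report$positions[[key]] <- res
    for (nm in names(res$shape_tests)) {
      shape_p[paste(key, nm, sep = " | ")] <- res$shape_tests[[nm]]$p_value
    }
    for (nm in names(res$size_tests)) {
      size_p[paste(key, nm, sep = " | ")] <- res$size_tests[[nm]]$p_value
    }
    all_sizes[[key]] <- res$sizes
  }
  report$shape_tests <- bh_family(shape_p, config$bh_q)
  report$size_tests <- bh_family(size_p, config$bh_q)
  size_df <- do.call(rbind, all_sizes)
  report$size_profile <- if (!is.null(size_df) && nrow(size_df)) {
    lapply(split(size_df, size_df$arcade), toothrow_size_profile)
  } else NULL
  class(report) <- "edj_report"
  if (!is.null(config$output_dir)) write_report(report, config$output_dir)
  report
}

bh_family <- function(pvec, q) {
  if (!length(pvec)) return(NULL)
  adj <- benjamini_hochberg(pvec, q)
  data.frame(
    test = names(pvec), p = unname(pvec), p_adjusted = unname(adj$adjusted),
    significant = unname(adj$reject)
  )
}

analyze_position <- function(specs, config, pos_seed) {
  configs <- lapply(specs, build_homologous_configuration)
  groups <- vapply(configs, function(c) as.character(c$group), "")
  known <- groups != config$unknown_label & !is.na(groups)
  al <- run_sliding_protocol(configs)
  im <- al$index_map
  cej_cs <- vapply(al$configs, function(c) {
    centroid_size(c$coords[im$cej, , drop = FALSE])
  }, numeric(1))
  sizes <- data.frame(
    specimen_id = vapply(al$configs, `[[`, "", "specimen_id"),
    group = groups,
    tooth = al$tooth$position_label,
    arcade = al$tooth$arcade,
    cs = cej_cs
  )
  space <- shape_pca(al)
  out <- list(
    tooth = al$tooth, n = length(configs), aligned = al, space = space,
    sizes = sizes,
    pc1_extremes = list(
      minus = pc_extreme_shape(space, 1, -1.5),
      plus = pc_extreme_shape(space, 1, +1.5)
    ),
    energy_trace = al$energy_trace
  )
  # group-pair permutation tests on the known specimens
  X <- aligned_matrix(al)
  gtab <- table(groups[known])
  gnames <- names(gtab)[gtab >= 2]
  pairs <- if (identical(config$test_pairs, "all")) {
    if (length(gnames) >= 2) utils::combn(gnames, 2, simplify = FALSE) else list()
  } else config$test_pairs
  shape_tests <- list(); size_tests <- list()
  for (j in seq_along(pairs)) {
    pr <- pairs[[j]]
    ia <- which(groups == pr[1]); ib <- which(groups == pr[2])
    if (length(ia) < 2 || length(ib) < 2) next
    nm <- paste(pr, collapse = " vs ")
    shape_tests[[nm]] <- permutation_test_shape(
      X[ia, , drop = FALSE], X[ib, , drop = FALSE],
      n_perm = config$n_perm, seed = pos_seed + 2L * j
    )
    size_tests[[nm]] <- permutation_test_size(
      cej_cs[ia], cej_cs[ib], n_perm = config$n_perm, seed = pos_seed + 2L * j + 1L
    )
  }
  out$shape_tests <- shape_tests
  out$size_tests <- size_tests
  # CVA sweep on groups with enough members
  cva_groups <- names(gtab)[gtab >= 3]
  if (length(cva_groups) >= 2) {
    ci <- which(groups %in% cva_groups)
    sub_al <- al
    sub_al$aligned <- al$aligned[ci]
    sub_al$ids <- al$ids[ci]
    sub_al$groups <- groups[ci]
    sub_space <- shape_pca(sub_al)
    cand <- config$pc_candidates[config$pc_candidates < length(ci) &
                                 config$pc_candidates <= ncol(sub_space$scores)]
    if (length(cand)) {
      sweep_res <- select_n_pcs(sub_space, groups[ci], cand)
      out$cva_sweep <- sweep_res
      out$cva <- cva(sub_space, groups[ci], sweep_res$n_pcs)
      # classify unknowns by projection into the labelled sample's space
      unk <- which(!known)
      if (length(unk)) {
        out$classifications <- lapply(unk, function(i) {
          classify_unknown(sub_space, groups[ci], al$aligned[[i]],
                           candidates = cand,
                           threshold = config$typicality_threshold)
        })
        names(out$classifications) <- al$ids[unk]
      }
    }
  }
  # distance and DBH distributions over known groups
  if (length(gnames) >= 1) {
    ki <- which(groups %in% gnames)
    out$distance_distributions <-
      suppressWarnings(pairwise_distances(X[ki, , drop = FALSE], groups[ki]))
    if (al$layout$n_fixed > 0) {
      sub_al <- al
      sub_al$aligned <- al$aligned[ki]
      sub_al$ids <- al$ids[ki]
      out$dbh <- suppressWarnings(dbh_distribution_analysis(
        sub_al, groups[ki], default_dbh_spec(al$layout)
      ))
    }
  }
  out
}

#' Human-readable summary tables of a report
#'
#' Builds the analogue tables of a full run: the significance matrix
#' (shape/size x tooth position after FDR control), the per-unknown
#' classification detail (one row per PC-candidate CVA), and the exceedance
#' flags implied by the distance distributions.
#'
#' @param report An `edj_report` from [run_analysis()].
#' @return List with `significance` (data frame, cells sig/ns/n.a.),
#'   `classifications` (data frame) and `limits` (95% within-group limits
#'   per position and group).
#' @export
report_summary <- function(report) {
  stopifnot(inherits(report, "edj_report"))
  keys <- names(report$positions)
  sig_cell <- function(fam, key) {
    if (is.null(fam)) return("n/a")
    rows <- fam[startsWith(fam$test, paste0(key, " | ")), , drop = FALSE]
    if (!nrow(rows)) return("n/a")
    paste(ifelse(rows$significant, "sig", "ns"), collapse = ",")
  }
  significance <- data.frame(
    position = keys,
    shape = vapply(keys, function(k) sig_cell(report$shape_tests, k), ""),
    size = vapply(keys, function(k) sig_cell(report$size_tests, k), "")
  )
  class_rows <- list()
  for (key in keys) {
    cl <- report$positions[[key]]$classifications
    for (id in names(cl)) {
      d <- cl[[id]]$detail
      d$specimen <- id; d$position <- key; d$summary <- cl[[id]]$label
      class_rows[[length(class_rows) + 1]] <- d
    }
  }
  limits_rows <- list()
  for (key in keys) {
    dd <- report$positions[[key]]$distance_distributions
    for (nm in names(dd)) {
      if (dd[[nm]]$type != "within") next
      limits_rows[[length(limits_rows) + 1]] <- data.frame(
        position = key, group = dd[[nm]]$label,
        n_pairs = dd[[nm]]$n_pairs, limit95 = dd[[nm]]$limit95
      )
    }
  }
  list(
    significance = significance,
    classifications = if (length(class_rows)) do.call(rbind, class_rows) else
      data.frame(),
    limits = if (length(limits_rows)) do.call(rbind, limits_rows) else
      data.frame()
  )
}

write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  summ <- report_summary(report)
  jsonlite::write_json(
    list(
      config = report$config,
      significance = summ$significance,
      classifications = summ$classifications,
      limits = summ$limits,
      errors = report$errors
    ),
    file.path(dir, "report.json"),
    auto_unbox = TRUE, digits = NA, dataframe = "rows"
  )
  for (key in names(report$positions)) {
    pos <- report$positions[[key]]
    fn <- gsub("\\s+", "_", key)
    utils::write.csv(
      data.frame(id = pos$space$ids, group = pos$aligned$groups,
                 pos$space$scores[, seq_len(min(10, ncol(pos$space$scores))),
                                  drop = FALSE]),
      file.path(dir, paste0("scores_", fn, ".csv")), row.names = FALSE
    )
    utils::write.csv(pos$sizes, file.path(dir, paste0("sizes_", fn, ".csv")),
                     row.names = FALSE)
  }
  invisible(dir)
}

#' Reference sample class counts
#'
#' Loads the bundled per-class tooth counts of the published comparative
#' sample (91 incisors, 54 canines, 212 premolars, 355 molars; 712 teeth in
#' total) and expands them into a skeleton manifest, one row per tooth, for
#' bookkeeping checks of the manifest machinery.
#'
#' @param path Optional path to a `class,count` CSV (defaults to the file
#'   shipped with the package).
#' @return List with `counts` (data frame) and `manifest` (712-row data
#'   frame with manifest columns; `path` entries are placeholders).
#' @export
reference_sample_counts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "reference_sample_counts.csv",
                        package = "edjmorph")
  }
  counts <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("class", "count") %in% names(counts)))
  class_positions <- list(
    incisor = c("I1", "I2"), canine = "C",
    premolar = c("P3", "P4"), molar = c("M1", "M2", "M3")
  )
  rows <- list()
  for (i in seq_len(nrow(counts))) {
    cls <- counts$class[i]
    pos <- class_positions[[cls]]
    n <- counts$count[i]
    rows[[i]] <- data.frame(
      specimen_id = sprintf("%s_%03d", cls, seq_len(n)),
      taxon = "reference", group = "reference",
      tooth = rep_len(pos, n),
      arcade = rep_len(c("mandibular", "maxillary"), n),
      side = "right",
      path = sprintf("%s_%03d.tps", cls, seq_len(n))
    )
  }
  list(counts = counts, manifest = do.call(rbind, rows))
}
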