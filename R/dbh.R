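#' Dentine-body-height subset specification
#'
#' Dentine body height is the distance from the cervix to the marginal
#' ridges that encircle the occlusal basin, measured on superimposed
#' (unit-centroid-size) coordinates so it describes body height relative to
#' overall crown shape. It is quantified as the distance between the
#' centroid of a ridge landmark subset (mesial + distal marginal ridge; on
#' lower molars two distal subsets flank the hypoconulid) and the centroid
#' of a corresponding cervix subset (mesial + distal). Mesial and distal
#' subsets must hold the same number of landmarks at each level. The exact
#' indices are configuration, chosen per tooth position to capture the
#' lowest portion of the marginal ridges between dentine horns;
#' [default_dbh_spec()] supplies defaults matched to the synthetic template
#' geometry.
#'
#' @param layout A [landmark_layout()].
#' @param ridge_mesial,ridge_distal Landmark indices of the mesial and
#'   distal marginal-ridge subsets (equal lengths; `ridge_distal` may be the
#'   concatenation of two hypoconulid-flanking subsets on lower molars).
#' @param cej_mesial,cej_distal Indices of the mesial and distal cervix
#'   subsets (equal lengths).
#' @return Object of class `dbh_spec`.
#' @export
dbh_spec <- function(layout, ridge_mesial, ridge_distal, cej_mesial, cej_distal) {
  stopifnot(inherits(layout, "landmark_layout"))
  if (length(ridge_mesial) != length(ridge_distal)) {
    stop("dbh_spec: unequal mesial/distal ridge subset sizes")
  }
  if (length(cej_mesial) != length(cej_distal)) {
    stop("dbh_spec: unequal mesial/distal cervix subset sizes")
  }
  all_idx <- c(ridge_mesial, ridge_distal, cej_mesial, cej_distal)
  if (any(all_idx < 1 | all_idx > layout$n_total)) {
    stop("dbh_spec: index out of layout range")
  }
  im <- layout_index_map(layout)
  if (!all(c(cej_mesial, cej_distal) %in% im$cej)) {
    stop("dbh_spec: cervix subset indices must lie on the CEJ ring")
  }
  structure(
    list(
      layout = layout,
      ridge_idx = c(ridge_mesial, ridge_distal),
      cej_idx = c(cej_mesial, cej_distal),
      ridge_mesial = ridge_mesial, ridge_distal = ridge_distal,
      cej_mesial = cej_mesial, cej_distal = cej_distal
    ),
    class = "dbh_spec"
  )
}

#' Default dentine-body-height subsets for a tooth class
#'
#' Defaults keyed to the synthetic template's angular conventions: the
#' mesial ridge subset is centred on the middle of the mesial ridge section
#' (between the first two dentine horns) and the distal subset on the middle
#' of the distal section; on mandibular molars the distal subset is split
#' into two halves flanking the hypoconulid position at the centre of the
#' distal section. Cervix subsets are centred on the mesial and distal
#' points of the CEJ ring. Five landmarks per side by default (six on
#' mandibular molars so the flanking halves have three each).
#'
#' @param layout A [landmark_layout()] of a postcanine class.
#' @param n_per_side Landmarks per (mesial or distal) subset.
#' @return A [dbh_spec()].
#' @export
default_dbh_spec <- function(layout, n_per_side = NULL) {
  stopifnot(inherits(layout, "landmark_layout"))
  if (layout$n_fixed == 0) {
    stop("dentine body height is defined for postcanine teeth only")
  }
  im <- layout_index_map(layout)
  tooth <- layout$tooth
  lower_molar <- tooth$family == "molar" && tooth$arcade == "mandibular"
  if (is.null(n_per_side)) n_per_side <- if (lower_molar) 6L else 5L
  centered_subset <- function(idx, n) {
    mid <- ceiling(length(idx) / 2)
    half <- (n - 1) %/% 2
    idx[(mid - half):(mid - half + n - 1)]
  }
  if (tooth$family == "premolar") {
    ridge_mes <- centered_subset(im$ridge1, n_per_side)  # mesial section
    ridge_dis <- centered_subset(im$ridge2, n_per_side)  # distal section
  } else {
    # molars: section 1 = mesial ridge, section 3 = distal ridge
    ridge_mes <- centered_subset(im$ridge1, n_per_side)
    if (lower_molar) {
      # two subsets flanking the hypoconulid at the centre of section 3
      if (n_per_side %% 2 != 0) stop("lower molars need an even n_per_side")
      h <- n_per_side %/% 2
      sec <- im$ridge3
      mid <- ceiling(length(sec) / 2)
      ridge_dis <- c(sec[(mid - h - 1):(mid - 2)], sec[(mid + 2):(mid + h + 1)])
    } else {
      ridge_dis <- centered_subset(im$ridge3, n_per_side)
    }
  }
  # CEJ ring: 40 points from the buccal start continuing mesially; mesial at
  # a quarter turn, distal at three quarters (mandibular molars start at the
  # mesiobuccal corner, shifting both centres by half a quarter turn)
  cej <- im$cej
  n_cej <- length(cej)
  offset <- if (lower_molar) -n_cej / 8 else 0
  centre_at <- function(frac) {
    pos <- (round(frac * n_cej + offset) %% n_cej) + 1
    half <- (n_per_side - 1) %/% 2
    cej[((pos - half - 1 + seq_len(n_per_side) - 1) %% n_cej) + 1]
  }
  dbh_spec(layout, ridge_mes, ridge_dis, centre_at(0.25), centre_at(0.75))
}

#' Dentine body height of one configuration
#'
#' Euclidean distance between the pooled ridge-subset centroid and the
#' pooled cervix-subset centroid. Invariant to rigid motion and linear in
#' uniform scale, hence well-defined on unit-centroid-size superimposed
#' shapes.
#'
#' @param coords k x 3 (superimposed) configuration, or a
#'   `homologous_config`.
#' @param spec A [dbh_spec()].
#' @return Non-negative scalar (shape units).
#' @export
dentine_body_height <- function(coords, spec) {
  if (inherits(coords, "homologous_config")) coords <- coords$coords
  coords <- as.matrix(coords)
  stopifnot(inherits(spec, "dbh_spec"), nrow(coords) == spec$layout$n_total)
  ridge_c <- colMeans(coords[spec$ridge_idx, , drop = FALSE])
  cej_c <- colMeans(coords[spec$cej_idx, , drop = FALSE])
  sqrt(sum((ridge_c - cej_c)^2))
}

#' Within/between-group distributions of dentine-body-height differences
#'
#' Computes dentine body height for every specimen of an aligned sample,
#' then absolute pairwise differences within each group (and between all
#' group pairs), their 95% limits, and a per-specimen value table.
#'
#' @param sample An `aligned_sample`.
#' @param labels Group label per specimen.
#' @param spec A [dbh_spec()].
#' @param between As in [pairwise_distances()].
#' @return List with `values` (data frame id/group/dbh) and `distributions`
#'   (list of `distance_distribution` objects over |DBH_i - DBH_j|).
#' @export
dbh_distribution_analysis <- function(sample, labels, spec, between = "all") {
  stopifnot(inherits(sample, "aligned_sample"))
  labels <- as.character(labels)
  vals <- vapply(sample$aligned, dentine_body_height, numeric(1), spec = spec)
  dists <- pairwise_distances(matrix(vals, ncol = 1), labels, between = between)
  list(
    values = data.frame(id = sample$ids, group = labels, dbh = vals),
    distributions = dists
  )
}

#' Log centroid-size profiles across the tooth row
#'
#' Natural-log CEJ-ring centroid sizes per tooth, arranged as per-individual
#' traces along the tooth row with per-group min-max envelopes, plus
#' evaluable size-pattern predicates (e.g. is M1 larger than M2 in a given
#' individual).
#'
#' @param sizes Data frame with columns `specimen_id`, `group`, `tooth`
#'   (position label) and `cs` (CEJ centroid size, mm).
#' @param positions Tooth-row order (default I1..M3).
#' @return Object of class `size_profile`: `traces` (individuals x
#'   positions matrix of ln CS, NA where missing), `envelopes` (per group:
#'   min/max per position), `groups`.
#' @export
toothrow_size_profile <- function(sizes,
                                  positions = c("I1", "I2", "C", "P3", "P4",
                                                "M1", "M2", "M3")) {
  need <- c("specimen_id", "group", "tooth", "cs")
  stopifnot(all(need %in% names(sizes)))
  if (any(sizes$cs <= 0)) stop("centroid sizes must be positive")
  inds <- unique(sizes$specimen_id)
  traces <- matrix(NA_real_, length(inds), length(positions),
                   dimnames = list(inds, positions))
  grp <- stats::setNames(rep(NA_character_, length(inds)), inds)
  for (i in seq_len(nrow(sizes))) {
    row <- sizes[i, ]
    if (!row$tooth %in% positions) next
    traces[row$specimen_id, row$tooth] <- log(row$cs)
    grp[row$specimen_id] <- row$group
  }
  gnames <- sort(unique(stats::na.omit(grp)))
  envelopes <- lapply(gnames, function(g) {
    sub <- traces[grp == g, , drop = FALSE]
    rbind(
      min = suppressWarnings(apply(sub, 2, min, na.rm = TRUE)),
      max = suppressWarnings(apply(sub, 2, max, na.rm = TRUE))
    )
  })
  names(envelopes) <- gnames
  structure(
    list(traces = traces, envelopes = envelopes, groups = grp,
         positions = positions),
    class = "size_profile"
  )
}

#' Evaluate a size-order predicate for one individual
#'
#' @param profile A [toothrow_size_profile()] result.
#' @param specimen_id Individual to query.
#' @param larger,smaller Tooth position labels; tests
#'   `lnCS(larger) > lnCS(smaller)`.
#' @return TRUE/FALSE, or NA if either tooth is missing.
#' @export
size_pattern <- function(profile, specimen_id, larger, smaller) {
  tr <- profile$traces[specimen_id, ]
  if (is.na(tr[larger]) || is.na(tr[smaller])) return(NA)
  unname(tr[larger] > tr[smaller])
}
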