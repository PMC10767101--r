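# Synthetic tooth cohorts with known ground truth.
#
# A template describes one tooth class as a pair of rings: a cervical (CEJ)
# ring with a superellipse-like radius function and mild mesiodistal
# elongation, and an EDJ marginal-ridge ring lifted a body height H above
# the cervix, carrying Gaussian dentine-horn bumps whose analytic maxima are
# the fixed cusp landmarks. A distal "talonid" sector can be radially
# reduced. Angular conventions: theta = 0 buccal, 90 mesial, 180 lingual,
# 270 distal; rings are traversed with increasing theta ("continuing
# mesially"), the right-side convention.

deg <- function(x) x * pi / 180

# default cusp angles per class (traversal order = cusp order)
template_cusp_angles <- function(tooth) {
  if (tooth$family == "premolar") c(0, 180)
  else if (tooth$family == "molar") c(45, 135, 225, 315)
  else numeric(0)
}

template_cej_start <- function(tooth) {
  if (tooth$family == "molar" && tooth$arcade == "mandibular") 45 else 0
}

#' Synthetic tooth template
#'
#' Parametric model of one tooth class used by the cohort generator. The
#' cervix ring has radius `r(theta) = r0 * ((|cos t|/1)^p + (|sin t|/elong)^p)^(-1/p)`
#' (a superellipse-like outline, mesiodistally elongated for `elong > 1`)
#' with a small sinusoidal vertical wave. The ridge ring sits at height `H`
#' (the dentine body height) with radius `ridge_scale * r(theta)`, reduced
#' by `talonid_reduction` over a Gaussian distal sector, plus per-cusp
#' Gaussian height bumps (the dentine horns). Evaluating the template at
#' zero noise yields a valid specimen whose homologous configuration passes
#' all layout invariants.
#'
#' @param tooth A [tooth_class()].
#' @param r0 Mean cervix ring radius (mm).
#' @param elong Mesiodistal elongation factor of the cervix outline.
#' @param p Superellipse exponent.
#' @param body_height Dentine body height H (mm, >= 0): vertical offset of
#'   the marginal-ridge plane above the cervix.
#' @param ridge_scale Ridge ring radius as a fraction of the cervix radius.
#' @param horn_heights Dentine horn heights (mm), one per cusp of the class.
#' @param horn_width Angular width of the horn bumps (degrees).
#' @param talonid_reduction Fractional radial reduction of the distal
#'   sector (0 = none).
#' @param talonid_width Angular width of the reduced sector (degrees).
#' @param cej_wave Amplitude of the cervical vertical wave (mm).
#' @return Object of class `tooth_template`.
#' @export
tooth_template <- function(tooth, r0 = 4.5, elong = 1.15, p = 2.5,
                           body_height = 2.8, ridge_scale = 0.62,
                           horn_heights = NULL, horn_width = 15,
                           talonid_reduction = 0, talonid_width = 40,
                           cej_wave = 0.15) {
  stopifnot(inherits(tooth, "tooth_class"), r0 > 0, body_height >= 0,
            ridge_scale > 0, talonid_reduction >= 0, talonid_reduction < 1)
  cusps <- template_cusp_angles(tooth)
  if (is.null(horn_heights)) {
    horn_heights <- if (length(cusps)) seq(2.0, 1.4, length.out = length(cusps)) else numeric(0)
  }
  if (length(horn_heights) != length(cusps)) {
    stop("horn_heights must have one entry per cusp (", length(cusps), ")")
  }
  if (any(horn_heights < 0)) stop("horn heights must be >= 0")
  structure(
    list(
      tooth = tooth, r0 = r0, elong = elong, p = p,
      body_height = body_height, ridge_scale = ridge_scale,
      cusp_angles = cusps, horn_heights = horn_heights,
      horn_width = horn_width,
      talonid_reduction = talonid_reduction, talonid_width = talonid_width,
      cej_wave = cej_wave,
      cej_start = template_cej_start(tooth)
    ),
    class = "tooth_template"
  )
}

#' @export
print.tooth_template <- function(x, ...) {
  cat(sprintf(
    "<tooth_template> %s %s: r0=%.2f mm, H=%.2f mm, %d horns, talonid red %.0f%%\n",
    x$tooth$arcade, x$tooth$position_label, x$r0, x$body_height,
    length(x$cusp_angles), 100 * x$talonid_reduction
  ))
  invisible(x)
}

template_cervix_radius <- function(tpl, theta_deg) {
  t <- deg(theta_deg)
  tpl$r0 * ((abs(cos(t)))^tpl$p + (abs(sin(t)) / tpl$elong)^tpl$p)^(-1 / tpl$p)
}

# wrapped angular difference in degrees, in [-180, 180)
ang_diff <- function(a, b) ((a - b + 180) %% 360) - 180

template_talonid_factor <- function(tpl, theta_deg) {
  if (tpl$talonid_reduction == 0) return(rep(1, length(theta_deg)))
  d <- ang_diff(theta_deg, 270)
  1 - tpl$talonid_reduction * exp(-0.5 * (d / tpl$talonid_width)^2)
}

template_horn_height <- function(tpl, theta_deg) {
  z <- rep(0, length(theta_deg))
  for (j in seq_along(tpl$cusp_angles)) {
    d <- ang_diff(theta_deg, tpl$cusp_angles[j])
    z <- z + tpl$horn_heights[j] * exp(-0.5 * (d / tpl$horn_width)^2)
  }
  z
}

template_cej_point <- function(tpl, theta_deg) {
  r <- template_cervix_radius(tpl, theta_deg)
  cbind(r * cos(deg(theta_deg)), r * sin(deg(theta_deg)),
        tpl$cej_wave * sin(2 * deg(theta_deg)))
}

template_ridge_point <- function(tpl, theta_deg) {
  r <- tpl$ridge_scale * template_cervix_radius(tpl, theta_deg) *
    template_talonid_factor(tpl, theta_deg)
  cbind(r * cos(deg(theta_deg)), r * sin(deg(theta_deg)),
        tpl$body_height + template_horn_height(tpl, theta_deg))
}

random_rotation <- function() {
  M <- matrix(stats::rnorm(9), 3, 3)
  qr_d <- qr(M)
  Q <- qr.Q(qr_d)
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

#' Realise one synthetic specimen from a template
#'
#' Samples the cervix and ridge rings of a template (>= 24 raw points each;
#' the ridge grid passes exactly through the cusp angles so the fixed
#' landmarks lie on the sampled curve), takes the cusp apices as fixed
#' landmarks, then applies an isotropic scale factor, iid Gaussian
#' coordinate noise, and a rigid pose. With `side = "left"` the specimen is
#' reflected into the left-side digitising convention (exercising
#' [mirror_to_right()]).
#'
#' @param template A [tooth_template()].
#' @param specimen_id Identifier.
#' @param scale Isotropic scale factor.
#' @param noise_sd Landmark noise standard deviation (mm) per coordinate.
#' @param pose `"random"` (uses the current RNG), `"identity"`, or a list
#'   with `rotation` (3 x 3) and `translation` (length 3).
#' @param side `"right"` or `"left"`.
#' @param n_ring,n_cej Raw samples per ring (>= 24).
#' @param taxon,group Metadata.
#' @param seed Optional integer seed for full determinism of this call.
#' @return A [raw_specimen()].
#' @export
realize_specimen <- function(template, specimen_id = "synthetic",
                             scale = 1, noise_sd = 0, pose = "random",
                             side = "right", n_ring = 36L, n_cej = 36L,
                             taxon = NA_character_, group = NA_character_,
                             seed = NULL) {
  stopifnot(inherits(template, "tooth_template"), n_ring >= 24, n_cej >= 24)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  tooth <- template$tooth
  n_fixed <- length(template$cusp_angles)
  if (n_fixed > 0) {
    th_ridge <- (template$cusp_angles[1] + (seq_len(n_ring) - 1) * 360 / n_ring) %% 360
    ridge <- template_ridge_point(template, th_ridge)
    fixed <- template_ridge_point(template, template$cusp_angles)
  } else {
    ridge <- matrix(numeric(0), 0, 3)
    fixed <- matrix(numeric(0), 0, 3)
  }
  th_cej <- (template$cej_start + (seq_len(n_cej) - 1) * 360 / n_cej) %% 360
  cej <- template_cej_point(template, th_cej)

  all_pts <- rbind(fixed, ridge, cej)
  all_pts <- all_pts * scale
  if (noise_sd > 0) {
    all_pts <- all_pts + matrix(stats::rnorm(length(all_pts), sd = noise_sd),
                                nrow(all_pts), 3)
  }
  if (identical(pose, "random")) {
    pose <- list(rotation = random_rotation(),
                 translation = stats::runif(3, -10, 10))
  } else if (identical(pose, "identity")) {
    pose <- list(rotation = diag(3), translation = c(0, 0, 0))
  }
  all_pts <- sweep(all_pts %*% t(pose$rotation), 2, pose$translation, `+`)

  fx <- all_pts[seq_len(n_fixed), , drop = FALSE]
  rg <- all_pts[n_fixed + seq_len(nrow(ridge)), , drop = FALSE]
  cj <- all_pts[n_fixed + nrow(ridge) + seq_len(n_cej), , drop = FALSE]
  if (side == "left") {
    # express in the left-side digitising convention: reflect across x and
    # reverse ring orderings keeping each start point (mirror_to_right is
    # the exact inverse)
    refl <- function(m) { if (nrow(m)) m[, 1] <- -m[, 1]; m }
    rev_ring <- function(m) if (nrow(m) < 2) m else m[c(1, nrow(m):2), , drop = FALSE]
    fx <- refl(fx)
    rg <- rev_ring(refl(rg))
    cj <- rev_ring(refl(cj))
  }
  raw_specimen(specimen_id, tooth, fx, rg, cj,
               taxon = taxon, group = group, side = side)
}

#' Ground-truth relative dentine body height of a template
#'
#' Builds the noiseless specimen, derives its homologous configuration, and
#' measures [dentine_body_height()] (default subsets) on the
#' unit-centroid-size shape: the value the pipeline should recover for
#' specimens drawn from this template.
#'
#' @param template A [tooth_template()].
#' @param spec Optional [dbh_spec()] (defaults to [default_dbh_spec()]).
#' @return Scalar relative dentine body height.
#' @export
template_truth_dbh <- function(template, spec = NULL) {
  sp <- realize_specimen(template, "truth", pose = "identity")
  cfg <- build_homologous_configuration(sp)
  if (is.null(spec)) spec <- default_dbh_spec(cfg$layout)
  dentine_body_height(cfg$coords / centroid_size(cfg$coords), spec)
}

#' Cohort specification for the generator
#'
#' @param groups List of group definitions from [group_spec()].
#' @param outliers List of planted outliers: each a list with `group` (name),
#'   and template parameter `overrides` (named list passed over the group
#'   template, e.g. `list(body_height = 1.4 * H)`).
#' @param seed Mandatory integer seed.
#' @param pose_translation Range (mm) of the uniform random translation.
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(groups, outliers = list(), seed, pose_translation = 10) {
  if (missing(seed)) stop("cohort_spec: a seed is mandatory")
  stopifnot(length(groups) >= 1)
  nms <- vapply(groups, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("duplicate group names")
  structure(
    list(groups = groups, outliers = outliers, seed = as.integer(seed),
         pose_translation = pose_translation),
    class = "cohort_spec"
  )
}

#' Group definition inside a [cohort_spec()]
#'
#' @param name Group label (ground truth).
#' @param template The group's [tooth_template()].
#' @param n Number of specimens (>= 1).
#' @param size_meanlog,size_sdlog Log-normal distribution of the isotropic
#'   scale factor.
#' @param noise_sd Landmark noise sd (mm); default 2% of the template's
#'   mean cervix radius, which keeps sliding in the small-displacement
#'   regime.
#' @return List describing the group.
#' @export
group_spec <- function(name, template, n, size_meanlog = 0, size_sdlog = 0.05,
                       noise_sd = NULL) {
  stopifnot(n >= 1, inherits(template, "tooth_template"))
  if (is.null(noise_sd)) noise_sd <- 0.02 * template$r0
  list(name = name, template = template, n = as.integer(n),
       size_meanlog = size_meanlog, size_sdlog = size_sdlog,
       noise_sd = noise_sd)
}

template_with_overrides <- function(template, overrides) {
  args <- list(
    tooth = template$tooth, r0 = template$r0, elong = template$elong,
    p = template$p, body_height = template$body_height,
    ridge_scale = template$ridge_scale, horn_heights = template$horn_heights,
    horn_width = template$horn_width,
    talonid_reduction = template$talonid_reduction,
    talonid_width = template$talonid_width, cej_wave = template$cej_wave
  )
  for (nm in names(overrides)) args[[nm]] <- overrides[[nm]]
  do.call(tooth_template, args)
}

#' Generate a synthetic cohort on disk
#'
#' Writes one landmark file per specimen plus a manifest and a ground-truth
#' JSON record (templates, per-specimen scale/noise, outlier flags). The
#' generator is fully deterministic in (spec, seed): the same spec yields
#' byte-identical files.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory (created if needed).
#' @param format Landmark file format (`"tps"` or `"csv"`).
#' @return List with `manifest` (the loaded `edj_manifest`),
#'   `manifest_path`, `truth_path` and `truth` (the ground-truth record).
#' @export
generate_cohort <- function(spec, dir, format = "tps") {
  stopifnot(inherits(spec, "cohort_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(spec$seed)
  rows <- list()
  truth_specimens <- list()
  for (grp in spec$groups) {
    overrides_by_index <- list()
    for (ol in spec$outliers) {
      if (identical(ol$group, grp$name)) {
        idx <- if (!is.null(ol$index)) ol$index else grp$n
        overrides_by_index[[as.character(idx)]] <- ol$overrides
      }
    }
    for (i in seq_len(grp$n)) {
      tpl <- grp$template
      is_outlier <- !is.null(overrides_by_index[[as.character(i)]])
      if (is_outlier) {
        tpl <- template_with_overrides(tpl, overrides_by_index[[as.character(i)]])
      }
      scale <- stats::rlnorm(1, grp$size_meanlog, grp$size_sdlog)
      id <- sprintf("%s_%02d", grp$name, i)
      sp <- realize_specimen(
        tpl, id, scale = scale, noise_sd = grp$noise_sd,
        pose = list(rotation = random_rotation(),
                    translation = stats::runif(3, -spec$pose_translation,
                                               spec$pose_translation)),
        taxon = grp$name, group = grp$name
      )
      fname <- paste0(id, if (format == "tps") ".tps" else ".csv")
      write_landmark_file(sp, file.path(dir, fname), format = format)
      rows[[length(rows) + 1]] <- data.frame(
        specimen_id = id, taxon = grp$name, group = grp$name,
        tooth = tpl$tooth$position_label, arcade = tpl$tooth$arcade,
        side = "right", path = fname
      )
      truth_specimens[[id]] <- list(
        group = grp$name, scale = scale, noise_sd = grp$noise_sd,
        outlier = is_outlier,
        body_height = tpl$body_height,
        truth_dbh = template_truth_dbh(tpl)
      )
    }
  }
  manifest_df <- do.call(rbind, rows)
  manifest_path <- file.path(dir, "manifest.csv")
  write_manifest(manifest_df, manifest_path)
  truth <- list(
    seed = spec$seed,
    groups = lapply(spec$groups, function(g) {
      list(name = g$name, n = g$n, noise_sd = g$noise_sd,
           body_height = g$template$body_height,
           talonid_reduction = g$template$talonid_reduction,
           truth_dbh = template_truth_dbh(g$template))
    }),
    specimens = truth_specimens
  )
  truth_path <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA)
  list(
    manifest = load_manifest(manifest_path), manifest_path = manifest_path,
    truth_path = truth_path, truth = truth
  )
}

#' Two-taxon benchmark emulating an australopith-like vs derived contrast
#'
#' Group A is a primitive-template cohort; group B differs by a relative
#' dentine-body-height increase `delta_h` and a radial reduction of the
#' distal (talonid) ridge sector, the generative analogue of the derived
#' postcanine pattern. The ground-truth record carries both templates'
#' parameters and noiseless relative DBH values.
#'
#' @param delta_h Relative body-height increase of group B (>= 0).
#' @param talonid_reduction Distal-sector radial reduction of group B.
#' @param n_per_group Specimens per group.
#' @param noise_sd Landmark noise sd (mm); default 2% of cervix radius.
#' @param seed Mandatory integer seed.
#' @param dir Output directory.
#' @param tooth Tooth class (default mandibular P3).
#' @return As [generate_cohort()], plus `templates` and `truth_dbh_diff`
#'   (noiseless relative DBH difference B - A).
#' @export
two_taxon_benchmark <- function(delta_h = 0.2, talonid_reduction = 0.15,
                                n_per_group = 15, noise_sd = NULL, seed,
                                dir = tempfile("two_taxon_"),
                                tooth = tooth_class("P3", "mandibular")) {
  stopifnot(delta_h >= 0)
  tpl_a <- tooth_template(tooth)
  tpl_b <- tooth_template(tooth,
                          body_height = tpl_a$body_height * (1 + delta_h),
                          talonid_reduction = talonid_reduction)
  groups <- list(
    group_spec("primitive", tpl_a, n_per_group, noise_sd = noise_sd),
    group_spec("derived", tpl_b, n_per_group, noise_sd = noise_sd)
  )
  res <- generate_cohort(cohort_spec(groups, seed = seed), dir)
  res$templates <- list(primitive = tpl_a, derived = tpl_b)
  res$truth_dbh_diff <- template_truth_dbh(tpl_b) - template_truth_dbh(tpl_a)
  res
}

#' Extant-analog reference cohorts
#'
#' Three single-species analogue cohorts (chimp-, gorilla- and human-like:
#' differing in size and relative body height) providing within-group
#' reference distributions of Procrustes distances and dentine-body-height
#' differences, against which focal differences are judged.
#'
#' @param n_per_group Specimens per group.
#' @param seed Mandatory integer seed.
#' @param dir Output directory.
#' @param tooth Tooth class (default mandibular P3).
#' @param noise_sd Landmark noise sd (mm); default 2% of cervix radius.
#' @return As [generate_cohort()].
#' @export
extant_analog_cohort <- function(n_per_group = 12, seed,
                                 dir = tempfile("extant_"),
                                 tooth = tooth_class("P3", "mandibular"),
                                 noise_sd = NULL) {
  templates <- list(
    pan_analog = tooth_template(tooth, r0 = 4.2, body_height = 2.4),
    gorilla_analog = tooth_template(tooth, r0 = 6.0, body_height = 3.0,
                                    horn_heights = c(2.4, 1.8)),
    human_analog = tooth_template(tooth, r0 = 4.0, body_height = 3.3,
                                  talonid_reduction = 0.2)
  )
  groups <- lapply(names(templates), function(nm) {
    group_spec(nm, templates[[nm]], n_per_group, noise_sd = noise_sd)
  })
  res <- generate_cohort(cohort_spec(groups, seed = seed), dir)
  res$templates <- templates
  res
}
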