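# semilandmark sliding along curve tangents, minimising TPS bending energy
# against the sample mean; fixed cusp landmarks never move.

# unit tangents by central differences over each ring ordering
ring_tangents <- function(coords, rings) {
  k <- nrow(coords)
  Tm <- matrix(0, k, 3)
  for (ring in rings) {
    m <- length(ring)
    nxt <- ring[c(2:m, 1)]
    prv <- ring[c(m, 1:(m - 1))]
    d <- coords[nxt, , drop = FALSE] - coords[prv, , drop = FALSE]
    len <- sqrt(rowSums(d^2))
    len[len < 1e-12] <- 1
    Tm[ring, ] <- d / len
  }
  Tm
}

# half the local inter-landmark spacing, per landmark, along its ring
ring_half_spacing <- function(coords, rings) {
  k <- nrow(coords)
  h <- rep(Inf, k)
  for (ring in rings) {
    m <- length(ring)
    nxt <- ring[c(2:m, 1)]
    prv <- ring[c(m, 1:(m - 1))]
    dn <- sqrt(rowSums((coords[nxt, , drop = FALSE] - coords[ring, , drop = FALSE])^2))
    dp <- sqrt(rowSums((coords[ring, , drop = FALSE] - coords[prv, , drop = FALSE])^2))
    h[ring] <- pmin(dn, dp) / 2
  }
  h
}

#' Slide semilandmarks of one configuration along their curve tangents
#'
#' Closed-form single step: each sliding landmark moves along its unit
#' tangent (central differences over its ring ordering) by the amplitude
#' vector that minimises the TPS bending-energy quadratic form against the
#' model reference, with fixed landmarks constrained to zero motion. The
#' normal system is `(B_ss * G) a = -rowSums(T_s * (B Y)_s)` where `B_ss` is
#' the bending block restricted to sliding landmarks and `G` the tangent
#' Gram matrix; a ridge jitter is added if the system is singular.
#' Displacements are capped at half the local inter-landmark spacing to keep
#' the move in the regime where re-projection onto the curve is valid.
#'
#' @param coords k x 3 aligned configuration.
#' @param model A [bending_energy_matrix()] model (reference = sample mean).
#' @param rings List of ring index vectors (see layouts); tangents and caps
#'   are computed per ring.
#' @param slide_idx Indices of landmarks allowed to slide (semilandmarks).
#' @param cap Apply the displacement cap (default TRUE).
#' @return List with `coords` (k x 3 slid configuration), `amplitudes`, and
#'   `energy_before`/`energy_after`.
#' @export
slide_semilandmarks <- function(coords, model, rings, slide_idx, cap = TRUE) {
  Y <- as.matrix(coords)
  B <- model$energy_matrix
  stopifnot(nrow(Y) == nrow(B))
  Tm <- ring_tangents(Y, rings)
  Ts <- Tm[slide_idx, , drop = FALSE]
  Bss <- B[slide_idx, slide_idx, drop = FALSE]
  A <- Bss * tcrossprod(Ts)
  BY <- B %*% Y
  b <- -rowSums(Ts * BY[slide_idx, , drop = FALSE])
  a <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(a)) {
    jit <- max(abs(A)) * 1e-10 + 1e-300
    warning("singular sliding system; ridge-regularised solve (jitter ",
            format(jit), ")")
    a <- solve(A + diag(jit, nrow(A)), b)
  }
  if (cap) {
    h <- ring_half_spacing(Y, rings)[slide_idx]
    a <- pmin(pmax(a, -h), h)
  }
  Y2 <- Y
  Y2[slide_idx, ] <- Y[slide_idx, ] + a * Ts
  list(
    coords = Y2, amplitudes = a,
    energy_before = bending_energy(model, Y),
    energy_after = bending_energy(model, Y2)
  )
}

#' Run the full two-round sliding superimposition protocol
#'
#' The protocol for a sample of homologous configurations of one tooth
#' class: generalised Procrustes superimposition; then, twice: slide the
#' semilandmarks of every specimen against the current Procrustes mean,
#' project the slid landmarks back onto each specimen's own fitted curve,
#' and re-superimpose. After the second round the landmarks are considered
#' geometrically homologous and the final aligned sample is returned.
#'
#' @param configs List of [build_homologous_configuration()] objects of one
#'   layout (their fitted curves are used for re-projection).
#' @param tol,max_iter Passed to [gpa()].
#' @return An `aligned_sample` (see [gpa()]) with extra fields
#'   `energy_trace` (summed bending energy vs the round's reference, before
#'   and after each sliding round), `tooth`, `layout`, `groups`, `taxa`, and
#'   `configs` (the final re-projected configurations).
#' @export
run_sliding_protocol <- function(configs, tol = 1e-10, max_iter = 100L) {
  stopifnot(length(configs) >= 2,
            all(vapply(configs, inherits, TRUE, "homologous_config")))
  layout <- configs[[1]]$layout
  rings <- layout_rings(layout)
  im <- configs[[1]]$index_map
  slide_idx <- sort(unlist(im[setdiff(names(im), "fixed")], use.names = FALSE))
  ids <- vapply(configs, `[[`, "", "specimen_id")
  coords <- lapply(configs, `[[`, "coords")
  names(coords) <- ids
  al <- gpa(coords, tol = tol, max_iter = max_iter)
  energy_trace <- list()
  for (round in 1:2) {
    model <- bending_energy_matrix(al$mean_shape)
    e_before <- 0; e_after <- 0
    for (i in seq_along(configs)) {
      sl <- slide_semilandmarks(al$aligned[[i]], model, rings, slide_idx)
      e_before <- e_before + sl$energy_before
      e_after <- e_after + sl$energy_after
      # map slid points back to the specimen's raw frame and re-project
      # onto its own spline
      raw_slid <- sweep(sl$coords %*% t(al$rotations[[i]]) * al$scales[i],
                        2, al$centers[[i]], `+`)
      cfg <- configs[[i]]
      if (!is.null(cfg$ridge_curve)) {
        ridge_idx <- setdiff(slide_idx, im$cej)
        for (j in ridge_idx) {
          s <- project_point(cfg$ridge_curve, raw_slid[j, ])
          raw_slid[j, ] <- curve_eval(cfg$ridge_curve, s)
        }
      }
      for (j in im$cej) {
        s <- project_point(cfg$cej_curve, raw_slid[j, ])
        raw_slid[j, ] <- curve_eval(cfg$cej_curve, s)
      }
      cfg$coords[slide_idx, ] <- raw_slid[slide_idx, ]
      configs[[i]] <- cfg
    }
    energy_trace[[round]] <- c(before = e_before, after = e_after)
    coords <- lapply(configs, `[[`, "coords")
    names(coords) <- ids
    al <- gpa(coords, tol = tol, max_iter = max_iter)
  }
  al$energy_trace <- energy_trace
  al$tooth <- layout$tooth
  al$layout <- layout
  al$index_map <- im
  al$groups <- vapply(configs, function(c) as.character(c$group), "")
  al$taxa <- vapply(configs, function(c) as.character(c$taxon), "")
  al$configs <- configs
  al
}
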