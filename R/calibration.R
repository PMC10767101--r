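# seeded Monte-Carlo calibration utilities for the statistical machinery

#' Type-I error calibration of the permutation tests
#'
#' Repeatedly generates null cohorts (two groups drawn from one template,
#' shared noise), runs the homologisation + superimposition path and both
#' permutation tests, and reports the rejection rates at `alpha`. Under the
#' null the rates should fall inside the binomial confidence band around
#' `alpha` and the p-values should be (super-)uniform.
#'
#' @param n_reps Number of replicate cohorts.
#' @param n_per_group Specimens per group in each cohort.
#' @param n_perm Permutations per test.
#' @param alpha Nominal level.
#' @param seed Master seed; replicate r uses `seed + r` internally.
#' @param template Tooth template for the null cohorts (default: an
#'   anterior tooth, whose CEJ-only layout carries both a shape and a size
#'   signal and keeps the simulation light).
#' @param noise_sd Landmark noise sd (mm).
#' @return List with `shape_p`, `size_p` (p-value vectors),
#'   `shape_rejection`, `size_rejection` and the settings.
#' @export
null_permutation_calibration <- function(n_reps = 200, n_per_group = 10,
                                         n_perm = 999, alpha = 0.05, seed,
                                         template = NULL, noise_sd = NULL) {
  if (missing(seed)) stop("a seed is required")
  if (is.null(template)) {
    template <- tooth_template(tooth_class("I1", "mandibular"))
  }
  if (is.null(noise_sd)) noise_sd <- 0.02 * template$r0
  shape_p <- numeric(n_reps)
  size_p <- numeric(n_reps)
  im <- layout_index_map(landmark_layout(template$tooth))
  for (r in seq_len(n_reps)) {
    old <- get_rng_state()
    set.seed(seed + r)
    cfgs <- lapply(seq_len(2 * n_per_group), function(i) {
      build_homologous_configuration(
        realize_specimen(template, sprintf("n%02d", i), noise_sd = noise_sd,
                         scale = stats::rlnorm(1, 0, 0.05))
      )
    })
    restore_rng_state(old)
    al <- gpa(lapply(cfgs, `[[`, "coords"))
    X <- aligned_matrix(al)
    ia <- seq_len(n_per_group)
    shape_p[r] <- permutation_test_shape(
      X[ia, , drop = FALSE], X[-ia, , drop = FALSE],
      n_perm = n_perm, seed = seed + 100000L + r
    )$p_value
    cs <- vapply(cfgs, function(c) centroid_size(c$coords[im$cej, ]), numeric(1))
    size_p[r] <- permutation_test_size(
      cs[ia], cs[-ia], n_perm = n_perm, seed = seed + 200000L + r
    )$p_value
  }
  list(
    shape_p = shape_p, size_p = size_p,
    shape_rejection = mean(shape_p <= alpha),
    size_rejection = mean(size_p <= alpha),
    n_reps = n_reps, n_per_group = n_per_group, n_perm = n_perm,
    alpha = alpha, seed = seed
  )
}

#' Empirical FDR of the Benjamini-Hochberg pass on a seeded mixture
#'
#' Simulates families of `m0` true-null and `m1` shifted-alternative
#' two-sample z statistics, applies [benjamini_hochberg()] at `q`, and
#' averages the false-discovery proportion over replicates.
#'
#' @param m0,m1 Numbers of true nulls and alternatives per family.
#' @param shift Mean shift of the alternatives (in null-sd units).
#' @param n_reps Replicates.
#' @param q FDR level.
#' @param seed Master seed.
#' @return List with `fdr` (mean false-discovery proportion), `power`
#'   (mean fraction of alternatives rejected) and the settings.
#' @export
bh_fdr_simulation <- function(m0 = 40, m1 = 10, shift = 3.5, n_reps = 500,
                              q = 0.05, seed) {
  if (missing(seed)) stop("a seed is required")
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  fdp <- numeric(n_reps)
  pow <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    z <- c(stats::rnorm(m0), stats::rnorm(m1, mean = shift))
    p <- 2 * stats::pnorm(-abs(z))
    rej <- benjamini_hochberg(p, q)$reject
    nr <- sum(rej)
    fdp[r] <- if (nr) sum(rej[seq_len(m0)]) / nr else 0
    pow[r] <- mean(rej[m0 + seq_len(m1)])
  }
  list(fdr = mean(fdp), power = mean(pow), m0 = m0, m1 = m1,
       n_reps = n_reps, q = q, seed = seed)
}
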