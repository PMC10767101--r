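# shared fixtures, built in code; expensive ones are memoised per session

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

p3_class <- function() tooth_class("P3", "mandibular")
m1_class <- function() tooth_class("M1", "mandibular")
i1_class <- function() tooth_class("I1", "mandibular")

p3_template <- function(...) tooth_template(p3_class(), ...)

# small noisy premolar cohort, deterministic
noisy_p3_configs <- function(n = 6, noise_sd = 0.09, seed = 42, group = "A",
                             template = p3_template()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    build_homologous_configuration(
      realize_specimen(template, sprintf("%s_%02d", group, i),
                       noise_sd = noise_sd, group = group)
    )
  })
}

# points on a circle of given radius in the z = 0 plane
circle_points <- function(n, radius = 1, phase = 0) {
  th <- phase + seq(0, 2 * pi, length.out = n + 1)[seq_len(n)]
  cbind(radius * cos(th), radius * sin(th), 0)
}

# random 3D rotation from a seeded RNG
rand_rotation <- function() {
  M <- matrix(rnorm(9), 3, 3)
  Q <- qr.Q(qr(M))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))

# wrap an n x 3k coordinate matrix as a minimal aligned_sample
make_aligned <- function(X, k) {
  structure(list(
    ids = as.character(seq_len(nrow(X))),
    aligned = lapply(seq_len(nrow(X)), function(i) matrix(X[i, ], k, 3, byrow = TRUE)),
    mean_shape = matrix(colMeans(X), k, 3, byrow = TRUE),
    centroid_sizes = rep(1, nrow(X)),
    groups = NULL, taxa = NULL
  ), class = "aligned_sample")
}
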