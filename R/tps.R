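#' Thin-plate-spline bending-energy model for a reference shape
#'
#' Assembles the 3D TPS interpolation system for the reference landmarks
#' (radial kernel U(r) = r and affine block [1 | X]) and extracts the k x k
#' bending-energy block of its inverse. The block is oriented so the
#' quadratic form is positive semidefinite: the bending energy of a target
#' configuration Y relative to the reference is
#' `sum_d y_d' B y_d` over the three coordinate columns, zero exactly on
#' affine transforms of the reference (a 4-dimensional null space in 3D).
#'
#' @param reference Numeric matrix k x 3.
#' @return Object of class `bending_energy_model` with fields `reference`,
#'   `energy_matrix` (k x k symmetric PSD) and `condition` (condition number
#'   of the TPS system; a pseudo-inverse is used when singular).
#' @export
bending_energy_matrix <- function(reference) {
  X <- as.matrix(reference)
  stopifnot(ncol(X) == 3, nrow(X) >= 5)
  k <- nrow(X)
  K <- as.matrix(stats::dist(X))
  P <- cbind(1, X)
  L <- rbind(cbind(K, P), cbind(t(P), matrix(0, 4, 4)))
  cond <- kappa(L, exact = FALSE)
  Li <- tryCatch(solve(L), error = function(e) NULL)
  if (is.null(Li)) {
    warning("singular TPS system (condition ", format(cond),
            "); using pseudo-inverse")
    sv <- svd(L)
    pos <- sv$d > max(sv$d) * 1e-12
    Li <- sv$v[, pos, drop = FALSE] %*% (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
  }
  # with U(r) = +r in 3D the raw block is negative semidefinite; negate so
  # the energy quadratic form is PSD and sliding is a minimisation
  B <- -Li[1:k, 1:k]
  B <- (B + t(B)) / 2
  structure(
    list(reference = X, energy_matrix = B, condition = cond),
    class = "bending_energy_model"
  )
}

#' @export
print.bending_energy_model <- function(x, ...) {
  cat(sprintf("<bending_energy_model> k=%d, condition %.3g\n",
              nrow(x$reference), x$condition))
  invisible(x)
}

#' Bending energy of a target configuration
#'
#' Quadratic-form bending energy of the TPS interpolant mapping the model's
#' reference onto `target`. Zero (to machine precision) iff `target` is an
#' affine transform of the reference.
#'
#' @param model A [bending_energy_matrix()] model.
#' @param target Numeric matrix k x 3.
#' @return Non-negative scalar.
#' @export
bending_energy <- function(model, target) {
  Y <- as.matrix(target)
  stopifnot(all(dim(Y) == dim(model$reference)))
  sum(Y * (model$energy_matrix %*% Y))
}
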