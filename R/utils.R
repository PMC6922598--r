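# Small geometry helpers shared across modules.

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation matrix for a right-handed rotation by `angle` degrees
#' about the (non-zero) axis vector `axis`.
#'
#' @param angle Rotation angle in degrees.
#' @param axis Length-3 axis vector; need not be normalized.
#' @return A 3x3 orthonormal rotation matrix.
#' @export
rotation_matrix <- function(angle, axis = c(0, 0, 1)) {
  stopifnot(length(axis) == 3)
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) stop("rotation axis must be non-zero")
  u <- axis / n
  th <- angle * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# rotate an n x 3 coordinate matrix about `axis` through `center`
rotate_coords <- function(xyz, angle, axis = c(0, 0, 1), center = c(0, 0, 0)) {
  R <- rotation_matrix(angle, axis)
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center, `+`)
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize zero vector")
  v / n
}

# deterministic unit vector perpendicular to d
any_perp <- function(d) {
  e <- diag(3)[, which.min(abs(d))]
  unitv(e - sum(e * d) * d)
}

# pairwise Euclidean distances between rows of two n x 3 matrices
cross_dist <- function(a, b) {
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
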