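#' Rigid-body geometry utilities
#'
#' Least-squares superposition (Kabsch), RMSD, collinearity tests and rigid
#' transforms. Used by the screening matcher, the cluster aligner and the
#' structure-based builder. All coordinates are in Angstrom.
#'
#' @name geometry
#' @keywords internal
NULL

#' Least-squares rigid superposition of two point sets
#'
#' Computes the proper rotation `R` and translation `t` minimising
#' `sum_i w_i ||R x_i + t - y_i||^2` (Kabsch algorithm with reflection
#' guard), i.e. the transform moving `x` onto `y`.
#'
#' @param x,y numeric matrices, n x 3, paired rows; n >= 3.
#' @param w optional non-negative weights of length n.
#' @return list with `rotation` (3x3), `translation` (length 3), `rmsd`
#'   (weighted RMSD of the superposed pairs).
#' @export
kabsch <- function(x, y, w = NULL) {
  x <- as.matrix(x); y <- as.matrix(y)
  stopifnot(ncol(x) == 3L, ncol(y) == 3L, nrow(x) == nrow(y), nrow(x) >= 3L)
  n <- nrow(x)
  if (is.null(w)) w <- rep(1, n)
  w <- w / sum(w)
  cx <- colSums(x * w); cy <- colSums(y * w)
  xc <- sweep(x, 2L, cx); yc <- sweep(y, 2L, cy)
  h <- crossprod(xc * w, yc)
  sv <- svd(h)
  d <- sign(det(tcrossprod(sv$v, sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cy - as.vector(rot %*% cx)
  moved <- apply_transform(x, rot, tr)
  list(rotation = rot, translation = tr,
       rmsd = sqrt(sum(w * rowSums((moved - y)^2))))
}

#' Apply a rigid transform to coordinates
#'
#' @param x n x 3 matrix (or length-3 vector).
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector.
#' @return transformed n x 3 matrix.
#' @export
apply_transform <- function(x, rotation, translation) {
  if (is.null(dim(x))) x <- matrix(x, ncol = 3L)
  sweep(x %*% t(rotation), 2L, translation, "+")
}

#' Root-mean-square deviation between paired coordinate sets
#' @param x,y n x 3 matrices, paired rows.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(x, y) {
  x <- as.matrix(x); y <- as.matrix(y)
  sqrt(mean(rowSums((x - y)^2)))
}

#' Test whether 3D points are collinear (or coincident)
#'
#' Points are collinear when all of them lie within `tol` of the principal
#' axis through their centroid; coincident point sets count as collinear.
#'
#' @param x n x 3 matrix.
#' @param tol distance tolerance in Angstrom.
#' @return logical.
#' @export
points_collinear <- function(x, tol = 1e-6) {
  x <- as.matrix(x)
  if (nrow(x) < 3L) return(TRUE)
  d <- stats::dist(x)
  if (all(d <= tol)) return(TRUE)
  xc <- sweep(x, 2L, colMeans(x))
  sv <- svd(xc, nu = 0L, nv = 3L)
  # residual distance from the first principal axis
  resid <- sqrt(pmax(0, rowSums(xc^2) - (xc %*% sv$v[, 1L])^2))
  all(resid <= tol)
}

#' A rotation matrix about an arbitrary axis
#' @param axis length-3 vector (need not be unit).
#' @param angle rotation angle in radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  c1 <- cos(angle); s1 <- sin(angle)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3L, 3L, byrow = TRUE)
  diag(3L) * c1 + s1 * ux + (1 - c1) * tcrossprod(u)
}

#' Random rotation matrix (uniform over SO(3))
#' @param rng_unif function(n) returning n uniforms in (0,1); defaults to
#'   [stats::runif()] so the caller's RNG state drives it.
#' @return 3x3 rotation matrix.
#' @keywords internal
random_rotation <- function(rng_unif = stats::runif) {
  u <- rng_unif(3L)
  # Arvo's method
  theta <- 2 * pi * u[1L]; phi <- 2 * pi * u[2L]; z <- u[3L]
  v <- c(cos(phi) * sqrt(z), sin(phi) * sqrt(z), sqrt(1 - z))
  rz <- rotation_matrix(c(0, 0, 1), theta)
  (2 * tcrossprod(v) - diag(3L)) %*% rz
}

# pairwise Euclidean distance between rows of a and rows of b
cross_dist <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# unit vector (zero vector left unchanged)
unitize <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) v else v / n
}

# angle at vertex b of the triangle a-b-c, in degrees
angle_deg <- function(a, b, c) {
  u <- unitize(a - b); v <- unitize(c - b)
  acos(max(-1, min(1, sum(u * v)))) * 180 / pi
}
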