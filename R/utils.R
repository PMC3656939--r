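#' @keywords internal
"_PACKAGE"

## Small geometry helpers shared across modules. All directions are rows of
## n x 3 matrices; all world coordinates are in mm.

#' Normalize rows of a matrix to unit Euclidean length
#' @noRd
normalize_rows <- function(m) {
  m <- as_dir_matrix(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) stop("cannot normalize a zero vector")
  m / nrm
}

#' Coerce a 3-vector or n x 3 matrix to an n x 3 matrix
#' @noRd
as_dir_matrix <- function(u) {
  if (is.null(dim(u))) {
    if (length(u) != 3L) stop("expected a 3-vector or an n x 3 matrix")
    u <- matrix(u, nrow = 1L)
  }
  if (ncol(u) != 3L) stop("expected an n x 3 matrix")
  storage.mode(u) <- "double"
  u
}

#' Cross product of two 3-vectors
#' @noRd
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Deterministic orthonormal basis of the plane perpendicular to n
#'
#' Returns a 3 x 2 matrix whose columns, together with `n`, form a
#' right-handed orthonormal frame. The first column is the component of the
#' global x-axis orthogonal to `n`; when `n` is nearly parallel to x
#' (|n . x| > 0.99) the y-axis is used instead so the construction never
#' degenerates.
#'
#' @param n unit 3-vector.
#' @return 3 x 2 matrix of in-plane basis vectors.
#' @export
perp_basis <- function(n) {
  n <- as.numeric(n)
  stopifnot(length(n) == 3L)
  n <- n / sqrt(sum(n^2))
  a <- if (abs(n[1]) > 0.99) c(0, 1, 0) else c(1, 0, 0)
  e1 <- a - sum(a * n) * n
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- cross3(n, e1)
  cbind(e1, e2)
}

#' Random 3D rotation matrix (uniform over SO(3))
#'
#' Draws a rotation uniformly from SO(3) using the QR decomposition of a
#' Gaussian matrix with sign correction. Used by the invariance test-benches.
#'
#' @param seed optional integer seed; when supplied the draw is reproducible.
#' @return orthogonal 3 x 3 matrix with determinant +1.
#' @export
random_rotation <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  qr_ <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  q <- q %*% diag(sign(diag(qr.R(qr_))))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Rotation matrix about an axis by an angle (Rodrigues)
#' @noRd
axis_angle_rotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

#' Trilinear interpolation of a 3D array at fractional voxel coordinates
#'
#' Voxel centers sit at integer 0-based coordinates; queries are clamped to
#' the valid cube so edge samples use nearest-edge values. Exact on linear
#' fields and bit-exact at integer coordinates.
#'
#' @param vol 3D numeric array.
#' @param coords n x 3 matrix of 0-based voxel coordinates.
#' @return numeric vector of n interpolated values.
#' @export
trilinear_interp <- function(vol, coords) {
  d <- dim(vol)
  stopifnot(length(d) == 3L)
  coords <- as_dir_matrix(coords)
  cl <- pmin(pmax(coords, 0), rep(d - 1L, each = nrow(coords)))
  i0 <- floor(cl)
  fr <- cl - i0
  i1 <- pmin(i0 + 1, rep(d - 1L, each = nrow(coords)))
  ix0 <- i0[, 1] + 1L; iy0 <- i0[, 2] + 1L; iz0 <- i0[, 3] + 1L
  ix1 <- i1[, 1] + 1L; iy1 <- i1[, 2] + 1L; iz1 <- i1[, 3] + 1L
  fx <- fr[, 1]; fy <- fr[, 2]; fz <- fr[, 3]
  at <- function(ix, iy, iz) vol[cbind(ix, iy, iz)]
  v00 <- at(ix0, iy0, iz0) * (1 - fx) + at(ix1, iy0, iz0) * fx
  v10 <- at(ix0, iy1, iz0) * (1 - fx) + at(ix1, iy1, iz0) * fx
  v01 <- at(ix0, iy0, iz1) * (1 - fx) + at(ix1, iy0, iz1) * fx
  v11 <- at(ix0, iy1, iz1) * (1 - fx) + at(ix1, iy1, iz1) * fx
  v0 <- v00 * (1 - fy) + v10 * fy
  v1 <- v01 * (1 - fy) + v11 * fy
  v0 * (1 - fz) + v1 * fz
}

#' Convert world (mm) coordinates to 0-based voxel coordinates
#' @noRd
world_to_voxel <- function(points, affine) {
  points <- as_dir_matrix(points)
  inv <- solve(affine)
  h <- cbind(points, 1) %*% t(inv)
  h[, 1:3, drop = FALSE]
}

#' Convert 0-based voxel coordinates to world (mm)
#' @noRd
voxel_to_world <- function(vox, affine) {
  vox <- as_dir_matrix(vox)
  h <- cbind(vox, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}
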