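## Numerical integration domains for the feature integrals: the unit sphere S
## (surface features) and the unit circle C(n) perpendicular to the local
## cortical normal (in-plane features).

#' Spherical and circular quadrature for the feature integrals
#'
#' Builds a product quadrature on the unit sphere: Gauss-Legendre nodes in
#' cos(theta) crossed with equally spaced azimuths. This rule integrates
#' spherical polynomials exactly up to degree `2 * n_theta - 1` (and all
#' azimuthal frequencies below `n_phi`), which comfortably covers the
#' 10th power of an order-6 SH expansion at the defaults. Circle integrals
#' use `circle_samples` equally spaced angles (the trapezoid rule on a
#' periodic integrand, exact below that frequency).
#'
#' @param n_theta Gauss-Legendre node count in cos(theta) (default 36).
#' @param n_phi equally spaced azimuth count (default 72).
#' @param circle_samples angular samples on C(n) (default 360).
#' @return object of class `sphere_quadrature` with fields `points`
#'   (n x 3 unit vectors), `weights` (summing to 4*pi) and `circle_samples`.
#' @export
sphere_quadrature <- function(n_theta = 36, n_phi = 72, circle_samples = 360) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  phi <- 2 * pi * (seq_len(n_phi) - 1) / n_phi
  ct <- rep(gl$x, each = n_phi)
  st <- sqrt(pmax(0, 1 - ct^2))
  ph <- rep(phi, times = n_theta)
  pts <- cbind(st * cos(ph), st * sin(ph), ct)
  w <- rep(gl$w, each = n_phi) * (2 * pi / n_phi)
  structure(list(points = pts, weights = w, circle_samples = circle_samples,
                 n_theta = n_theta, n_phi = n_phi),
            class = "sphere_quadrature")
}

#' @export
print.sphere_quadrature <- function(x, ...) {
  cat(sprintf("<sphere_quadrature> %d sphere points (GL %d x %d azimuths), %d circle samples\n",
              nrow(x$points), x$n_theta, x$n_phi, x$circle_samples))
  invisible(x)
}

## cache of the SH basis evaluated on a quadrature, keyed by geometry
.quad_cache <- new.env(parent = emptyenv())

#' SH basis evaluated at quadrature points (cached)
#' @noRd
quad_sh_basis <- function(quad, max_order) {
  key <- sprintf("b_%d_%d_%d", quad$n_theta, quad$n_phi, max_order)
  b <- .quad_cache[[key]]
  if (is.null(b)) {
    b <- sh_basis(quad$points, max_order)
    .quad_cache[[key]] <- b
  }
  b
}

#' Directions of the unit circle perpendicular to n
#' @noRd
circle_directions <- function(n, m) {
  b <- perp_basis(n)
  ang <- 2 * pi * (seq_len(m) - 1) / m
  outer(cos(ang), b[, 1]) + outer(sin(ang), b[, 2])
}
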