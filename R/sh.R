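## Even-order real spherical-harmonic modelling of the apparent diffusion
## coefficient (ADC) profile f(u) = -(1/b) log(S(u)/S0) on the unit sphere.
## Only even orders enter the basis: diffusion measurements are antipodally
## symmetric, so odd orders carry no signal.

#' Number of even-order real SH coefficients up to a maximum order
#' @param max_order even non-negative integer.
#' @return integer coefficient count (1 + 5 + 9 + 13 = 28 for order 6).
#' @export
sh_coefficient_count <- function(max_order) {
  ks <- seq(0, max_order, by = 2)
  sum(2L * ks + 1L)
}

#' Names of the SH coefficients in canonical order
#'
#' Canonical ordering is order k ascending over even orders, and within each
#' order the index i running from -k to k. The i < 0 entries multiply
#' sin(|i| phi), i > 0 entries cos(i phi), in the real, orthonormal,
#' antipodally symmetric convention standard in diffusion MRI.
#'
#' @param max_order even non-negative integer.
#' @return character vector like `a_0_0`, `a_2_-2`, ..., `a_6_6`.
#' @export
sh_coefficient_names <- function(max_order) {
  unlist(lapply(seq(0, max_order, by = 2),
                function(k) sprintf("a_%d_%d", k, -k:k)))
}

#' Real even-order spherical-harmonic basis matrix
#'
#' Evaluates the real orthonormal SH basis restricted to even orders at a set
#' of unit directions. Columns follow [sh_coefficient_names()] order; the
#' order-0 column is the constant 1/sqrt(4*pi).
#'
#' @param directions n x 3 matrix of unit vectors (a single 3-vector is
#'   accepted).
#' @param max_order maximum even order (default 6).
#' @return n x [sh_coefficient_count()] basis matrix.
#' @export
sh_basis <- function(directions, max_order = 6) {
  if (max_order < 0 || max_order %% 2 != 0)
    stop("max_order must be an even non-negative integer")
  u <- as_dir_matrix(directions)
  ct <- pmin(1, pmax(-1, u[, 3]))
  phi <- atan2(u[, 2], u[, 1])
  n <- nrow(u)
  out <- matrix(0, n, sh_coefficient_count(max_order))
  col <- 0L
  for (k in seq(0, max_order, by = 2)) {
    P <- pracma::legendre(k, ct)           # (k+1) x n, rows m = 0..k
    if (k == 0) P <- matrix(P, nrow = 1L)
    if (n == 1L) P <- matrix(P, ncol = 1L)
    for (i in -k:k) {
      m <- abs(i)
      nrm <- sqrt((2 * k + 1) / (4 * pi) * exp(lgamma(k - m + 1) - lgamma(k + m + 1)))
      col <- col + 1L
      out[, col] <- if (i < 0) {
        sqrt(2) * nrm * P[m + 1L, ] * sin(m * phi)
      } else if (i == 0) {
        nrm * P[1L, ]
      } else {
        sqrt(2) * nrm * P[m + 1L, ] * cos(m * phi)
      }
    }
  }
  colnames(out) <- sh_coefficient_names(max_order)
  out
}

#' Convert diffusion-weighted signals to ADC samples
#'
#' Applies the monoexponential log transform ADC = -(1/b) log(S / S0)
#' per direction. Signals at or below a floor of `log_floor * S0` are clamped
#' to the floor before the log (the Rician noise floor, drift correction or
#' interpolation can produce non-positive apparent signals); the number of
#' clamped samples is reported. Signals above S0 are used as-is and yield
#' negative ADC samples.
#'
#' @param signals numeric vector of diffusion-weighted signals.
#' @param reference_signal positive reference (low-b) signal S0.
#' @param bvalue b-value (s/mm^2), scalar or per-signal vector.
#' @param log_floor relative clamp floor (default 1e-6).
#' @return list with `adc` (numeric vector, mm^2/s) and `n_clamped`.
#' @export
signal_to_adc <- function(signals, reference_signal, bvalue, log_floor = 1e-6) {
  if (!is.finite(reference_signal) || reference_signal <= 0)
    stop("reference_signal must be positive")
  if (any(bvalue <= 0)) stop("bvalue must be positive")
  floor_val <- log_floor * reference_signal
  clamped <- signals < floor_val
  s <- pmax(signals, floor_val)
  list(adc = -log(s / reference_signal) / bvalue,
       n_clamped = sum(clamped))
}

#' Construct an ADC profile object
#' @param coefficients numeric vector in [sh_coefficient_names()] order.
#' @param max_order maximum even SH order of the fit.
#' @param bvalue b-value (s/mm^2) used in the log transform, if known.
#' @return object of class `adc_profile`.
#' @export
adc_profile <- function(coefficients, max_order = 6, bvalue = NA_real_) {
  nc <- sh_coefficient_count(max_order)
  coefficients <- as.numeric(coefficients)
  if (length(coefficients) != nc)
    stop(sprintf("expected %d coefficients for max_order %d, got %d",
                 nc, max_order, length(coefficients)))
  names(coefficients) <- sh_coefficient_names(max_order)
  structure(list(coefficients = coefficients, max_order = max_order,
                 bvalue = bvalue),
            class = "adc_profile")
}

#' @export
print.adc_profile <- function(x, ...) {
  cat(sprintf("<adc_profile> even-order SH fit, max order %d (%d coefficients)\n",
              x$max_order, length(x$coefficients)))
  invisible(x)
}

#' Fit the even-order SH model to per-direction ADC samples
#'
#' Ordinary least squares of the ADC samples on the even-order real SH basis
#' evaluated at the scheme's directions; an optional ridge penalty is
#' available for noisy data but is off by default.
#'
#' @param adc_samples numeric vector of ADC samples (mm^2/s), one per scheme
#'   direction.
#' @param scheme a [gradient_scheme()].
#' @param max_order maximum even SH order (default 6).
#' @param ridge_weight nonnegative ridge penalty on all non-constant
#'   coefficients (default 0, plain least squares).
#' @return an [adc_profile()].
#' @export
fit_adc_profile <- function(adc_samples, scheme, max_order = 6,
                            ridge_weight = 0) {
  co <- fit_adc_profiles(matrix(adc_samples, ncol = 1), scheme,
                         max_order = max_order, ridge_weight = ridge_weight)
  adc_profile(co[, 1], max_order = max_order,
              bvalue = scheme$bvalues[1])
}

#' Fit SH models to many vertices at once
#'
#' Matrix form of [fit_adc_profile()]: each column of `adc_matrix` holds the
#' ADC samples of one vertex, all sharing the same gradient scheme, so the
#' basis is factorized once.
#'
#' @param adc_matrix n_directions x n_vertices matrix of ADC samples.
#' @param scheme a [gradient_scheme()].
#' @param max_order maximum even SH order.
#' @param ridge_weight nonnegative ridge penalty (default 0).
#' @return coefficient matrix, [sh_coefficient_count()] x n_vertices.
#' @export
fit_adc_profiles <- function(adc_matrix, scheme, max_order = 6,
                             ridge_weight = 0) {
  adc_matrix <- as.matrix(adc_matrix)
  B <- sh_basis(scheme$directions, max_order)
  if (nrow(B) < ncol(B))
    stop(sprintf("underdetermined fit: %d directions < %d coefficients",
                 nrow(B), ncol(B)))
  if (nrow(adc_matrix) != nrow(B))
    stop("adc_matrix rows must match the number of scheme directions")
  if (ridge_weight < 0) stop("ridge_weight must be nonnegative")
  if (ridge_weight == 0) {
    qr_ <- qr(B)
    if (qr_$rank < ncol(B))
      stop("rank-deficient SH basis for this direction set")
    co <- qr.coef(qr_, adc_matrix)
  } else {
    pen <- diag(ncol(B)) * ridge_weight
    pen[1, 1] <- 0  # never shrink the mean term
    co <- solve(crossprod(B) + pen, crossprod(B, adc_matrix))
  }
  rownames(co) <- sh_coefficient_names(max_order)
  co
}

#' Evaluate an ADC profile at unit directions
#' @param profile an [adc_profile()].
#' @param directions n x 3 matrix of unit vectors (or one 3-vector).
#' @return numeric vector of ADC values (mm^2/s).
#' @export
evaluate_profile <- function(profile, directions) {
  stopifnot(inherits(profile, "adc_profile"))
  drop(sh_basis(directions, profile$max_order) %*% profile$coefficients)
}

#' Curvature (tangent-plane Hessian) of the ADC profile at a direction
#'
#' Second derivative of f restricted to the unit sphere at the direction `n`,
#' expressed in an orthonormal tangent basis at `n`. Computed by central
#' finite differences with tangent step `h` radians, perturbed points being
#' re-projected to the sphere; by default a Richardson extrapolation over
#' steps `h` and `h/2` removes the leading O(h^2) truncation term, so the
#' eigenvalues are reproducible to ~1e-8 relative across tangent-basis
#' choices and co-rotations. The eigenvalues of the returned matrix are
#' independent of the tangent-basis choice.
#'
#' @param profile an [adc_profile()].
#' @param n unit 3-vector.
#' @param h finite-difference step in radians (default 1e-3).
#' @param basis optional 3 x 2 tangent basis; defaults to [perp_basis()].
#' @param richardson extrapolate over `h` and `h/2` (default TRUE).
#' @return symmetric 2 x 2 matrix.
#' @export
tangent_hessian <- function(profile, n, h = 1e-3, basis = NULL,
                            richardson = TRUE) {
  n <- as.numeric(n)
  stopifnot(abs(sum(n^2) - 1) < 1e-6)
  if (is.null(basis)) basis <- perp_basis(n)
  if (richardson) {
    H1 <- tangent_hessian(profile, n, h = h, basis = basis,
                          richardson = FALSE)
    H2 <- tangent_hessian(profile, n, h = h / 2, basis = basis,
                          richardson = FALSE)
    return((4 * H2 - H1) / 3)
  }
  e1 <- basis[, 1]; e2 <- basis[, 2]
  pts <- rbind(n,
               n + h * e1, n - h * e1,
               n + h * e2, n - h * e2,
               n + h * e1 + h * e2, n + h * e1 - h * e2,
               n - h * e1 + h * e2, n - h * e1 - h * e2)
  pts <- normalize_rows(pts)
  f <- evaluate_profile(profile, pts)
  h11 <- (f[2] - 2 * f[1] + f[3]) / h^2
  h22 <- (f[4] - 2 * f[1] + f[5]) / h^2
  h12 <- (f[6] - f[7] - f[8] + f[9]) / (4 * h^2)
  matrix(c(h11, h12, h12, h22), 2, 2)
}
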