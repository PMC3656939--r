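## The 27-element per-vertex tissue fingerprint. Seven families:
##   1. mean of f over the sphere
##   2. central moments of f over the sphere, k = 2..10
##   3. f along the local cortical normal n
##   4. mean of f on the unit circle perpendicular to n
##   5. central moments of f on that circle, k = 2..10
##   6. the two eigenvalues of the Hessian of f at n (descending)
##   7. per-order SH power invariants, k = 0, 2, 4, 6
## Families 1, 2 and 7 are fully rotation invariant; 3-6 are referenced to n
## and invariant only under co-rotation of the data with n.

#' Canonical names of the 27 features, in order
#' @return character vector of length 27.
#' @export
feature_names <- function() {
  c("mean_sphere", sprintf("mom_sphere_k%d", 2:10),
    "adc_normal", "mean_perp", sprintf("mom_perp_k%d", 2:10),
    "hess_eig1", "hess_eig2",
    sprintf("shpow_k%d", c(0, 2, 4, 6)))
}

#' Mean of the ADC profile over the unit sphere
#'
#' (1/4pi) * integral of f over S, by quadrature.
#'
#' @param profile an [adc_profile()].
#' @param quad a [sphere_quadrature()].
#' @return mean ADC (mm^2/s).
#' @export
sphere_mean <- function(profile, quad = sphere_quadrature()) {
  f <- drop(quad_sh_basis(quad, profile$max_order) %*% profile$coefficients)
  sum(quad$weights * f) / (4 * pi)
}

#' Central moments of the ADC profile over the sphere
#'
#' mu_k = (1/4pi) * integral of (f - mean)^k over S for k in `k_range`.
#' Central moments decouple the profile's shape from its mean; raw moments
#' (about zero) are available with `central = FALSE`.
#'
#' @param profile an [adc_profile()].
#' @param quad a [sphere_quadrature()].
#' @param k_range integer moment orders (default 2:10).
#' @param central subtract the sphere mean first (default TRUE).
#' @return named numeric vector of moments.
#' @export
sphere_moments <- function(profile, quad = sphere_quadrature(),
                           k_range = 2:10, central = TRUE) {
  stopifnot(all(k_range >= 2))
  f <- drop(quad_sh_basis(quad, profile$max_order) %*% profile$coefficients)
  if (central) f <- f - sum(quad$weights * f) / (4 * pi)
  mom <- vapply(k_range, function(k) sum(quad$weights * f^k) / (4 * pi),
                numeric(1))
  names(mom) <- sprintf("mom_sphere_k%d", k_range)
  mom
}

#' ADC along the local cortical normal
#' @param profile an [adc_profile()].
#' @param n unit 3-vector.
#' @return f(n) (mm^2/s).
#' @export
adc_along_normal <- function(profile, n) {
  evaluate_profile(profile, n)
}

#' Mean ADC on the unit circle perpendicular to n
#'
#' (1/2pi) * integral of f over C(n): the mean ADC in the plane of the
#' cortex. The in-plane basis is deterministic but the result is invariant
#' to its choice.
#'
#' @param profile an [adc_profile()].
#' @param n unit 3-vector.
#' @param quad a [sphere_quadrature()] (supplies `circle_samples`).
#' @return mean in-plane ADC (mm^2/s).
#' @export
perp_mean <- function(profile, n, quad = sphere_quadrature()) {
  f <- evaluate_profile(profile, circle_directions(n, quad$circle_samples))
  mean(f)
}

#' Central moments of the ADC profile on the circle perpendicular to n
#'
#' mu_k = (1/2pi) * integral of (f - perp mean)^k over C(n).
#'
#' @inheritParams perp_mean
#' @param k_range integer moment orders (default 2:10).
#' @param central subtract the in-plane mean first (default TRUE).
#' @return named numeric vector of moments.
#' @export
perp_moments <- function(profile, n, quad = sphere_quadrature(),
                         k_range = 2:10, central = TRUE) {
  stopifnot(all(k_range >= 2))
  f <- evaluate_profile(profile, circle_directions(n, quad$circle_samples))
  if (central) f <- f - mean(f)
  mom <- vapply(k_range, function(k) mean(f^k), numeric(1))
  names(mom) <- sprintf("mom_perp_k%d", k_range)
  mom
}

#' Eigenvalues of the profile Hessian at n, descending
#'
#' Principal curvatures of the ADC profile on the sphere at the local
#' normal; sensitive to the dispersion of fibre orientations.
#'
#' @param profile an [adc_profile()].
#' @param n unit 3-vector.
#' @param h finite-difference step passed to [tangent_hessian()].
#' @return numeric length-2 vector, largest first.
#' @export
hessian_eigenvalues <- function(profile, n, h = 1e-3) {
  sort(eigen(tangent_hessian(profile, n, h = h), symmetric = TRUE,
             only.values = TRUE)$values, decreasing = TRUE)
}

#' Per-order rotation-invariant SH power
#'
#' P_k = sum over i of a_ki^2 for each even order k: the squared L2 norm of f
#' projected onto order k, invariant under any rotation of the profile. A
#' square-root (RMS-amplitude) variant is available with `sqrt_variant`.
#'
#' @param profile an [adc_profile()].
#' @param orders even orders to report (default 0, 2, 4, 6).
#' @param sqrt_variant return sqrt(P_k) instead (default FALSE).
#' @return named numeric vector.
#' @export
order_power_invariants <- function(profile, orders = c(0, 2, 4, 6),
                                   sqrt_variant = FALSE) {
  co <- profile$coefficients
  ks <- as.integer(sub("^a_(\\d+)_.*$", "\\1", names(co)))
  p <- vapply(orders, function(k) sum(co[ks == k]^2), numeric(1))
  if (sqrt_variant) p <- sqrt(p)
  names(p) <- sprintf("shpow_k%d", orders)
  p
}

#' Assemble the canonical 27-element feature vector
#'
#' @param profile an [adc_profile()] of max order >= 6 for the full power
#'   family (order 6 is the default fit).
#' @param n local unit normal.
#' @param quad a [sphere_quadrature()].
#' @param h Hessian finite-difference step.
#' @return named numeric vector of length 27 in [feature_names()] order.
#' @export
assemble_feature_vector <- function(profile, n, quad = sphere_quadrature(),
                                    h = 1e-3) {
  v <- c(mean_sphere = sphere_mean(profile, quad),
         sphere_moments(profile, quad),
         adc_normal = adc_along_normal(profile, n),
         mean_perp = perp_mean(profile, n, quad),
         perp_moments(profile, n, quad),
         hess_eig1 = NA_real_, hess_eig2 = NA_real_,
         order_power_invariants(profile))
  he <- hessian_eigenvalues(profile, n, h = h)
  v["hess_eig1"] <- he[1]
  v["hess_eig2"] <- he[2]
  stopifnot(identical(names(v), feature_names()))
  v
}

#' Compute feature vectors for a table of vertex records
#'
#' Runs the full per-vertex chain (log transform, SH fit, 27 features) over
#' an extracted vertex-record table. The sphere-integral features are
#' evaluated for all vertices in one pass through the quadrature basis; the
#' normal-referenced features loop over vertices.
#'
#' @param records vertex-record data frame from [extract_vertex_records()]
#'   (columns `vertex_id`, `nx`, `ny`, `nz`, `ref`, `i001`...).
#' @param scheme the [gradient_scheme()] of the acquisition.
#' @param max_order maximum even SH order (default 6).
#' @param quad a [sphere_quadrature()].
#' @param ridge_weight ridge penalty for the SH fit (default 0).
#' @param log_floor relative signal clamp floor for the log transform.
#' @return data frame: `vertex_id` then the 27 features in canonical order.
#'   The number of clamped signals is attached as attribute `n_clamped`.
#' @export
compute_features <- function(records, scheme, max_order = 6,
                             quad = sphere_quadrature(), ridge_weight = 0,
                             log_floor = 1e-6) {
  icols <- grep("^i\\d+$", names(records), value = TRUE)
  if (length(icols) != nrow(scheme$directions))
    stop("record intensity columns do not match the gradient scheme")
  nv <- nrow(records)
  sig <- t(as.matrix(records[, icols]))      # n_dir x n_vertex
  adc <- matrix(0, nrow(sig), ncol(sig))
  n_clamped <- 0L
  for (j in seq_len(nv)) {
    a <- signal_to_adc(sig[, j], records$ref[j], scheme$bvalues,
                       log_floor = log_floor)
    adc[, j] <- a$adc
    n_clamped <- n_clamped + a$n_clamped
  }
  co <- fit_adc_profiles(adc, scheme, max_order = max_order,
                         ridge_weight = ridge_weight)

  B <- quad_sh_basis(quad, max_order)
  fs <- B %*% co                              # sphere samples, pts x vertices
  w <- quad$weights
  m_sphere <- colSums(w * fs) / (4 * pi)
  dev <- sweep(fs, 2, m_sphere)
  mom_sphere <- vapply(2:10, function(k) colSums(w * dev^k) / (4 * pi),
                       numeric(nv))
  ks <- as.integer(sub("^a_(\\d+)_.*$", "\\1", sh_coefficient_names(max_order)))
  pow <- vapply(c(0, 2, 4, 6), function(k)
    colSums(co[ks == k, , drop = FALSE]^2), numeric(nv))

  normal_feats <- matrix(0, nv, 13L)
  for (j in seq_len(nv)) {
    pr <- adc_profile(co[, j], max_order = max_order,
                      bvalue = scheme$bvalues[1])
    n <- c(records$nx[j], records$ny[j], records$nz[j])
    fc <- evaluate_profile(pr, circle_directions(n, quad$circle_samples))
    mc <- mean(fc)
    dc <- fc - mc
    he <- hessian_eigenvalues(pr, n)
    normal_feats[j, ] <- c(evaluate_profile(pr, n), mc,
                           vapply(2:10, function(k) mean(dc^k), numeric(1)),
                           he)
  }

  out <- data.frame(vertex_id = records$vertex_id,
                    mean_sphere = m_sphere)
  out[sprintf("mom_sphere_k%d", 2:10)] <- if (nv == 1L) as.list(mom_sphere) else
    as.data.frame(mom_sphere)
  out[c("adc_normal", "mean_perp", sprintf("mom_perp_k%d", 2:10),
        "hess_eig1", "hess_eig2")] <- as.data.frame(normal_feats)
  out[sprintf("shpow_k%d", c(0, 2, 4, 6))] <- if (nv == 1L) as.list(pow) else
    as.data.frame(pow)
  stopifnot(identical(names(out), c("vertex_id", feature_names())))
  attr(out, "n_clamped") <- n_clamped
  out
}
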