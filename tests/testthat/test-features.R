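test_that("sphere features match single-tensor closed forms", {
  quad <- fixture_quad()
  D <- diag(c(1.7, 0.5, 0.2)) * 1e-3
  pr <- tensor_profile(D)

  expect_equal(sphere_mean(pr, quad), sum(diag(D)) / 3, tolerance = 1e-8)

  iso <- fit_adc_profile(rep(6e-4, 61), fixture_scheme())
  expect_equal(sphere_mean(iso, quad), 6e-4, tolerance = 1e-10)
  expect_lt(max(abs(sphere_moments(iso, quad))), 1e-12)

  ## rotational invariance of the mean
  R <- random_rotation(seed = 2)
  prR <- tensor_profile(R %*% D %*% t(R))
  expect_equal(sphere_mean(prR, quad), sphere_mean(pr, quad),
               tolerance = 1e-8)

  ## quadrature refinement changes nothing material
  fine <- sphere_quadrature(72, 144, 1440)
  expect_equal(sphere_mean(pr, fine), sphere_mean(pr, quad),
               tolerance = 1e-8)
  expect_equal(sphere_moments(pr, fine)["mom_sphere_k2"],
               sphere_moments(pr, quad)["mom_sphere_k2"], tolerance = 1e-7)
})

test_that("sphere moments scale homogeneously and match dense quadrature", {
  quad <- fixture_quad()
  D <- diag(c(1.4, 0.6, 0.3)) * 1e-3
  pr <- tensor_profile(D)
  pr3 <- pr; pr3$coefficients <- 3 * pr$coefficients
  m1 <- sphere_moments(pr, quad); m3 <- sphere_moments(pr3, quad)
  for (k in 2:4)
    expect_equal(m3[[sprintf("mom_sphere_k%d", k)]],
                 3^k * m1[[sprintf("mom_sphere_k%d", k)]], tolerance = 1e-10)
  expect_true(all(m1[c(1, 3, 5, 7, 9)] >= 0))  # even-k moments

  dense <- sphere_quadrature(120, 240)
  expect_equal(m1[["mom_sphere_k2"]],
               sphere_moments(pr, dense)[["mom_sphere_k2"]],
               tolerance = 1e-7)
})

test_that("normal-referenced features match their closed forms", {
  quad <- fixture_quad()
  lam <- c(1.7e-3, 0.5e-3, 0.2e-3)
  D <- diag(lam)
  pr <- tensor_profile(D)

  for (i in 1:3) {
    n <- diag(3)[, i]
    expect_equal(adc_along_normal(pr, n), lam[i], tolerance = 1e-9)
  }
  expect_equal(adc_along_normal(pr, c(0, 0, 1)),
               evaluate_profile(pr, c(0, 0, 1)))

  set.seed(8)
  for (rep in 1:5) {
    n <- stats::rnorm(3); n <- n / sqrt(sum(n^2))
    expect_equal(perp_mean(pr, n, quad),
                 (sum(lam) - drop(t(n) %*% D %*% n)) / 2, tolerance = 1e-8)
  }
  iso <- fit_adc_profile(rep(9e-4, 61), fixture_scheme())
  expect_equal(perp_mean(iso, c(0, 1, 0), quad), 9e-4, tolerance = 1e-10)

  ## co-rotation invariance of the in-plane mean
  R <- random_rotation(seed = 13)
  prR <- tensor_profile(R %*% D %*% t(R))
  n0 <- c(1, 2, 2) / 3
  expect_equal(perp_mean(prR, as.numeric(R %*% n0), quad),
               perp_mean(pr, n0, quad), tolerance = 1e-9)
})

test_that("in-plane moments match a dense circle average", {
  quad <- fixture_quad()
  D <- diag(c(1.7e-3, 2e-4, 2e-4))   # prolate along x
  pr <- tensor_profile(D)
  n <- c(0, 0, 1)                     # axis perpendicular to n
  m <- perp_moments(pr, n, quad)
  expect_gt(m[["mom_perp_k2"]], 0)

  ## brute force: 1e4 circle samples evaluated on the quadratic form itself
  ang <- 2 * pi * (0:9999) / 1e4
  u <- cbind(cos(ang), sin(ang), 0)
  f <- rowSums((u %*% D) * u)
  brute <- vapply(2:10, function(k) mean((f - mean(f))^k), numeric(1))
  expect_equal(unname(m), brute, tolerance = 1e-6)

  ## axis parallel to n: in-plane profile constant
  m_par <- perp_moments(pr, c(1, 0, 0), quad)
  expect_lt(max(abs(m_par)), 1e-9)
  iso <- fit_adc_profile(rep(5e-4, 61), fixture_scheme())
  expect_lt(max(abs(perp_moments(iso, n, quad))), 1e-12)
})

test_that("Hessian eigenvalue features follow the curvature oracle", {
  lam <- c(1.7e-3, 0.5e-3, 0.2e-3)
  pr <- tensor_profile(diag(lam))
  ev <- hessian_eigenvalues(pr, c(0, 0, 1))
  expect_gte(ev[1], ev[2])
  expect_equal(ev, 2 * (lam[1:2] - lam[3]), tolerance = 1e-6)

  ## swapping the two in-plane eigenvalues leaves the set unchanged
  pr_sw <- tensor_profile(diag(lam[c(2, 1, 3)]))
  expect_equal(hessian_eigenvalues(pr_sw, c(0, 0, 1)), ev, tolerance = 1e-9)

  iso <- fit_adc_profile(rep(8e-4, 61), fixture_scheme())
  expect_lt(max(abs(hessian_eigenvalues(iso, c(0, 1, 0)))), 1e-6)
})

test_that("per-order SH power is rotation invariant and homogeneous", {
  sch <- fixture_scheme()
  mix <- tissue_class("mix", list(
    list(mode = "fixed", fraction = 0.7, eigenvalues = c(1.6e-3, 3e-4, 2e-4),
         axis = c(1, 1, 0) / sqrt(2)),
    list(mode = "fixed", fraction = 0.3, eigenvalues = rep(8e-4, 3),
         axis = c(0, 0, 1))))
  s <- simulate_class_signal(mix, c(0, 0, 1), sch, 1000)
  adc <- signal_to_adc(s, 1000, 1000)$adc
  pr <- fit_adc_profile(adc, sch)
  p0 <- order_power_invariants(pr)
  expect_true(all(p0 >= 0))

  ## refit on rotated direction sets: each order's power is preserved
  for (seed in 1:100) {
    R <- random_rotation(seed = 100 + seed)
    prR <- fit_adc_profile(adc, gradient_scheme(sch$directions %*% t(R),
                                                sch$bvalues))
    expect_equal(order_power_invariants(prR), p0, tolerance = 1e-8)
  }

  pr2 <- pr; pr2$coefficients <- 2 * pr$coefficients
  expect_equal(order_power_invariants(pr2), 4 * p0, tolerance = 1e-12)

  iso <- fit_adc_profile(rep(8e-4, 61), sch)
  expect_lt(max(order_power_invariants(iso)[-1]), 1e-18)
})

test_that("the assembled 27-vector has the canonical layout and values", {
  quad <- fixture_quad()
  iso <- fit_adc_profile(rep(8e-4, 61), fixture_scheme())
  v <- assemble_feature_vector(iso, c(0, 0, 1), quad)
  expect_length(v, 27)
  expect_identical(names(v), feature_names())
  d <- 8e-4
  expect_equal(unname(v[c("mean_sphere", "adc_normal", "mean_perp")]),
               rep(d, 3), tolerance = 1e-9)
  expect_lt(max(abs(v[sprintf("mom_sphere_k%d", 2:10)])), 1e-12)
  expect_lt(max(abs(v[sprintf("mom_perp_k%d", 2:10)])), 1e-12)
  expect_lt(max(abs(v[c("hess_eig1", "hess_eig2")])), 1e-6)
  expect_equal(unname(v["shpow_k0"]), (d * sqrt(4 * pi))^2, tolerance = 1e-9)
  expect_lt(max(abs(v[c("shpow_k2", "shpow_k4", "shpow_k6")])), 1e-18)
  expect_gte(v["hess_eig1"], v["hess_eig2"])
})

test_that("invariance partitions: data rotation vs co-rotation", {
  quad <- fixture_quad()
  sch <- fixture_scheme()
  D <- diag(c(1.7e-3, 3e-4, 2e-4))   # prolate, axis x
  adc <- rowSums((sch$directions %*% D) * sch$directions)
  pr <- fit_adc_profile(adc, sch)
  n <- c(0, 0, 1)
  base <- assemble_feature_vector(pr, n, quad)
  inv_idx <- c(1:10, 24:27)
  ref_idx <- 11:23

  R <- random_rotation(seed = 31)
  prR <- fit_adc_profile(adc, gradient_scheme(sch$directions %*% t(R),
                                              sch$bvalues))
  rot_only <- assemble_feature_vector(prR, n, quad)
  corot <- assemble_feature_vector(prR, as.numeric(R %*% n), quad)

  scale_ref <- pmax(abs(base), 1e-12)
  expect_lt(max(abs(rot_only[inv_idx] - base[inv_idx]) / scale_ref[inv_idx]),
            1e-7)
  expect_lt(max(abs(corot - base) / scale_ref), 1e-7)
  ## normal-referenced entries must actually move under data-only rotation
  expect_gt(max(abs(rot_only[ref_idx] - base[ref_idx]) / scale_ref[ref_idx]),
            1e-3)
})
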