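test_that("vertex normals follow mesh geometry and orientation", {
  flat <- make_ribbon_surfaces(10, 6, fold_amplitude = 0)
  nrm <- vertex_normals(flat$inner_vertices, flat$faces, flat$outer_vertices)
  expect_true(all(abs(sweep(nrm, 2, c(0, 0, 1))) < 1e-10))

  ## unit sphere: vertex normal within 2 degrees of the radial direction
  sph <- icosphere_mesh(3)
  out <- sph$vertices * 1.1
  nrm <- vertex_normals(sph$vertices, sph$faces, out)
  ang <- acos(pmin(1, rowSums(nrm * sph$vertices)))
  expect_lt(max(ang) * 180 / pi, 2)

  ## zero-area face excluded with a warning
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  f <- rbind(c(1, 2, 3), c(1, 1, 2))
  expect_warning(nrm <- vertex_normals(v, f), "zero-area")
  expect_true(all(abs(nrm[, 3]) == 1))
})

test_that("mid-thickness sampling interpolates trilinearly in world space", {
  surf <- make_ribbon_surfaces(6, 4, fold_amplitude = 0)
  surf$inner_vertices[, 3] <- surf$inner_vertices[, 3] + 1  # lift off z=0
  surf$outer_vertices[, 3] <- surf$outer_vertices[, 3] + 1
  dims <- c(10, 8, 8)
  const <- array(4.25, dims)
  aff <- diag(4)
  ms <- midpoint_sample(const, aff, surf)
  expect_true(all(ms$samples == 4.25))
  expect_false(any(ms$missing))

  ## linear field v(x,y,z) = x_world is reproduced exactly at the sample point
  xs <- array(rep(0:(dims[1] - 1), prod(dims[2:3])), dims)
  p <- surf$inner_vertices + 0.5 * (surf$outer_vertices - surf$inner_vertices)
  ms <- midpoint_sample(xs, aff, surf)
  expect_equal(drop(ms$samples), p[, 1], tolerance = 1e-9)

  ## fraction endpoints
  zfield <- array(rep(0:(dims[3] - 1), each = prod(dims[1:2])), dims)
  m0 <- midpoint_sample(zfield, aff, surf, fraction = 0)
  expect_equal(drop(m0$samples), surf$inner_vertices[, 3], tolerance = 1e-12)
  m1 <- midpoint_sample(zfield, aff, surf, fraction = 1)
  expect_equal(drop(m1$samples), surf$outer_vertices[, 3], tolerance = 1e-12)

  ## a vertex outside the volume is flagged missing
  surf$outer_vertices[1, 3] <- 50
  mm <- midpoint_sample(zfield, aff, surf)
  expect_true(mm$missing[1])
  expect_true(all(is.na(mm$samples[1, ])))
})

test_that("drift correction is the stated incremental translation", {
  dims <- c(12, 12, 6, 68)
  aff <- diag(4)
  yfield <- array(rep(rep(0:(dims[2] - 1), each = dims[1]), dims[3] * dims[4]),
                  dims)
  expect_identical(drift_correct(yfield, aff, c(0, 0, 0)), yfield)

  Tv <- c(0, 0.68, 0)
  out <- drift_correct(yfield, aff, Tv, n_volumes = 68)
  ## volume j is translated by j*T/68: the linear-in-y field drops by that much
  interior <- 4:9
  for (j in c(1, 34, 68)) {
    shift <- j * Tv[2] / 68
    expect_equal(out[6, interior, 3, j] , yfield[6, interior, 3, j] - shift,
                 tolerance = 1e-9)
  }

  ## forward then backward drift recovers a smooth field away from edges
  sm <- array(0, dims[1:3])
  co <- expand.grid(x = 1:dims[1], y = 1:dims[2], z = 1:dims[3])
  sm[] <- sin(co$x / 6) * cos(co$y / 8) + co$z / 10
  stack <- array(sm, c(dims[1:3], 4))
  fwd <- drift_correct(stack, aff, c(0.4, -0.3, 0.2), n_volumes = 4)
  back <- drift_correct(fwd, aff, -c(0.4, -0.3, 0.2), n_volumes = 4)
  expect_lt(max(abs(back[3:10, 3:10, 2:5, ] - stack[3:10, 3:10, 2:5, ])),
            0.02)
})

test_that("surface smoothing is averaging with the stated fixed points", {
  surf <- make_ribbon_surfaces(20, 20, fold_amplitude = 0)
  v <- rep(3.5, 400)
  expect_equal(smooth_on_surface(v, surf$faces, 5), v)
  x <- stats::rnorm(400)
  expect_identical(smooth_on_surface(x, surf$faces, 0), x)
  sm <- smooth_on_surface(x, surf$faces, 2)
  expect_gte(min(sm), min(x))
  expect_lte(max(sm), max(x))

  ## unit impulse at the interior of a regular grid: mass conserved per
  ## iteration while the response stays away from the boundary
  imp <- numeric(400)
  imp[10 * 20 + 10] <- 1
  for (it in 1:3)
    expect_equal(sum(smooth_on_surface(imp, surf$faces, it)), 1,
                 tolerance = 1e-9)
})

test_that("smoothing kernel width calibrates near the 1.8 mm target", {
  surf <- make_ribbon_surfaces(40, 20, spacing = 1, fold_amplitude = 0)
  fwhm <- smoothing_fwhm(surf$inner_vertices, surf$faces, iterations = 1)
  expect_gt(fwhm, 1.5)
  expect_lt(fwhm, 2.1)
})

test_that("record extraction produces the per-vertex layout and flags misses", {
  ph <- build_phantom(phantom_spec(vertices_per_class = 20, n_trans = 4,
                                   snr = Inf))
  rec <- extract_vertex_records(ph$repeats[[1]], ph$affine, ph$surface,
                                ph$scheme)
  expect_equal(sum(grepl("^i\\d+$", names(rec))), 61)
  expect_equal(nrow(rec), 60)
  expect_equal(attr(rec, "n_missing"), 0)
  expect_true(all(c("vertex_id", "x", "y", "z", "nx", "ny", "nz",
                    "voxel_id", "ref") %in% names(rec)))
  expect_false(anyDuplicated(rec$vertex_id) > 0)

  ## push one vertex far outside the volume: dropped and counted
  surf2 <- ph$surface
  surf2$inner_vertices[5, ] <- c(500, 500, 500)
  surf2$outer_vertices[5, ] <- c(500, 500, 503)
  rec2 <- extract_vertex_records(ph$repeats[[1]], ph$affine, surf2,
                                 ph$scheme)
  expect_equal(attr(rec2, "n_missing"), 1)
  expect_false(4 %in% rec2$vertex_id)  # vertex ids are 0-based
})

test_that("sampling commutes with rigid translation of volume and surfaces", {
  ph <- build_phantom(phantom_spec(vertices_per_class = 12, n_trans = 4,
                                   snr = 20))
  t0 <- c(3.5, -2.25, 1.75)
  aff2 <- ph$affine
  aff2[1:3, 4] <- aff2[1:3, 4] + t0
  surf2 <- ph$surface
  surf2$inner_vertices <- sweep(surf2$inner_vertices, 2, -t0)
  surf2$outer_vertices <- sweep(surf2$outer_vertices, 2, -t0)
  r1 <- extract_vertex_records(ph$repeats[[1]], ph$affine, ph$surface,
                               ph$scheme)
  r2 <- extract_vertex_records(ph$repeats[[1]], aff2, surf2, ph$scheme)
  icols <- grep("^i\\d+$", names(r1))
  expect_equal(as.matrix(r2[, icols]), as.matrix(r1[, icols]),
               tolerance = 1e-9)
  expect_identical(r2$voxel_id, r1$voxel_id)
})
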