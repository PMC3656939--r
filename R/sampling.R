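## Per-vertex extraction of DWI signals at cortical mid-thickness, with
## B0-drift correction and iterative surface-based smoothing.

#' Area-weighted per-vertex normals of a triangle mesh
#'
#' Averages incident face normals weighted by face area, then normalizes.
#' Zero-area faces are excluded from the average with a warning. When a
#' matching outer surface is supplied the normals are flipped, vertex by
#' vertex, to point from the inner toward the outer surface.
#'
#' @param vertices n x 3 matrix (mm).
#' @param faces m x 3 matrix of 1-based indices.
#' @param outer_vertices optional n x 3 matrix fixing the outward
#'   orientation.
#' @return n x 3 matrix of unit normals.
#' @export
vertex_normals <- function(vertices, faces, outer_vertices = NULL) {
  vertices <- as_dir_matrix(vertices)
  faces <- as.matrix(faces)
  a <- vertices[faces[, 1], , drop = FALSE]
  ab <- vertices[faces[, 2], , drop = FALSE] - a
  ac <- vertices[faces[, 3], , drop = FALSE] - a
  fn <- cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])  # 2*area weighted
  area2 <- sqrt(rowSums(fn^2))
  if (any(area2 == 0)) {
    warning(sum(area2 == 0), " zero-area face(s) excluded from normals")
    fn <- fn[area2 > 0, , drop = FALSE]
    faces <- faces[area2 > 0, , drop = FALSE]
  }
  nrm <- matrix(0, nrow(vertices), 3)
  for (j in 1:3) {
    for (d in 1:3) {
      s <- tapply(fn[, d], faces[, j], sum)
      idx <- as.integer(names(s))
      nrm[idx, d] <- nrm[idx, d] + s
    }
  }
  bad <- rowSums(nrm^2) == 0
  if (any(bad)) nrm[bad, 3] <- 1
  nrm <- normalize_rows(nrm)
  if (!is.null(outer_vertices)) {
    flip <- rowSums(nrm * (as_dir_matrix(outer_vertices) - vertices)) < 0
    nrm[flip, ] <- -nrm[flip, ]
  }
  nrm
}

#' Sample a DWI stack at a fixed cortical depth along the local normal
#'
#' For each vertex the sample point is
#' `inner + fraction * (outer - inner)` (mid-thickness at the default
#' fraction 0.5). World coordinates map to voxel space through the inverse
#' affine; each volume of the stack is sampled by trilinear interpolation.
#' Vertices whose sample point falls outside the volume are flagged missing.
#'
#' @param volume_4d 4D array (or 3D for a single volume).
#' @param affine 4 x 4 voxel-to-world matrix (0-based voxel indices).
#' @param surface a `surface_model`.
#' @param fraction cortical depth fraction in [0, 1] (default 0.5).
#' @return list with `samples` (n_vertices x n_volumes matrix, NA rows for
#'   missing vertices), `voxel_id` (0-based linearized index of the
#'   containing voxel) and `missing` (logical vector).
#' @export
midpoint_sample <- function(volume_4d, affine, surface, fraction = 0.5) {
  stopifnot(fraction >= 0, fraction <= 1)
  d <- dim(volume_4d)
  if (length(d) == 3) {
    volume_4d <- array(volume_4d, c(d, 1))
    d <- dim(volume_4d)
  }
  p <- surface$inner_vertices +
    fraction * (surface$outer_vertices - surface$inner_vertices)
  vox <- world_to_voxel(p, affine)
  missing <- apply(vox, 1, function(v) any(v < 0 | v > d[1:3] - 1))
  nv <- nrow(vox)
  samples <- matrix(NA_real_, nv, d[4])
  ok <- which(!missing)
  for (t in seq_len(d[4]))
    samples[ok, t] <- trilinear_interp(volume_4d[, , , t],
                                       vox[ok, , drop = FALSE])
  near <- round(vox)
  voxel_id <- as.integer(near[, 1] + d[1] * (near[, 2] + d[2] * near[, 3]))
  voxel_id[missing] <- NA_integer_
  list(samples = samples, voxel_id = voxel_id, missing = missing)
}

#' Incremental translation correction for B0 drift
#'
#' Volume j (1-based) of the stack is translated by `j * T / n_volumes`
#' (world mm), the monotonic per-volume increment that cancels a linear
#' field drift over the acquisition. Resampling is trilinear with
#' nearest-edge padding; `T = c(0,0,0)` returns the stack unchanged.
#'
#' @param volume_stack 4D array.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param translation 3-vector T (mm): the total drift measured between the
#'   reference volumes of successive datasets.
#' @param n_volumes divisor of the increment (default 68, the combined
#'   volume count over which the drift translation is measured).
#' @return corrected 4D array.
#' @export
drift_correct <- function(volume_stack, affine, translation,
                          n_volumes = 68) {
  stopifnot(length(translation) == 3, all(is.finite(translation)),
            n_volumes >= 1)
  d <- dim(volume_stack)
  if (all(translation == 0)) return(volume_stack)
  vox_shift_per <- solve(affine[1:3, 1:3], translation) / n_volumes
  ctr <- as.matrix(expand.grid(x = 0:(d[1] - 1), y = 0:(d[2] - 1),
                               z = 0:(d[3] - 1)))
  out <- volume_stack
  for (j in seq_len(d[4])) {
    src <- sweep(ctr, 2, j * vox_shift_per, "-")
    out[, , , j] <- array(trilinear_interp(volume_stack[, , , j], src),
                          d[1:3])
  }
  out
}

#' Iterative neighbor-mean smoothing of per-vertex values on a mesh
#'
#' Each iteration replaces a vertex value by the unweighted mean of itself
#' and its mesh neighbors. A constant field is a fixed point and the value
#' range never expands. The kernel width grows with the iteration count;
#' see [smoothing_fwhm()] to calibrate iterations against a target FWHM.
#'
#' @param values numeric vector (or matrix, one column per measurement,
#'   smoothed independently) of per-vertex values.
#' @param faces m x 3 matrix of 1-based indices.
#' @param iterations number of smoothing passes (0 = identity).
#' @return smoothed values with the input's shape.
#' @export
smooth_on_surface <- function(values, faces, iterations = 1) {
  stopifnot(iterations >= 0)
  if (iterations == 0) return(values)
  vec <- is.null(dim(values))
  v <- as.matrix(values)
  nb <- neighbor_list(faces, nrow(v))
  deg <- lengths(nb)
  for (it in seq_len(iterations)) {
    acc <- v
    for (i in seq_len(nrow(v)))
      acc[i, ] <- (v[i, ] + colSums(v[nb[[i]], , drop = FALSE])) / (deg[i] + 1)
    v <- acc
  }
  if (vec) drop(v) else v
}

#' @noRd
neighbor_list <- function(faces, n_vertices) {
  faces <- as.matrix(faces)
  ed <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  ed <- rbind(ed, ed[, 2:1])
  ed <- unique(ed)
  split(ed[, 2], factor(ed[, 1], levels = seq_len(n_vertices)))
}

#' FWHM of the smoothing impulse response on a mesh
#'
#' Places a unit impulse at `center_vertex`, smooths, and estimates the
#' full width at half maximum of the response assuming an isotropic 2D
#' Gaussian on the surface: FWHM = 2.3548 * sigma with
#' sigma^2 = E[r^2] / 2 under the response weights.
#'
#' @param vertices n x 3 vertex coordinates (mm).
#' @param faces m x 3 face indices.
#' @param iterations smoothing passes.
#' @param center_vertex impulse location (default: vertex nearest the
#'   centroid).
#' @return FWHM in mm.
#' @export
smoothing_fwhm <- function(vertices, faces, iterations = 1,
                           center_vertex = NULL) {
  vertices <- as_dir_matrix(vertices)
  if (is.null(center_vertex)) {
    ctr <- colMeans(vertices)
    center_vertex <- which.min(rowSums(sweep(vertices, 2, ctr)^2))
  }
  imp <- numeric(nrow(vertices))
  imp[center_vertex] <- 1
  resp <- smooth_on_surface(imp, faces, iterations)
  r2 <- rowSums(sweep(vertices, 2, vertices[center_vertex, ])^2)
  sigma2 <- sum(resp * r2) / sum(resp) / 2
  2 * sqrt(2 * log(2)) * sqrt(sigma2)
}

#' Extract per-vertex DWI records at mid-thickness
#'
#' Samples the reference volume and every DWI at the mid-thickness point of
#' each vertex, optionally smooths each direction's values across the
#' surface, and assembles the per-vertex record table: vertex id, world
#' position, local normal, containing-voxel id, reference intensity and one
#' intensity per diffusion direction. Vertices sampling outside the volume
#' are dropped; their count is attached as attribute `n_missing`.
#'
#' @param volume_stack 4D array, volume 1 the reference then one volume per
#'   scheme direction.
#' @param affine 4 x 4 voxel-to-world matrix.
#' @param surface a `surface_model`.
#' @param scheme the [gradient_scheme()] (defines the intensity count).
#' @param fraction cortical depth fraction (default 0.5).
#' @param smooth_iterations surface-smoothing passes applied within each
#'   direction (default 0).
#' @return data frame of vertex records (`vertex_id` is 0-based).
#' @export
extract_vertex_records <- function(volume_stack, affine, surface, scheme,
                                   fraction = 0.5, smooth_iterations = 0) {
  n_dir <- nrow(scheme$directions)
  if (dim(volume_stack)[4] != n_dir + 1L)
    stop("volume stack must hold 1 reference + ", n_dir, " DWI volumes")
  ms <- midpoint_sample(volume_stack, affine, surface, fraction = fraction)
  samples <- ms$samples
  if (smooth_iterations > 0) {
    ok <- !ms$missing
    if (all(ok)) {
      samples <- smooth_on_surface(samples, surface$faces, smooth_iterations)
    } else {
      sub <- smooth_on_surface(samples[ok, , drop = FALSE],
                               subset_faces(surface$faces, ok),
                               smooth_iterations)
      samples[ok, ] <- sub
    }
  }
  keep <- which(!ms$missing)
  rec <- data.frame(vertex_id = keep - 1L,
                    x = surface$inner_vertices[keep, 1],
                    y = surface$inner_vertices[keep, 2],
                    z = surface$inner_vertices[keep, 3],
                    nx = surface$normals[keep, 1],
                    ny = surface$normals[keep, 2],
                    nz = surface$normals[keep, 3],
                    voxel_id = ms$voxel_id[keep],
                    ref = samples[keep, 1])
  rec[sprintf("i%03d", seq_len(n_dir))] <-
    as.data.frame(samples[keep, -1, drop = FALSE])
  attr(rec, "n_missing") <- sum(ms$missing)
  rec
}

#' @noRd
subset_faces <- function(faces, keep_logical) {
  map <- cumsum(keep_logical)
  ok <- keep_logical[faces[, 1]] & keep_logical[faces[, 2]] &
    keep_logical[faces[, 3]]
  f <- faces[ok, , drop = FALSE]
  matrix(map[f], ncol = 3)
}
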