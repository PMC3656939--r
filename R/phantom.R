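## Synthetic two-repeat HARDI phantom over a folded cortical ribbon.
## Each tissue class is a mixture of Gaussian diffusion-tensor compartments
## whose principal axes are resolved against the local surface normal
## (radial or tangential to the cortex, or a fixed world axis), emulating
## the radial and tangential myelinated-fibre populations that give grey
## matter its directional HARDI contrast.

#' Define a tissue class as a mixture of tensor compartments
#'
#' @param name class label.
#' @param compartments list of compartments, each a list with fields
#'   `mode` (one of "radial", "tangential", "fixed"), `fraction` (volume
#'   fraction), `eigenvalues` (length-3, mm^2/s, principal first) and, for
#'   mode "fixed", `axis` (world 3-vector).
#' @return object of class `tissue_class`.
#' @export
tissue_class <- function(name, compartments) {
  fr <- vapply(compartments, function(c) c$fraction, numeric(1))
  if (abs(sum(fr) - 1) > 1e-12)
    stop("compartment volume fractions must sum to 1")
  for (c in compartments) {
    if (!c$mode %in% c("radial", "tangential", "fixed"))
      stop("unknown compartment mode: ", c$mode)
    if (length(c$eigenvalues) != 3 || any(c$eigenvalues < 0))
      stop("eigenvalues must be 3 nonnegative values (mm^2/s)")
    if (c$mode == "fixed" && is.null(c$axis))
      stop("fixed-axis compartments need an `axis`")
  }
  structure(list(name = name, compartments = compartments),
            class = "tissue_class")
}

#' Default three-class library for phantom experiments
#'
#' Three plausible grey-matter contrasts: a radial-dominant class (70%
#' stick-like tensor along the cortical normal, eigenvalues
#' (1.2, 0.2, 0.2) x 1e-3 mm^2/s, plus 30% isotropic 0.8e-3), a
#' tangential-dominant class (same mixture with the stick in the cortical
#' plane) and a fully isotropic class (0.8e-3 mm^2/s).
#'
#' @return list of three [tissue_class()] objects.
#' @export
default_tissue_classes <- function() {
  stick <- c(1.2e-3, 0.2e-3, 0.2e-3)
  iso <- list(mode = "radial", fraction = 0.3,
              eigenvalues = rep(0.8e-3, 3))
  list(
    tissue_class("radial_dominant", list(
      list(mode = "radial", fraction = 0.7, eigenvalues = stick), iso)),
    tissue_class("tangential_dominant", list(
      list(mode = "tangential", fraction = 0.7, eigenvalues = stick), iso)),
    tissue_class("isotropic_like", list(
      list(mode = "radial", fraction = 1, eigenvalues = rep(0.8e-3, 3)))))
}

#' Build the diffusion tensor of one compartment at a given surface normal
#' @noRd
compartment_tensor <- function(comp, normal) {
  axis <- switch(comp$mode,
                 radial = normal,
                 tangential = perp_basis(normal)[, 1],
                 fixed = comp$axis / sqrt(sum(comp$axis^2)))
  b2 <- perp_basis(axis)
  R <- cbind(axis, b2)
  R %*% diag(comp$eigenvalues) %*% t(R)
}

#' Noise-free HARDI signal of a tissue class at one vertex
#'
#' Multi-tensor signal model: S(u) = s0 * sum_c f_c exp(-b u' D_c u), with
#' each compartment tensor's principal axis resolved against the local
#' surface normal per its orientation mode.
#'
#' @param class a [tissue_class()].
#' @param normal local unit surface normal.
#' @param scheme a [gradient_scheme()].
#' @param s0 un-attenuated signal amplitude (arbitrary MR units).
#' @return numeric vector, one signal per scheme direction, in (0, s0].
#' @export
simulate_class_signal <- function(class, normal, scheme, s0 = 1000) {
  normal <- as.numeric(normal)
  stopifnot(abs(sum(normal^2) - 1) < 1e-8)
  u <- scheme$directions
  s <- numeric(nrow(u))
  for (comp in class$compartments) {
    D <- compartment_tensor(comp, normal)
    q <- rowSums((u %*% D) * u)
    s <- s + comp$fraction * exp(-scheme$bvalues * q)
  }
  unname(s0 * s)
}

#' Reference (low-b) signal of a tissue class
#'
#' The reference image is acquired at a small but nonzero b-value; its
#' direction dependence is negligible at b = 100 s/mm^2, so each compartment
#' is attenuated by its mean diffusivity.
#'
#' @inheritParams simulate_class_signal
#' @return scalar reference signal.
#' @export
reference_signal <- function(class, scheme, s0 = 1000) {
  s0 * sum(vapply(class$compartments, function(comp)
    comp$fraction * exp(-scheme$reference_b * mean(comp$eigenvalues)),
    numeric(1)))
}

#' Add Rician noise to magnitude-MRI signals
#'
#' Each output is sqrt((S + e1)^2 + e2^2) with e1, e2 independent zero-mean
#' Gaussians of standard deviation `sigma`. `sigma = 0` returns the input
#' unchanged (bit-for-bit).
#'
#' @param signals numeric vector, matrix or array of noise-free signals.
#' @param sigma noise standard deviation in signal units (>= 0).
#' @param seed integer seed; same seed gives identical output.
#' @return noisy signals with the shape of the input.
#' @export
add_rician_noise <- function(signals, sigma, seed = 1) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(signals)
  set.seed(seed)
  e1 <- stats::rnorm(length(signals), sd = sigma)
  e2 <- stats::rnorm(length(signals), sd = sigma)
  out <- sqrt((signals + e1)^2 + e2^2)
  attributes(out) <- attributes(signals)
  out
}

#' Build a folded two-surface cortical ribbon
#'
#' The inner (GM/WM) surface is a regular grid sheet with a sinusoidal fold
#' along its long axis, z = A sin(2*pi*x / wavelength); the outer (pial)
#' surface is the inner surface displaced along the analytic inner normal by
#' a constant cortical thickness. With a sufficient fold amplitude
#' (A * 2*pi/wavelength >= 1) the normal directions span more than 90
#' degrees, reproducing the varied spatial orientation of folded cortex.
#'
#' @param n_long vertices along the folded (x) axis.
#' @param n_trans vertices across the sheet (y axis).
#' @param spacing vertex spacing (mm, default 1).
#' @param thickness cortical thickness (mm, default 3; human cortex is
#'   2-4 mm).
#' @param fold_amplitude fold amplitude A (mm); 0 gives a flat sheet.
#' @param fold_wavelength fold wavelength (mm, default 40).
#' @return object of class `surface_model`: `inner_vertices`,
#'   `outer_vertices` (n x 3, mm), `faces` (m x 3, 1-based), `normals`
#'   (n x 3 unit, inner surface, pointing to the outer surface) and
#'   `thickness`.
#' @export
make_ribbon_surfaces <- function(n_long, n_trans, spacing = 1, thickness = 3,
                                 fold_amplitude = 0, fold_wavelength = 40) {
  stopifnot(n_long >= 2, n_trans >= 2, spacing > 0, thickness > 0)
  x <- (seq_len(n_long) - 1) * spacing
  y <- (seq_len(n_trans) - 1) * spacing
  g <- expand.grid(x = x, y = y)              # x fastest
  k <- 2 * pi / fold_wavelength
  z <- fold_amplitude * sin(k * g$x)
  inner <- cbind(g$x, g$y, z)
  slope <- fold_amplitude * k * cos(k * g$x)
  normals <- normalize_rows(cbind(-slope, 0, rep(1, nrow(inner))))
  outer <- inner + thickness * normals
  idx <- function(i, j) (j - 1L) * n_long + i
  f1 <- f2 <- matrix(0L, (n_long - 1) * (n_trans - 1), 3)
  r <- 0L
  for (j in seq_len(n_trans - 1)) {
    for (i in seq_len(n_long - 1)) {
      r <- r + 1L
      f1[r, ] <- c(idx(i, j), idx(i + 1, j), idx(i + 1, j + 1))
      f2[r, ] <- c(idx(i, j), idx(i + 1, j + 1), idx(i, j + 1))
    }
  }
  faces <- rbind(f1, f2)
  surf <- structure(list(inner_vertices = inner, outer_vertices = outer,
                         faces = faces, normals = normals,
                         thickness = thickness),
                    class = "surface_model")
  a <- inner[faces[, 1], ]; b <- inner[faces[, 2], ]; c_ <- inner[faces[, 3], ]
  ab <- b - a; ac <- c_ - a
  area2 <- sqrt(rowSums(cbind(ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2],
                              ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3],
                              ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1])^2))
  if (any(area2 <= 0)) stop("ribbon construction produced degenerate faces")
  surf
}

#' @export
print.surface_model <- function(x, ...) {
  cat(sprintf("<surface_model> %d vertices x 2 surfaces, %d faces, thickness %g mm\n",
              nrow(x$inner_vertices), nrow(x$faces), x$thickness))
  invisible(x)
}

#' Specify a synthetic two-repeat HARDI phantom
#'
#' Defaults are the standard phantom conditions used throughout the package:
#' three tissue classes with 500 vertices each, 61 directions at
#' b = 1000 s/mm^2 plus a b = 100 reference, reference-signal SNR 20 and
#' repeat seeds 1 and 2.
#'
#' @param classes list of [tissue_class()] objects.
#' @param vertices_per_class vertices per class (>= 1).
#' @param snr reference-signal signal-to-noise ratio (> 0; `Inf` disables
#'   noise).
#' @param seeds two distinct integer seeds, one per repeat.
#' @param n_directions diffusion directions (default 61).
#' @param bvalue diffusion b-value (s/mm^2, default 1000).
#' @param reference_b reference b-value (s/mm^2, default 100).
#' @param s0 un-attenuated signal amplitude.
#' @param n_trans vertices across the ribbon.
#' @param spacing vertex spacing (mm).
#' @param thickness cortical thickness (mm).
#' @param fold_amplitude,fold_wavelength ribbon fold geometry (mm).
#' @param voxel_size isotropic voxel size of the rasterized volume (mm).
#' @param margin background margin around the ribbon (voxels).
#' @param scheme_seed seed for the gradient-direction layout (shared by both
#'   repeats).
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(classes = default_tissue_classes(),
                         vertices_per_class = 500, snr = 20, seeds = c(1, 2),
                         n_directions = 61, bvalue = 1000, reference_b = 100,
                         s0 = 1000, n_trans = 10, spacing = 1, thickness = 3,
                         fold_amplitude = 7, fold_wavelength = 40,
                         voxel_size = 1, margin = 3, scheme_seed = 99) {
  if (snr <= 0) stop("snr must be positive")
  if (vertices_per_class < 1) stop("vertices_per_class must be >= 1")
  if (length(seeds) != 2 || seeds[1] == seeds[2])
    stop("seeds must be two distinct integers (independent noise realizations)")
  total <- vertices_per_class * length(classes)
  if (total %% n_trans != 0)
    stop("vertices_per_class * classes must be divisible by n_trans")
  structure(as.list(environment()), class = "phantom_spec")
}

#' Build the two-repeat phantom
#'
#' Rasterizes the class-wise multi-tensor signals onto a voxel grid
#' containing the ribbon: every voxel whose center lies within the ribbon
#' (between the inner surface and the inner surface plus thickness along the
#' local normal of its nearest mid-thickness vertex) carries the noise-free
#' signal of that vertex's class at that vertex's normal; voxels outside the
#' ribbon carry an isotropic free-water-like background (3.0e-3 mm^2/s).
#' The two repeats share the noise-free volume and differ only in the Rician
#' noise seed. Class labels tile the ribbon in contiguous blocks along the
#' long axis.
#'
#' @param spec a [phantom_spec()].
#' @return object of class `hardi_phantom`: `repeats` (list of two 4D arrays,
#'   volume 1 the reference then one volume per direction), `affine` (4 x 4,
#'   0-based voxel to world mm), `surface` ([make_ribbon_surfaces()] output),
#'   `labels` (data frame `vertex_id`, `class_name`), `scheme`,
#'   `clean_signals` (n_volumes x n_vertices noise-free vertex signals) and
#'   `spec`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n_class <- length(spec$classes)
  total <- spec$vertices_per_class * n_class
  n_long <- total %/% spec$n_trans
  if (n_long %% n_class != 0)
    stop("class blocks cannot tile the long axis evenly")
  surf <- make_ribbon_surfaces(n_long, spec$n_trans, spacing = spec$spacing,
                               thickness = spec$thickness,
                               fold_amplitude = spec$fold_amplitude,
                               fold_wavelength = spec$fold_wavelength)
  scheme <- make_gradient_scheme(spec$n_directions, seed = spec$scheme_seed)
  scheme$bvalues[] <- spec$bvalue
  scheme$reference_b <- spec$reference_b

  ## contiguous class patches: blocks of columns along the long axis
  col_of <- ((seq_len(total) - 1) %% n_long) + 1
  block <- n_long %/% n_class
  class_idx <- pmin(((col_of - 1) %/% block) + 1, n_class)
  class_names <- vapply(spec$classes, function(cl) cl$name, character(1))
  labels <- data.frame(vertex_id = seq_len(total) - 1L,
                       class_name = class_names[class_idx],
                       stringsAsFactors = FALSE)

  ## noise-free per-vertex signal stack (reference first)
  n_vol <- spec$n_directions + 1L
  clean <- matrix(0, n_vol, total)
  for (v in seq_len(total)) {
    cl <- spec$classes[[class_idx[v]]]
    clean[, v] <- c(reference_signal(cl, scheme, spec$s0),
                    simulate_class_signal(cl, surf$normals[v, ], scheme,
                                          spec$s0))
  }

  ## voxel grid: world-aligned, voxel centers on multiples of voxel_size so
  ## a flat unit-spacing ribbon lands exactly on voxel centers
  allv <- rbind(surf$inner_vertices, surf$outer_vertices)
  lo <- floor(apply(allv, 2, min) / spec$voxel_size) - spec$margin
  hi <- ceiling(apply(allv, 2, max) / spec$voxel_size) + spec$margin
  dims <- as.integer(hi - lo + 1)
  affine <- diag(c(rep(spec$voxel_size, 3), 1))
  affine[1:3, 4] <- lo * spec$voxel_size

  ## assign each voxel center to its nearest mid-thickness vertex
  mid <- surf$inner_vertices + 0.5 * (surf$outer_vertices - surf$inner_vertices)
  ctr <- as.matrix(expand.grid(x = 0:(dims[1] - 1), y = 0:(dims[2] - 1),
                               z = 0:(dims[3] - 1)))
  ctr_w <- voxel_to_world(ctr, affine)
  n_vox <- nrow(ctr_w)
  nearest <- integer(n_vox)
  midsq <- rowSums(mid^2)
  chunk <- 8000L
  for (s in seq(1, n_vox, by = chunk)) {
    e <- min(s + chunk - 1L, n_vox)
    cc <- ctr_w[s:e, , drop = FALSE]
    d2 <- outer(rowSums(cc^2), midsq, "+") - 2 * cc %*% t(mid)
    nearest[s:e] <- max.col(-d2, ties.method = "first")
  }
  rel <- ctr_w - surf$inner_vertices[nearest, , drop = FALSE]
  depth <- rowSums(rel * surf$normals[nearest, , drop = FALSE])
  inside <- depth >= 0 & depth <= spec$thickness

  bg_adc <- 3.0e-3
  bg <- spec$s0 * exp(-c(spec$reference_b, scheme$bvalues) * bg_adc)
  vox_sig <- matrix(bg, n_vox, n_vol, byrow = TRUE)
  vox_sig[inside, ] <- t(clean[, nearest[inside], drop = FALSE])

  sigma <- if (is.infinite(spec$snr)) 0 else
    mean(clean[1, ]) / spec$snr
  repeats <- lapply(1:2, function(r) {
    noisy <- add_rician_noise(vox_sig, sigma, seed = spec$seeds[r])
    array(noisy, dim = c(dims, n_vol))
  })

  structure(list(repeats = repeats, affine = affine, surface = surf,
                 labels = labels, scheme = scheme, clean_signals = clean,
                 sigma = sigma, spec = spec),
            class = "hardi_phantom")
}

#' @export
print.hardi_phantom <- function(x, ...) {
  d <- dim(x$repeats[[1]])
  cat(sprintf("<hardi_phantom> 2 repeats of %dx%dx%dx%d, %d labeled vertices, %d classes, sigma %.3g\n",
              d[1], d[2], d[3], d[4], nrow(x$labels),
              length(unique(x$labels$class_name)), x$sigma))
  invisible(x)
}
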