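## Gradient schemes: the set of diffusion-encoding directions and b-values
## of a HARDI acquisition, plus the b-value of the low-b reference image.

#' Construct a gradient scheme
#'
#' A gradient scheme holds the unit diffusion-encoding directions and their
#' b-values (s/mm^2), together with the b-value of the reference image the
#' acquisition uses in place of a true b = 0 volume.
#'
#' @param directions n x 3 matrix of unit direction vectors.
#' @param bvalues numeric vector of n positive b-values (s/mm^2).
#' @param reference_b b-value of the reference volume (s/mm^2).
#' @return object of class `gradient_scheme`.
#' @export
gradient_scheme <- function(directions, bvalues, reference_b = 100) {
  directions <- as_dir_matrix(directions)
  bvalues <- as.numeric(bvalues)
  if (length(bvalues) == 1L) bvalues <- rep(bvalues, nrow(directions))
  if (length(bvalues) != nrow(directions))
    stop("bvalues length must match the number of directions")
  nrm <- sqrt(rowSums(directions^2))
  if (any(abs(nrm - 1) > 1e-10))
    stop("all directions must have unit norm (max deviation ",
         format(max(abs(nrm - 1))), ")")
  if (any(bvalues <= 0)) stop("all bvalues must be positive")
  if (reference_b <= 0) stop("reference_b must be positive")
  structure(list(directions = directions, bvalues = bvalues,
                 reference_b = reference_b),
            class = "gradient_scheme")
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("<gradient_scheme> %d directions, b = %s s/mm^2, reference b = %g\n",
              nrow(x$directions),
              paste(unique(x$bvalues), collapse = "/"), x$reference_b))
  invisible(x)
}

#' Minimum pairwise angle of a direction set, treating +v and -v as identical
#'
#' @param directions n x 3 matrix of unit vectors.
#' @return smallest pairwise angle in radians, antipodally symmetrized.
#' @export
min_pairwise_angle <- function(directions) {
  u <- normalize_rows(directions)
  g <- abs(u %*% t(u))
  diag(g) <- 0
  acos(pmin(1, max(g)))
}

#' Generate evenly distributed diffusion-encoding directions
#'
#' Builds `n_directions` unit vectors spread evenly over the sphere, as HARDI
#' acquisitions require. A spherical Fibonacci lattice provides the initial
#' configuration; electrostatic-repulsion refinement (treating each direction
#' and its antipode as one electrode, the standard symmetry for diffusion
#' encoding) then maximizes the minimum pairwise angle approximately. The
#' seed only randomizes a global rotation of the lattice, so the angular
#' distribution statistics are seed-independent.
#'
#' @param n_directions number of directions (>= 6).
#' @param seed integer seed controlling the global orientation.
#' @param n_iter repulsion refinement iterations.
#' @return a [gradient_scheme()] with b = 1000 s/mm^2 on every direction and
#'   reference b = 100 s/mm^2 (override fields afterwards if needed).
#' @export
make_gradient_scheme <- function(n_directions, seed = 1, n_iter = 200) {
  if (n_directions < 6) stop("n_directions must be at least 6")
  i <- seq_len(n_directions) - 0.5
  golden <- pi * (3 - sqrt(5))
  z <- 1 - 2 * i / n_directions
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- golden * seq_len(n_directions)
  u <- cbind(r * cos(phi), r * sin(phi), z)
  u <- u %*% random_rotation(seed = seed)
  ## antipodally symmetric Coulomb repulsion, projected gradient ascent
  step <- 0.005
  for (it in seq_len(n_iter)) {
    frc <- matrix(0, n_directions, 3)
    for (j in seq_len(n_directions)) {
      dminus <- sweep(u[-j, , drop = FALSE], 2, u[j, ], function(a, b) b - a)
      dplus  <- sweep(u[-j, , drop = FALSE], 2, u[j, ], function(a, b) b + a)
      nm <- pmax(rowSums(dminus^2)^1.5, 1e-12)
      np <- pmax(rowSums(dplus^2)^1.5, 1e-12)
      frc[j, ] <- colSums(dminus / nm) + colSums(dplus / np)
    }
    frc <- frc - u * rowSums(frc * u)  # tangential component
    u <- normalize_rows(u + step * frc / max(1, sqrt(max(rowSums(frc^2)))))
  }
  gradient_scheme(u, bvalues = 1000, reference_b = 100)
}
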