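## Shared fixtures, built in code. Heavy objects (the full-size two-repeat
## phantom and its feature sets) are memoized per test run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  v <- .fixture_cache[[key]]
  if (is.null(v)) {
    v <- builder()
    .fixture_cache[[key]] <- v
  }
  v
}

## 61-direction scheme shared by many tests
fixture_scheme <- function() {
  memo("scheme61", function() make_gradient_scheme(61, seed = 1))
}

fixture_quad <- function() {
  memo("quad", function() sphere_quadrature())
}

## Fit the band-limited SH representation of a single-tensor ADC profile
## ADC(u) = u' D u sampled noise-free on the scheme directions.
tensor_profile <- function(D, scheme = fixture_scheme(), max_order = 6) {
  adc <- rowSums((scheme$directions %*% D) * scheme$directions)
  fit_adc_profile(adc, scheme, max_order = max_order)
}

## Default-conditions phantom (3 classes x 500 vertices, SNR 20, seeds 1/2)
## plus per-repeat feature sets; built once.
fixture_phantom_features <- function() {
  memo("phantom_features", function() {
    ph <- build_phantom(phantom_spec())
    quad <- fixture_quad()
    sets <- lapply(1:2, function(r) {
      rec <- extract_vertex_records(ph$repeats[[r]], ph$affine, ph$surface,
                                    ph$scheme)
      fe <- compute_features(rec, ph$scheme, quad = quad)
      lab <- ph$labels$class_name[match(fe$vertex_id, ph$labels$vertex_id)]
      list(records = rec, features = as.matrix(fe[, feature_names()]),
           labels = lab)
    })
    list(phantom = ph, sets = sets)
  })
}

## Small unit icosphere mesh (subdivided icosahedron) for surface tests
icosphere_mesh <- function(level = 3) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (l in seq_len(level)) {
    mids <- new.env(parent = emptyenv())
    nv <- nrow(v)
    vlist <- list(v)
    getmid <- function(a, b) {
      k <- paste(min(a, b), max(a, b))
      if (!is.null(mids[[k]])) return(mids[[k]])
      m <- v[a, ] + v[b, ]
      vlist[[length(vlist) + 1L]] <<- m / sqrt(sum(m^2))
      nv <<- nv + 1L
      mids[[k]] <- nv
      nv
    }
    nf <- matrix(0L, nrow(f) * 4L, 3L)
    for (i in seq_len(nrow(f))) {
      a <- f[i, 1]; b <- f[i, 2]; cc <- f[i, 3]
      ab <- getmid(a, b); bc <- getmid(b, cc); ca <- getmid(cc, a)
      nf[(i - 1L) * 4L + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- do.call(rbind, vlist)
    f <- nf
  }
  list(vertices = v, faces = f)
}
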