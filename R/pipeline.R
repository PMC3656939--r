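## End-to-end orchestration: simulate -> extract -> features -> classify /
## cluster, with per-stage outputs on disk and a single JSON run report as
## the source of all metrics.

#' Default pipeline configuration
#'
#' Every field has a default; [run_pipeline()] serializes the effective
#' configuration into its report. Fields mirror the stage arguments:
#' phantom generation (`vertices_per_class`, `snr`, `seeds`,
#' `n_directions`, `bvalue`, fold geometry), sampling (`fraction`,
#' `smooth_iterations`), SH fit (`max_order`, `ridge_weight`), quadrature
#' (`n_theta`, `n_phi`, `circle_samples`), SVM (`svm_cost`, `svm_gamma`
#' NULL = 1/27) and clustering (`kmeans_k`, `kmeans_seed`).
#'
#' @param ... overrides of the default fields.
#' @return named list of configuration values.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    vertices_per_class = 500, snr = 20, seeds = c(1, 2),
    n_directions = 61, bvalue = 1000, reference_b = 100, s0 = 1000,
    n_trans = 10, spacing = 1, thickness = 3,
    fold_amplitude = 7, fold_wavelength = 40, voxel_size = 1,
    scheme_seed = 99,
    fraction = 0.5, smooth_iterations = 0,
    max_order = 6, ridge_weight = 0, log_floor = 1e-6,
    n_theta = 36, n_phi = 72, circle_samples = 360,
    svm_cost = 1, svm_gamma = NULL,
    kmeans_k = 10, kmeans_seed = 7,
    pca_threshold = 0.95,
    dwi = NULL, bvec = NULL, bval = NULL,
    inner_surf = NULL, outer_surf = NULL, labels = NULL,
    out_dir = NULL)
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config fields: ",
                            paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from a YAML key-value file
#' @param path YAML file; keys as in [default_run_config()].
#' @return full configuration list with defaults filled in.
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(default_run_config, vals)
}

#' Run the full fingerprinting pipeline
#'
#' With no real-input paths in the configuration, simulates the default
#' two-repeat phantom; otherwise reads the supplied DWI volumes, gradient
#' tables and surfaces (both repeats must then be given as length-2 vectors
#' in `dwi`). Each repeat is sampled at mid-thickness and converted to
#' 27-feature vectors; repeat 1 trains the three-way SVM, repeat 2 is
#' classified; both repeats are parcellated by ordered k-means and compared
#' by adjusted Rand index; the per-ROI direction profiles are summarized by
#' [testretest_report()]. All stage outputs (NIfTI volumes, OFF meshes,
#' TSV tables, JSON report) are written under `out_dir` when it is set.
#'
#' @param config list from [default_run_config()] or [read_run_config()].
#' @return run report (list), invisibly also written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config = default_run_config()) {
  cfg <- do.call(default_run_config, config)
  real_inputs <- !is.null(cfg$dwi)
  if (real_inputs && (is.null(cfg$bvec) || is.null(cfg$bval) ||
                      is.null(cfg$inner_surf) || is.null(cfg$outer_surf) ||
                      is.null(cfg$labels)))
    stop("validation: real-input runs need dwi, bvec, bval, inner_surf, outer_surf and labels")
  out_dir <- cfg$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  log <- list()

  if (!real_inputs) {
    spec <- phantom_spec(vertices_per_class = cfg$vertices_per_class,
                         snr = cfg$snr, seeds = cfg$seeds,
                         n_directions = cfg$n_directions, bvalue = cfg$bvalue,
                         reference_b = cfg$reference_b, s0 = cfg$s0,
                         n_trans = cfg$n_trans, spacing = cfg$spacing,
                         thickness = cfg$thickness,
                         fold_amplitude = cfg$fold_amplitude,
                         fold_wavelength = cfg$fold_wavelength,
                         voxel_size = cfg$voxel_size,
                         scheme_seed = cfg$scheme_seed)
    ph <- build_phantom(spec)
    volumes <- ph$repeats
    affine <- ph$affine
    surface <- ph$surface
    labels <- ph$labels
    scheme <- ph$scheme
    if (!is.null(out_dir)) {
      for (r in 1:2)
        write_volume(volumes[[r]], affine,
                     file.path(out_dir, sprintf("dwi_rep%d.nii.gz", r)))
      write_gradients(scheme, file.path(out_dir, "dwi.bvec"),
                      file.path(out_dir, "dwi.bval"))
      write_mesh(surface$inner_vertices, surface$faces,
                 file.path(out_dir, "inner.off"))
      write_mesh(surface$outer_vertices, surface$faces,
                 file.path(out_dir, "outer.off"))
      write_labels(labels, file.path(out_dir, "labels.tsv"))
    }
    log$simulate <- list(vertices = nrow(labels), sigma = ph$sigma,
                         volume_dim = dim(volumes[[1]]))
  } else {
    stopifnot(length(cfg$dwi) == 2)
    v1 <- read_volume(cfg$dwi[1]); v2 <- read_volume(cfg$dwi[2])
    volumes <- list(v1$data, v2$data)
    affine <- v1$affine
    scheme <- read_gradients(cfg$bvec, cfg$bval)
    inner <- read_mesh(cfg$inner_surf)
    outer <- read_mesh(cfg$outer_surf)
    normals <- vertex_normals(inner$vertices, inner$faces, outer$vertices)
    surface <- structure(list(inner_vertices = inner$vertices,
                              outer_vertices = outer$vertices,
                              faces = inner$faces, normals = normals,
                              thickness = NA_real_),
                         class = "surface_model")
    labels <- read_labels(cfg$labels)
  }

  quad <- sphere_quadrature(cfg$n_theta, cfg$n_phi, cfg$circle_samples)
  sets <- vector("list", 2)
  records <- vector("list", 2)
  for (r in 1:2) {
    rec <- extract_vertex_records(volumes[[r]], affine, surface, scheme,
                                  fraction = cfg$fraction,
                                  smooth_iterations = cfg$smooth_iterations)
    feats <- compute_features(rec, scheme, max_order = cfg$max_order,
                              quad = quad, ridge_weight = cfg$ridge_weight,
                              log_floor = cfg$log_floor)
    lab <- labels$class_name[match(feats$vertex_id, labels$vertex_id)]
    keep <- !is.na(lab)
    sets[[r]] <- labeled_feature_set(feats[keep, feature_names()], lab[keep],
                                     vertex_ids = feats$vertex_id[keep],
                                     repeat_id = r)
    records[[r]] <- rec
    log[[sprintf("extract_rep%d", r)]] <-
      list(vertices_sampled = nrow(rec),
           vertices_missing = attr(rec, "n_missing"),
           signals_clamped = attr(feats, "n_clamped"))
    if (!is.null(out_dir)) {
      write_vertex_records(rec, file.path(out_dir,
                                          sprintf("records_rep%d.tsv", r)))
      write_feature_table(feats[keep, ], lab[keep],
                          file.path(out_dir,
                                    sprintf("features_rep%d.tsv", r)))
    }
  }

  z <- zscore_train_apply(sets[[1]]$features, sets[[2]]$features)
  model <- train_svm(labeled_feature_set(z$train, sets[[1]]$labels),
                     cost = cfg$svm_cost, gamma = cfg$svm_gamma)
  res <- classify_unseen(model, labeled_feature_set(z$test, sets[[2]]$labels,
                                                    repeat_id = 2))

  km <- lapply(1:2, function(r)
    kmeans_parcellate(sets[[r]]$features, k = cfg$kmeans_k,
                      seed = cfg$kmeans_seed))
  shared <- intersect(sets[[1]]$vertex_ids, sets[[2]]$vertex_ids)
  i1 <- match(shared, sets[[1]]$vertex_ids)
  i2 <- match(shared, sets[[2]]$vertex_ids)
  km_ari <- adjusted_rand(km[[1]]$labels[i1], km[[2]]$labels[i2])

  trt <- testretest_report(records[[1]], records[[2]], labels)
  idim <- intrinsic_dimension(rbind(sets[[1]]$features, sets[[2]]$features),
                              cfg$pca_threshold)

  report <- list(
    config = cfg[!vapply(cfg, is.null, logical(1))],
    log = log,
    classification = list(
      overall_rate = res$overall,
      per_region_rate = as.list(res$per_region),
      confusion = as.data.frame(res$confusion)),
    kmeans = list(k = cfg$kmeans_k, seed = cfg$kmeans_seed,
                  between_repeat_ari = km_ari,
                  chain_length = c(km[[1]]$chain_length,
                                   km[[2]]$chain_length)),
    intrinsic_dimension = list(threshold = cfg$pca_threshold,
                               components = as.integer(idim)),
    testretest = trt$summary)
  if (!is.null(out_dir))
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  report
}

#' Per-ROI direction-profile test/retest summary
#'
#' For each ROI the 61-entry mean-signal profile over the diffusion
#' directions is computed per repeat (the per-region direction
#' "time-course"). Reported per ROI: the two profiles, their Pearson
#' correlation across repeats, and the matrix of between-ROI profile
#' correlations (repeat 1 vs repeat 2), whose diagonal should dominate when
#' regions are reproducible and distinct.
#'
#' @param records_rep1,records_rep2 vertex-record tables from
#'   [extract_vertex_records()].
#' @param roi_labels data frame with `vertex_id` and `class_name`.
#' @return list with `profiles` (per ROI x repeat), `summary` (data frame:
#'   roi, n_vertices, within-ROI correlation) and `cross_correlation`.
#' @export
testretest_report <- function(records_rep1, records_rep2, roi_labels) {
  icols <- grep("^i\\d+$", names(records_rep1), value = TRUE)
  rois <- sort(unique(roi_labels$class_name))
  prof <- function(rec, roi) {
    ids <- roi_labels$vertex_id[roi_labels$class_name == roi]
    rows <- rec$vertex_id %in% ids
    n <- sum(rows)
    if (n == 0) return(NULL)
    if (n == 1) warning("ROI ", roi, " has a single vertex; profile is one record")
    colMeans(rec[rows, icols, drop = FALSE])
  }
  profiles <- lapply(rois, function(roi)
    list(rep1 = prof(records_rep1, roi), rep2 = prof(records_rep2, roi)))
  names(profiles) <- rois
  have <- !vapply(profiles, function(p) is.null(p$rep1) || is.null(p$rep2),
                  logical(1))
  rois <- rois[have]
  profiles <- profiles[have]
  ## a flat (direction-independent) profile has zero variance; correlation is
  ## defined as 1 when the two repeats are numerically identical, NA otherwise
  safe_cor <- function(a, b) {
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      if (max(abs(a - b)) == 0) 1 else NA_real_
    } else stats::cor(a, b)
  }
  wcor <- vapply(profiles, function(p) safe_cor(p$rep1, p$rep2), numeric(1))
  cross <- matrix(NA_real_, length(rois), length(rois),
                  dimnames = list(rep1 = rois, rep2 = rois))
  for (i in seq_along(rois))
    for (j in seq_along(rois))
      cross[i, j] <- safe_cor(profiles[[i]]$rep1, profiles[[j]]$rep2)
  nvert <- vapply(rois, function(roi)
    sum(roi_labels$class_name == roi), numeric(1))
  list(profiles = profiles,
       summary = data.frame(roi = rois, n_vertices = nvert,
                            within_correlation = wcor, row.names = NULL),
       cross_correlation = cross)
}
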