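## On-disk formats: FSL-dialect bvec/bval gradient tables, NIfTI-1 volumes,
## ASCII OFF surface meshes and tab-separated per-vertex tables. All writers
## are deterministic (fixed numeric formats), so identical inputs produce
## byte-identical files.

fmt_num <- function(x, digits = 6) {
  formatC(x, digits = digits, format = "g")
}

#' Read an FSL-dialect gradient table
#'
#' `bvec` holds three whitespace-separated rows (x, y, z components) of N
#' entries; `bval` one row of N b-values. Rows with b at or below
#' `reference_max_b` (or zero direction vectors) are treated as reference
#' volumes: they are excluded from the returned directions and their
#' b-value is recorded as `reference_b`.
#'
#' @param bvec_path,bval_path file paths.
#' @param reference_max_b b-values at or below this are reference volumes
#'   (default 150 s/mm^2).
#' @return a [gradient_scheme()]; the indices of the diffusion-weighted
#'   columns within the file are attached as attribute `dwi_index`.
#' @export
read_gradients <- function(bvec_path, bval_path, reference_max_b = 150) {
  if (!file.exists(bvec_path)) stop("bvec file not found: ", bvec_path)
  if (!file.exists(bval_path)) stop("bval file not found: ", bval_path)
  lines <- readLines(bvec_path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 3)
    stop(sprintf("%s: expected 3 rows of direction components, found %d",
                 bvec_path, length(lines)))
  rows <- lapply(seq_along(lines), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[i]), "\\s+")[[1]]))
    if (anyNA(v))
      stop(sprintf("%s: line %d contains non-numeric entries", bvec_path, i))
    v
  })
  n <- length(rows[[1]])
  for (i in 2:3) if (length(rows[[i]]) != n)
    stop(sprintf("%s: line %d has %d entries, expected %d",
                 bvec_path, i, length(rows[[i]]), n))
  bl <- readLines(bval_path)
  bl <- bl[nzchar(trimws(bl))]
  if (length(bl) != 1)
    stop(sprintf("%s: expected a single row of b-values", bval_path))
  bval <- suppressWarnings(as.numeric(strsplit(trimws(bl[1]), "\\s+")[[1]]))
  if (anyNA(bval))
    stop(sprintf("%s: line 1 contains non-numeric entries", bval_path))
  if (length(bval) != n)
    stop(sprintf("%s: line 1 has %d b-values, bvec has %d columns",
                 bval_path, length(bval), n))
  u <- cbind(rows[[1]], rows[[2]], rows[[3]])
  nrm <- sqrt(rowSums(u^2))
  is_ref <- bval <= reference_max_b | nrm < 1e-6
  if (all(is_ref)) stop(bval_path, ": no diffusion-weighted entries found")
  ref_b <- if (any(is_ref)) max(bval[is_ref], 1) else 1
  dwi <- which(!is_ref)
  scheme <- gradient_scheme(u[dwi, , drop = FALSE] / nrm[dwi],
                            bval[dwi], reference_b = ref_b)
  attr(scheme, "dwi_index") <- dwi
  scheme
}

#' Write an FSL-dialect gradient table
#'
#' Writes the reference volume as a zero direction with `reference_b` in the
#' first column, followed by the scheme's diffusion directions.
#'
#' @param scheme a [gradient_scheme()].
#' @param bvec_path,bval_path output paths.
#' @param include_reference prepend the reference column (default TRUE).
#' @return invisibly, the two paths.
#' @export
write_gradients <- function(scheme, bvec_path, bval_path,
                            include_reference = TRUE) {
  u <- scheme$directions
  b <- scheme$bvalues
  if (include_reference) {
    u <- rbind(c(0, 0, 0), u)
    b <- c(scheme$reference_b, b)
  }
  writeLines(vapply(1:3, function(i) paste(fmt_num(u[, i]), collapse = " "),
                    character(1)), bvec_path)
  writeLines(paste(fmt_num(b), collapse = " "), bval_path)
  invisible(c(bvec_path, bval_path))
}

#' Read a NIfTI-1 volume
#' @param path file path (.nii or .nii.gz).
#' @return list with `data` (numeric array) and `affine` (4 x 4 matrix
#'   mapping 0-based voxel indices to world mm).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("not a readable NIfTI file: ",
                                           path, " (", conditionMessage(e), ")"))
  aff <- structure(RNifti::xform(img), imagedim = NULL, code = NULL)
  attributes(aff) <- list(dim = c(4L, 4L))
  list(data = as.array(img), affine = aff)
}

#' Write a NIfTI-1 volume
#' @param data 3D or 4D numeric array.
#' @param affine 4 x 4 matrix mapping 0-based voxel indices to world mm.
#' @param path output path (.nii or .nii.gz).
#' @param datatype storage type (default "float" = float32).
#' @return invisibly, the path.
#' @export
write_volume <- function(data, affine, path, datatype = "float") {
  img <- RNifti::asNifti(data)
  ## the sform stores a general affine exactly; the quaternion qform cannot
  ## carry anisotropic scaling, so only the sform is written (code 2)
  RNifti::sform(img) <- structure(affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = datatype)
  invisible(path)
}

#' Read an ASCII OFF mesh
#' @param path file path.
#' @return list with `vertices` (n x 3) and `faces` (m x 3, 1-based).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop("mesh not found: ", path)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
  if (length(keep) == 0 || trimws(lines[keep[1]]) != "OFF")
    stop(path, ": line 1: missing OFF header")
  counts <- suppressWarnings(as.numeric(
    strsplit(trimws(lines[keep[2]]), "\\s+")[[1]]))
  if (length(counts) < 2 || anyNA(counts[1:2]))
    stop(sprintf("%s: line %d: malformed count line", path, keep[2]))
  nv <- counts[1]; nf <- counts[2]
  if (length(keep) < 2 + nv + nf)
    stop(sprintf("%s: expected %d vertex and %d face lines, file has %d data lines",
                 path, nv, nf, length(keep) - 2))
  vl <- keep[2 + seq_len(nv)]
  fl <- keep[2 + nv + seq_len(nf)]
  verts <- matrix(0, nv, 3)
  for (i in seq_len(nv)) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(lines[vl[i]]), "\\s+")[[1]]))
    if (length(v) != 3 || anyNA(v))
      stop(sprintf("%s: line %d: malformed vertex line", path, vl[i]))
    verts[i, ] <- v
  }
  faces <- matrix(0L, nf, 3)
  for (i in seq_len(nf)) {
    v <- suppressWarnings(as.integer(strsplit(trimws(lines[fl[i]]), "\\s+")[[1]]))
    if (length(v) < 4 || anyNA(v) || v[1] != 3)
      stop(sprintf("%s: line %d: only triangular faces are supported",
                   path, fl[i]))
    if (any(v[2:4] < 0) || any(v[2:4] >= nv))
      stop(sprintf("%s: line %d: face index out of range", path, fl[i]))
    faces[i, ] <- v[2:4] + 1L
  }
  list(vertices = verts, faces = faces)
}

#' Write an ASCII OFF mesh
#' @param vertices n x 3 matrix (mm).
#' @param faces m x 3 matrix of 1-based vertex indices.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_mesh <- function(vertices, faces, path) {
  vertices <- as_dir_matrix(vertices)
  faces <- as.matrix(faces)
  if (any(faces < 1) || any(faces > nrow(vertices)))
    stop("face index out of range")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(vertices), nrow(faces)), con)
  writeLines(sprintf("%s %s %s", fmt_num(vertices[, 1], 9),
                     fmt_num(vertices[, 2], 9), fmt_num(vertices[, 3], 9)), con)
  writeLines(sprintf("3 %d %d %d", faces[, 1] - 1L, faces[, 2] - 1L,
                     faces[, 3] - 1L), con)
  invisible(path)
}

#' Write a per-vertex feature table
#'
#' TSV with header `vertex_id`, `label`, then the 27 canonical feature names;
#' values are written with 12 significant digits so read/write round-trips
#' preserve them at that precision.
#'
#' @param features data frame with `vertex_id` and the 27 feature columns
#'   (as from [compute_features()]).
#' @param labels character vector of region labels, one per row.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_feature_table <- function(features, labels, path) {
  if (anyDuplicated(features$vertex_id))
    stop("duplicate vertex_id in feature table")
  if (length(labels) != nrow(features))
    stop("labels length must match feature rows")
  fn <- feature_names()
  if (!all(fn %in% names(features)))
    stop("feature table is missing canonical feature columns")
  out <- data.frame(vertex_id = features$vertex_id, label = labels,
                    stringsAsFactors = FALSE)
  for (f in fn) out[[f]] <- formatC(features[[f]], digits = 12, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-vertex feature table written by [write_feature_table()]
#' @param path file path.
#' @return data frame: `vertex_id`, `label`, then the 27 features.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop("feature table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("vertex_id", "label", feature_names())
  if (!identical(names(tab), need))
    stop(path, ": line 1: header does not match the canonical feature order")
  if (anyDuplicated(tab$vertex_id))
    stop(path, ": duplicate vertex_id entries")
  tab
}

#' Write a vertex-record table
#'
#' TSV with columns `vertex_id`, `x`, `y`, `z`, `nx`, `ny`, `nz`,
#' `voxel_id`, `ref`, then one intensity column per diffusion direction
#' (`i001`...).
#'
#' @param records data frame from [extract_vertex_records()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_vertex_records <- function(records, path) {
  if (anyDuplicated(records$vertex_id)) stop("duplicate vertex_id in records")
  out <- records
  for (cn in setdiff(names(out), c("vertex_id", "voxel_id")))
    out[[cn]] <- formatC(out[[cn]], digits = 12, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a vertex-record table written by [write_vertex_records()]
#' @param path file path.
#' @return data frame of vertex records.
#' @export
read_vertex_records <- function(path) {
  if (!file.exists(path)) stop("record table not found: ", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("vertex_id", "x", "y", "z", "nx", "ny", "nz", "voxel_id", "ref")
  if (!all(need %in% names(tab)))
    stop(path, ": line 1: missing required record columns")
  if (anyDuplicated(tab$vertex_id)) stop(path, ": duplicate vertex_id entries")
  tab
}

#' Write a vertex label table (TSV: vertex_id, class_name)
#' @param labels data frame with `vertex_id` and `class_name`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(labels[, c("vertex_id", "class_name")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a vertex label table
#' @param path file path.
#' @return data frame with `vertex_id` and `class_name`.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("vertex_id", "class_name") %in% names(tab)))
    stop(path, ": line 1: expected columns vertex_id, class_name")
  tab
}
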