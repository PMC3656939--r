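## Supervised and unsupervised discrimination of cortical tissue from
## feature vectors: train-on-repeat-1 / test-on-repeat-2 SVM classification,
## pairwise balanced-rate matrices, ordered k-means parcellation and a PCA
## dimensionality report. The 27 features span orders of magnitude
## (mm^2/s means vs squared-coefficient powers), so features are z-scored
## with training-set statistics before any classifier sees them.

#' Bundle a feature matrix with labels
#'
#' @param features numeric matrix or data frame of feature columns (the 27
#'   canonical columns for pipeline data, but any column set is accepted).
#' @param labels character vector of region labels, one per row.
#' @param vertex_ids optional vertex ids (default row sequence).
#' @param repeat_id 1 or 2.
#' @return object of class `labeled_feature_set`.
#' @export
labeled_feature_set <- function(features, labels, vertex_ids = NULL,
                                repeat_id = 1) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  if (nrow(x) != length(labels)) stop("row count must equal label count")
  if (is.null(vertex_ids)) vertex_ids <- seq_len(nrow(x))
  if (anyDuplicated(vertex_ids)) stop("duplicate vertex_id within a repeat")
  structure(list(features = x, labels = as.character(labels),
                 vertex_ids = vertex_ids, repeat_id = repeat_id),
            class = "labeled_feature_set")
}

#' Standardize features by training-set statistics
#'
#' Centers and scales every column of the training matrix to mean 0 / SD 1
#' and applies the *training* statistics to the test matrix, so no test-set
#' information leaks into the transform. Zero-variance columns are passed
#' through unscaled with a warning.
#'
#' @param train_features,test_features numeric matrices with matching
#'   columns.
#' @return list with `train`, `test`, `center`, `scale`.
#' @export
zscore_train_apply <- function(train_features, test_features) {
  tr <- as.matrix(train_features)
  te <- as.matrix(test_features)
  if (ncol(tr) != ncol(te)) stop("train and test must share columns")
  ctr <- colMeans(tr)
  scl <- apply(tr, 2, stats::sd)
  degenerate <- !is.finite(scl) | scl == 0
  if (any(degenerate)) {
    warning(sum(degenerate), " zero-variance column(s) passed through unscaled")
    ctr[degenerate] <- 0
    scl[degenerate] <- 1
  }
  list(train = sweep(sweep(tr, 2, ctr), 2, scl, "/"),
       test = sweep(sweep(te, 2, ctr), 2, scl, "/"),
       center = ctr, scale = scl)
}

#' Train a support-vector machine on a labeled feature set
#'
#' RBF-kernel SVM (cost 1, kernel width gamma = 1 / n_features by default,
#' the off-the-shelf defaults of the libsvm lineage). Features are assumed
#' already standardized; no further scaling is applied. Multi-class problems
#' use libsvm's one-against-one scheme.
#'
#' @param train a [labeled_feature_set()] (standardized features).
#' @param kernel,cost,gamma SVM hyperparameters.
#' @return fitted `svm` model (class probabilities disabled; deterministic
#'   given the data order).
#' @export
train_svm <- function(train, kernel = "radial", cost = 1, gamma = NULL) {
  stopifnot(inherits(train, "labeled_feature_set"))
  y <- factor(train$labels, levels = sort(unique(train$labels)))
  if (nlevels(y) < 2) stop("need at least 2 classes to train")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  if (is.null(gamma)) gamma <- 1 / ncol(train$features)
  e1071::svm(x = train$features, y = y, kernel = kernel, cost = cost,
             gamma = gamma, scale = FALSE)
}

#' Classify an unseen labeled set and report correct rates
#'
#' @param model a fitted SVM from [train_svm()].
#' @param test a [labeled_feature_set()] standardized with the training
#'   statistics.
#' @return list with `predicted` (character), `per_region` (named vector of
#'   percent-correct per true region), `overall` (percent correct) and
#'   `confusion` (true x predicted table).
#' @export
classify_unseen <- function(model, test) {
  stopifnot(inherits(test, "labeled_feature_set"))
  pred <- as.character(predict(model, test$features))
  true <- test$labels
  regions <- sort(unique(true))
  per_region <- vapply(regions, function(r)
    100 * mean(pred[true == r] == r), numeric(1))
  list(predicted = pred,
       per_region = per_region,
       overall = 100 * mean(pred == true),
       confusion = table(true = true, predicted = pred))
}

#' Pairwise balanced classification-rate matrix
#'
#' For each unordered pair of regions, trains a two-class SVM on the
#' repeat-1 data of those regions only (standardized by that pair's training
#' statistics) and classifies the repeat-2 data. Each pair yields two
#' per-region correct fractions; their mean is the balanced rate, which
#' avoids misleading high scores from pairs of very different sizes. Regions
#' absent from either repeat are excluded and reported.
#'
#' @param train,test [labeled_feature_set()] objects (raw, unstandardized
#'   features; standardization happens per pair).
#' @param regions region names to compare (default: regions present in the
#'   training set).
#' @param ... passed to [train_svm()].
#' @return list with `rates` (symmetric percent matrix, NA diagonal) and
#'   `excluded` (character vector).
#' @export
pairwise_matrix <- function(train, test, regions = NULL, ...) {
  if (is.null(regions)) regions <- sort(unique(train$labels))
  present <- regions %in% train$labels & regions %in% test$labels
  excluded <- regions[!present]
  regions <- regions[present]
  k <- length(regions)
  rates <- matrix(NA_real_, k, k, dimnames = list(regions, regions))
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        pair <- c(regions[i], regions[j])
        tri <- train$labels %in% pair
        tei <- test$labels %in% pair
        z <- zscore_train_apply(train$features[tri, , drop = FALSE],
                                test$features[tei, , drop = FALSE])
        m <- train_svm(labeled_feature_set(z$train, train$labels[tri]), ...)
        res <- classify_unseen(m, labeled_feature_set(z$test, test$labels[tei],
                                                      repeat_id = 2))
        rates[i, j] <- rates[j, i] <- mean(res$per_region[pair])
      }
    }
  }
  list(rates = rates, excluded = excluded)
}

#' @noRd
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums(sweep(x, 2, x[centers[1], ])^2)
  for (i in 2:k) {
    p <- d2 / sum(d2)
    centers[i] <- sample.int(n, 1, prob = p)
    d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[i], ])^2))
  }
  x[centers, , drop = FALSE]
}

#' Order cluster centres along a short connecting chain
#'
#' Finds an ordering of the centres that heuristically minimizes the sum of
#' Euclidean distances between consecutive centres (an open-path travelling
#' salesman objective, NP-hard in general): greedy nearest-neighbor chaining
#' from the most extremal centre, refined by 2-opt moves until no
#' improvement.
#'
#' @param centers k x d matrix of cluster centres.
#' @return list with `order` (permutation of 1..k) and `chain_length`.
#' @export
order_centers <- function(centers) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k == 1) return(list(order = 1L, chain_length = 0))
  d <- as.matrix(stats::dist(centers))
  start <- which.max(rowSums(sweep(centers, 2, colMeans(centers))^2))
  ord <- integer(k)
  ord[1] <- start
  used <- rep(FALSE, k)
  used[start] <- TRUE
  for (i in 2:k) {
    cand <- which(!used)
    ord[i] <- cand[which.min(d[ord[i - 1], cand])]
    used[ord[i]] <- TRUE
  }
  chain <- function(o) sum(d[cbind(o[-k], o[-1])])
  best <- chain(ord)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in 1:(k - 1)) {
      for (j in (i + 1):k) {
        cand <- ord
        cand[i:j] <- rev(cand[i:j])
        cl <- chain(cand)
        if (cl < best - 1e-12) {
          ord <- cand
          best <- cl
          improved <- TRUE
        }
      }
    }
  }
  list(order = ord, chain_length = best)
}

#' K-means parcellation with ordered cluster ids
#'
#' K-means (k-means++ initialization, fixed seed, Lloyd/Hartigan-Wong
#' refinement via [stats::kmeans()]) on optionally standardized features.
#' Cluster ids are then relabeled along the [order_centers()] chain so that
#' clusters with nearby centres get nearby ids, which makes parcellation
#' maps colorable on a single scale.
#'
#' @param features numeric feature matrix.
#' @param k number of clusters (>= 2, <= sample count).
#' @param seed integer seed (controls the k-means++ draw).
#' @param standardize z-score columns first (default TRUE).
#' @return list with `labels` (ordered cluster ids 1..k), `centers`
#'   (ordered, in the clustering space), `chain_length` and `withinss`.
#' @export
kmeans_parcellate <- function(features, k, seed = 1, standardize = TRUE) {
  x <- as.matrix(features)
  if (k < 2) stop("k must be >= 2")
  if (k > nrow(x)) stop("k exceeds the sample count")
  if (standardize) {
    sc <- apply(x, 2, stats::sd)
    sc[!is.finite(sc) | sc == 0] <- 1
    x <- sweep(sweep(x, 2, colMeans(x)), 2, sc, "/")
  }
  set.seed(seed)
  init <- kmeanspp_centers(x, k)
  km <- stats::kmeans(x, centers = init, iter.max = 100)
  oc <- order_centers(km$centers)
  relabel <- integer(k)
  relabel[oc$order] <- seq_len(k)
  list(labels = relabel[km$cluster],
       centers = km$centers[oc$order, , drop = FALSE],
       chain_length = oc$chain_length,
       withinss = sum(km$withinss))
}

#' Chance-adjusted agreement between two partitions (adjusted Rand index)
#'
#' @param a,b integer or character label vectors of equal length.
#' @return adjusted Rand index (1 = identical partitions, 0 = chance).
#' @export
adjusted_rand <- function(a, b) {
  e1071::classAgreement(table(a, b))$crand
}

#' Number of principal components needed to reach a variance threshold
#'
#' PCA on standardized features; reports the smallest component count whose
#' cumulative explained variance reaches the threshold. Zero-variance
#' columns are dropped before scaling.
#'
#' @param features numeric feature matrix.
#' @param variance_threshold cumulative explained-variance target
#'   (default 0.95).
#' @return integer component count; the cumulative variance profile is
#'   attached as attribute `cumulative`.
#' @export
intrinsic_dimension <- function(features, variance_threshold = 0.95) {
  x <- as.matrix(features)
  keep <- apply(x, 2, stats::sd) > 0
  x <- x[, keep, drop = FALSE]
  pc <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  cum <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
  n <- which(cum >= variance_threshold - 1e-12)[1]
  structure(as.integer(n), cumulative = cum)
}

#' Classify an untrained region and report its label composition
#'
#' Applies a trained classifier to feature vectors from a region it never
#' saw (the border-probe experiment: does an unseen area inherit a neighbor's
#' labels or split at a natural border?). Reports the fraction of vertices
#' assigned to each trained label and, when mesh faces are supplied, the
#' size of the largest connected component per assigned label.
#'
#' @param model fitted SVM from [train_svm()].
#' @param features standardized feature matrix of the unseen region (may
#'   have zero rows).
#' @param vertex_index optional vertex indices (into `faces`) of the rows.
#' @param faces optional m x 3 mesh faces providing vertex adjacency.
#' @return list with `assigned` (character per vertex), `fractions` (named,
#'   summing to 1 when non-empty) and `largest_component` (named, or NULL
#'   when no adjacency was given).
#' @export
unseen_region_probe <- function(model, features, vertex_index = NULL,
                                faces = NULL) {
  features <- as.matrix(features)
  if (nrow(features) == 0)
    return(list(assigned = character(0), fractions = numeric(0),
                largest_component = NULL))
  assigned <- as.character(predict(model, features))
  fractions <- table(assigned) / length(assigned)
  fractions <- stats::setNames(as.numeric(fractions), names(fractions))
  largest <- NULL
  if (!is.null(faces) && !is.null(vertex_index)) {
    nb <- neighbor_list(faces, max(faces))
    largest <- vapply(names(fractions), function(lab) {
      verts <- vertex_index[assigned == lab]
      largest_component_size(verts, nb)
    }, numeric(1))
  }
  list(assigned = assigned, fractions = fractions,
       largest_component = largest)
}

#' @noRd
largest_component_size <- function(verts, nb) {
  if (length(verts) == 0) return(0)
  inset <- logical(length(nb))
  inset[verts] <- TRUE
  seen <- logical(length(nb))
  best <- 0
  for (v in verts) {
    if (seen[v]) next
    size <- 0
    stack <- v
    seen[v] <- TRUE
    while (length(stack)) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      size <- size + 1
      for (w in nb[[cur]]) {
        if (inset[w] && !seen[w]) {
          seen[w] <- TRUE
          stack <- c(stack, w)
        }
      }
    }
    best <- max(best, size)
  }
  best
}
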