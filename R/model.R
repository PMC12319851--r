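#' Order clusters by mean myelin water fraction
#'
#' Tissue classes are reported in a fixed semantic order: ordered label 1 has
#' the highest mean native-unit MWF over its hard-assigned voxels and labels
#' descend in mean MWF. Ties are broken by descending mean uFA, then by raw
#' cluster index.
#'
#' @param labels integer vector of raw (unordered) hard cluster assignments
#'   in 1..K.
#' @param features N x 3 native-unit feature matrix (columns MWF, uFA, CMD)
#'   aligned with `labels`.
#' @return Integer permutation `p` with `p[raw] = ordered`; ordered labels
#'   are `p[labels]`.
#' @export
order_clusters_by_mwf <- function(labels, features) {
  labels <- as.integer(labels)
  features <- as.matrix(features)
  K <- max(labels)
  if (any(tabulate(labels, K) == 0L))
    stop("empty cluster: cannot order ", K, " clusters")
  mwf_mean <- vapply(seq_len(K),
                     function(k) mean(features[labels == k, 1L]), 0)
  ufa_mean <- vapply(seq_len(K),
                     function(k) mean(features[labels == k, 2L]), 0)
  ranked <- order(-mwf_mean, -ufa_mean, seq_len(K))
  p <- integer(K)
  p[ranked] <- seq_len(K)
  p
}

#' Fit a microstructural tissue-classification model
#'
#' The model-building pipeline: pool all valid masked voxels of the training
#' subjects, standardise with a Gaussian scaler, cluster the scaled pool
#' with fuzzy c-means, hard-assign every pooled voxel, order the clusters by
#' descending mean MWF, and retain a stratified labelled subsample as the
#' k-nearest-neighbour training set used to classify new subjects.
#'
#' For tractability the fuzzy c-means optimisation runs on a seeded uniform
#' subsample of the pool (`fit_cap` rows); all pooled voxels are then
#' hard-assigned from the fitted centroids. The KNN training set is a seeded
#' stratified subsample capped at `knn_cap` points per ordered cluster.
#'
#' @param subjects list of [subject_dataset] objects (>= 2).
#' @param K number of tissue classes (default 6).
#' @param m fuzzifier (> 1, default 2).
#' @param knn_k neighbours used in classification (default 5).
#' @param seed integer seed controlling subsampling and the FCM starts.
#' @param n_init number of seeded pilot starts explored before the final
#'   fuzzy c-means fit (best pilot warm-starts it).
#' @param fit_cap maximum pool rows used in the FCM optimisation.
#' @param knn_cap maximum stored training points per ordered cluster.
#' @param tol,max_iter fuzzy c-means convergence controls.
#' @return An object of class `tc_model` with components `K`, `m`, `knn_k`,
#'   `scaler`, `centroids` (K x 3, scaled space, raw FCM order),
#'   `label_order` (raw -> ordered permutation), `train_x` / `train_y`
#'   (labelled scaled training points), `cluster_summary` (per-ordered-cluster
#'   native-unit statistics) and `metadata`.
#' @seealso [predict.tc_model()], [summary.tc_model()], [write_tc_model()]
#' @examples
#' spec <- phantom_spec(grid_shape = c(16, 16, 16))
#' cohort <- generate_cohort(spec, n_subjects = 3, seed = 1)
#' fit <- tc_fit(cohort$subjects, K = 6, seed = 1)
#' fit
#' @export
tc_fit <- function(subjects, K = 6L, m = 2, knn_k = 5L, seed = 1L,
                   n_init = 10L, fit_cap = 2e5, knn_cap = 1e4, tol = 1e-5,
                   max_iter = 1000L) {
  if (length(subjects) < 2L) stop("need at least two training subjects")
  pool <- pool_subjects(subjects)
  scaler <- fit_scaler(pool)
  z <- apply_scaler(scaler, pool)

  n <- nrow(z)
  set.seed(as.integer(seed))
  fit_rows <- if (n > fit_cap) sort(sample.int(n, fit_cap)) else seq_len(n)
  fit <- fcm_fit_robust(z[fit_rows, , drop = FALSE], K = K, m = m,
                        seed = seed, tol = tol, max_iter = max_iter,
                        n_init = n_init)

  raw <- hard_assign(fcm_membership(fit, z))
  label_order <- order_clusters_by_mwf(raw, pool$features)
  ordered <- label_order[raw]

  cluster_summary <- cluster_summary_table(ordered, pool$features)

  # stratified seeded subsample of labelled points for the KNN classifier
  set.seed(as.integer(seed) + 1L)
  keep <- unlist(lapply(seq_len(K), function(k) {
    rows <- which(ordered == k)
    if (length(rows) > knn_cap) sort(sample(rows, knn_cap)) else rows
  }), use.names = FALSE)

  structure(list(
    K = as.integer(K), m = m, knn_k = as.integer(knn_k),
    scaler = scaler,
    centroids = fit$centroids,
    label_order = label_order,
    train_x = z[keep, , drop = FALSE],
    train_y = ordered[keep],
    cluster_summary = cluster_summary,
    fcm_info = list(n_iterations = fit$n_iterations,
                    final_objective = fit$final_objective,
                    n_fit_rows = length(fit_rows)),
    metadata = list(subject_ids = pool$subject_ids,
                    n_pool = n, seed = as.integer(seed),
                    fit_cap = fit_cap, knn_cap = knn_cap,
                    schema = "tc_model/1")
  ), class = "tc_model")
}

cluster_summary_table <- function(ordered_labels, features) {
  K <- max(ordered_labels)
  rows <- lapply(seq_len(K), function(k) {
    xk <- features[ordered_labels == k, , drop = FALSE]
    data.frame(cluster = k,
               count = nrow(xk),
               mwf_mean = mean(xk[, 1L]), mwf_sd = stats::sd(xk[, 1L]),
               ufa_mean = mean(xk[, 2L]), ufa_sd = stats::sd(xk[, 2L]),
               cmd_mean = mean(xk[, 3L]), cmd_sd = stats::sd(xk[, 3L]))
  })
  do.call(rbind, rows)
}

#' @export
print.tc_model <- function(x, ...) {
  cat("Tissue classification model\n")
  cat("  K =", x$K, "clusters (ordered by descending mean MWF), m =", x$m,
      ", knn_k =", x$knn_k, "\n")
  cat("  trained on", length(x$metadata$subject_ids), "subject(s),",
      x$metadata$n_pool, "pooled voxels\n")
  cat("  KNN training set:", nrow(x$train_x), "labelled points\n")
  invisible(x)
}

#' Per-cluster metric summary of a fitted model
#'
#' Native-unit mean and standard deviation of each metric within each ordered
#' tissue class of the training pool, plus voxel counts. Cluster 1 has the
#' highest mean MWF by construction.
#'
#' @param object a `tc_model`.
#' @param ... unused.
#' @return A data frame with one row per ordered cluster.
#' @export
summary.tc_model <- function(object, ...) {
  s <- object$cluster_summary
  class(s) <- c("summary.tc_model", "data.frame")
  s
}

#' @export
print.summary.tc_model <- function(x, ...) {
  cat("Per-cluster training-pool statistics (native units):\n")
  print.data.frame(format(as.data.frame(x), digits = 4), row.names = FALSE)
  invisible(x)
}

#' Ordered cluster centroids in native units
#'
#' @param object a `tc_model`.
#' @param ... unused.
#' @return K x 3 matrix of centroids (rows = ordered clusters 1..K, columns
#'   MWF, uFA, CMD) mapped back to native units through the scaler.
#' @export
coef.tc_model <- function(object, ...) {
  native <- apply_scaler(object$scaler, object$centroids, inverse = TRUE)
  out <- native[order(object$label_order), , drop = FALSE]
  rownames(out) <- paste0("cluster", seq_len(object$K))
  colnames(out) <- c("MWF", "uFA", "CMD")
  out
}

#' Plot per-cluster metric profiles
#'
#' Base-graphics profile plot of the ordered cluster centroids in native
#' units, one panel per metric.
#'
#' @param x a `tc_model`.
#' @param ... passed to [graphics::barplot()].
#' @return Invisibly, the centroid matrix plotted.
#' @export
plot.tc_model <- function(x, ...) {
  cen <- coef(x)
  op <- graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  for (j in seq_len(ncol(cen)))
    graphics::barplot(cen[, j], names.arg = seq_len(nrow(cen)),
                      xlab = "cluster", ylab = colnames(cen)[j],
                      main = colnames(cen)[j], ...)
  invisible(cen)
}

knn_classify_matrix <- function(model, z) {
  if (nrow(z) == 0L) return(integer(0))
  .knn_label_cpp(as.matrix(z), model$train_x, as.integer(model$train_y),
                 as.integer(model$knn_k))
}

#' Classify a subject with a fitted model
#'
#' Every valid masked voxel (mask `TRUE`, all three metrics finite) is scaled
#' with the model's training scaler — never refit — and assigned the majority
#' ordered label among its `knn_k` nearest training points in scaled feature
#' space; vote ties go to the lowest ordered label. Voxels outside the mask
#' or with non-finite features receive label 0.
#'
#' @param model a `tc_model`.
#' @param subject a [subject_dataset].
#' @return A [label_volume] on the subject's grid.
#' @export
classify_subject <- function(model, subject) {
  if (!inherits(model, "tc_model")) stop("'model' must be a tc_model")
  if (!inherits(subject, "subject_dataset"))
    stop("'subject' must be a subject_dataset")
  idx <- which(subject$mask$values)
  lab <- array(0L, dim = subject$grid_shape)
  if (length(idx) > 0L) {
    feat <- cbind(subject$mwf$values[idx], subject$ufa$values[idx],
                  subject$cmd$values[idx])
    ok <- rowSums(is.finite(feat)) == 3L
    n_bad <- sum(!ok)
    if (n_bad > 0L)
      message(n_bad, " masked voxel(s) with non-finite features assigned label 0")
    if (any(ok)) {
      z <- apply_scaler(model$scaler, feat[ok, , drop = FALSE])
      lab[idx[ok]] <- knn_classify_matrix(model, z)
    }
  }
  label_volume(lab, K = model$K)
}

#' Predict method for tissue-classification models
#'
#' Dispatches on the input: a [subject_dataset] yields a [label_volume]
#' (see [classify_subject()]); a numeric matrix of native-unit metric
#' triples yields an integer vector of ordered labels.
#'
#' @param object a `tc_model`.
#' @param newdata a [subject_dataset] or an N x 3 native-unit matrix.
#' @param ... unused.
#' @return A [label_volume] or an integer vector.
#' @export
predict.tc_model <- function(object, newdata, ...) {
  if (inherits(newdata, "subject_dataset"))
    return(classify_subject(object, newdata))
  z <- apply_scaler(object$scaler, as.matrix(newdata))
  knn_classify_matrix(object, z)
}

#' Voxelwise average metric atlas
#'
#' Builds a population-average pseudo-subject: at each voxel, each metric is
#' the mean over the subjects whose mask covers that voxel, and the atlas
#' mask keeps voxels covered by at least half of the subjects. All subjects
#' must share one grid (synthetic cohorts do; real data require prior
#' spatial normalisation, which is outside this package).
#'
#' @param subjects list of [subject_dataset] objects.
#' @param subject_id identifier for the atlas pseudo-subject.
#' @return A [subject_dataset] holding the averaged maps.
#' @export
build_metric_atlas <- function(subjects, subject_id = "atlas") {
  if (length(subjects) == 0L) stop("no subjects")
  shp <- subjects[[1L]]$grid_shape
  for (s in subjects)
    if (!identical(s$grid_shape, shp))
      stop("all subjects must share one grid to build an atlas")
  nsub <- length(subjects)
  cover <- array(0L, dim = shp)
  sums <- list(MWF = array(0, shp), uFA = array(0, shp), CMD = array(0, shp))
  for (s in subjects) {
    w <- s$mask$values & is.finite(s$mwf$values) & is.finite(s$ufa$values) &
      is.finite(s$cmd$values)
    cover <- cover + w
    sums$MWF[w] <- sums$MWF[w] + s$mwf$values[w]
    sums$uFA[w] <- sums$uFA[w] + s$ufa$values[w]
    sums$CMD[w] <- sums$CMD[w] + s$cmd$values[w]
  }
  any_cover <- cover > 0L
  if (!any(any_cover)) stop("no common coverage across subjects")
  avg <- lapply(sums, function(a) {
    out <- array(NA_real_, shp)
    out[any_cover] <- a[any_cover] / cover[any_cover]
    out
  })
  mask_arr <- (2L * cover) >= nsub
  aff <- subjects[[1L]]$mwf$affine
  vx <- subjects[[1L]]$mwf$voxel_size_mm
  subject_dataset(subject_id,
                  metric_volume(avg$MWF, "MWF", vx, aff),
                  metric_volume(avg$uFA, "uFA", vx, aff),
                  metric_volume(avg$CMD, "CMD", vx, aff),
                  brain_mask(mask_arr), group = "other")
}

#' Classify a metric atlas
#'
#' The atlas pseudo-subject is classified with the same model as any
#' individual — no special casing — to give the population-averaged tissue
#' classification that individuals are compared against.
#'
#' @param model a `tc_model`.
#' @param atlas_subject the [subject_dataset] from [build_metric_atlas()].
#' @return A [label_volume].
#' @export
classify_atlas <- function(model, atlas_subject) {
  classify_subject(model, atlas_subject)
}

#' Summarise clusters over a labelled pool
#'
#' Per-ordered-cluster native-unit mean/SD of each metric plus voxel counts,
#' for an arbitrary feature pool classified by the model.
#'
#' @param model a `tc_model`.
#' @param pool a `voxel_pool` (or native-unit N x 3 matrix).
#' @return A data frame, one row per ordered cluster.
#' @export
summarize_clusters <- function(model, pool) {
  feat <- if (inherits(pool, "voxel_pool")) pool$features else as.matrix(pool)
  lab <- predict(model, feat)
  keep <- lab > 0L
  cluster_summary_table(lab[keep], feat[keep, , drop = FALSE])
}

## ---- model serialisation ---------------------------------------------------

#' Write a tissue-classification model to JSON
#'
#' The full model state (scaler, centroids, label order, labelled training
#' points, metadata) in one schema-versioned JSON document; portable and
#' diffable. [read_tc_model()] restores a model that classifies identically.
#'
#' @param model a `tc_model`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tc_model <- function(model, path) {
  doc <- list(
    schema = model$metadata$schema,
    K = model$K, m = model$m, knn_k = model$knn_k,
    scaler = list(mean = unname(model$scaler$mean),
                  sd = unname(model$scaler$sd)),
    centroids = unname(model$centroids),
    label_order = model$label_order,
    train_x = unname(model$train_x),
    train_y = model$train_y,
    cluster_summary = model$cluster_summary,
    fcm_info = model$fcm_info,
    metadata = model$metadata
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a tissue-classification model from JSON
#'
#' @param path file written by [write_tc_model()].
#' @return A `tc_model`.
#' @export
read_tc_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "tc_model/1"))
    stop("unrecognised model schema: ", doc$schema)
  metric_names <- c("MWF", "uFA", "CMD")
  scaler <- structure(list(mean = stats::setNames(doc$scaler$mean, metric_names),
                           sd = stats::setNames(doc$scaler$sd, metric_names)),
                      class = "scaler_params")
  structure(list(
    K = as.integer(doc$K), m = doc$m, knn_k = as.integer(doc$knn_k),
    scaler = scaler,
    centroids = matrix(as.numeric(doc$centroids), nrow = doc$K,
                       dimnames = list(NULL, metric_names)),
    label_order = as.integer(doc$label_order),
    train_x = matrix(as.numeric(doc$train_x), ncol = 3L,
                     dimnames = list(NULL, metric_names)),
    train_y = as.integer(doc$train_y),
    cluster_summary = as.data.frame(doc$cluster_summary),
    fcm_info = doc$fcm_info,
    metadata = doc$metadata
  ), class = "tc_model")
}
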