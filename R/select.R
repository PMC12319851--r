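#' Select the number of tissue clusters
#'
#' For each candidate K, fuzzy c-means is fitted on the (scaled) training
#' pool, each test pool is classified through the KNN step, and the
#' Calinski-Harabasz and Davies-Bouldin indices are computed on the
#' classified test data (test-side scoring, averaged across test pools).
#' The selected K maximises the combined rank: CH ranked descending plus DB
#' ranked ascending; rank-sum ties are broken by the higher CH score, then
#' by the lowest K. The full per-K score table is returned so a human can
#' override the automatic choice.
#'
#' Large pools are handled with seeded uniform subsamples: `fit_cap` rows
#' for the FCM optimisation, `test_cap` rows per test pool for index
#' computation, and `knn_cap` labelled points per cluster for the
#' classification step.
#'
#' @param train_pool a `voxel_pool` (or native-unit matrix) of training
#'   voxels.
#' @param test_pools list of `voxel_pool`s (or matrices), one per test
#'   subject.
#' @param K_range integer vector of candidate cluster numbers (all >= 2).
#' @param m fuzzifier.
#' @param seed integer seed.
#' @param knn_k neighbours for the classification step.
#' @param n_init seeded pilot starts per fuzzy c-means fit.
#' @param fit_cap,test_cap,knn_cap subsampling caps (see Details).
#' @param tol fuzzy c-means convergence tolerance for the scan.
#' @return An object of class `cluster_validity`: list with `scores` (data
#'   frame: K, calinski_harabasz, davies_bouldin, rank_sum), `selected_K`
#'   and `K_range`.
#' @export
select_cluster_number <- function(train_pool, test_pools, K_range = 2:10,
                                  m = 2, seed = 1L, knn_k = 5L,
                                  n_init = 6L, fit_cap = 3e4,
                                  test_cap = 1e4, knn_cap = 1000,
                                  tol = 1e-4) {
  K_range <- sort(unique(as.integer(K_range)))
  if (length(K_range) == 0L) stop("empty K_range")
  if (any(K_range < 2L)) stop("candidate K must be >= 2")
  xtr <- if (inherits(train_pool, "voxel_pool")) train_pool$features
         else as.matrix(train_pool)
  if (max(K_range) >= nrow(xtr)) stop("K_range must stay below N")
  if (!is.list(test_pools) || inherits(test_pools, "voxel_pool"))
    test_pools <- list(test_pools)
  scaler <- fit_scaler(xtr)
  z <- apply_scaler(scaler, xtr)
  set.seed(as.integer(seed))
  fit_rows <- if (nrow(z) > fit_cap) sort(sample.int(nrow(z), fit_cap))
              else seq_len(nrow(z))
  zfit <- z[fit_rows, , drop = FALSE]
  ztests <- lapply(test_pools, function(p) {
    xt <- if (inherits(p, "voxel_pool")) p$features else as.matrix(p)
    zt <- apply_scaler(scaler, xt)
    if (nrow(zt) > test_cap) zt[sort(sample.int(nrow(zt), test_cap)), ,
                                drop = FALSE] else zt
  })

  ch <- db <- numeric(length(K_range))
  for (i in seq_along(K_range)) {
    K <- K_range[i]
    fit <- fcm_fit_robust(zfit, K = K, m = m, seed = seed, tol = tol,
                          n_init = n_init, pilot_cap = 5e3)
    lab_fit <- hard_assign(fit$memberships)
    # stratified labelled subsample for the KNN classification step
    set.seed(as.integer(seed) + K)
    keep <- unlist(lapply(seq_len(K), function(k) {
      rows <- which(lab_fit == k)
      if (length(rows) > knn_cap) sort(sample(rows, knn_cap)) else rows
    }), use.names = FALSE)
    tx <- zfit[keep, , drop = FALSE]; ty <- lab_fit[keep]
    ch_i <- db_i <- numeric(length(ztests))
    for (j in seq_along(ztests)) {
      lab <- .knn_label_cpp(ztests[[j]], tx, as.integer(ty),
                            as.integer(knn_k))
      ch_i[j] <- tryCatch(calinski_harabasz(ztests[[j]], lab),
                          error = function(e) NA_real_)
      db_i[j] <- tryCatch(davies_bouldin(ztests[[j]], lab),
                          error = function(e) NA_real_)
    }
    ch[i] <- mean(ch_i, na.rm = TRUE)
    db[i] <- mean(db_i, na.rm = TRUE)
  }
  ch[!is.finite(ch)] <- NA_real_
  rs <- rank(-ch, ties.method = "average", na.last = "keep") +
    rank(db, ties.method = "average", na.last = "keep")
  rs[is.na(rs)] <- Inf
  selected <- K_range[order(rs, -ch, K_range, na.last = TRUE)][1L]
  structure(list(
    scores = data.frame(K = K_range, calinski_harabasz = ch,
                        davies_bouldin = db, rank_sum = rs),
    selected_K = selected, K_range = K_range
  ), class = "cluster_validity")
}

#' @export
print.cluster_validity <- function(x, ...) {
  cat("Cluster-number selection over K in",
      paste(range(x$K_range), collapse = ".."), "\n")
  print.data.frame(format(x$scores, digits = 4), row.names = FALSE)
  cat("Selected K =", x$selected_K, "(rank-sum of CH desc + DB asc)\n")
  invisible(x)
}

#' Rotating train/test classification
#'
#' Cohort-stability check: subjects are randomly partitioned (seeded shuffle,
#' contiguous blocks) into `n_folds` folds; each subject is classified
#' exactly once, by the model trained on all subjects outside its own fold.
#' With `compare_full = TRUE` a model trained on the whole cohort classifies
#' every subject too, and the per-subject voxelwise agreement between
#' fold-model and full-model labels is reported — stable clusterings change
#' only a small fraction of voxels.
#'
#' @param subjects list of [subject_dataset] objects.
#' @param n_folds number of folds (default 5; the last fold absorbs any
#'   remainder).
#' @param K,m,knn_k,fit_cap,knn_cap model parameters passed to [tc_fit()].
#' @param seed integer seed (partition and every model fit).
#' @param compare_full also fit the all-subject model and report agreement.
#' @return An object of class `rotation_cv`: list with `folds` (data frame
#'   subject_id, fold), `labels` (named list of [label_volume]s, fold
#'   models), `full_labels` (if requested), `agreement` (data frame
#'   subject_id, fold, agreement over voxels labelled by both) and `models`.
#' @export
rotation_cv <- function(subjects, n_folds = 5L, K = 6L, m = 2, knn_k = 5L,
                        seed = 1L, fit_cap = 2e5, knn_cap = 1e4,
                        compare_full = TRUE) {
  nsub <- length(subjects)
  if (nsub < n_folds) stop("fewer subjects (", nsub, ") than folds (",
                           n_folds, ")")
  ids <- vapply(subjects, `[[`, "", "subject_id")
  set.seed(as.integer(seed))
  perm <- sample.int(nsub)
  base <- nsub %/% n_folds
  sizes <- rep(base, n_folds)
  sizes[n_folds] <- sizes[n_folds] + nsub %% n_folds
  fold_of <- integer(nsub)
  fold_of[perm] <- rep(seq_len(n_folds), times = sizes)

  labels <- vector("list", nsub); names(labels) <- ids
  models <- vector("list", n_folds)
  for (f in seq_len(n_folds)) {
    train <- subjects[fold_of != f]
    models[[f]] <- tc_fit(train, K = K, m = m, knn_k = knn_k, seed = seed,
                          fit_cap = fit_cap, knn_cap = knn_cap)
    for (i in which(fold_of == f))
      labels[[i]] <- classify_subject(models[[f]], subjects[[i]])
  }

  out <- list(folds = data.frame(subject_id = ids, fold = fold_of),
              labels = labels, models = models)
  if (compare_full) {
    full_model <- tc_fit(subjects, K = K, m = m, knn_k = knn_k, seed = seed,
                         fit_cap = fit_cap, knn_cap = knn_cap)
    full_labels <- lapply(subjects, classify_subject, model = full_model)
    names(full_labels) <- ids
    agree <- vapply(seq_len(nsub), function(i) {
      a <- labels[[i]]$labels; b <- full_labels[[i]]$labels
      both <- a > 0L & b > 0L
      mean(a[both] == b[both])
    }, 0)
    out$full_labels <- full_labels
    out$full_model <- full_model
    out$agreement <- data.frame(subject_id = ids, fold = fold_of,
                                agreement = agree)
  }
  class(out) <- "rotation_cv"
  out
}

#' @export
print.rotation_cv <- function(x, ...) {
  cat("Rotating train/test classification:", nrow(x$folds), "subjects,",
      length(x$models), "folds\n")
  if (!is.null(x$agreement))
    cat("fold-model vs full-model voxel agreement: median",
        format(stats::median(x$agreement$agreement), digits = 4),
        "(min", format(min(x$agreement$agreement), digits = 4), ")\n")
  invisible(x)
}
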