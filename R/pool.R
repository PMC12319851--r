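#' Pool masked voxel features across subjects
#'
#' Builds the N x 3 feature matrix (columns MWF, uFA, CMD) of all valid
#' masked voxels across subjects. A voxel is valid when the mask is `TRUE`
#' and all three metrics are finite there; invalid in-mask voxels are dropped
#' with a message. No spatial coordinate enters the features — clustering
#' sees microstructure only. Row order is deterministic: subjects in input
#' order, voxels in column-major scan order, so pooling is
#' permutation-equivariant over subjects.
#'
#' @param subjects list of [subject_dataset] objects (at least one).
#' @return An object of class `voxel_pool`: list with `features` (N x 3
#'   numeric matrix), `subject_id` (character, per row), `voxel_index`
#'   (integer linear grid index, per row) and `subject_ids`.
#' @export
pool_subjects <- function(subjects) {
  if (!is.list(subjects) || length(subjects) == 0L)
    stop("need at least one subject")
  if (inherits(subjects, "subject_dataset")) subjects <- list(subjects)
  blocks <- vector("list", length(subjects))
  ids <- character(length(subjects))
  n_dropped <- 0L
  for (s in seq_along(subjects)) {
    sub <- subjects[[s]]
    if (!inherits(sub, "subject_dataset"))
      stop("element ", s, " is not a subject_dataset")
    idx <- which(sub$mask$values)
    feat <- cbind(MWF = sub$mwf$values[idx],
                  uFA = sub$ufa$values[idx],
                  CMD = sub$cmd$values[idx])
    ok <- is.finite(feat[, 1L]) & is.finite(feat[, 2L]) & is.finite(feat[, 3L])
    n_dropped <- n_dropped + sum(!ok)
    if (!any(ok)) {
      warning("subject ", sub$subject_id,
              " has zero valid masked voxels; skipped")
      blocks[[s]] <- NULL
      next
    }
    blocks[[s]] <- list(id = sub$subject_id, feat = feat[ok, , drop = FALSE],
                        idx = idx[ok])
    ids[s] <- sub$subject_id
  }
  blocks <- Filter(Negate(is.null), blocks)
  if (length(blocks) == 0L) stop("no subject contributed any valid voxel")
  if (n_dropped > 0L)
    message(n_dropped, " in-mask voxel(s) with non-finite metrics dropped from the pool")
  features <- do.call(rbind, lapply(blocks, `[[`, "feat"))
  structure(list(
    features = features,
    subject_id = rep(vapply(blocks, `[[`, "", "id"),
                     vapply(blocks, function(b) nrow(b$feat), 0L)),
    voxel_index = unlist(lapply(blocks, `[[`, "idx"), use.names = FALSE),
    subject_ids = vapply(blocks, `[[`, "", "id")
  ), class = "voxel_pool")
}

#' @export
print.voxel_pool <- function(x, ...) {
  cat("Voxel feature pool:", nrow(x$features), "voxels from",
      length(x$subject_ids), "subject(s)\n")
  invisible(x)
}

#' Fit a standard Gaussian scaler
#'
#' Per-column mean and population (divide-by-N) standard deviation of the
#' pooled features, in native units. This is the conventional standard
#' scaler; test subjects are always scaled with the training-pool parameters,
#' never refit.
#'
#' @param pool a `voxel_pool` or an N x 3 numeric matrix (N >= 2).
#' @return An object of class `scaler_params`: list with `mean` and `sd`
#'   (length-3 named numeric vectors).
#' @export
fit_scaler <- function(pool) {
  x <- if (inherits(pool, "voxel_pool")) pool$features else as.matrix(pool)
  if (nrow(x) < 2L) stop("need at least two rows to fit a scaler")
  mu <- colMeans(x)
  sdev <- sqrt(colMeans(sweep(x, 2L, mu)^2))   # population SD
  bad <- which(sdev <= 0 | !is.finite(sdev))
  if (length(bad))
    stop("degenerate data: zero variance in metric ",
         paste(colnames(x)[bad], collapse = ", "))
  structure(list(mean = mu, sd = sdev), class = "scaler_params")
}

#' Apply (or invert) a Gaussian scaler
#'
#' Columnwise affine map `z = (x - mean) / sd`; with `inverse = TRUE` the
#' exact inverse `x = z * sd + mean`.
#'
#' @param params a `scaler_params` from [fit_scaler()].
#' @param features N x 3 numeric matrix (or `voxel_pool`).
#' @param inverse logical.
#' @return N x 3 numeric matrix.
#' @export
apply_scaler <- function(params, features, inverse = FALSE) {
  x <- if (inherits(features, "voxel_pool")) features$features
       else as.matrix(features)
  if (ncol(x) != length(params$mean))
    stop("feature matrix has ", ncol(x), " columns; scaler expects ",
         length(params$mean))
  if (inverse)
    sweep(sweep(x, 2L, params$sd, `*`), 2L, params$mean, `+`)
  else
    sweep(sweep(x, 2L, params$mean), 2L, params$sd, `/`)
}
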