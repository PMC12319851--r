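#' Correlation and principal-component structure of the metrics
#'
#' Checks that the three metrics carry non-redundant information: Pearson
#' correlation matrix of MWF, uFA and CMD over the pooled voxels, and PCA of
#' the z-scored columns (correlation PCA, matching the Gaussian scaling used
#' before clustering) with explained-variance ratios and loadings.
#'
#' @param pool a `voxel_pool` or native-unit N x 3 matrix (N >= 3, nonzero
#'   variance per column).
#' @return An object of class `metric_structure`: list with `correlation`
#'   (3 x 3), `explained_variance_ratio` (descending, sums to 1) and
#'   `loadings` (metric x component rotation matrix).
#' @export
metric_structure <- function(pool) {
  x <- if (inherits(pool, "voxel_pool")) pool$features else as.matrix(pool)
  if (nrow(x) < 3L) stop("need at least three voxels")
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0))
    stop("degenerate column: zero variance in ",
         paste(colnames(x)[sds == 0], collapse = ", "))
  pca <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  evr <- pca$sdev^2 / sum(pca$sdev^2)
  structure(list(correlation = stats::cor(x),
                 explained_variance_ratio = evr,
                 loadings = pca$rotation),
            class = "metric_structure")
}

#' @export
print.metric_structure <- function(x, ...) {
  cat("Metric correlation matrix:\n")
  print(round(x$correlation, 3))
  cat("Explained variance ratios:",
      paste0(format(100 * x$explained_variance_ratio, digits = 3), "%",
             collapse = ", "), "\n")
  invisible(x)
}
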