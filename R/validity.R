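#' Calinski-Harabasz index
#'
#' Variance-ratio criterion for a hard clustering: `CH = (B/(K-1)) /
#' (W/(N-K))` with between-cluster dispersion `B = sum_k n_k ||c_k - c||^2`
#' and within-cluster dispersion `W = sum_k sum_{i in k} ||x_i - c_k||^2`.
#' Higher is better. If every cluster is fully collapsed (`W = 0`) the
#' index diverges and `Inf` is returned.
#'
#' @param x numeric matrix of points.
#' @param labels integer cluster labels (every cluster in `1:K` nonempty,
#'   `2 <= K < N`).
#' @return Numeric scalar.
#' @export
calinski_harabasz <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  n <- nrow(x)
  tab <- table(factor(labels, levels = sort(unique(labels))))
  K <- length(tab)
  if (K < 2L) stop("Calinski-Harabasz needs at least 2 clusters")
  if (K >= n) stop("K must be < N")
  if (any(tab == 0L)) stop("empty cluster")
  gmean <- colMeans(x)
  B <- 0; W <- 0
  for (k in as.integer(names(tab))) {
    xk <- x[labels == k, , drop = FALSE]
    ck <- colMeans(xk)
    B <- B + nrow(xk) * sum((ck - gmean)^2)
    W <- W + sum(sweep(xk, 2L, ck)^2)
  }
  if (W == 0) return(Inf)
  (B / (K - 1)) / (W / (n - K))
}

#' Davies-Bouldin index
#'
#' `DB = (1/K) sum_i max_{j != i} (s_i + s_j) / d_ij` with `s_i` the mean
#' distance of cluster-i points to their centroid and `d_ij` the distance
#' between centroids i and j. Lower is better; singleton (or collapsed)
#' clusters contribute zero scatter.
#'
#' @inheritParams calinski_harabasz
#' @return Numeric scalar.
#' @export
davies_bouldin <- function(x, labels) {
  x <- as.matrix(x)
  labels <- as.integer(labels)
  lv <- sort(unique(labels))
  K <- length(lv)
  if (K < 2L) stop("Davies-Bouldin needs at least 2 clusters")
  cen <- matrix(0, K, ncol(x))
  s <- numeric(K)
  for (i in seq_len(K)) {
    xk <- x[labels == lv[i], , drop = FALSE]
    cen[i, ] <- colMeans(xk)
    s[i] <- mean(sqrt(rowSums(sweep(xk, 2L, cen[i, ])^2)))
  }
  ratios <- matrix(NA_real_, K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) {
    if (i == j) next
    dij <- sqrt(sum((cen[i, ] - cen[j, ])^2))
    if (dij == 0)
      stop("coincident centroids for clusters ", lv[i], " and ", lv[j],
           ": Davies-Bouldin undefined (division by zero)")
    ratios[i, j] <- (s[i] + s[j]) / dij
  }
  mean(apply(ratios, 1L, max, na.rm = TRUE))
}
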