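#' Fuzzy c-means clustering
#'
#' Minimises the fuzzified within-cluster objective
#' \deqn{J_m = \sum_i \sum_k u_{ik}^m \| x_i - c_k \|^2}
#' subject to row-stochastic memberships, by alternating the centroid update
#' \eqn{c_k = \sum_i u_{ik}^m x_i / \sum_i u_{ik}^m} and the membership
#' update \eqn{u_{ik} = 1 / \sum_j (d_{ik}/d_{ij})^{2/(m-1)}} with Euclidean
#' distances. Iteration stops when the maximum absolute membership change
#' falls below `tol` or after `max_iter` sweeps. If a point coincides with
#' one or more centroids (zero distance), its membership mass 1 is split
#' evenly among the zero-distance clusters.
#'
#' Memberships are initialised as seeded uniform random rows normalised to
#' sum to one, or — when `init` supplies a K x d centroid matrix — from the
#' membership formula evaluated at those centroids (a warm start).
#'
#' @param x numeric matrix (rows = points, already scaled).
#' @param K number of clusters, `1 <= K < nrow(x)`.
#' @param m fuzzifier, > 1 (default 2).
#' @param seed integer seed for the membership initialisation.
#' @param tol convergence tolerance on max |change in u| (default 1e-5).
#' @param max_iter iteration cap (default 1000).
#' @param init optional K x d centroid matrix to warm-start from.
#' @return An object of class `fcm_fit`: list with `centroids` (K x d),
#'   `memberships` (N x K), `m`, `n_iterations`, `final_objective`,
#'   `objective_trace` (one value per iteration, non-increasing) and `seed`.
#' @export
fcm_fit <- function(x, K, m = 2, seed = 1L, tol = 1e-5, max_iter = 1000L,
                    init = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (!all(is.finite(x))) stop("non-finite features passed to fcm_fit")
  n <- nrow(x); K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K >= n) stop("K = ", K, " must be smaller than the number of points ", n)
  if (m <= 1) stop("fuzzifier m must be > 1")

  if (K == 1L) {
    cen <- matrix(colMeans(x), nrow = 1L, dimnames = list(NULL, colnames(x)))
    u <- matrix(1, n, 1L)
    obj <- sum(rowSums(sweep(x, 2L, cen[1L, ])^2))
    return(structure(list(centroids = cen, memberships = u, m = m,
                          n_iterations = 0L, final_objective = obj,
                          objective_trace = obj, seed = as.integer(seed)),
                     class = "fcm_fit"))
  }

  sq_dist <- function(cen) {
    d2 <- matrix(0, n, K)
    for (k in seq_len(K)) d2[, k] <- rowSums(sweep(x, 2L, cen[k, ])^2)
    d2
  }
  memberships_from_d2 <- function(d2) {
    zero <- d2 <= 0
    has_zero <- rowSums(zero) > 0L
    # exponent 2/(m-1) applied to d (= d2^(1/(m-1)) on squared distances)
    w <- d2^(-1 / (m - 1))
    unew <- w / rowSums(w)
    if (any(has_zero)) {
      rows <- which(has_zero)
      unew[rows, ] <- zero[rows, , drop = FALSE] /
        rowSums(zero[rows, , drop = FALSE])
    }
    unew
  }

  if (is.null(init)) {
    set.seed(as.integer(seed))
    u <- matrix(stats::runif(n * K), n, K)
    u <- u / rowSums(u)
  } else {
    init <- as.matrix(init)
    if (!all(dim(init) == c(K, ncol(x))))
      stop("'init' must be a K x d centroid matrix")
    u <- memberships_from_d2(sq_dist(init))
  }

  trace <- numeric(0)
  iter <- 0L
  repeat {
    iter <- iter + 1L
    um <- u^m
    cen <- crossprod(um, x) / colSums(um)
    d2 <- sq_dist(cen)
    unew <- memberships_from_d2(d2)
    trace[iter] <- sum(unew^m * d2)
    delta <- max(abs(unew - u))
    u <- unew
    if (delta < tol || iter >= max_iter) break
  }
  dimnames(cen) <- list(NULL, colnames(x))
  structure(list(centroids = cen, memberships = u, m = m,
                 n_iterations = iter, final_objective = trace[iter],
                 objective_trace = trace, seed = as.integer(seed)),
            class = "fcm_fit")
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat("Fuzzy c-means fit: K =", nrow(x$centroids), ", m =", x$m,
      ",", x$n_iterations, "iterations, objective",
      format(x$final_objective, digits = 6), "\n")
  invisible(x)
}

# Multi-start FCM: cheap pilot fits on a seeded subsample explore starts,
# the best (lowest-objective) pilot centroids warm-start one full fit.
# Random-membership starts put all centroids near the global mean, so a
# fraction of them settle in merged/split local minima; the pilot stage makes
# the final fit reproducibly land on the best basin found.
fcm_fit_robust <- function(x, K, m = 2, seed = 1L, tol = 1e-5,
                           max_iter = 1000L, n_init = 10L,
                           pilot_cap = 1e4) {
  n <- nrow(x)
  if (K == 1L || n_init <= 1L)
    return(fcm_fit(x, K, m = m, seed = seed, tol = tol, max_iter = max_iter))
  set.seed(as.integer(seed))
  rows <- if (n > pilot_cap) sort(sample.int(n, pilot_cap)) else seq_len(n)
  xp <- x[rows, , drop = FALSE]
  best <- NULL
  for (i in seq_len(n_init)) {
    f <- fcm_fit(xp, K, m = m, seed = as.integer(seed) + i - 1L,
                 tol = max(tol, 1e-4), max_iter = max_iter)
    if (is.null(best) || f$final_objective < best$final_objective) best <- f
  }
  fcm_fit(x, K, m = m, seed = seed, tol = tol, max_iter = max_iter,
          init = best$centroids)
}

#' Hard cluster assignment from memberships
#'
#' Argmax per row; ties broken toward the lowest cluster index.
#'
#' @param memberships N x K membership matrix (rows sum to 1).
#' @return Integer vector of cluster indices in 1..K.
#' @export
hard_assign <- function(memberships) {
  max.col(as.matrix(memberships), ties.method = "first")
}

#' Membership of new points under a fitted fuzzy clustering
#'
#' Evaluates the FCM membership formula at fixed centroids; the argmax
#' coincides with nearest-centroid assignment.
#'
#' @param fit an `fcm_fit`.
#' @param x numeric matrix of new points (same columns, same scaling).
#' @return N x K membership matrix.
#' @export
fcm_membership <- function(fit, x) {
  x <- as.matrix(x)
  K <- nrow(fit$centroids)
  n <- nrow(x)
  d2 <- matrix(0, n, K)
  for (k in seq_len(K)) d2[, k] <- rowSums(sweep(x, 2L, fit$centroids[k, ])^2)
  if (K == 1L) return(matrix(1, n, 1L))
  zero <- d2 <= 0
  has_zero <- rowSums(zero) > 0L
  w <- d2^(-1 / (fit$m - 1))
  u <- w / rowSums(w)
  if (any(has_zero)) {
    rows <- which(has_zero)
    u[rows, ] <- zero[rows, , drop = FALSE] /
      rowSums(zero[rows, , drop = FALSE])
  }
  u
}
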