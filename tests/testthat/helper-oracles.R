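# Independent brute-force implementations of the validity indices, written
# as direct double loops over the defining formulas. They deliberately share
# no code with the package.

ch_brute <- function(x, labels) {
  x <- as.matrix(x); n <- nrow(x)
  lv <- sort(unique(labels)); K <- length(lv)
  g <- colMeans(x)
  B <- 0; W <- 0
  for (l in lv) {
    xk <- x[labels == l, , drop = FALSE]
    ck <- colMeans(xk)
    B <- B + nrow(xk) * sum((ck - g)^2)
    for (i in seq_len(nrow(xk))) W <- W + sum((xk[i, ] - ck)^2)
  }
  (B / (K - 1)) / (W / (n - K))
}

db_brute <- function(x, labels) {
  x <- as.matrix(x)
  lv <- sort(unique(labels)); K <- length(lv)
  cen <- do.call(rbind, lapply(lv, function(l)
    colMeans(x[labels == l, , drop = FALSE])))
  s <- sapply(seq_len(K), function(i) {
    xk <- x[labels == lv[i], , drop = FALSE]
    mean(sapply(seq_len(nrow(xk)),
                function(r) sqrt(sum((xk[r, ] - cen[i, ])^2))))
  })
  total <- 0
  for (i in seq_len(K)) {
    worst <- -Inf
    for (j in seq_len(K)) {
      if (i == j) next
      r <- (s[i] + s[j]) / sqrt(sum((cen[i, ] - cen[j, ])^2))
      if (r > worst) worst <- r
    }
    total <- total + worst
  }
  total / K
}
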