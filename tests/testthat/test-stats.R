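test_that("one-way ANOVA on cluster sizes behaves at the boundaries", {
  # every group sees the same distribution {0.1, 0.3}: between-group SS = 0
  sizes <- matrix(rep(c(0.1, 0.3), times = 6), ncol = 2)
  groups <- rep(c("HC", "RRMS", "ProgMS"), each = 2)
  res <- anova_cluster_sizes(sizes, groups)
  # identical group distributions: zero between-group variance
  expect_equal(res$F, c(0, 0))
  expect_identical(res$df1, c(2L, 2L))
  expect_identical(res$df2, c(3L, 3L))
  # clearly separated groups: p below any fixed alpha
  set.seed(4)
  sep <- cbind(c(rnorm(3, 0, 1e-4), rnorm(3, 1, 1e-4)))
  res2 <- anova_cluster_sizes(sep, rep(c("a", "b"), each = 3))
  expect_lt(res2$p, 1e-10)
  # permuting subjects leaves results unchanged
  perm <- sample(6)
  res3 <- anova_cluster_sizes(sep[perm, , drop = FALSE],
                              rep(c("a", "b"), each = 3)[perm])
  expect_equal(res3$F, res2$F)
  expect_error(anova_cluster_sizes(sizes, rep("HC", 6)), "two groups")
})

test_that("Tukey HSD intervals and p-values are mutually consistent", {
  set.seed(12)
  vals <- c(rnorm(8, 0), rnorm(8, 0.8), rnorm(8, 0.9))
  groups <- rep(c("HC", "RRMS", "ProgMS"), each = 8)
  tk <- tukey_posthoc(vals, groups)
  expect_identical(nrow(tk), 3L)
  excl0 <- tk$lower > 0 | tk$upper < 0
  expect_identical(excl0, tk$p_adj < 0.05)
  # identical groups: p ~ 1, CIs contain 0
  same <- tukey_posthoc(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_true(all(same$p_adj > 0.99))
  expect_true(all(same$lower < 0 & same$upper > 0))
})

test_that("Tukey HSD reproduces a directly computed studentised range case", {
  # balanced one-way layout; compare against the closed-form HSD interval
  y <- c(18, 22, 21, 17, 25, 27, 29, 28, 30, 35, 33, 31)
  g <- rep(c("g1", "g2", "g3"), each = 4)
  tk <- tukey_posthoc(y, g)
  mse <- sum(unlist(lapply(split(y, g), function(v) sum((v - mean(v))^2)))) / 9
  half <- qtukey(0.95, 3, 9) * sqrt(mse / 4)
  means <- tapply(y, g, mean)
  i <- which(tk$comparison == "g2-g1")
  expect_equal(tk$difference[i], unname(means["g2"] - means["g1"]))
  expect_equal(tk$upper[i] - tk$lower[i], 2 * half, tolerance = 1e-6)
})

test_that("Welch test matches the direct formula and its symmetries", {
  x <- c(1, 2, 3, 4); y <- c(1, 2, 3, 4)
  same <- welch_severity(x, y)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  set.seed(3)
  a <- rnorm(9, 0, 1); b <- rnorm(14, 1, 2)
  w <- welch_severity(a, b)
  # brute-force Welch statistic and Satterthwaite df
  se2 <- var(a) / 9 + var(b) / 14
  t_direct <- (mean(a) - mean(b)) / sqrt(se2)
  df_direct <- se2^2 / ((var(a) / 9)^2 / 8 + (var(b) / 14)^2 / 13)
  expect_equal(w$t, t_direct, tolerance = 1e-12)
  expect_equal(w$df, df_direct, tolerance = 1e-12)
  expect_equal(w$p, 2 * pt(-abs(t_direct), df_direct), tolerance = 1e-12)
  # swapping groups flips the sign of t only
  w2 <- welch_severity(b, a)
  expect_equal(w2$t, -w$t)
  expect_equal(w2$p, w$p)
})

test_that("Spearman correlation is monotone-invariant and handles missing", {
  sev <- c(a = 1, b = 2, c = 3, d = 4, e = 5)
  clin <- data.frame(subject_id = letters[1:5], group = "RRMS",
                     EDSS = 1:5, SDMT = c(50, 45, 40, 35, 30))
  res <- spearman_clinical(sev, clin, score = "SDMT")
  expect_equal(res$r, -1)
  expect_identical(res$n, 5L)
  res_edss <- spearman_clinical(sev, clin, score = "EDSS")
  expect_equal(res_edss$r, 1)
  # invariant under strictly monotone transforms of either variable
  clin2 <- clin; clin2$SDMT <- exp(clin$SDMT / 10)
  expect_equal(spearman_clinical(sev^3, clin2)$r, res$r)
  # a missing score drops that subject and reports the reduced n
  clin3 <- clin; clin3$SDMT[2] <- NA
  res3 <- spearman_clinical(sev, clin3)
  expect_identical(res3$n, 4L)
})

test_that("clinical tables validate EDSS range", {
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(subject_id = "s1", group = "RRMS",
                       EDSS = 11, SDMT = 50), path, row.names = FALSE)
  expect_error(read_clinical_scores(path), "EDSS")
  write.csv(data.frame(subject_id = c("s1", "s2"), group = "RRMS",
                       EDSS = c(2, NA), SDMT = c(50, NA)),
            path, row.names = FALSE)
  tab <- read_clinical_scores(path)
  expect_true(is.na(tab$SDMT[2]))
})
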