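test_that("cluster ordering sorts by descending mean MWF with tie rules", {
  feats <- rbind(matrix(rep(c(0.05, 0.5, 0.1), 4), ncol = 3, byrow = TRUE),
                 matrix(rep(c(0.15, 0.5, 0.1), 4), ncol = 3, byrow = TRUE),
                 matrix(rep(c(0.10, 0.5, 0.1), 4), ncol = 3, byrow = TRUE))
  labels <- rep(1:3, each = 4)
  # means: A=0.05, B=0.15, C=0.10 -> B->1, C->2, A->3
  expect_identical(order_clusters_by_mwf(labels, feats), c(3L, 1L, 2L))
  # already-descending means give the identity permutation
  desc <- order_clusters_by_mwf(rep(1:3, each = 4),
                                feats[c(5:8, 9:12, 1:4), ])
  expect_identical(desc, 1:3)
  # permuting raw indices leaves the ordered labels of each voxel unchanged
  perm <- c(2L, 3L, 1L)
  relabeled <- perm[labels]
  p2 <- order_clusters_by_mwf(relabeled, feats)
  expect_identical(p2[relabeled], order_clusters_by_mwf(labels, feats)[labels])
  # MWF ties broken by descending mean uFA
  ftie <- rbind(matrix(rep(c(0.1, 0.4, 0.1), 3), ncol = 3, byrow = TRUE),
                matrix(rep(c(0.1, 0.8, 0.1), 3), ncol = 3, byrow = TRUE))
  expect_identical(order_clusters_by_mwf(rep(1:2, each = 3), ftie), c(2L, 1L))
})

test_that("model fitting is deterministic and serialises reproducibly", {
  co <- small_cohort()
  m1 <- small_model()
  m2 <- tc_fit(co$subjects, K = 6, seed = 7)
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_tc_model(m1, f1); write_tc_model(m2, f2)
  expect_identical(readLines(f1), readLines(f2))
  # reload classifies identically
  m3 <- read_tc_model(f1)
  sub <- co$subjects[[1]]
  expect_identical(classify_subject(m3, sub)$labels,
                   classify_subject(m1, sub)$labels)
})

test_that("ordered label 1 has the highest mean MWF, strictly descending", {
  m <- small_model()
  s <- summary(m)
  expect_true(all(diff(s$mwf_mean[1:5]) < 0))
  expect_equal(which.max(s$mwf_mean), 1L)
  expect_identical(sum(s$count), m$metadata$n_pool)
})

test_that("a voxel equal to a training point gets that point's label at k=1", {
  m <- small_model()
  m1 <- m; m1$knn_k <- 1L
  i <- c(10L, 500L, 2000L)
  native <- apply_scaler(m$scaler, m$train_x[i, , drop = FALSE],
                         inverse = TRUE)
  expect_identical(predict(m1, native), m$train_y[i])
})

test_that("invalid-feature voxels classify to label 0", {
  co <- small_cohort()
  sub <- co$subjects[[2]]
  idx <- which(sub$mask$values)
  sub$mwf$values[idx] <- NaN  # every masked voxel invalid
  expect_message(lab <- classify_subject(small_model(), sub), "label 0")
  expect_true(all(lab$labels == 0L))
})

test_that("classification is a pure function of model and subject", {
  co <- small_cohort()
  m <- small_model()
  l1 <- classify_subject(m, co$subjects[[3]])
  l2 <- classify_subject(m, co$subjects[[3]])
  expect_identical(l1$labels, l2$labels)
})

test_that("phantom classification is diagonally dominant per true class", {
  co <- small_cohort()
  m <- small_model()
  lab <- classify_subject(m, co$subjects[[1]])
  to <- co$truth_ordered$labels
  conf <- table(truth = to[to > 0], assigned = lab$labels[to > 0])
  for (r in seq_len(nrow(conf))) {
    diag_entry <- conf[r, colnames(conf) == rownames(conf)[r]]
    expect_true(all(diag_entry > conf[r, colnames(conf) != rownames(conf)[r]]))
  }
})

test_that("metric atlas averages voxelwise and handles sign cancellation", {
  s1 <- tiny_subject(id = "a", seed = 1)
  atlas <- build_metric_atlas(list(s1, s1, s1))
  idx <- which(s1$mask$values)
  expect_equal(atlas$mwf$values[idx], s1$mwf$values[idx])
  expect_identical(atlas$mask$values, s1$mask$values)
  # two subjects with values v and -v average to 0 (flagged out of range)
  s2 <- s1
  suppressMessages({
    s2$mwf <- metric_volume(-s1$mwf$values, "MWF")
    s2$ufa <- metric_volume(-s1$ufa$values, "uFA")
    s2$cmd <- metric_volume(-s1$cmd$values, "CMD")
    atlas2 <- build_metric_atlas(list(s1, s2))
  })
  expect_true(all(abs(atlas2$mwf$values[idx]) < 1e-15))
})

test_that("atlas classification equals single-subject labels for identical cohorts", {
  co <- small_cohort()
  m <- small_model()
  sub <- co$subjects[[1]]
  atlas <- build_metric_atlas(list(sub, sub))
  expect_identical(classify_atlas(m, atlas)$labels,
                   classify_subject(m, sub)$labels)
})

test_that("cluster summaries on a pool partition all classified voxels", {
  co <- small_cohort()
  m <- small_model()
  pool <- pool_subjects(co$subjects[1:2])
  s <- summarize_clusters(m, pool)
  expect_identical(sum(s$count), nrow(pool$features))
  expect_true(all(diff(s$mwf_mean[1:5]) < 0))
})
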