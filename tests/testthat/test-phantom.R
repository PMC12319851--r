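test_that("cohort generation is bit-reproducible from the seed", {
  spec <- phantom_spec(grid_shape = c(12, 12, 12))
  c1 <- generate_cohort(spec, 2, seed = 5)
  c2 <- generate_cohort(spec, 2, seed = 5)
  expect_identical(c1$subjects[[1]]$mwf$values, c2$subjects[[1]]$mwf$values)
  expect_identical(c1$subjects[[2]]$cmd$values, c2$subjects[[2]]$cmd$values)
  expect_identical(c1$truth$labels, c2$truth$labels)
  c3 <- generate_cohort(spec, 2, seed = 6)
  expect_false(identical(c1$subjects[[1]]$mwf$values,
                         c3$subjects[[1]]$mwf$values))
})

test_that("zero noise and zero subject effect reproduce the class means", {
  spec <- phantom_spec(grid_shape = c(12, 12, 12),
                       class_sds = matrix(0, 6, 3),
                       subject_effect_sd = c(0, 0, 0))
  co <- generate_cohort(spec, 1, seed = 1)
  sub <- co$subjects[[1]]
  idx <- which(co$truth$labels > 0)
  cls <- co$truth$labels[idx]
  expect_equal(sub$mwf$values[idx], spec$class_means[cls, 1])
  expect_equal(sub$ufa$values[idx], spec$class_means[cls, 2])
  expect_equal(sub$cmd$values[idx], spec$class_means[cls, 3])
})

test_that("every generated class region is nonempty and masked", {
  co <- small_cohort()
  counts <- tabulate(co$truth$labels[co$truth$labels > 0], 6)
  expect_true(all(counts > 0))
  sub <- co$subjects[[1]]
  expect_identical(which(sub$mask$values), which(co$truth$labels > 0))
  # physical truncation bounds hold
  idx <- which(sub$mask$values)
  expect_true(all(sub$mwf$values[idx] >= 0 & sub$mwf$values[idx] <= 1))
  expect_true(all(sub$cmd$values[idx] >= 0))
})

test_that("the expected ordered labels permute only the grey-matter classes", {
  spec <- phantom_spec()
  p <- expected_class_order(spec)
  expect_identical(sort(p), 1:6)
  expect_identical(p[1:4], 1:4)  # white matter and border keep their ids
})

test_that("lesion injection is confined, non-overlapping and seeded", {
  co <- small_cohort()
  sub <- co$subjects[[1]]
  les <- inject_lesions(sub, co$truth, co$spec, n_lesions = 3,
                        radius_vox = c(1.5, 2.5), seed = 11)
  expect_identical(les$n_placed, 3L)
  # lesion voxels only inside host classes (never CSF/background)
  expect_true(all(co$truth$labels[les$lesion_mask] %in% 1:3))
  # non-lesion voxels untouched
  keep <- sub$mask$values & !les$lesion_mask
  expect_identical(les$subject$mwf$values[keep], sub$mwf$values[keep])
  # deterministic
  les2 <- inject_lesions(sub, co$truth, co$spec, n_lesions = 3,
                         radius_vox = c(1.5, 2.5), seed = 11)
  expect_identical(les$lesion_mask, les2$lesion_mask)
  expect_identical(les$subject$mwf$values, les2$subject$mwf$values)
  # zero lesions: unchanged subject
  l0 <- inject_lesions(sub, co$truth, co$spec, n_lesions = 0)
  expect_identical(l0$subject$mwf$values, sub$mwf$values)
  expect_identical(l0$lesion_fraction, 0)
})

test_that("impossible lesion placements fail with the placed count", {
  co <- small_cohort()
  expect_error(
    inject_lesions(co$subjects[[1]], co$truth, co$spec, n_lesions = 500,
                   radius_vox = c(6, 6), seed = 1, max_tries = 5),
    "placed")
})

test_that("lesion voxels shift toward the target class distribution", {
  spec <- phantom_spec(grid_shape = c(24, 24, 24))
  co <- generate_cohort(spec, 1, seed = 2)
  les <- inject_lesions(co$subjects[[1]], co$truth, spec, n_lesions = 2,
                        radius_vox = c(2.5, 3.5), target_shift = 1, seed = 3)
  idx <- which(les$lesion_mask)
  cls <- co$truth$labels[idx]
  tgt <- pmin(cls + 1L, 5L)
  dev <- abs(les$subject$mwf$values[idx] - spec$class_means[tgt, 1])
  # values now sit near the shifted class mean, many SDs from the host mean
  expect_lt(max(dev), 5 * max(spec$class_sds[, 1]))
  expect_gt(min(abs(spec$class_means[cls, 1] - spec$class_means[tgt, 1])),
            2 * max(spec$class_sds[, 1]))
})

test_that("synthetic clinical scores encode the constructed association", {
  ids <- sprintf("s%02d", 1:25)
  burden <- seq(0, 0.02, length.out = 25)
  tab <- emit_clinical_scores(ids, burden, noise_sd = 0,
                              missing_sdmt = "s03", seed = 1)
  expect_identical(nrow(tab), 25L)
  expect_true(is.na(tab$SDMT[3]))
  ok <- !is.na(tab$SDMT)
  expect_equal(cor(burden[ok], tab$SDMT[ok], method = "spearman"), -1)
  expect_true(all(tab$EDSS >= 0 & tab$EDSS <= 10))
  tab2 <- emit_clinical_scores(ids, burden, noise_sd = 0,
                               missing_sdmt = "s03", seed = 1)
  expect_identical(tab, tab2)
})
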