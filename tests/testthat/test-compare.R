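mk_labels <- function(vec, K = 6) {
  n <- length(vec)
  label_volume(array(as.integer(vec), dim = c(n, 1, 1)), K = K)
}

test_that("normalised cluster sizes divide counts by brain voxels", {
  lab <- mk_labels(c(rep(1, 250), rep(2, 750)))
  cs <- normalized_cluster_sizes(lab)
  expect_equal(cs$normalised_size[1], 0.25)
  expect_equal(cs$normalised_size[3], 0)          # empty cluster
  expect_equal(sum(cs$normalised_size), 1)
  expect_identical(attr(cs, "total_brain_voxels"), 1000L)
  expect_error(normalized_cluster_sizes(mk_labels(rep(0, 5))), "background")
})

test_that("difference map follows the atlas white-matter semantics", {
  atlas <- mk_labels(c(1, 2, 4, 3, 2, 0, 1))
  subj  <- mk_labels(c(3, 1, 6, 3, 2, 5, 0))
  dm <- difference_map(atlas, subj, wm_labels = 1:3)
  # atlas 1 -> subject 3: difference 2
  expect_identical(dm$values[1, 1, 1], 2L)
  # atlas 2 -> subject 1 is an opposite change, zero in the map
  expect_identical(dm$values[2, 1, 1], 0L)
  expect_identical(dm$n_opposite, 1L)
  # atlas label 4 (non-WM) never enters the map, whatever the subject label
  expect_identical(dm$values[3, 1, 1], 0L)
  # unchanged voxels counted as equal
  expect_identical(dm$n_equal, 2L)
  # subject label 0 inside atlas WM is invalid, not opposite
  expect_identical(dm$n_invalid, 1L)
  # atlas label 0 contributes nothing
  expect_identical(dm$n_evaluated, 4L)
  expect_error(difference_map(atlas, mk_labels(c(1, 2))), "mismatch")
})

test_that("difference and opposite counts partition atlas-WM disagreements", {
  set.seed(21)
  K <- 6
  a <- sample(0:K, 500, replace = TRUE)
  s <- sample(0:K, 500, replace = TRUE)
  dm <- difference_map(mk_labels(a), mk_labels(s))
  n_pos <- sum(dm$values > 0)
  expect_identical(n_pos + dm$n_opposite + dm$n_equal, dm$n_evaluated)
})

test_that("opposite change fraction uses the subject brain denominator", {
  atlas <- mk_labels(c(rep(2, 100), rep(4, 900)))
  subj  <- mk_labels(c(rep(1, 100), rep(4, 900)))
  expect_equal(opposite_change_fraction(atlas, subj), 0.1)
  expect_equal(opposite_change_fraction(atlas, atlas), 0)
})

test_that("severity score implements the affine formula exactly", {
  # zero diff-1 voxels -> exactly -50
  empty <- difference_map(mk_labels(rep(1, 10)), mk_labels(rep(1, 10)))
  expect_identical(severity_score(empty, 1000)$severity_score, -50)
  # 50 diff-1 voxels in a 1000-voxel brain -> exactly 0
  d50 <- difference_map(mk_labels(rep(1, 50)), mk_labels(rep(2, 50)))
  expect_identical(severity_score(d50, 1000)$severity_score, 0)
  # 87 diff-1 voxels in a 1000-voxel brain -> 37
  d87 <- difference_map(mk_labels(rep(1, 87)), mk_labels(rep(2, 87)))
  expect_identical(severity_score(d87, 1000)$severity_score, 37)
  expect_error(severity_score(d87, 0), "positive")
})

test_that("adding one diff-1 voxel raises severity by exactly 1000/V", {
  V <- 640
  for (n1 in c(0, 3, 17)) {
    dm_a <- difference_map(mk_labels(rep(1, n1 + 5)),
                           mk_labels(c(rep(2, n1), rep(1, 5))))
    dm_b <- difference_map(mk_labels(rep(1, n1 + 5)),
                           mk_labels(c(rep(2, n1 + 1), rep(1, 4))))
    expect_equal(severity_score(dm_b, V)$severity_score -
                   severity_score(dm_a, V)$severity_score, 1000 / V)
  }
})

test_that("generalized scores keep the per-mille scale without the offset", {
  atlas <- mk_labels(c(rep(1, 30), rep(1, 10), rep(2, 960)))
  subj  <- mk_labels(c(rep(3, 30), rep(4, 10), rep(2, 960)))
  sev <- severity_score(difference_map(atlas, subj), 1000)
  expect_equal(unname(sev$generalized_scores["d2"]), 30)
  expect_equal(unname(sev$generalized_scores["d3"]), 10)
  expect_identical(sev$severity_score, -50)
})

test_that("comparing a subject against its own classification scores -50", {
  co <- small_cohort()
  m <- small_model()
  sub <- co$subjects[[4]]
  own <- classify_subject(m, sub)
  cmp <- compare_subject(m, own, sub)
  expect_identical(cmp$severity$severity_score, -50)
  expect_true(all(cmp$diff$values == 0L))
  expect_equal(cmp$severity$opposite_fraction, 0)
  row <- comparison_row(cmp)
  expect_identical(nrow(row), 1L)
  expect_equal(sum(row[paste0("size_", 1:6)]), 1)
})
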