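# Shared fixtures. Expensive cohort-scale objects are built once per test run
# and memoised so several test files can reuse them.

.qc_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .qc_cache)) {
    assign(name, force(expr), envir = .qc_cache)
  }
  get(name, envir = .qc_cache)
}

# tiny deterministic subject built directly from arrays
tiny_subject <- function(shape = c(8, 8, 8), id = "tiny", value = 0.1,
                         seed = 42) {
  set.seed(seed)
  mk <- function(base, name) {
    v <- array(base + stats::runif(prod(shape), 0, 0.01), dim = shape)
    metric_volume(v, name)
  }
  mask <- array(FALSE, dim = shape)
  mask[3:6, 3:6, 3:6] <- TRUE
  subject_dataset(id, mk(value, "MWF"), mk(0.5, "uFA"), mk(0.2, "CMD"),
                  brain_mask(mask))
}

# small phantom cohort for unit tests (fast: ~5k brain voxels)
small_cohort <- function(n = 5, seed = 7) {
  cached(sprintf("small_cohort_%d_%d", n, seed), {
    generate_cohort(phantom_spec(grid_shape = c(24, 24, 24)), n, seed = seed)
  })
}

small_model <- function() {
  cached("small_model", {
    co <- small_cohort()
    tc_fit(co$subjects, K = 6, seed = 7)
  })
}

# cohort-scale fixtures for the acceptance suite
ph48_spec <- function() phantom_spec(grid_shape = c(48, 48, 48))

ph48_cohort <- function() {
  cached("ph48_cohort", generate_cohort(ph48_spec(), 25, seed = 101))
}

ph48_model <- function() {
  cached("ph48_model", tc_fit(ph48_cohort()$subjects, K = 6, seed = 101))
}

ph48_holdout <- function() {
  cached("ph48_holdout",
         generate_cohort(ph48_spec(), 1, seed = 202,
                         id_prefix = "holdout")$subjects[[1]])
}

ph32_spec <- function() phantom_spec(grid_shape = c(32, 32, 32))

ph32_cohort <- function() {
  cached("ph32_cohort", generate_cohort(ph32_spec(), 25, seed = 303))
}

ph32_model <- function() {
  cached("ph32_model",
         tc_fit(ph32_cohort()$subjects, K = 6, seed = 303, knn_cap = 3e3))
}

ph32_atlas_labels <- function() {
  cached("ph32_atlas_labels", {
    atlas <- build_metric_atlas(ph32_cohort()$subjects)
    classify_atlas(ph32_model(), atlas)
  })
}
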