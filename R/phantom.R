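#' Phantom cohort specification
#'
#' Describes a synthetic brain phantom whose voxels are drawn from K
#' per-tissue-class Gaussian distributions over (MWF, uFA, CMD), arranged in
#' spatially contiguous regions: concentric ellipsoidal shells from deep
#' white matter (class 1, innermost) out to cortical grey matter, with two
#' embedded deep-grey blobs for the iron-like class K, and background/CSF
#' outside the brain ellipsoid.
#'
#' The default class parameters follow the qualitative signatures of the six
#' healthy tissue classes: class 1 high myelin / high anisotropy / low
#' heterogeneity, descending MWF through classes 2-5 (cortical grey matter:
#' low myelin, low anisotropy, high heterogeneity), and an iron-like class 6
#' whose apparently high MWF breaks the monotone ordering by design, with
#' low anisotropy and high heterogeneity. Between-subject offsets are larger
#' for MWF than for uFA and CMD, mirroring the observation that the
#' diffusion-derived maps vary less across individuals.
#'
#' @param grid_shape integer length-3 (default `c(48, 48, 48)`, roughly 40%
#'   brain coverage).
#' @param K_classes number of tissue classes (default 6; the last is the
#'   iron-like class).
#' @param class_means K x 3 matrix of native-unit class means (MWF, uFA,
#'   CMD).
#' @param class_sds K x 3 matrix of within-class voxel noise SDs.
#' @param subject_effect_sd length-3 per-metric SD of subject-level offsets.
#' @param shell_radii increasing normalised ellipsoidal radii; with an iron
#'   class they bound classes 1..K-1 (length K-1), otherwise classes 1..K
#'   (length K). The last must be 1, the brain boundary.
#' @param iron_class if `TRUE` (default), class K is the iron-like deep-grey
#'   class realised as embedded blobs rather than a shell.
#' @param blob_radius_frac iron-blob radius as a fraction of the smallest
#'   brain semi-axis.
#' @param smoothing_fwhm_vox optional Gaussian smoothing FWHM in voxels
#'   (0 = off; smoothing correlates neighbours and blurs class boundaries,
#'   emulating partial volume).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48),
                         K_classes = 6L,
                         class_means = NULL,
                         class_sds = NULL,
                         subject_effect_sd = c(MWF = 0.005, uFA = 0.004,
                                               CMD = 0.003),
                         shell_radii = NULL,
                         blob_radius_frac = 0.27,
                         smoothing_fwhm_vox = 0,
                         iron_class = K_classes >= 6L) {
  K_classes <- as.integer(K_classes)
  n_shells <- if (iron_class) K_classes - 1L else K_classes
  if (is.null(shell_radii)) {
    if (iron_class && K_classes == 6L) {
      shell_radii <- c(0.55, 0.72, 0.84, 0.93, 1.00)
    } else {
      # equal-volume shells
      shell_radii <- (seq_len(n_shells) / n_shells)^(1 / 3)
      shell_radii[n_shells] <- 1
    }
  }
  if (is.null(class_means)) {
    class_means <- matrix(c(
      0.15, 0.90, 0.05,   # 1 deep WM: high myelin, high anisotropy, low heterogeneity
      0.12, 0.80, 0.12,   # 2 deep WM, mixed fibre sizes
      0.09, 0.70, 0.08,   # 3 sub-cortical WM: thinner myelin, uniform packing
      0.06, 0.55, 0.20,   # 4 sub-cortical GM/WM border
      0.03, 0.40, 0.30,   # 5 cortical GM
      0.05, 0.32, 0.38),  # 6 iron-rich deep GM (apparent MWF above its GM company)
      ncol = 3L, byrow = TRUE,
      dimnames = list(NULL, c("MWF", "uFA", "CMD")))
    class_means <- class_means[seq_len(K_classes), , drop = FALSE]
  }
  if (is.null(class_sds))
    class_sds <- matrix(rep(c(0.010, 0.020, 0.015), each = K_classes),
                        ncol = 3L,
                        dimnames = list(NULL, c("MWF", "uFA", "CMD")))
  stopifnot(nrow(class_means) == K_classes, nrow(class_sds) == K_classes,
            length(shell_radii) == n_shells)
  n_tissue <- if (iron_class) K_classes - 1L else K_classes
  if (any(diff(class_means[seq_len(n_tissue), 1L]) >= 0))
    stop("class MWF means must strictly descend over the shell classes")
  structure(list(grid_shape = as.integer(grid_shape),
                 K_classes = K_classes,
                 class_means = class_means, class_sds = class_sds,
                 subject_effect_sd = subject_effect_sd,
                 shell_radii = shell_radii,
                 blob_radius_frac = blob_radius_frac,
                 smoothing_fwhm_vox = smoothing_fwhm_vox,
                 iron_class = iron_class),
            class = "phantom_spec")
}

phantom_geometry <- function(spec) {
  shp <- spec$grid_shape
  ctr <- (shp + 1) / 2
  semi <- 0.45 * shp
  ax <- (seq_len(shp[1]) - ctr[1]) / semi[1]
  ay <- (seq_len(shp[2]) - ctr[2]) / semi[2]
  az <- (seq_len(shp[3]) - ctr[3]) / semi[3]
  rho <- sqrt(outer(outer(ax^2, ay^2, `+`), az^2, `+`))
  truth <- array(0L, dim = shp)
  bounds <- c(0, spec$shell_radii)
  n_shells <- length(spec$shell_radii)
  for (k in seq_len(n_shells))
    truth[rho >= bounds[k] & rho < bounds[k + 1L]] <- k
  if (isTRUE(spec$iron_class)) {
    # iron-like blobs embedded in the deep-WM shells
    rb <- spec$blob_radius_frac * min(semi)
    for (sgn in c(-1, 1)) {
      cx <- ctr[1] + sgn * 0.26 * semi[1]
      dx2 <- outer(outer((seq_len(shp[1]) - cx)^2,
                         (seq_len(shp[2]) - ctr[2])^2, `+`),
                   (seq_len(shp[3]) - ctr[3])^2, `+`)
      truth[dx2 <= rb^2 & truth > 0L] <- spec$K_classes
    }
  }
  counts <- tabulate(truth[truth > 0L], spec$K_classes)
  if (any(counts == 0L))
    stop("degenerate geometry: empty class region(s) ",
         paste(which(counts == 0L), collapse = ", "))
  truth
}

truncate_metrics <- function(feat) {
  feat[, 1L] <- pmin(pmax(feat[, 1L], 0), 1)  # MWF
  feat[, 2L] <- pmin(pmax(feat[, 2L], 0), 1)  # uFA
  feat[, 3L] <- pmax(feat[, 3L], 0)           # CMD
  feat
}

gaussian_smooth_3d <- function(arr, fwhm) {
  sigma <- fwhm / 2.354820045
  r <- max(1L, ceiling(3 * sigma))
  kern <- stats::dnorm(-r:r, sd = sigma)
  kern <- kern / sum(kern)
  for (ax in 1:3) {
    arr <- apply(arr, setdiff(1:3, ax), function(v) {
      as.numeric(stats::filter(c(rev(v[seq_len(r)]), v,
                                 rev(v[length(v) - seq_len(r) + 1L])),
                               kern, sides = 2L))[r + seq_along(v)]
    })
    arr <- aperm(array(arr, dim = dim(arr)), order(c(ax, setdiff(1:3, ax))))
  }
  arr
}

draw_subject_metrics <- function(spec, truth, subject_offset) {
  shp <- spec$grid_shape
  idx <- which(truth > 0L)
  cls <- truth[idx]
  vols <- list()
  for (j in 1:3) {
    vals <- array(NA_real_, dim = shp)
    vals[idx] <- spec$class_means[cls, j] + subject_offset[j] +
      stats::rnorm(length(idx), 0, spec$class_sds[cls, j])
    vols[[j]] <- vals
  }
  feat <- cbind(vols[[1]][idx], vols[[2]][idx], vols[[3]][idx])
  feat <- truncate_metrics(feat)
  for (j in 1:3) vols[[j]][idx] <- feat[, j]
  if (spec$smoothing_fwhm_vox > 0)
    for (j in 1:3) {
      sm <- vols[[j]]; sm[is.na(sm)] <- spec$class_means[spec$K_classes, j]
      sm <- gaussian_smooth_3d(sm, spec$smoothing_fwhm_vox)
      sm[-idx] <- NA_real_
      vols[[j]] <- array(sm, dim = shp)
    }
  vols
}

#' Generate a synthetic phantom cohort
#'
#' Draws `n_subjects` co-registered phantoms from a [phantom_spec]: the
#' ground-truth class layout is fixed by the geometry and shared across the
#' cohort, each subject gets per-metric Gaussian offsets
#' (inter-subject variability), and each voxel adds class-specific Gaussian
#' noise, truncated at the physical bounds (\[0, 1\] for MWF/uFA, \[0, Inf)
#' for CMD). Fully reproducible from `seed`.
#'
#' Because tissue classes are reported in mean-MWF order while the iron-like
#' generated class K may break that order by design, the return value also
#' carries `expected_order` — the permutation mapping generated class ids to
#' the ordered labels a correctly fitted model assigns — and
#' `truth_ordered`, the ground truth already expressed in ordered labels.
#' With the default parameters the iron class sits between the grey-matter
#' classes (ordered label 5), so white matter keeps ordered labels 1-3.
#'
#' @param spec a [phantom_spec].
#' @param n_subjects cohort size.
#' @param seed integer seed.
#' @param group cohort label for all subjects (default `"HC"`).
#' @param id_prefix subject-id prefix.
#' @return List with `subjects` (list of [subject_dataset]), `truth` (the
#'   shared ground-truth [label_volume] in generated class ids),
#'   `truth_ordered` ([label_volume] in expected ordered labels),
#'   `expected_order` (integer permutation) and `spec`.
#' @export
generate_cohort <- function(spec, n_subjects, seed = 1L, group = "HC",
                            id_prefix = "phantom") {
  stopifnot(inherits(spec, "phantom_spec"), n_subjects >= 1L)
  truth <- phantom_geometry(spec)
  mask <- brain_mask(truth > 0L)
  set.seed(as.integer(seed))
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    offset <- stats::rnorm(3L, 0, spec$subject_effect_sd)
    vols <- draw_subject_metrics(spec, truth, offset)
    id <- sprintf("%s%02d", id_prefix, s)
    subjects[[s]] <- subject_dataset(
      id,
      metric_volume(vols[[1]], "MWF"),
      metric_volume(vols[[2]], "uFA"),
      metric_volume(vols[[3]], "CMD"),
      mask, group = group)
  }
  p <- expected_class_order(spec)
  list(subjects = subjects,
       truth = label_volume(truth, K = spec$K_classes),
       truth_ordered = label_volume(array(c(0L, p)[truth + 1L],
                                          dim = spec$grid_shape),
                                    K = spec$K_classes),
       expected_order = p,
       spec = spec)
}

#' Expected ordered labels of the generated classes
#'
#' The permutation `p` with `p[class] = ordered label` obtained by ranking
#' the generating class means exactly as [order_clusters_by_mwf()] ranks
#' fitted clusters (descending mean MWF, ties by descending uFA): what a
#' correctly recovered model will call each generated class.
#'
#' @param spec a [phantom_spec].
#' @return Integer permutation of `1:K_classes`.
#' @export
expected_class_order <- function(spec) {
  ranked <- order(-spec$class_means[, 1L], -spec$class_means[, 2L],
                  seq_len(spec$K_classes))
  p <- integer(spec$K_classes)
  p[ranked] <- seq_len(spec$K_classes)
  p
}

#' Inject MS-like lesions into a phantom subject
#'
#' Places `n_lesions` non-overlapping spheres entirely inside the host
#' tissue classes and redraws the metric values of lesion voxels from the
#' distribution of class `c + target_shift` (`c` = the voxel's true class,
#' capped at the highest non-iron class), emulating focal demyelination and
#' axonal damage. Deterministic given `seed`.
#'
#' @param subject a [subject_dataset] from [generate_cohort()].
#' @param truth the cohort's ground-truth [label_volume].
#' @param spec the [phantom_spec] used to generate the cohort.
#' @param n_lesions number of lesions.
#' @param radius_vox numeric length-2 range of lesion radii in voxels.
#' @param target_shift class shift d >= 1 of lesion tissue.
#' @param host_classes classes a lesion may occupy (default `1:3`).
#' @param seed integer seed.
#' @param max_tries placement attempts per lesion before giving up.
#' @return List with `subject` (modified copy), `lesion_mask` (logical 3-D
#'   array), `n_placed` and `lesion_fraction` (lesion voxels / brain
#'   voxels).
#' @export
inject_lesions <- function(subject, truth, spec, n_lesions,
                           radius_vox = c(2, 4), target_shift = 1L,
                           host_classes = 1:3, seed = 1L,
                           max_tries = 200L) {
  stopifnot(inherits(subject, "subject_dataset"),
            inherits(truth, "label_volume"), target_shift >= 1L)
  shp <- subject$grid_shape
  lesion_mask <- array(FALSE, dim = shp)
  if (n_lesions == 0L)
    return(list(subject = subject, lesion_mask = lesion_mask, n_placed = 0L,
                lesion_fraction = 0))
  host <- array(truth$labels %in% host_classes, dim = shp)
  host_idx <- which(host)
  if (length(host_idx) == 0L) stop("no host-class voxels available")
  host_ijk <- arrayInd(host_idx, shp)
  set.seed(as.integer(seed))
  placed <- 0L
  for (l in seq_len(n_lesions)) {
    done <- FALSE
    for (try in seq_len(max_tries)) {
      r <- stats::runif(1, radius_vox[1], radius_vox[2])
      ctr <- host_ijk[sample.int(nrow(host_ijk), 1L), ]
      rr <- ceiling(r)
      ranges <- lapply(1:3, function(a)
        max(1L, ctr[a] - rr):min(shp[a], ctr[a] + rr))
      cand <- as.matrix(expand.grid(ranges))
      d2 <- rowSums(sweep(cand, 2L, ctr)^2)
      cand <- cand[d2 <= r^2, , drop = FALSE]
      cidx <- cand[, 1L] + (cand[, 2L] - 1L) * shp[1] +
        (cand[, 3L] - 1L) * shp[1] * shp[2]
      if (all(host[cidx]) && !any(lesion_mask[cidx])) {
        lesion_mask[cidx] <- TRUE
        done <- TRUE
        break
      }
    }
    if (!done)
      stop("could not place ", n_lesions, " non-overlapping lesions (placed ",
           placed, ")")
    placed <- placed + 1L
  }
  les_idx <- which(lesion_mask)
  cls <- truth$labels[les_idx]
  tgt <- pmin(cls + as.integer(target_shift), spec$K_classes - 1L)
  feat <- cbind(
    spec$class_means[tgt, 1L] + stats::rnorm(length(tgt), 0, spec$class_sds[tgt, 1L]),
    spec$class_means[tgt, 2L] + stats::rnorm(length(tgt), 0, spec$class_sds[tgt, 2L]),
    spec$class_means[tgt, 3L] + stats::rnorm(length(tgt), 0, spec$class_sds[tgt, 3L]))
  feat <- truncate_metrics(feat)
  mwf <- subject$mwf$values; mwf[les_idx] <- feat[, 1L]
  ufa <- subject$ufa$values; ufa[les_idx] <- feat[, 2L]
  cmd <- subject$cmd$values; cmd[les_idx] <- feat[, 3L]
  mod <- subject_dataset(subject$subject_id,
                         metric_volume(mwf, "MWF", subject$mwf$voxel_size_mm,
                                       subject$mwf$affine),
                         metric_volume(ufa, "uFA", subject$ufa$voxel_size_mm,
                                       subject$ufa$affine),
                         metric_volume(cmd, "CMD", subject$cmd$voxel_size_mm,
                                       subject$cmd$affine),
                         subject$mask, group = subject$group)
  list(subject = mod, lesion_mask = lesion_mask, n_placed = placed,
       lesion_fraction = length(les_idx) / sum(subject$mask$values))
}

#' Synthetic clinical scores tied to lesion burden
#'
#' Emits an SDMT/EDSS table with a constructed monotone association:
#' `SDMT = sdmt_baseline - sdmt_slope * burden + noise` (cognition falls
#' with damage) and `EDSS = edss_baseline + edss_slope * burden + noise`,
#' clamped to \[0, 10\]. With zero noise the severity-SDMT rank correlation
#' over a burden-monotone cohort is exactly -1. Missing scores can be
#' injected to exercise downstream exclusion rules.
#'
#' @param subject_ids character vector.
#' @param burden per-subject lesion volume fraction (same length).
#' @param group per-subject group labels (recycled).
#' @param sdmt_baseline,sdmt_slope,edss_baseline,edss_slope linear-model
#'   constants.
#' @param noise_sd Gaussian noise SD added to both scores.
#' @param missing_sdmt subject ids whose SDMT is set missing.
#' @param seed integer seed.
#' @return Data frame `subject_id, group, EDSS, SDMT`.
#' @export
emit_clinical_scores <- function(subject_ids, burden, group = "RRMS",
                                 sdmt_baseline = 70, sdmt_slope = 600,
                                 edss_baseline = 1.5, edss_slope = 150,
                                 noise_sd = 0, missing_sdmt = character(0),
                                 seed = 1L) {
  n <- length(subject_ids)
  stopifnot(length(burden) == n)
  set.seed(as.integer(seed))
  sdmt <- sdmt_baseline - sdmt_slope * burden + stats::rnorm(n, 0, noise_sd)
  edss <- pmin(pmax(edss_baseline + edss_slope * burden +
                      stats::rnorm(n, 0, noise_sd), 0), 10)
  sdmt[subject_ids %in% missing_sdmt] <- NA_real_
  data.frame(subject_id = subject_ids, group = rep_len(group, n),
             EDSS = edss, SDMT = sdmt)
}
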