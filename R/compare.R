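#' Normalised cluster sizes
#'
#' Per ordered cluster, the voxel count divided by the total number of
#' voxels in the subject's brain. "Brain" means the nonzero-labelled
#' (CSF-excluded) voxels by default, consistent with CSF being masked out
#' before clustering; pass `total_voxels` explicitly to use a different
#' denominator (e.g. a mask count that retains CSF).
#'
#' @param labels a [label_volume] with at least one nonzero voxel.
#' @param total_voxels optional positive denominator overriding the default
#'   nonzero-label count.
#' @return An object of class `cluster_sizes`: data frame with `cluster`,
#'   `count`, `normalised_size`, plus attribute `total_brain_voxels`.
#'   With the default denominator, normalised sizes over clusters 1..K sum
#'   to 1.
#' @export
normalized_cluster_sizes <- function(labels, total_voxels = NULL) {
  if (!inherits(labels, "label_volume")) stop("'labels' must be a label_volume")
  lab <- labels$labels
  counts <- tabulate(lab[lab > 0L], nbins = labels$K)
  total <- sum(counts)
  if (total == 0L) stop("all-background label volume")
  denom <- if (is.null(total_voxels)) total else as.numeric(total_voxels)
  if (denom <= 0) stop("total_voxels must be positive")
  out <- data.frame(cluster = seq_len(labels$K), count = counts,
                    normalised_size = counts / denom)
  attr(out, "total_brain_voxels") <- denom
  class(out) <- c("cluster_sizes", "data.frame")
  out
}

#' White-matter difference map
#'
#' Voxelwise comparison of a subject's tissue classification against the
#' atlas classification, restricted to the atlas labels regarded as white
#' matter (clusters 1-3 by default). At voxels where the atlas label is in
#' `wm_labels` and both labels are nonzero, the map holds
#' `subject - atlas` when positive — a shift toward lower-myelin classes —
#' and 0 otherwise. Shifts in the opposite direction (subject < atlas,
#' i.e. apparently more myelinated than the healthy average) are excluded
#' from the map and tallied separately; see [opposite_change_fraction()].
#' Subject label 0 inside atlas white matter (invalid features) is excluded
#' from both tallies and counted in `n_invalid`.
#'
#' @param atlas_labels [label_volume] of the atlas classification, already
#'   on the subject's grid.
#' @param subject_labels [label_volume] of the subject.
#' @param wm_labels atlas labels treated as white matter (default `1:3`).
#' @return An object of class `difference_map`: list with `values` (3-D
#'   integer array, entries in 0..K-1), `wm_labels`, `n_evaluated` (atlas-WM
#'   voxels inside the subject's labelled brain), `n_opposite`, `n_equal`,
#'   `n_invalid` and `K`.
#' @export
difference_map <- function(atlas_labels, subject_labels, wm_labels = 1:3) {
  if (!inherits(atlas_labels, "label_volume") ||
      !inherits(subject_labels, "label_volume"))
    stop("both inputs must be label_volume objects")
  if (!identical(atlas_labels$grid_shape, subject_labels$grid_shape))
    stop("grid mismatch between atlas and subject label volumes")
  a <- atlas_labels$labels
  s <- subject_labels$labels
  wm <- (a %in% wm_labels) & a > 0L
  dim(wm) <- dim(a)
  vals <- array(0L, dim = dim(a))
  eval_mask <- wm & s > 0L
  d <- s[eval_mask] - a[eval_mask]
  v <- integer(length(d))
  v[d > 0L] <- d[d > 0L]
  vals[eval_mask] <- v
  structure(list(values = vals,
                 wm_labels = as.integer(wm_labels),
                 n_evaluated = sum(eval_mask),
                 n_opposite = sum(d < 0L),
                 n_equal = sum(d == 0L),
                 n_invalid = sum(wm & s == 0L),
                 K = subject_labels$K),
            class = "difference_map")
}

#' @export
print.difference_map <- function(x, ...) {
  tab <- tabulate(x$values[x$values > 0L], nbins = x$K - 1L)
  cat("White-matter difference map (atlas WM labels ",
      paste(x$wm_labels, collapse = ","), "):\n", sep = "")
  cat(" ", x$n_evaluated, "evaluated voxels;", x$n_equal, "unchanged;",
      x$n_opposite, "opposite-direction;", x$n_invalid, "invalid\n")
  for (d in seq_along(tab)) if (tab[d] > 0L)
    cat("  difference", d, ":", tab[d], "voxels\n")
  invisible(x)
}

#' Opposite cluster-number change fraction
#'
#' Fraction of the subject's brain voxels at which an atlas white-matter
#' voxel is classified as a lower (more-myelinated) cluster in the subject —
#' changes that would imply higher myelin content than the healthy average.
#' Denominator: total nonzero-labelled voxels in the subject's brain.
#'
#' @inheritParams difference_map
#' @return Numeric scalar in \[0, 1\].
#' @export
opposite_change_fraction <- function(atlas_labels, subject_labels,
                                     wm_labels = 1:3) {
  dm <- difference_map(atlas_labels, subject_labels, wm_labels)
  total <- sum(subject_labels$labels > 0L)
  if (total == 0L) stop("subject has no labelled brain voxels")
  dm$n_opposite / total
}

#' Severity score from a difference map
#'
#' The diffuse white-matter damage summary
#' \deqn{S = \frac{\#\{\mathrm{diff} = 1\}}{\mathrm{total\ brain\ voxels}}
#' \times 1000 - 50,}
#' an affine, strictly increasing function of the count of voxels one
#' cluster further from myelination than the atlas; a subject identical to
#' the atlas scores exactly -50. Scores for larger cluster differences
#' (d >= 2) are reported on the same per-mille scale but without the -50
#' offset, which is defined only for the d = 1 score.
#'
#' @param diff a `difference_map`.
#' @param total_brain_voxels positive integer; the subject's CSF-excluded
#'   brain voxel count.
#' @return An object of class `severity_result`: list with `severity_score`,
#'   `generalized_scores` (named numeric, levels `d2`, `d3`, ...),
#'   `opposite_fraction`, `diff_counts` and `total_brain_voxels`.
#' @export
severity_score <- function(diff, total_brain_voxels) {
  if (!inherits(diff, "difference_map")) stop("'diff' must be a difference_map")
  total_brain_voxels <- as.numeric(total_brain_voxels)
  if (length(total_brain_voxels) != 1L || total_brain_voxels <= 0)
    stop("total_brain_voxels must be a positive scalar")
  counts <- tabulate(diff$values[diff$values > 0L], nbins = max(diff$K - 1L, 1L))
  s <- counts[1L] / total_brain_voxels * 1000 - 50
  gen <- if (diff$K > 2L) {
    g <- counts[-1L] / total_brain_voxels * 1000
    stats::setNames(g, paste0("d", seq_along(g) + 1L))
  } else stats::setNames(numeric(0), character(0))
  structure(list(severity_score = s,
                 generalized_scores = gen,
                 opposite_fraction = diff$n_opposite / total_brain_voxels,
                 diff_counts = stats::setNames(counts,
                                               paste0("d", seq_along(counts))),
                 total_brain_voxels = total_brain_voxels),
            class = "severity_result")
}

#' @export
print.severity_result <- function(x, ...) {
  cat("Severity score:", format(x$severity_score, digits = 5), "\n")
  if (length(x$generalized_scores))
    cat("  higher-difference scores:",
        paste(names(x$generalized_scores),
              format(x$generalized_scores, digits = 4), sep = "=",
              collapse = ", "), "\n")
  cat("  opposite-change fraction:",
      format(x$opposite_fraction, digits = 4), "\n")
  invisible(x)
}

#' Compare a subject against the atlas classification
#'
#' End-to-end individual evaluation: classify the subject with the model,
#' build the white-matter difference map against the atlas classification,
#' and derive severity scores, the opposite-change fraction and normalised
#' cluster sizes.
#'
#' @param model a `tc_model`.
#' @param atlas_labels [label_volume] of the atlas classification on the
#'   subject's grid.
#' @param subject a [subject_dataset].
#' @param wm_labels atlas labels treated as white matter.
#' @return An object of class `subject_comparison`: list with `subject_id`,
#'   `group`, `labels` ([label_volume]), `diff` (`difference_map`),
#'   `severity` (`severity_result`) and `cluster_sizes`.
#' @export
compare_subject <- function(model, atlas_labels, subject, wm_labels = 1:3) {
  labels <- classify_subject(model, subject)
  sizes <- normalized_cluster_sizes(labels)
  dm <- difference_map(atlas_labels, labels, wm_labels)
  sev <- severity_score(dm, attr(sizes, "total_brain_voxels"))
  structure(list(subject_id = subject$subject_id, group = subject$group,
                 labels = labels, diff = dm, severity = sev,
                 cluster_sizes = sizes),
            class = "subject_comparison")
}

#' @export
print.subject_comparison <- function(x, ...) {
  cat("Subject", x$subject_id, sprintf("(%s)", x$group),
      "vs atlas classification\n")
  print(x$severity)
  invisible(x)
}

#' One-row summary of a subject comparison
#'
#' Flattens a `subject_comparison` into the per-subject CSV row layout:
#' severity, higher-difference scores, opposite fraction and normalised
#' cluster sizes.
#'
#' @param comparison a `subject_comparison`.
#' @return A one-row data frame.
#' @export
comparison_row <- function(comparison) {
  sev <- comparison$severity
  sizes <- comparison$cluster_sizes
  row <- data.frame(subject_id = comparison$subject_id,
                    group = comparison$group,
                    severity = sev$severity_score,
                    opposite_fraction = sev$opposite_fraction)
  for (nm in names(sev$generalized_scores))
    row[[paste0("score_", nm)]] <- sev$generalized_scores[[nm]]
  for (k in sizes$cluster)
    row[[paste0("size_", k)]] <- sizes$normalised_size[k]
  row
}
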