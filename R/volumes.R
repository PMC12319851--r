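#' Metric volume
#'
#' Container for one 3-D quantitative MRI map on a voxel grid. Three metrics
#' are understood by the pipeline: myelin water fraction (`"MWF"`, a myelin
#' proxy in \[0, 1\]), microscopic fractional anisotropy (`"uFA"`, an axonal
#' integrity proxy in \[0, 1\]) and the normalised variance of sub-voxel mean
#' diffusivities (`"CMD"`, a tissue heterogeneity proxy, non-negative).
#'
#' Values outside the physical range of a metric are flagged with a message
#' and kept as-is: clipping would silently distort downstream cluster
#' statistics. Non-finite values are permitted here; they are treated as
#' invalid voxels when pooling or classifying.
#'
#' @param values numeric 3-D array.
#' @param name one of `"MWF"`, `"uFA"`, `"CMD"`.
#' @param voxel_size_mm numeric length-3, voxel edge lengths in mm.
#' @param affine 4x4 numeric grid-to-world transform. Voxel indexing is
#'   0-based (i, j, k) array order; world coordinates come only from the
#'   affine, so no orientation-dependent logic exists downstream.
#' @return An object of class `metric_volume`.
#' @export
metric_volume <- function(values, name = c("MWF", "uFA", "CMD"),
                          voxel_size_mm = c(1, 1, 1), affine = diag(4)) {
  name <- match.arg(name)
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array, got dimensionality ",
         length(dim(values)))
  storage.mode(values) <- "double"
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be 4x4")
  v <- structure(list(
    name = name,
    values = values,
    grid_shape = dim(values),
    voxel_size_mm = as.numeric(voxel_size_mm),
    affine = affine
  ), class = "metric_volume")
  n_bad <- count_out_of_range(v)
  if (n_bad > 0L)
    message(sprintf("%s volume: %d finite value(s) outside the physical range (kept, not clipped)",
                    name, n_bad))
  v
}

count_out_of_range <- function(vol) {
  x <- vol$values[is.finite(vol$values)]
  if (vol$name == "CMD") sum(x < 0) else sum(x < 0 | x > 1)
}

#' Brain mask
#'
#' Boolean voxel grid marking brain tissue (CSF excluded) for one subject.
#'
#' @param values logical 3-D array; must contain at least one `TRUE` voxel.
#' @return An object of class `brain_mask`.
#' @export
brain_mask <- function(values) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("mask must be a 3-D array")
  values <- array(as.logical(values), dim = dim(values))
  if (!any(values, na.rm = TRUE)) stop("degenerate mask: no TRUE voxels")
  values[is.na(values)] <- FALSE
  structure(list(values = values, grid_shape = dim(values)),
            class = "brain_mask")
}

#' Label volume
#'
#' Integer voxel grid of ordered tissue-class labels 1..K; 0 marks
#' background/CSF and is not a tissue class.
#'
#' @param labels integer 3-D array with values in `0:K`.
#' @param K number of tissue classes.
#' @return An object of class `label_volume`.
#' @export
label_volume <- function(labels, K) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("labels must be a 3-D array")
  storage.mode(labels) <- "integer"
  K <- as.integer(K)
  rng <- range(labels)
  if (rng[1] < 0L || rng[2] > K)
    stop("labels must lie in 0..K = 0..", K, " (found range ",
         rng[1], "..", rng[2], ")")
  structure(list(labels = labels, K = K, grid_shape = dim(labels)),
            class = "label_volume")
}

#' Subject dataset
#'
#' The three co-registered metric volumes plus a CSF-excluded brain mask for
#' one subject, all on a single grid. No registration is performed here:
#' grids and affines must already agree.
#'
#' @param subject_id character scalar.
#' @param mwf,ufa,cmd [metric_volume] objects named `"MWF"`, `"uFA"`, `"CMD"`.
#' @param mask a [brain_mask] on the same grid.
#' @param group cohort label, one of `"HC"`, `"RRMS"`, `"ProgMS"`, `"other"`.
#' @return An object of class `subject_dataset`.
#' @export
subject_dataset <- function(subject_id, mwf, ufa, cmd, mask,
                            group = c("HC", "RRMS", "ProgMS", "other")) {
  group <- match.arg(group)
  vols <- list(mwf = mwf, ufa = ufa, cmd = cmd)
  expect_names <- c(mwf = "MWF", ufa = "uFA", cmd = "CMD")
  for (nm in names(vols)) {
    v <- vols[[nm]]
    if (!inherits(v, "metric_volume"))
      stop("'", nm, "' must be a metric_volume")
    if (v$name != expect_names[[nm]])
      stop("'", nm, "' must carry metric name ", expect_names[[nm]])
  }
  if (!inherits(mask, "brain_mask")) stop("'mask' must be a brain_mask")
  ref <- mwf$grid_shape
  for (nm in c("ufa", "cmd")) {
    v <- vols[[nm]]
    if (!identical(v$grid_shape, ref))
      stop("grid congruence error: volume '", nm, "' has shape ",
           paste(v$grid_shape, collapse = "x"), " but MWF has ",
           paste(ref, collapse = "x"))
    if (max(abs(v$affine - mwf$affine)) > 1e-4)
      stop("grid congruence error: affine of '", nm,
           "' differs from the MWF affine")
  }
  if (!identical(mask$grid_shape, ref))
    stop("grid congruence error: mask has shape ",
         paste(mask$grid_shape, collapse = "x"), " but metrics have ",
         paste(ref, collapse = "x"))
  structure(list(subject_id = as.character(subject_id),
                 mwf = mwf, ufa = ufa, cmd = cmd, mask = mask,
                 group = group, grid_shape = ref),
            class = "subject_dataset")
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("Subject", x$subject_id, sprintf("(%s)", x$group), "-",
      paste(x$grid_shape, collapse = "x"), "grid,",
      sum(x$mask$values), "brain voxels\n")
  invisible(x)
}

#' Extract masked voxel values
#'
#' Returns the metric values at the mask's `TRUE` voxels together with their
#' linear voxel indices, in deterministic column-major scan order. The index
#' mapping is invertible: [scatter_back()] reconstructs the masked region
#' exactly.
#'
#' @param volume a [metric_volume].
#' @param mask a [brain_mask] on the same grid.
#' @return A list with `values` (numeric vector) and `index` (integer vector
#'   of 1-based linear grid indices).
#' @seealso [scatter_back()]
#' @export
apply_mask <- function(volume, mask) {
  if (!identical(volume$grid_shape, mask$grid_shape))
    stop("grid congruence error: volume and mask shapes differ")
  idx <- which(mask$values)
  if (length(idx) == 0L) stop("degenerate mask: no TRUE voxels")
  list(values = volume$values[idx], index = idx)
}

#' Scatter masked values back onto a grid
#'
#' Inverse of [apply_mask()]: places `values` at linear indices `index` on a
#' grid of shape `grid_shape`, `fill` elsewhere.
#'
#' @param values numeric vector.
#' @param index 1-based linear indices, same length as `values`.
#' @param grid_shape integer length-3.
#' @param fill value for unindexed voxels (default 0).
#' @return A 3-D array.
#' @export
scatter_back <- function(values, index, grid_shape, fill = 0) {
  out <- array(fill, dim = grid_shape)
  out[index] <- values
  out
}

## ---- NIfTI I/O -------------------------------------------------------------

read_nifti_array <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 4L && d[4] == 1L) {
    img2 <- array(as.numeric(img), dim = d[1:3])
    attr(img2, "affine") <- RNifti::xform(img)
    attr(img2, "pixdim") <- RNifti::pixdim(img)[1:3]
    return(img2)
  }
  if (length(d) != 3L) stop("format error: '", path, "' is not a 3-D volume")
  arr <- array(as.numeric(img), dim = d)
  attr(arr, "affine") <- RNifti::xform(img)
  attr(arr, "pixdim") <- RNifti::pixdim(img)[1:3]
  arr
}

#' Read one metric volume from NIfTI
#'
#' @param path NIfTI file (`.nii` or `.nii.gz`).
#' @param name metric identifier (`"MWF"`, `"uFA"`, `"CMD"`).
#' @return A [metric_volume].
#' @export
read_metric_volume <- function(path, name) {
  arr <- read_nifti_array(path)
  aff <- attr(arr, "affine"); px <- attr(arr, "pixdim")
  attributes(arr) <- list(dim = dim(arr))
  metric_volume(arr, name = name, voxel_size_mm = px, affine = aff)
}

#' Load a subject from NIfTI files
#'
#' Reads the three metric maps and the brain mask and assembles a validated
#' [subject_dataset]; grid congruence failures name the offending volume.
#'
#' @param mwf_path,ufa_path,cmd_path,mask_path NIfTI file paths.
#' @param subject_id character scalar.
#' @param group cohort label.
#' @return A [subject_dataset].
#' @export
load_subject <- function(subject_id, mwf_path, ufa_path, cmd_path, mask_path,
                         group = "other") {
  mwf <- read_metric_volume(mwf_path, "MWF")
  ufa <- read_metric_volume(ufa_path, "uFA")
  cmd <- read_metric_volume(cmd_path, "CMD")
  marr <- read_nifti_array(mask_path)
  attributes(marr) <- list(dim = dim(marr))
  subject_dataset(subject_id, mwf, ufa, cmd, brain_mask(marr > 0),
                  group = group)
}

#' Read a subject manifest
#'
#' CSV with columns `subject_id, group, mwf_path, ufa_path, cmd_path,
#' mask_path`; relative paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV.
#' @return A list of [subject_dataset] objects.
#' @export
read_subject_manifest <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "mwf_path", "ufa_path", "cmd_path",
            "mask_path")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  base <- dirname(normalizePath(path))
  resolve <- function(p) ifelse(grepl("^(/|[A-Za-z]:)", p), p,
                                file.path(base, p))
  lapply(seq_len(nrow(tab)), function(i) {
    load_subject(tab$subject_id[i],
                 resolve(tab$mwf_path[i]), resolve(tab$ufa_path[i]),
                 resolve(tab$cmd_path[i]), resolve(tab$mask_path[i]),
                 group = tab$group[i])
  })
}

#' Write a metric volume to NIfTI
#'
#' Written as float64 so that read-back agrees to numerical precision.
#'
#' @param volume a [metric_volume].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_metric_volume <- function(volume, path) {
  img <- RNifti::asNifti(volume$values, datatype = "double")
  img <- RNifti::`sform<-`(img, structure(volume$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a label volume to NIfTI
#'
#' Labels are validated and written as unsigned 16-bit integers; reloading
#' reproduces them exactly.
#'
#' @param labels a [label_volume].
#' @param path output file path.
#' @param affine optional 4x4 grid-to-world transform (default identity).
#' @return `path`, invisibly.
#' @export
save_label_volume <- function(labels, path, affine = diag(4)) {
  if (!inherits(labels, "label_volume")) stop("'labels' must be a label_volume")
  if (max(labels$labels) > labels$K)
    stop("validation error: labels exceed K = ", labels$K)
  img <- RNifti::asNifti(labels$labels, datatype = "uint16")
  img <- RNifti::`sform<-`(img, structure(as.matrix(affine), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a label volume from NIfTI
#'
#' @param path NIfTI file.
#' @param K number of tissue classes; defaults to the maximum label found.
#' @return A [label_volume].
#' @export
read_label_volume <- function(path, K = NULL) {
  arr <- read_nifti_array(path)
  attributes(arr) <- list(dim = dim(arr))
  storage.mode(arr) <- "integer"
  if (is.null(K)) K <- max(arr)
  label_volume(arr, K = K)
}

#' Write a subject's volumes to NIfTI files
#'
#' Convenience writer used by the phantom generator: writes
#' `<id>_mwf.nii.gz`, `<id>_ufa.nii.gz`, `<id>_cmd.nii.gz`,
#' `<id>_mask.nii.gz` under `dir`.
#'
#' @param subject a [subject_dataset].
#' @param dir output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
save_subject <- function(subject, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  id <- subject$subject_id
  paths <- c(mwf = file.path(dir, paste0(id, "_mwf.nii.gz")),
             ufa = file.path(dir, paste0(id, "_ufa.nii.gz")),
             cmd = file.path(dir, paste0(id, "_cmd.nii.gz")),
             mask = file.path(dir, paste0(id, "_mask.nii.gz")))
  save_metric_volume(subject$mwf, paths[["mwf"]])
  save_metric_volume(subject$ufa, paths[["ufa"]])
  save_metric_volume(subject$cmd, paths[["cmd"]])
  mimg <- RNifti::asNifti(array(as.integer(subject$mask$values),
                                dim = subject$grid_shape),
                          datatype = "uint8")
  mimg <- RNifti::`sform<-`(mimg, structure(subject$mwf$affine, code = 2L))
  RNifti::writeNifti(mimg, paths[["mask"]])
  invisible(paths)
}
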