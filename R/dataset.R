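#' Diffusion-weighted MRI dataset
#'
#' A validated 4-D magnitude-MR signal grid (x, y, z, volume) with its
#' gradient scheme, voxel geometry and free-form provenance metadata.
#'
#' @param signal 4-D numeric array, non-negative and finite.
#' @param scheme a [gradient_scheme()] whose length matches `dim(signal)[4]`.
#' @param voxel_size length-3 numeric, voxel edge lengths in mm.
#' @param meta named list of provenance fields (protocol, subject, repeat, ...).
#' @return Object of class `dwi_dataset`.
#' @export
dwi_dataset <- function(signal, scheme, voxel_size = c(3, 3, 3), meta = list()) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  signal <- as.array(signal)
  if (length(dim(signal)) == 3L) dim(signal) <- c(dim(signal), 1L)
  if (length(dim(signal)) != 4L) stop("signal must be a 4-D array")
  if (dim(signal)[4] != length(scheme$bvals)) {
    stop(sprintf("format error: %d volumes in signal but %d gradient entries",
                 dim(signal)[4], length(scheme$bvals)))
  }
  if (any(!is.finite(signal))) stop("signal must be finite (magnitude MR data)")
  if (any(signal < 0)) stop("signal must be non-negative (magnitude MR data)")
  if (length(voxel_size) != 3L || any(voxel_size <= 0)) {
    stop("voxel_size must be three positive lengths in mm")
  }
  x <- list(signal = signal, scheme = scheme,
            voxel_size = as.numeric(voxel_size),
            slice_count = dim(signal)[3], meta = meta)
  class(x) <- "dwi_dataset"
  x
}

#' @export
print.dwi_dataset <- function(x, ...) {
  d <- dim(x$signal)
  cat(sprintf("dwi_dataset: %dx%dx%d grid, %d volumes, voxels %s mm\n",
              d[1], d[2], d[3], d[4],
              paste(signif(x$voxel_size, 3), collapse = "x")))
  print(x$scheme)
  invisible(x)
}

#' Read a diffusion dataset from NIfTI + FSL gradient files
#'
#' Reads a 4-D NIfTI-1 volume together with FSL-dialect `.bval` / `.bvec`
#' files (whitespace-separated; bvec as 3 rows by N columns). Direction
#' vectors are normalised to unit length (with a warning when a norm deviates
#' from 1) and the shell structure is detected.
#'
#' @param nifti_path path to a `.nii` / `.nii.gz` file.
#' @param bval_path path to the b-value file.
#' @param bvec_path path to the direction file.
#' @param averages optional per-volume signal averages (default 1).
#' @param meta named list merged into the dataset metadata.
#' @return A [dwi_dataset()].
#' @export
read_dwi <- function(nifti_path, bval_path, bvec_path,
                     averages = NULL, meta = list()) {
  for (p in c(nifti_path, bval_path, bvec_path)) {
    if (!file.exists(p)) stop(sprintf("file not found: %s", p))
  }
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  nvol <- dim(arr)[4]
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- utils::read.table(bvec_path)
  if (nrow(bvec_rows) != 3L) stop("format error: .bvec must have 3 rows (FSL dialect)")
  bvecs <- t(as.matrix(bvec_rows))
  if (length(bvals) != nvol) {
    stop(sprintf("format error: %d b-values but %d volumes in %s",
                 length(bvals), nvol, basename(nifti_path)))
  }
  if (nrow(bvecs) != nvol) {
    stop(sprintf("format error: %d direction vectors but %d volumes",
                 nrow(bvecs), nvol))
  }
  if (is.null(averages)) averages <- rep(1L, nvol)
  scheme <- gradient_scheme(bvals, bvecs, averages)
  vx <- RNifti::pixdim(img)[1:3]
  dwi_dataset(arr, scheme, voxel_size = vx,
              meta = c(list(source = nifti_path), meta))
}

#' Write a scalar map as 32-bit float NIfTI-1
#'
#' NaN encodes excluded voxels and survives the round trip. Values are stored
#' as IEEE single precision; reading the file back returns exactly the stored
#' single-precision values.
#'
#' @param map 3-D (or 2-D) numeric array; finite or NaN.
#' @param voxel_size length-3 voxel edge lengths in mm, written to the header.
#' @param out_path destination `.nii` / `.nii.gz` path.
#' @return `out_path`, invisibly.
#' @export
write_scalar_map <- function(map, voxel_size, out_path) {
  map <- as.array(map)
  if (length(map) == 0L) stop("validation error: empty map")
  if (any(is.infinite(map))) stop("map values must be finite or NaN")
  img <- RNifti::asNifti(map)
  nd <- length(dim(map))
  vs <- rep(1, nd)
  vs[seq_len(min(3L, nd))] <- voxel_size[seq_len(min(3L, nd))]
  RNifti::pixdim(img) <- vs
  ok <- tryCatch({RNifti::writeNifti(img, out_path, datatype = "float"); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(out_path)) {
    stop(sprintf("I/O error: cannot write %s", out_path))
  }
  invisible(out_path)
}

#' Read a scalar map written by [write_scalar_map()]
#' @param path NIfTI file path.
#' @return numeric array.
#' @export
read_scalar_map <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  attributes(arr) <- list(dim = dim(arr))
  arr
}

#' ROI label map
#'
#' Integer labels aligned to a dataset's spatial grid; 0 is background,
#' 1 the pancreas, further positive labels allowed.
#'
#' @param labels 3-D array of non-negative integers.
#' @param reference optional [dwi_dataset()] checked for shape agreement.
#' @return Object of class `roi_label_map`.
#' @export
roi_label_map <- function(labels, reference = NULL) {
  labels <- as.array(labels)
  if (length(dim(labels)) != 3L) stop("labels must be a 3-D grid")
  if (any(!is.finite(labels)) || any(labels < 0) || any(labels != round(labels))) {
    stop("labels must be non-negative integers")
  }
  if (!is.null(reference)) {
    if (!all(dim(labels) == dim(reference$signal)[1:3])) {
      stop("label grid does not match the dataset's spatial grid")
    }
  }
  storage.mode(labels) <- "integer"
  structure(list(labels = labels), class = "roi_label_map")
}

#' Restrict a dataset to a set of b-value shells
#'
#' Keeps only volumes whose b-value lies within the shell tolerance
#' (25 s/mm^2) of a requested shell; the gradient scheme is subset
#' consistently. Used to fit the tensor on b = 200/1000 only, which removes
#' perfusion-related (IVIM) signal contamination at low b.
#'
#' @param dataset a [dwi_dataset()].
#' @param shells numeric vector of requested b-values (0 allowed).
#' @return A [dwi_dataset()] containing only the requested shells.
#' @export
select_shells <- function(dataset, shells) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  scheme <- dataset$scheme
  avail <- c(if (any(scheme$bvals <= SHELL_TOL)) 0, scheme$shells)
  keep <- rep(FALSE, length(scheme$bvals))
  for (s in shells) {
    idx <- abs(scheme$bvals - s) <= SHELL_TOL
    if (!any(idx)) {
      stop(sprintf("validation error: shell b=%g not present; available shells: {%s}",
                   s, paste(round(avail), collapse = ", ")))
    }
    keep <- keep | idx
  }
  dwi_dataset(dataset$signal[, , , keep, drop = FALSE],
              subset_scheme(scheme, keep),
              voxel_size = dataset$voxel_size, meta = dataset$meta)
}
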