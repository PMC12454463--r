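#' Diffusion gradient scheme
#'
#' Bundles the per-volume diffusion weighting of an acquisition: b-values
#' (s/mm^2), unit direction vectors, and the number of scanner signal averages
#' each delivered volume represents. Directions on nonzero shells are
#' normalised to unit length; b = 0 entries carry the zero vector.
#'
#' @param bvals numeric vector of b-values in s/mm^2, one per volume.
#' @param bvecs direction vectors, either an N x 3 or 3 x N numeric matrix.
#' @param averages integer vector of signal averages per volume (default 1).
#' @return An object of class `gradient_scheme`: a list with `bvals`,
#'   `bvecs` (N x 3), `averages` and the detected `shells` (distinct nonzero
#'   b-values, grouped within the shell tolerance).
#' @seealso [shell_table()], [select_shells()]
#' @export
gradient_scheme <- function(bvals, bvecs, averages = rep(1L, length(bvals))) {
  bvals <- as.numeric(bvals)
  if (any(!is.finite(bvals))) stop("b-values must be finite")
  if (any(bvals < 0)) stop("validation error: negative b-value in gradient scheme")
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) == length(bvals) && nrow(bvecs) == 3L && length(bvals) != 3L) {
    bvecs <- t(bvecs)
  } else if (nrow(bvecs) == 3L && ncol(bvecs) == 3L) {
    # ambiguous 3x3: assume FSL layout (3 rows x N columns)
    bvecs <- t(bvecs)
  }
  if (nrow(bvecs) != length(bvals) || ncol(bvecs) != 3L) {
    stop(sprintf("format error: %d direction vectors for %d b-values",
                 if (ncol(bvecs) == 3L) nrow(bvecs) else ncol(bvecs), length(bvals)))
  }
  if (length(averages) != length(bvals)) {
    stop(sprintf("format error: %d averages entries for %d b-values",
                 length(averages), length(bvals)))
  }
  if (any(averages < 1)) stop("signal averages must be >= 1")

  nrm <- sqrt(rowSums(bvecs^2))
  nz <- bvals > 0
  bad <- nz & abs(nrm - 1) > 1e-6
  if (any(bad & nrm == 0)) {
    stop("validation error: zero direction vector on a nonzero b-value volume")
  }
  if (any(bad)) {
    warning(sprintf("normalised %d direction vector(s) with non-unit norm", sum(bad)))
    bvecs[bad, ] <- bvecs[bad, , drop = FALSE] / nrm[bad]
  }
  bvecs[!nz, ] <- 0

  x <- list(bvals = bvals, bvecs = bvecs,
            averages = as.integer(averages),
            shells = detect_shells(bvals))
  class(x) <- "gradient_scheme"
  x
}

# Shell membership tolerance in s/mm^2 (scanners jitter nominal b-values).
SHELL_TOL <- 25

#' @keywords internal
detect_shells <- function(bvals, tol = SHELL_TOL) {
  b <- sort(unique(bvals[bvals > tol]))
  if (length(b) == 0L) return(numeric(0))
  grp <- cumsum(c(TRUE, diff(b) > tol))
  as.numeric(tapply(b, grp, stats::median))
}

#' Shell summary of a gradient scheme
#'
#' @param scheme a [gradient_scheme()].
#' @return data.frame with one row per distinct nonzero shell: nominal
#'   b-value, number of volumes and total signal averages.
#' @export
shell_table <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  sh <- scheme$shells
  data.frame(
    b = sh,
    n_volumes = vapply(sh, function(s) sum(abs(scheme$bvals - s) <= SHELL_TOL), 0L),
    n_averages = vapply(sh, function(s)
      sum(scheme$averages[abs(scheme$bvals - s) <= SHELL_TOL]), 0L)
  )
}

#' Volumes belonging to a shell
#'
#' @param scheme a [gradient_scheme()].
#' @param b target b-value; `0` selects unweighted volumes.
#' @param tol shell tolerance in s/mm^2.
#' @return integer indices of volumes on the shell.
#' @export
shell_volumes <- function(scheme, b, tol = SHELL_TOL) {
  which(abs(scheme$bvals - b) <= tol)
}

#' @export
print.gradient_scheme <- function(x, ...) {
  cat(sprintf("gradient_scheme: %d volumes, shells {%s} s/mm^2, %d b=0\n",
              length(x$bvals), paste(round(x$shells), collapse = ", "),
              sum(x$bvals <= SHELL_TOL)))
  invisible(x)
}

#' @keywords internal
subset_scheme <- function(scheme, idx) {
  gradient_scheme(scheme$bvals[idx], scheme$bvecs[idx, , drop = FALSE],
                  scheme$averages[idx])
}
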