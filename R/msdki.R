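#' Directional average of the signal per shell
#'
#' For every distinct nonzero shell, the per-voxel mean signal over all
#' directions on that shell (the "powder average"). The number of
#' contributing volumes per shell is recorded for downstream weighting.
#'
#' @param dataset a [dwi_dataset()].
#' @param include_b0 keep an entry for b = 0 volumes (default FALSE).
#' @return list with `b` (shell b-values), `n_dirs` (volumes per shell) and
#'   `ms` (array x,y,z,shell of mean signals).
#' @export
directional_average <- function(dataset, include_b0 = FALSE) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  shells <- dataset$scheme$shells
  if (include_b0 && any(dataset$scheme$bvals <= SHELL_TOL)) shells <- c(0, shells)
  if (length(shells) == 0L) stop("validation error: no nonzero shells present")
  dims <- dim(dataset$signal)
  ms <- array(NA_real_, c(dims[1:3], length(shells)))
  n_dirs <- integer(length(shells))
  for (i in seq_along(shells)) {
    idx <- shell_volumes(dataset$scheme, shells[i])
    if (length(idx) == 0L) stop("validation error: empty shell")
    n_dirs[i] <- length(idx)
    sub <- dataset$signal[, , , idx, drop = FALSE]
    ms[, , , i] <- rowMeans(matrix(sub, ncol = length(idx)))
  }
  list(b = shells, n_dirs = n_dirs, ms = ms)
}

#' Mean-signal diffusion kurtosis fit
#'
#' Fits `MS(b) = S0 * exp(-b*MD + (1/6) b^2 MD^2 MK)` to the directional
#' averages by weighted linear least squares on `log MS` with regressors
#' `[1, -b, b^2]`; the quadratic coefficient maps to `MK = 6*theta2/MD^2`.
#' Weights are `n_dirs * predicted MS^2`, refined over two passes; with
#' exactly three shells the solution is the exact interpolant and the weights
#' are immaterial.
#'
#' @param avg output of [directional_average()] restricted to the kurtosis
#'   shells (typically b = 200, 1000, 1700 s/mm^2; b = 0 excluded so the free
#'   S0 absorbs the perfusion-suppressed baseline).
#' @param n_passes re-weighting passes (default 2).
#' @return a [scalar_maps()] with `md` (mm^2/s), `mk` (dimensionless,
#'   NaN where MD <= 0 or any shell mean is non-positive) and `s0_msdki`.
#' @export
fit_msdki <- function(avg, n_passes = 2L) {
  b <- avg$b
  if (length(b) < 3L) stop("validation error: mean-signal DKI needs >= 3 nonzero shells")
  dims <- dim(avg$ms)
  nvox <- prod(dims[1:3])
  MS <- matrix(avg$ms, nrow = nvox, ncol = length(b))
  X <- cbind(1, -b, b^2)

  ok <- rowSums(MS <= 0 | !is.finite(MS)) == 0L
  theta <- matrix(NaN, nvox, 3L)
  Y <- log(MS[ok, , drop = FALSE])
  if (length(b) == 3L) {
    # exact interpolation: weights cancel
    theta[ok, ] <- t(solve(X, t(Y)))
  } else {
    Xi <- solve(crossprod(X), t(X))
    th <- t(Xi %*% t(Y))
    for (pass in seq_len(n_passes)) {
      for (r in seq_len(nrow(th))) {
        w <- avg$n_dirs * exp(2 * drop(X %*% th[r, ]))
        Xw <- X * w
        th[r, ] <- tryCatch(drop(solve(crossprod(Xw, X), crossprod(Xw, Y[r, ]))),
                            error = function(e) th[r, ])
      }
    }
    theta[ok, ] <- th
  }

  md <- theta[, 2]
  mk <- 6 * theta[, 3] / md^2
  mk[!is.finite(md) | md <= 0] <- NaN
  scalar_maps(md = array(md, dims[1:3]),
              mk = array(mk, dims[1:3]),
              s0_msdki = array(exp(theta[, 1]), dims[1:3]))
}

#' Two-point apparent diffusion coefficient
#'
#' Clinical-style monoexponential ADC from a single diffusion direction at
#' two shells: `ADC = log(S(b_low)/S(b_high)) / (b_high - b_low)`.
#'
#' @param dataset a [dwi_dataset()] containing both shells.
#' @param b_low,b_high the two b-values (defaults 200 and 1000 s/mm^2).
#' @param direction_index which diffusion direction to use, counted within
#'   the ordered volumes of each shell (default 1, "the first diffusion
#'   direction", as in clinical practice).
#' @return 3-D array of ADC in mm^2/s; NaN where either signal is
#'   non-positive.
#' @export
compute_adc <- function(dataset, b_low = 200, b_high = 1000,
                        direction_index = 1L) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  i_low <- shell_volumes(dataset$scheme, b_low)
  i_high <- shell_volumes(dataset$scheme, b_high)
  if (length(i_low) < direction_index || length(i_high) < direction_index) {
    stop(sprintf("validation error: direction %d not present at both shells",
                 direction_index))
  }
  s1 <- dataset$signal[, , , i_low[direction_index], drop = FALSE]
  s2 <- dataset$signal[, , , i_high[direction_index], drop = FALSE]
  dims <- dim(dataset$signal)[1:3]
  dim(s1) <- dims; dim(s2) <- dims
  adc <- log(s1 / s2) / (b_high - b_low)
  adc[s1 <= 0 | s2 <= 0] <- NaN
  adc
}
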