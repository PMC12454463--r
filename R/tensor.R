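#' Design matrix of the log-linear diffusion tensor model
#'
#' Maps the parameter vector (log S0', Dxx, Dyy, Dzz, Dxy, Dxz, Dyz) to the
#' log-signal: row i is
#' `[1, -b gx^2, -b gy^2, -b gz^2, -2b gx gy, -2b gx gz, -2b gy gz]`.
#' The intercept is the perfusion-suppressed log baseline when only
#' b >= 200 s/mm^2 volumes enter the fit.
#'
#' @param scheme a [gradient_scheme()]; b = 0 volumes contribute
#'   intercept-only rows (the perfusion-suppressed fit excludes them via
#'   [select_shells()] before calling this).
#' @return N x 7 numeric matrix of full column rank.
#' @export
build_design_matrix <- function(scheme) {
  stopifnot(inherits(scheme, "gradient_scheme"))
  b <- scheme$bvals
  g <- scheme$bvecs
  X <- cbind(1,
             -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2],
             -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  colnames(X) <- c("logS0", "Dxx", "Dyy", "Dzz", "Dxy", "Dxz", "Dyz")
  if (nrow(X) < 7L || qr(X)$rank < 7L) {
    stop("validation error: insufficient directions (design matrix rank < 7)")
  }
  X
}

#' Weighted-least-squares diffusion tensor fit
#'
#' Per-voxel tensor estimation on a perfusion-suppressed sub-dataset
#' (b = 200 and 1000 s/mm^2; b = 0 volumes are not used, so the intercept
#' absorbs the perfusion-suppressed baseline). Ordinary least squares on the
#' log-signal initialises the fit; each subsequent pass re-weights by the
#' squared signal predictions of the previous pass.
#'
#' @param dataset a [dwi_dataset()] restricted to the fitting shells, e.g.
#'   via `select_shells(ds, c(200, 1000))`.
#' @param mask optional logical 3-D array; voxels outside are NaN.
#' @param n_passes number of re-weighted passes after the OLS
#'   initialisation (default 2).
#' @return Object of class `tensor_field`: arrays `log_s0` (x,y,z), `D`
#'   (x,y,z,6: Dxx, Dyy, Dzz, Dxy, Dxz, Dyz in mm^2/s), `eigvals` (x,y,z,3;
#'   descending) and `eigvecs` (x,y,z,3,3; columns are eigenvectors).
#' @export
fit_dti_wls <- function(dataset, mask = NULL, n_passes = 2L) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  X <- build_design_matrix(dataset$scheme)
  dims <- dim(dataset$signal)
  nvox <- prod(dims[1:3])
  S <- matrix(dataset$signal, nrow = nvox, ncol = dims[4])
  if (is.null(mask)) mask <- rep(TRUE, nvox) else mask <- as.logical(mask)

  eps_floor <- .Machine$double.eps * max(S)
  n_clipped <- sum(S[mask, ] < eps_floor & S[mask, ] > 0) + sum(S[mask, ] == 0)

  beta <- matrix(NaN, nvox, 7L)
  XtX_chol <- chol(crossprod(X))
  for (v in which(mask)) {
    s <- S[v, ]
    if (all(s <= 0)) next   # all-zero series: leave NaN
    y <- log(pmax(s, eps_floor))
    b <- backsolve(XtX_chol, backsolve(XtX_chol, crossprod(X, y),
                                       transpose = TRUE))
    for (pass in seq_len(n_passes)) {
      w <- exp(2 * drop(X %*% b))        # squared predicted signals
      w <- w / max(w)
      Xw <- X * w
      b <- tryCatch(solve(crossprod(Xw, X), crossprod(Xw, y)),
                    error = function(e) b)
    }
    beta[v, ] <- b
  }
  if (n_clipped > 0) {
    message(sprintf("fit_dti_wls: clipped %d non-positive signal value(s) before log",
                    n_clipped))
  }

  tf <- structure(
    list(log_s0 = array(beta[, 1], dims[1:3]),
         D = array(beta[, 2:7], c(dims[1:3], 6L)),
         eigvals = NULL, eigvecs = NULL,
         voxel_size = dataset$voxel_size),
    class = "tensor_field")
  eigendecompose(tf)
}

#' Eigen-decomposition of a tensor field
#'
#' Populates per-voxel eigenvalues (sorted descending; negative values
#' preserved for downstream quality control) and orthonormal eigenvectors.
#'
#' @param tf a `tensor_field` from [fit_dti_wls()] or [tensor_field()].
#' @return the same `tensor_field` with `eigvals` and `eigvecs` filled.
#' @export
eigendecompose <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"))
  dims <- dim(tf$D)[1:3]
  nvox <- prod(dims)
  Dm <- matrix(tf$D, nrow = nvox, ncol = 6L)
  vals <- matrix(NaN, nvox, 3L)
  vecs <- array(NaN, c(nvox, 3L, 3L))
  for (v in seq_len(nvox)) {
    d <- Dm[v, ]
    if (any(!is.finite(d))) next
    A <- matrix(c(d[1], d[4], d[5],
                  d[4], d[2], d[6],
                  d[5], d[6], d[3]), 3L, 3L)
    e <- eigen(A, symmetric = TRUE)   # descending values, orthonormal vectors
    vals[v, ] <- e$values
    vecs[v, , ] <- e$vectors
  }
  tf$eigvals <- array(vals, c(dims, 3L))
  tf$eigvecs <- array(vecs, c(dims, 3L, 3L))
  tf
}

#' Construct a tensor field from explicit components
#'
#' @param D array (x,y,z,6) of tensor components (Dxx, Dyy, Dzz, Dxy, Dxz,
#'   Dyz) in mm^2/s.
#' @param log_s0 optional (x,y,z) log-baseline array.
#' @return a `tensor_field` with eigen-decomposition populated.
#' @export
tensor_field <- function(D, log_s0 = NULL) {
  D <- as.array(D)
  if (length(dim(D)) == 2L && ncol(D) == 6L) dim(D) <- c(nrow(D), 1L, 1L, 6L)
  stopifnot(length(dim(D)) == 4L, dim(D)[4] == 6L)
  if (is.null(log_s0)) log_s0 <- array(0, dim(D)[1:3])
  tf <- structure(list(log_s0 = log_s0, D = D, eigvals = NULL, eigvecs = NULL,
                       voxel_size = c(3, 3, 3)),
                  class = "tensor_field")
  eigendecompose(tf)
}

#' Scalar DTI maps from a tensor field
#'
#' MD = (l1+l2+l3)/3; AD = l1; RD = (l2+l3)/2;
#' FA = sqrt(3/2 * ((l1-MD)^2 + (l2-MD)^2 + (l3-MD)^2) / (l1^2+l2^2+l3^2)),
#' NaN where the eigenvalue norm vanishes.
#'
#' @param tf a `tensor_field` with eigenvalues populated.
#' @return Object of class `scalar_maps`: list of arrays `md`, `ad`, `rd`,
#'   `fa` plus a `units_note`; diffusivities in mm^2/s (reported downstream
#'   as x1e-3 mm^2/s).
#' @export
compute_dti_maps <- function(tf) {
  stopifnot(inherits(tf, "tensor_field"), !is.null(tf$eigvals))
  dims <- dim(tf$eigvals)[1:3]
  l1 <- tf$eigvals[, , , 1, drop = FALSE]; dim(l1) <- dims
  l2 <- tf$eigvals[, , , 2, drop = FALSE]; dim(l2) <- dims
  l3 <- tf$eigvals[, , , 3, drop = FALSE]; dim(l3) <- dims
  md <- (l1 + l2 + l3) / 3
  nrm2 <- l1^2 + l2^2 + l3^2
  fa <- sqrt(1.5 * ((l1 - md)^2 + (l2 - md)^2 + (l3 - md)^2) / nrm2)
  fa[nrm2 == 0] <- NaN
  scalar_maps(md = md, ad = l1, rd = (l2 + l3) / 2, fa = fa)
}

#' Scalar map set container
#'
#' @param ... named 3-D arrays (md, ad, rd, fa, mk, adc, s0_msdki, ...).
#' @return object of class `scalar_maps`.
#' @export
scalar_maps <- function(...) {
  maps <- list(...)
  if (length(maps) && length(unique(lapply(maps, dim))) != 1L) {
    stop("all maps must share the same grid")
  }
  maps$units_note <- "diffusivities in mm^2/s; report as x1e-3 mm^2/s"
  class(maps) <- "scalar_maps"
  maps
}

#' Names of the scalar maps present in a set
#' @param maps a `scalar_maps` object.
#' @return character vector.
#' @export
map_names <- function(maps) {
  setdiff(names(maps), "units_note")
}
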