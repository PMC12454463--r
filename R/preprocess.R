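#' Marchenko-Pastur PCA denoising
#'
#' Sliding-window principal-component denoising of a 4-D diffusion series.
#' For each voxel, the window-by-volume signal matrix centred on it is
#' decomposed; eigenvalues falling inside the Marchenko-Pastur noise bulk are
#' classified as noise by the standard iterative mean-vs-MP-range criterion
#' and the corresponding components suppressed. Only the centre voxel of each
#' window is assigned (no overlapping-window averaging). Returns the denoised
#' dataset together with the per-voxel MP noise-level estimate and the number
#' of retained signal components.
#'
#' @param dataset a [dwi_dataset()].
#' @param window three odd integers, the spatial window (default `c(5, 5, 3)`:
#'   75 window voxels, at least the volume count of a 16-direction protocol,
#'   while fitting a 6-slice stack).
#' @return list with elements `dataset` (denoised [dwi_dataset()]) and
#'   `noise` (class `noise_map`: arrays `sigma` and `retained_components`).
#' @references Veraart et al. (2016), denoising of diffusion MRI using random
#'   matrix theory.
#' @export
mppca_denoise <- function(dataset, window = c(5L, 5L, 3L)) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  window <- as.integer(window)
  if (length(window) != 3L || any(window < 1L) || any(window %% 2L == 0L)) {
    stop("window must be three odd positive integers")
  }
  dims <- dim(dataset$signal)
  if (any(window > dims[1:3])) {
    stop("validation error: window larger than the image grid")
  }
  M <- dims[4]
  nwin <- prod(window)
  if (nwin < M) {
    warning(sprintf(
      "window holds %d voxels for %d volumes; MP classification is unreliable",
      nwin, M))
  }

  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  # flatten to (voxel, volume)
  S <- matrix(dataset$signal, nrow = nx * ny * nz, ncol = M)
  out <- S
  sigma <- numeric(nx * ny * nz)
  kept <- integer(nx * ny * nz)

  hw <- (window - 1L) %/% 2L
  # window start coordinates, shifted inwards at the edges
  xs <- pmin(pmax(seq_len(nx) - hw[1], 1L), nx - window[1] + 1L)
  ys <- pmin(pmax(seq_len(ny) - hw[2], 1L), ny - window[2] + 1L)
  zs <- pmin(pmax(seq_len(nz) - hw[3], 1L), nz - window[3] + 1L)
  offx <- 0:(window[1] - 1L)
  offy <- 0:(window[2] - 1L)
  offz <- 0:(window[3] - 1L)

  for (z in seq_len(nz)) {
    zi <- zs[z] + offz
    for (y in seq_len(ny)) {
      yi <- ys[y] + offy
      base_yz <- rep((zi - 1L) * nx * ny, each = window[1] * window[2]) +
        rep(rep((yi - 1L) * nx, each = window[1]), times = window[3])
      for (x in seq_len(nx)) {
        xi <- xs[x] + offx
        rows <- rep(xi, times = window[2] * window[3]) + base_yz
        X <- S[rows, , drop = FALSE]
        res <- mp_denoise_block(X)
        centre <- which(rows == (z - 1L) * nx * ny + (y - 1L) * nx + x)[1]
        v <- (z - 1L) * nx * ny + (y - 1L) * nx + x
        out[v, ] <- res$recon[centre, ]
        sigma[v] <- res$sigma
        kept[v] <- res$ncomp
      }
    }
  }

  den <- pmax(out, 0)  # magnitude data stays non-negative
  ds <- dwi_dataset(array(den, dims), dataset$scheme,
                    voxel_size = dataset$voxel_size, meta = dataset$meta)
  noise <- structure(
    list(sigma = array(sigma, dims[1:3]),
         retained_components = array(kept, dims[1:3])),
    class = "noise_map")
  list(dataset = ds, noise = noise)
}

# MP classification + low-rank reconstruction of one window matrix X (N x M).
# Eigenvalues of X'X / N, ascending; starting from the full set, shrink the
# candidate noise set while its range exceeds the MP bulk width 4*sigma^2*
# sqrt(c/N) implied by its own mean. Noise components are zeroed.
#' @keywords internal
mp_denoise_block <- function(X) {
  N <- nrow(X); M <- ncol(X)
  if (N <= 1L) {
    # no spatial redundancy: nothing can be classified, pass through
    return(list(recon = X, sigma = 0, ncomp = M))
  }
  C <- crossprod(X) / N
  ed <- eigen(C, symmetric = TRUE)
  lam <- rev(ed$values)           # ascending
  lam[lam < 0] <- 0
  V <- ed$vectors[, rev(seq_len(M)), drop = FALSE]

  c_noise <- M
  sig2 <- mean(lam)
  while (c_noise > 1 &&
         (lam[c_noise] - lam[1]) > 4 * sqrt(c_noise / N) * sig2) {
    c_noise <- c_noise - 1L
    sig2 <- mean(lam[seq_len(c_noise)])
  }
  ncomp <- M - c_noise
  if ((lam[c_noise] - lam[1]) <= .Machine$double.eps * max(lam, 1)) {
    # degenerate: noise set is numerically zero (noiseless low-rank input)
    sig2 <- 0
    ncomp <- sum(lam > .Machine$double.eps * max(lam, 1) * M)
  }
  if (ncomp >= M) {
    recon <- X
  } else if (ncomp == 0L) {
    recon <- matrix(0, N, M)
  } else {
    Vs <- V[, M - seq_len(ncomp) + 1L, drop = FALSE]
    recon <- (X %*% Vs) %*% t(Vs)
  }
  list(recon = recon, sigma = sqrt(max(sig2, 0)), ncomp = ncomp)
}

#' Gibbs-ringing removal by subvoxel shifts
#'
#' Removes truncation (Gibbs) ringing from each axial slice of each volume
#' using the subvoxel-shift method: along each in-plane axis, `n_shifts`
#' sub-voxel shifts are evaluated through Fourier-interpolated phase ramps and,
#' per voxel, the shift minimising a local finite-difference oscillation
#' measure over `neighborhood` voxels is selected; the value is then
#' interpolated back to the voxel centre. The two axis results are combined
#' through the standard smooth k-space weighting that assigns each axis the
#' frequency band in which it rings.
#'
#' @param dataset a [dwi_dataset()].
#' @param neighborhood positive integer, half-width of the oscillation window
#'   (default 3).
#' @param n_shifts positive integer, number of subvoxel shifts per side
#'   (default 20).
#' @return a [dwi_dataset()] with unrung signal.
#' @references Kellner et al. (2016), Gibbs-ringing artifact removal based on
#'   local subvoxel-shifts.
#' @export
gibbs_unring <- function(dataset, neighborhood = 3L, n_shifts = 20L) {
  stopifnot(inherits(dataset, "dwi_dataset"))
  if (neighborhood < 1L || n_shifts < 1L) stop("parameters must be positive")
  dims <- dim(dataset$signal)
  if (dims[1] < 4L || dims[2] < 4L) {
    stop("validation error: in-plane grid too small for unringing")
  }
  out <- dataset$signal
  for (v in seq_len(dims[4])) {
    for (z in seq_len(dims[3])) {
      out[, , z, v] <- unring_slice(dataset$signal[, , z, v],
                                    neighborhood, n_shifts)
    }
  }
  out <- pmax(out, 0)
  dwi_dataset(out, dataset$scheme, voxel_size = dataset$voxel_size,
              meta = dataset$meta)
}

# Kellner-style axis split: G_x keeps the frequencies where ringing runs
# along x, G_y the complement; each part is unrung along its own axis.
#' @keywords internal
unring_slice <- function(img, nb, nsh) {
  nx <- nrow(img); ny <- ncol(img)
  kx <- 2 * pi * ifelse(seq_len(nx) - 1 < nx / 2,
                        seq_len(nx) - 1, seq_len(nx) - 1 - nx) / nx
  ky <- 2 * pi * ifelse(seq_len(ny) - 1 < ny / 2,
                        seq_len(ny) - 1, seq_len(ny) - 1 - ny) / ny
  cx <- outer(1 + cos(kx), rep(1, ny))
  cy <- outer(rep(1, nx), 1 + cos(ky))
  den <- cx + cy
  wx <- ifelse(den > 1e-12, cy / den, 0.5)  # weight for the x-unrung part
  K <- stats::fft(img)
  Gx <- Re(stats::fft(K * wx, inverse = TRUE)) / (nx * ny)
  Gy <- Re(stats::fft(K * (1 - wx), inverse = TRUE)) / (nx * ny)
  ux <- apply(Gx, 2, unring_1d, nb = nb, nsh = nsh)
  uy <- t(apply(Gy, 1, unring_1d, nb = nb, nsh = nsh))
  ux + uy
}

# 1-D subvoxel-shift unringing of a single line. The oscillation measure is
# one-sided (minimum of the left and right neighbourhoods, excluding the
# voxel's own step) so that genuine edges are not smoothed away.
#' @keywords internal
unring_1d <- function(s, nb, nsh) {
  n <- length(s)
  if (n < 4L) return(s)
  shifts <- (-nsh:nsh) / (2 * nsh)          # in voxels, |t| <= 0.5
  f <- ifelse(seq_len(n) - 1 < n / 2, seq_len(n) - 1, seq_len(n) - 1 - n)
  Fs <- stats::fft(s)
  nsh_tot <- length(shifts)
  # shifted copies: s_t(x) ~ s(x - t)
  sh <- matrix(0, n, nsh_tot)
  for (k in seq_len(nsh_tot)) {
    ph <- exp(-2i * pi * f * shifts[k] / n)
    sh[, k] <- Re(stats::fft(Fs * ph, inverse = TRUE)) / n
  }
  d <- abs(sh[-1, , drop = FALSE] - sh[-n, , drop = FALSE])  # d[i,] = |s(i+1)-s(i)|
  oscR <- matrix(0, n, nsh_tot)
  oscL <- matrix(0, n, nsh_tot)
  for (j in 1:nb) {
    ir <- pmin(seq_len(n) + j, n - 1L)       # |s(x+j+1) - s(x+j)|
    il <- pmax(seq_len(n) - j - 1L, 1L)      # |s(x-j) - s(x-j-1)|
    oscR <- oscR + d[ir, , drop = FALSE]
    oscL <- oscL + d[il, , drop = FALSE]
  }
  osc <- pmin(oscR, oscL)
  pick <- max.col(-osc, ties.method = "first")
  t_opt <- shifts[pick]
  v0 <- sh[cbind(seq_len(n), pick)]
  vp <- sh[cbind(pmin(seq_len(n) + 1L, n), pick)]
  vm <- sh[cbind(pmax(seq_len(n) - 1L, 1L), pick)]
  # the voxel-centre value sits between shifted samples: linear interpolation
  ifelse(t_opt >= 0, (1 - t_opt) * v0 + t_opt * vp,
         (1 + t_opt) * v0 - t_opt * vm)
}
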