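# Fixture builders shared across the suite. Everything is generated in code;
# no binary files are stored.

# two-shell scheme with the icosahedral 6-direction set
two_shell_scheme <- function(bvals = c(200, 1000)) {
  dirs <- make_direction_set(6)
  b <- rep(bvals, each = nrow(dirs))
  g <- dirs[rep(seq_len(nrow(dirs)), length(bvals)), ]
  gradient_scheme(b, g)
}

# noiseless single-tensor dataset on a tiny grid
tensor_dataset <- function(D, scheme = two_shell_scheme(), s0 = 1000,
                           grid = c(2, 2, 1)) {
  bd <- build_design_matrix(scheme)
  beta <- c(log(s0), D[1, 1], D[2, 2], D[3, 3], D[1, 2], D[1, 3], D[2, 3])
  s <- exp(drop(bd %*% beta))
  arr <- array(rep(s, each = prod(grid)), c(grid, length(s)))
  dwi_dataset(arr, scheme)
}

# symmetric 3x3 from a 6-vector (Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
sym3 <- function(d) {
  matrix(c(d[1], d[4], d[5],
           d[4], d[2], d[6],
           d[5], d[6], d[3]), 3, 3)
}

# random positive-definite diffusion-scale tensor
random_pd_tensor <- function() {
  A <- matrix(stats::rnorm(9), 3, 3)
  S <- crossprod(A) + diag(3) * 0.5
  S / max(abs(S)) * 1.5e-3
}

# eigenvalue oracle: roots of the characteristic polynomial
eig_poly_oracle <- function(A) {
  cp <- c(-det(A),
          A[1, 1] * A[2, 2] + A[1, 1] * A[3, 3] + A[2, 2] * A[3, 3] -
            A[1, 2]^2 - A[1, 3]^2 - A[2, 3]^2,
          -(A[1, 1] + A[2, 2] + A[3, 3]),
          1)
  sort(Re(polyroot(cp)), decreasing = TRUE)
}

# small spec used in pipeline-level tests: study acquisition conditions on a
# desk-scale grid
small_spec <- function(...) {
  phantom_spec(grid = c(24L, 24L, 6L), ...)
}
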