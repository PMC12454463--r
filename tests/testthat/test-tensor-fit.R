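test_that("design matrix maps the tensor parameters to log-signal", {
  sch <- gradient_scheme(1000, matrix(c(1, 0, 0), 1, 3), averages = 1)
  # a single-volume scheme is rank-deficient, so build the full matrix by hand
  expect_error(build_design_matrix(sch), "insufficient directions")

  sch2 <- two_shell_scheme()
  X <- build_design_matrix(sch2)
  expect_equal(dim(X), c(12L, 7L))
  expect_equal(qr(X)$rank, 7L)
  i <- which(sch2$bvals == 1000)[1]
  g <- sch2$bvecs[i, ]
  expect_equal(unname(X[i, ]),
               c(1, -1000 * g[1]^2, -1000 * g[2]^2, -1000 * g[3]^2,
                 -2000 * g[1] * g[2], -2000 * g[1] * g[3], -2000 * g[2] * g[3]))

  # axis-aligned direction gives the canonical row (two shells: a single
  # shell leaves the intercept collinear with the squared-direction columns)
  dirs7 <- rbind(diag(3), make_direction_set(6)[c(1, 3, 5), ])
  sch3 <- gradient_scheme(rep(c(200, 1000), each = 6),
                          dirs7[rep(1:6, 2), ])
  X3 <- build_design_matrix(sch3)
  expect_equal(qr(X3)$rank, 7L)
  expect_equal(unname(X3[7, ]), c(1, -1000, 0, 0, 0, 0, 0))

  # 3 directions on one shell under-determine the tensor
  sch4 <- gradient_scheme(rep(1000, 3), diag(3))
  expect_error(build_design_matrix(sch4), "insufficient directions")
  # any single-shell scheme is rank-deficient, whatever the direction count
  sch5 <- gradient_scheme(rep(1000, 16), make_direction_set(16))
  expect_error(build_design_matrix(sch5), "insufficient directions")

  # b = 0 volumes contribute intercept-only rows
  X0 <- build_design_matrix(gradient_scheme(c(0, rep(c(200, 1000), each = 6)),
                                            rbind(0, make_direction_set(6)[rep(1:6, 2), ])))
  expect_equal(unname(X0[1, ]), c(1, 0, 0, 0, 0, 0, 0))
})

test_that("noiseless tensors are recovered exactly by the WLS fit", {
  D <- diag(c(1.3e-3, 0.85e-3, 0.85e-3))
  ds <- tensor_dataset(D)
  tf <- fit_dti_wls(ds)
  expect_equal(tf$D[1, 1, 1, ], c(1.3e-3, 0.85e-3, 0.85e-3, 0, 0, 0),
               tolerance = 1e-9)
  expect_equal(tf$eigvals[1, 1, 1, 1], 1.3e-3, tolerance = 1e-9)
  expect_equal(exp(tf$log_s0[1, 1, 1]), 1000, tolerance = 1e-9)

  # isotropic decay: all eigenvalues equal
  iso <- tensor_dataset(diag(rep(1e-3, 3)))
  tfi <- fit_dti_wls(iso)
  expect_equal(tfi$eigvals[1, 1, 1, ], rep(1e-3, 3), tolerance = 1e-9)
})

test_that("with equal weights the fit reduces to ordinary least squares", {
  set.seed(11)
  sch <- two_shell_scheme()
  X <- build_design_matrix(sch)
  beta <- c(log(1000), 1.2e-3, 0.9e-3, 0.8e-3, 1e-4, -5e-5, 2e-5)
  y <- drop(X %*% beta) + stats::rnorm(nrow(X), 0, 0.05)
  arr <- array(rep(exp(y), each = 1), c(1, 1, 1, length(y)))
  ds <- dwi_dataset(arr, sch)
  tf0 <- fit_dti_wls(ds, n_passes = 0L)   # OLS only
  ols <- stats::lm.fit(X, y)$coefficients
  expect_equal(c(tf0$log_s0[1, 1, 1], tf0$D[1, 1, 1, ]), unname(ols),
               tolerance = 1e-9)
})

test_that("all-zero voxel series yields NaN instead of failing", {
  sch <- two_shell_scheme()
  arr <- array(0, c(2, 1, 1, 12))
  arr[1, 1, 1, ] <- 1000 * exp(-sch$bvals * 1e-3)
  ds <- dwi_dataset(arr, sch)
  tf <- fit_dti_wls(ds)
  expect_true(all(is.nan(tf$D[2, 1, 1, ])))
  expect_equal(tf$eigvals[1, 1, 1, ], rep(1e-3, 3), tolerance = 1e-9)
})

test_that("eigen-decomposition matches a characteristic-polynomial oracle", {
  expect_equal(tensor_field(matrix(c(3e-3, 2e-3, 1e-3, 0, 0, 0), 1, 6))$
                 eigvals[1, 1, 1, ], c(3e-3, 2e-3, 1e-3))
  set.seed(21)
  for (i in 1:20) {
    A <- random_pd_tensor() - diag(3) * stats::runif(1, 0, 5e-4)
    tf <- tensor_field(matrix(c(A[1, 1], A[2, 2], A[3, 3],
                                A[1, 2], A[1, 3], A[2, 3]), 1, 6))
    expect_equal(tf$eigvals[1, 1, 1, ], eig_poly_oracle(A), tolerance = 1e-10)
    # reconstruction and orthonormality invariants
    V <- tf$eigvecs[1, 1, 1, , ]
    expect_equal(crossprod(V), diag(3), tolerance = 1e-6)
    expect_equal(V %*% diag(tf$eigvals[1, 1, 1, ]) %*% t(V), A,
                 tolerance = 1e-9)
  }
})

test_that("eigenvalues are rotation invariant", {
  set.seed(31)
  lam <- c(1.5e-3, 0.9e-3, 0.4e-3)
  Q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  A <- Q %*% diag(lam) %*% t(Q)
  tf <- tensor_field(matrix(c(A[1, 1], A[2, 2], A[3, 3],
                              A[1, 2], A[1, 3], A[2, 3]), 1, 6))
  expect_equal(tf$eigvals[1, 1, 1, ], lam, tolerance = 1e-12)
})

test_that("scalar DTI maps follow the eigenvalue definitions", {
  mk_maps <- function(lam) {
    tf <- tensor_field(matrix(c(lam, 0, 0, 0), 1, 6))
    compute_dti_maps(tf)
  }
  iso <- mk_maps(c(1e-3, 1e-3, 1e-3))
  expect_equal(iso$md[1, 1, 1], 1e-3)
  expect_equal(iso$ad[1, 1, 1], 1e-3)
  expect_equal(iso$rd[1, 1, 1], 1e-3)
  expect_equal(iso$fa[1, 1, 1], 0)

  stick <- mk_maps(c(1, 0, 0))
  expect_equal(stick$fa[1, 1, 1], 1)

  # median axial/radial diffusivities of a healthy pancreas (x1e-3 mm^2/s)
  panc <- mk_maps(c(1.343e-3, 0.903e-3, 0.903e-3))
  expect_equal(panc$fa[1, 1, 1], 0.23742, tolerance = 1e-4)

  # MD = (AD + 2 RD)/3 and FA scale invariance over random tensors
  set.seed(41)
  for (i in 1:25) {
    lam <- sort(stats::runif(3, 0, 2e-3), decreasing = TRUE)
    m <- mk_maps(lam)
    expect_equal(m$md[1, 1, 1], (m$ad[1, 1, 1] + 2 * m$rd[1, 1, 1]) / 3,
                 tolerance = 1e-12)
    m2 <- mk_maps(lam * 7.3)
    expect_equal(m2$fa[1, 1, 1], m$fa[1, 1, 1], tolerance = 1e-12)
  }
})

test_that("WLS matches a nonlinear least-squares oracle on noiseless tensors", {
  set.seed(51)
  sch <- two_shell_scheme()
  X <- build_design_matrix(sch)
  for (i in 1:100) {
    A <- random_pd_tensor()
    beta <- c(log(1000), A[1, 1], A[2, 2], A[3, 3], A[1, 2], A[1, 3], A[2, 3])
    s <- exp(drop(X %*% beta))
    ds <- dwi_dataset(array(s, c(1, 1, 1, length(s))), sch)
    tf <- fit_dti_wls(ds)
    fitted <- c(tf$log_s0[1, 1, 1], tf$D[1, 1, 1, ])
    # independent oracle: direct nonlinear LS on the exponential model
    resid_fn <- function(b) s - exp(drop(X %*% b))
    opt <- minpack.lm::nls.lm(par = beta * (1 + 1e-2), fn = resid_fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 500, ftol = 1e-15, ptol = 1e-15))
    expect_equal(fitted, unname(opt$par), tolerance = 1e-6)
  }
})

test_that("fitting only b >= 200 suppresses an IVIM perfusion component", {
  spec0 <- phantom_spec(grid = c(16L, 16L, 2L), snr = Inf,
                        tissue = list("1" = list(ad = 1.3e-3, rd = 0.85e-3,
                                                 mk = 0, s0 = 1000)),
                        perfusion = list(f = 0, dstar = 20e-3))
  specf <- phantom_spec(grid = c(16L, 16L, 2L), snr = Inf,
                        tissue = list("1" = list(ad = 1.3e-3, rd = 0.85e-3,
                                                 mk = 0, s0 = 1000)),
                        perfusion = list(f = 0.1, dstar = 20e-3))
  md_of <- function(spec, shells) {
    sim <- simulate_dataset(spec)
    tf <- fit_dti_wls(select_shells(sim$dataset, shells))
    maps <- compute_dti_maps(tf)
    stats::median(maps$md[sim$roi$labels == 1], na.rm = TRUE)
  }
  md_clean <- md_of(spec0, c(200, 1000))
  md_perf <- md_of(specf, c(200, 1000))
  md_naive <- md_of(specf, c(0, 200, 1000))
  expect_lt(abs(md_perf / md_clean - 1), 0.02)
  expect_gt(abs(md_naive / md_clean - 1), 0.05)
})
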