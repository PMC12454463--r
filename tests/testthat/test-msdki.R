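msdki_dataset <- function(ms_by_shell, ndir = 2L, grid = c(1, 1, 1)) {
  b <- rep(as.numeric(names(ms_by_shell)), each = ndir)
  dirs <- make_direction_set(6)[seq_len(ndir), , drop = FALSE]
  g <- dirs[rep(seq_len(ndir), length(ms_by_shell)), , drop = FALSE]
  vals <- unlist(lapply(ms_by_shell, function(v) rep(v, length.out = ndir)))
  arr <- array(rep(vals, each = prod(grid)), c(grid, length(vals)))
  dwi_dataset(arr, gradient_scheme(b, g))
}

test_that("directional averaging returns per-shell mean signals", {
  ds <- msdki_dataset(list("1000" = 100), ndir = 6L)
  avg <- directional_average(ds)
  expect_equal(avg$b, 1000)
  expect_equal(avg$n_dirs, 6L)
  expect_equal(avg$ms[1, 1, 1, 1], 100)

  ds2 <- msdki_dataset(list("1000" = c(90, 110)), ndir = 2L)
  expect_equal(directional_average(ds2)$ms[1, 1, 1, 1], 100)
})

test_that("discrete 16-direction average approximates the orientation average", {
  # anisotropic tensor signal; oracle: dense spherical quadrature
  dirs <- make_direction_set(16)
  ad <- 1.3e-3; rd <- 0.85e-3; b <- 1000
  sig <- function(g) exp(-b * (rd + (ad - rd) * g[, 1]^2))
  ds <- dwi_dataset(array(sig(dirs), c(1, 1, 1, 16)),
                    gradient_scheme(rep(b, 16), dirs))
  ms <- directional_average(ds)$ms[1, 1, 1, 1]
  n <- 10000
  i <- seq_len(n)
  z <- (2 * i - 1) / n - 1
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  quad <- cbind(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  oracle <- mean(sig(quad))
  expect_equal(ms, oracle, tolerance = 0.01)
})

test_that("three-shell mean-signal DKI recovers the generating parameters", {
  s0 <- 1000; md <- 1.0e-3; mk <- 0.66
  tb <- c(200, 1000, 1700)
  ms <- s0 * exp(-tb * md + tb^2 * md^2 * mk / 6)
  # sanity on the forward model itself
  expect_equal(ms, c(822.3, 410.7, 251.1), tolerance = 1e-3)
  ds <- msdki_dataset(as.list(stats::setNames(ms, tb)))
  fit <- fit_msdki(directional_average(ds))
  expect_equal(fit$md[1, 1, 1], md, tolerance = 1e-12)
  expect_equal(fit$mk[1, 1, 1], mk, tolerance = 1e-12)
  expect_equal(fit$s0_msdki[1, 1, 1], s0, tolerance = 1e-9)
})

test_that("monoexponential signals yield zero kurtosis", {
  tb <- c(200, 1000, 1700)
  ms <- 800 * exp(-tb * 1e-3)
  ds <- msdki_dataset(as.list(stats::setNames(ms, tb)))
  fit <- fit_msdki(directional_average(ds))
  expect_lt(abs(fit$mk[1, 1, 1]), 1e-9)
})

test_that("pathological signals are flagged as NaN kurtosis", {
  # signal increasing with b implies negative MD
  ds <- msdki_dataset(list("200" = 100, "1000" = 150, "1700" = 220))
  fit <- fit_msdki(directional_average(ds))
  expect_true(fit$md[1, 1, 1] < 0)
  expect_true(is.nan(fit$mk[1, 1, 1]))

  expect_error(fit_msdki(directional_average(
    msdki_dataset(list("200" = 100, "1000" = 50)))), "3 nonzero shells")
})

test_that("mean-signal fit is invariant to global scaling", {
  s0 <- 1000; md <- 0.9e-3; mk <- 0.8
  tb <- c(200, 1000, 1700)
  ms <- s0 * exp(-tb * md + tb^2 * md^2 * mk / 6)
  f1 <- fit_msdki(directional_average(msdki_dataset(as.list(stats::setNames(ms, tb)))))
  f2 <- fit_msdki(directional_average(msdki_dataset(as.list(stats::setNames(5 * ms, tb)))))
  expect_equal(f2$md[1, 1, 1], f1$md[1, 1, 1], tolerance = 1e-12)
  expect_equal(f2$mk[1, 1, 1], f1$mk[1, 1, 1], tolerance = 1e-12)
  expect_equal(f2$s0_msdki[1, 1, 1], 5 * f1$s0_msdki[1, 1, 1], tolerance = 1e-9)
})

test_that("with more than three shells the weighted fit still solves the model", {
  s0 <- 1200; md <- 1.1e-3; mk <- 0.5
  tb <- c(200, 600, 1000, 1700)
  ms <- s0 * exp(-tb * md + tb^2 * md^2 * mk / 6)
  ds <- msdki_dataset(as.list(stats::setNames(ms, tb)))
  fit <- fit_msdki(directional_average(ds))
  expect_equal(fit$md[1, 1, 1], md, tolerance = 1e-8)
  expect_equal(fit$mk[1, 1, 1], mk, tolerance = 1e-6)
})

test_that("two-point ADC follows the monoexponential formula", {
  ds <- msdki_dataset(list("200" = 800, "1000" = 310))
  adc <- compute_adc(ds)
  expect_equal(adc[1, 1, 1], log(800 / 310) / 800, tolerance = 1e-12)
  expect_equal(adc[1, 1, 1], 1.185e-3, tolerance = 1e-3)

  ds0 <- msdki_dataset(list("200" = 500, "1000" = 500))
  expect_equal(compute_adc(ds0)[1, 1, 1], 0)

  d <- 1.2e-3
  ds2 <- msdki_dataset(list("200" = 1000 * exp(-200 * d),
                            "1000" = 1000 * exp(-1000 * d)))
  expect_equal(compute_adc(ds2)[1, 1, 1], d, tolerance = 1e-12)

  # non-positive signal propagates NaN
  ds3 <- msdki_dataset(list("200" = 0, "1000" = 10))
  expect_true(is.nan(compute_adc(ds3)[1, 1, 1]))
})

test_that("DTI-MD, mean-signal MD and ADC agree on an isotropic Gaussian phantom", {
  spec <- phantom_spec(grid = c(12L, 12L, 2L), snr = Inf,
                       tissue = list("1" = list(ad = 1e-3, rd = 1e-3,
                                                mk = 0, s0 = 1000)))
  sim <- simulate_dataset(spec)
  roi <- sim$roi$labels == 1
  tf <- fit_dti_wls(select_shells(sim$dataset, c(200, 1000)))
  md_dti <- compute_dti_maps(tf)$md
  kur <- fit_msdki(directional_average(select_shells(sim$dataset,
                                                     c(200, 1000, 1700))))
  adc <- compute_adc(sim$dataset)
  expect_equal(md_dti[roi], rep(1e-3, sum(roi)), tolerance = 1e-9)
  expect_equal(kur$md[roi], rep(1e-3, sum(roi)), tolerance = 1e-9)
  expect_equal(adc[roi], rep(1e-3, sum(roi)), tolerance = 1e-9)
})

test_that("MK precision scales inversely with SNR", {
  # Monte-Carlo spread of fitted MK at fixed truth, three SNR levels
  sd_at <- function(snr, seed) {
    r <- snr_scaling_experiment(snr_base = snr, thickness_ratio = 1.001,
                                n_voxels = 30000L, seed = seed)
    r$sd_mk_base
  }
  sds <- vapply(c(20, 30, 50), sd_at, 0, seed = 123L)
  scaled <- sds * c(20, 30, 50)
  expect_lt(max(scaled) / min(scaled) - 1, 0.10)
})
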