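fold_angles <- function(g) {
  ang <- acos(pmin(abs(g %*% t(g)), 1)) * 180 / pi
  diag(ang) <- Inf
  ang
}

test_that("direction sets are unit, even and antipodally separated", {
  g6 <- make_direction_set(6)
  expect_equal(unname(sqrt(rowSums(g6^2))), rep(1, 6))
  expect_equal(min(fold_angles(g6)), 63.43495, tolerance = 1e-4)

  g16 <- make_direction_set(16)
  expect_equal(unname(sqrt(rowSums(g16^2))), rep(1, 16), tolerance = 1e-9)
  expect_gt(min(fold_angles(g16)), 25)
  # deterministic
  expect_equal(make_direction_set(16), g16)

  expect_error(make_direction_set(5), "6 directions")
})

test_that("the phantom delivers the declared acquisition layout", {
  spec <- small_spec(snr = Inf)
  sim <- simulate_dataset(spec)
  ndir <- 6L
  expect_equal(dim(sim$dataset$signal)[4], 1L + 3L * ndir)
  expect_equal(sim$dataset$scheme$shells, c(200, 1000, 1700))
  expect_equal(sort(unique(sim$dataset$scheme$averages)), c(1L, 2L, 4L, 5L))
  expect_equal(dim(sim$roi$labels), spec$grid)
  expect_gt(sum(sim$roi$labels == 1L), 20)
  expect_gt(sum(sim$roi$labels == 2L), sum(sim$roi$labels == 1L))

  spec16 <- small_spec(protocol = "16dir", snr = Inf)
  expect_equal(dim(simulate_dataset(spec16)$dataset$signal)[4], 1L + 3L * 16L)
})

test_that("a noiseless Gaussian phantom is recovered exactly end to end", {
  spec <- small_spec(snr = Inf,
                     tissue = list("1" = list(ad = 1.3e-3, rd = 0.85e-3,
                                              mk = 0, s0 = 1000),
                                   "2" = list(ad = 1.1e-3, rd = 1.0e-3,
                                              mk = 0, s0 = 800)))
  sim <- simulate_dataset(spec)
  roi <- sim$roi$labels == 1
  cfg <- pipeline_config(input = spec, preprocess = list(enabled = FALSE))
  fit <- fit_acquisition(sim$dataset, cfg)
  for (m in c("md", "ad", "rd", "fa")) {
    expect_equal(fit$maps[[m]][roi], sim$truth[[m]][roi], tolerance = 1e-9)
  }
  expect_equal(fit$maps$mk[roi], sim$truth$mk_msdki[roi], tolerance = 1e-9)
  expect_equal(fit$maps$adc[roi], sim$truth$adc[roi], tolerance = 1e-9)
})

test_that("air voxels sit at the Rician noise floor", {
  spec <- phantom_spec(grid = c(32L, 32L, 6L), snr = 30)
  sim <- simulate_dataset(spec)
  air <- sim$roi$labels == 0L
  sigma <- spec$tissue[["1"]]$s0 / spec$snr
  b0 <- sim$dataset$signal[, , , 1]
  expect_equal(mean(b0[air]), sigma * sqrt(pi / 2), tolerance = 0.02)
})

test_that("repeats share the noiseless component and differ only by noise", {
  spec <- small_spec(snr = 30)
  clean <- simulate_dataset(small_spec(snr = Inf))$dataset$signal
  r1 <- simulate_dataset(spec, subject = 1, repeat_idx = 1)$dataset$signal
  r2 <- simulate_dataset(spec, subject = 1, repeat_idx = 2)$dataset$signal
  # compare noise residuals over tissue voxels, where the Rician bias is
  # negligible and cannot induce shared spatial structure
  tissue <- simulate_dataset(small_spec(snr = Inf))$roi$labels > 0L
  n1 <- apply(r1 - clean, 4, function(x) x[tissue])
  n2 <- apply(r2 - clean, 4, function(x) x[tissue])
  expect_false(identical(r1, r2))
  expect_lt(abs(stats::cor(as.vector(n1), as.vector(n2))), 0.05)
  # determinism: same subject/repeat regenerates bit-identical data
  r1b <- simulate_dataset(spec, subject = 1, repeat_idx = 1)$dataset$signal
  expect_identical(r1, r1b)
})

test_that("between-subject variability is deterministic per subject", {
  spec <- phantom_spec(grid = c(12L, 12L, 2L), snr = Inf, subject_cv = 0.1)
  s1r1 <- simulate_dataset(spec, subject = 1, repeat_idx = 1)
  s1r2 <- simulate_dataset(spec, subject = 1, repeat_idx = 2)
  s2 <- simulate_dataset(spec, subject = 2)
  roi <- s1r1$roi$labels == 1L
  # repeats of a subject share its tissue parameters exactly
  expect_identical(s1r1$dataset$signal, s1r2$dataset$signal)
  # different subjects have different truth
  expect_false(isTRUE(all.equal(s1r1$truth$md[roi], s2$truth$md[roi])))
  # cv = 0 restores identical subjects
  spec0 <- phantom_spec(grid = c(12L, 12L, 2L), snr = Inf)
  expect_identical(simulate_dataset(spec0, subject = 1)$dataset$signal,
                   simulate_dataset(spec0, subject = 2)$dataset$signal)
})

test_that("doubling signal averages shrinks effective noise by sqrt(2)", {
  base <- phantom_spec(grid = c(32L, 32L, 6L), snr = 30,
                       averages = c("0" = 1, "200" = 2, "1000" = 4, "1700" = 5))
  dbl <- phantom_spec(grid = c(32L, 32L, 6L), snr = 30,
                      averages = c("0" = 1, "200" = 2, "1000" = 8, "1700" = 5))
  clean <- simulate_dataset(phantom_spec(grid = c(32L, 32L, 6L), snr = Inf))
  tissue <- clean$roi$labels > 0L
  vol <- shell_volumes(clean$dataset$scheme, 1000)[1]
  resid <- function(spec, seed_subj) {
    s <- simulate_dataset(spec, subject = seed_subj)$dataset$signal[, , , vol]
    s[tissue] - clean$dataset$signal[, , , vol][tissue]
  }
  sd_base <- stats::sd(resid(base, 1))
  sd_dbl <- stats::sd(resid(dbl, 2))
  expect_equal(sd_base / sd_dbl, sqrt(2), tolerance = 0.05)
})

test_that("the study tree on disk is manifest-consistent and deterministic", {
  td <- withr::local_tempdir()
  spec <- phantom_spec(grid = c(12L, 12L, 6L), n_subjects = 2L, n_repeats = 2L,
                       snr = 30)
  man <- simulate_repeatability_study(spec, file.path(td, "study"))
  man <- utils::read.csv(file.path(td, "study", "manifest.csv"))
  expect_equal(nrow(man), 4L)
  expect_equal(unique(man$n_volumes), 19L)
  for (i in seq_len(nrow(man))) {
    ds <- read_dwi(file.path(td, "study", man$dwi[i]),
                   file.path(td, "study", man$bval[i]),
                   file.path(td, "study", man$bvec[i]))
    expect_equal(dim(ds$signal)[4], man$n_volumes[i])
    expect_equal(ds$scheme$shells, c(200, 1000, 1700))
    roi <- read_scalar_map(file.path(td, "study", man$roi[i]))
    expect_equal(dim(roi), spec$grid)
  }

  # refusal on existing non-empty output without overwrite
  expect_error(simulate_repeatability_study(spec, file.path(td, "study")),
               "refusing")

  # same master seed regenerates identical content
  simulate_repeatability_study(spec, file.path(td, "study2"))
  a <- read_scalar_map(file.path(td, "study", man$dwi[1]))
  b <- read_scalar_map(file.path(td, "study2", man$dwi[1]))
  expect_identical(a, b)

  one <- phantom_spec(grid = c(12L, 12L, 6L), n_subjects = 1L, n_repeats = 1L)
  man1 <- simulate_repeatability_study(one, file.path(td, "single"))
  expect_equal(nrow(man1), 1L)
})

test_that("the SNR scaling experiment reports the closed-form gain", {
  res <- snr_scaling_experiment(snr_base = 30, thickness_ratio = 5 / 3,
                                n_voxels = 2000L, seed = 4L)
  expect_equal(res$snr_scaled / res$snr_base, 5 / 3, tolerance = 1e-12)
  expect_equal(res$theoretical_reduction, 40)

  same <- snr_scaling_experiment(thickness_ratio = 1, n_voxels = 5000L,
                                 seed = 2L)
  expect_lt(abs(same$percent_reduction), 5)

  dbl <- snr_scaling_experiment(thickness_ratio = 2, n_voxels = 10000L,
                                seed = 3L)
  expect_equal(dbl$sd_mk_scaled / dbl$sd_mk_base, 0.5, tolerance = 0.10)

  expect_error(snr_scaling_experiment(n_voxels = 10), ">= 1000")
  expect_error(snr_scaling_experiment(thickness_ratio = -1), "positive")
})
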