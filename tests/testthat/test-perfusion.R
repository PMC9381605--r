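test_that("gamma-variate curve has the analytic onset, peak and linearity", {
  aif <- aif_model(t0 = 2, alpha = 2, beta = 1.5, amplitude = 100)
  t <- seq(0, 40, by = 0.01)
  y <- gamma_variate(aif, t)
  expect_equal(y[t <= 2], rep(0, sum(t <= 2)))
  # peak at t0 + alpha * beta
  expect_equal(t[which.max(y)], 2 + 2 * 1.5, tolerance = 0.02)
  y2 <- gamma_variate(aif_model(2, 2, 1.5, 200), t)
  expect_equal(y2, 2 * y)
  expect_error(aif_model(alpha = -1), "positive")
})

test_that("simulated series is zero without flow and scales linearly with CBF", {
  tissue <- uniform_core_tissue()
  spec0 <- uniform_core_spec(cbf = 30, mtt = 8, ttp = 10)
  spec0$tissue_params$mean[spec0$tissue_params$parameter == "cbf"] <- c(2, 1, 0)
  series0 <- simulate_ctp(tissue, spec0)   # core CBF = 0, noise-free
  core_vox <- which(tissue$labels == 3L)[1]
  idx <- arrayInd(core_vox, dim(tissue$labels))
  expect_equal(series0$data[idx[1], idx[2], idx[3], ], rep(0, length(series0$times)))

  s1 <- simulate_ctp(tissue, uniform_core_spec(cbf = 20, mtt = 8, ttp = 10))
  s2 <- simulate_ctp(tissue, uniform_core_spec(cbf = 40, mtt = 8, ttp = 10))
  c1 <- s1$data[idx[1], idx[2], idx[3], ]
  c2 <- s2$data[idx[1], idx[2], idx[3], ]
  expect_equal(max(c2), 2 * max(c1), tolerance = 1e-10)
})

test_that("tissue curve area over AIF area is proportional to CBV", {
  tissue <- uniform_core_tissue()
  dt <- 2
  for (cbv_target in c(1, 2)) {
    mtt <- 8
    cbf <- cbv_target * 60 / mtt
    s <- simulate_ctp(tissue, uniform_core_spec(cbf = cbf, mtt = mtt, ttp = 10))
    core_vox <- arrayInd(which(tissue$labels == 3L)[1], dim(tissue$labels))
    curve <- s$data[core_vox[1], core_vox[2], core_vox[3], ]
    tz <- function(y) dt * (sum(y) - (y[1] + y[length(y)]) / 2)
    ratio <- (0.73 / 1.05) * 100 * tz(curve) / tz(s$aif_curve)
    expect_equal(ratio, cbv_target, tolerance = 0.05)
  }
})

test_that("non-uniform sampling times are rejected", {
  tissue <- uniform_core_tissue()
  spec <- uniform_core_spec(cbf = 30, mtt = 8, ttp = 10)
  expect_error(simulate_ctp(tissue, spec, times = c(0, 2, 5, 6)), "uniform")
})

test_that("deconvolution recovers CBF, CBV and TTP on noise-free phantoms", {
  for (cbf in c(10, 60)) for (mtt in c(4, 12)) {
    tissue <- uniform_core_tissue()
    spec <- uniform_core_spec(cbf = cbf, mtt = mtt, ttp = 12)
    series <- simulate_ctp(tissue, spec)
    maps <- bsvd_deconvolve(series, mask = tissue$labels != 0L)
    core <- tissue$labels == 3L
    expect_lt(abs(median(maps$cbf[core]) - cbf) / cbf, 0.10)
    cbv_true <- cbf * mtt / 60
    expect_lt(abs(median(maps$cbv[core]) - cbv_true) / cbv_true, 0.10)
    expect_lte(abs(median(maps$ttp[core]) - 12), 2)
    # central-volume consistency of the jointly produced maps
    nz <- maps$mask & maps$cbf > 0
    expect_equal(maps$mtt[nz], maps$cbv[nz] / maps$cbf[nz] * 60,
                 tolerance = 1e-6)
  }
})

test_that("recovered CBF preserves the true ordering and scales linearly", {
  tissue <- uniform_core_tissue()
  recovered <- vapply(c(10, 30, 60), function(cbf) {
    s <- simulate_ctp(tissue, uniform_core_spec(cbf = cbf, mtt = 8, ttp = 10))
    m <- bsvd_deconvolve(s, mask = tissue$labels != 0L)
    median(m$cbf[tissue$labels == 3L])
  }, numeric(1))
  expect_true(all(diff(recovered) > 0))
  expect_equal(recovered[3] / recovered[1], 6, tolerance = 0.02)
})

test_that("zero tissue signal yields zero maps with a flat-voxel flag", {
  times <- seq(0, 48, by = 2)
  aif <- gamma_variate(aif_model(), times)
  data <- array(0, dim = c(2, 2, 1, length(times)))
  data[1, 1, 1, ] <- aif
  series <- ctp_series(data, times, aif, c(1L, 1L, 1L), c(1, 1, 1))
  maps <- bsvd_deconvolve(series)
  expect_true(all(maps$cbf[maps$mask] == 0))
  expect_true(all(maps$mtt[maps$mask] == 0))
  expect_gt(length(attr(maps, "flat_voxels")), 0)

  zero_series <- ctp_series(array(0, dim = c(2, 2, 1, length(times))),
                            times, rep(0, length(times)), c(1L, 1L, 1L),
                            c(1, 1, 1))
  expect_error(bsvd_deconvolve(zero_series), "zero")
})

test_that("truncation fraction is validated and controls residue roughness", {
  tissue <- uniform_core_tissue()
  spec <- uniform_core_spec(cbf = 30, mtt = 8, ttp = 10, noise_sd = 2)
  series <- simulate_ctp(tissue, spec, seed = 21)
  expect_error(deconv_settings(svd_truncation_fraction = 0), "0, 1")
  expect_error(deconv_settings(svd_truncation_fraction = 1.2), "0, 1")

  # total variation of the recovered residue never rises with truncation
  dt <- 2
  core <- arrayInd(which(tissue$labels == 3L)[1], dim(tissue$labels))
  curve <- series$data[core[1], core[2], core[3], ]
  tv <- vapply(c(0.02, 0.1, 0.3), function(frac) {
    k <- ctprob:::circulant_pseudoinverse(series$aif_curve, dt, frac) %*%
      c(curve, numeric(length(curve)))
    sum(abs(diff(as.numeric(k))))
  }, numeric(1))
  expect_true(all(diff(tv) <= 1e-9))
})

test_that("deconvolution is linear in the tissue signal", {
  tissue <- uniform_core_tissue()
  spec <- uniform_core_spec(cbf = 25, mtt = 6, ttp = 8)
  series <- simulate_ctp(tissue, spec)
  m1 <- bsvd_deconvolve(series, mask = tissue$labels != 0L)
  series3 <- series
  av <- series$aif_voxel
  aif_curve <- series$data[av[1], av[2], av[3], ]
  series3$data <- series$data * 3
  series3$data[av[1], av[2], av[3], ] <- aif_curve  # AIF unscaled
  m3 <- bsvd_deconvolve(series3, mask = tissue$labels != 0L)
  core <- tissue$labels == 3L
  expect_equal(m3$cbf[core], 3 * m1$cbf[core], tolerance = 1e-8)
  expect_equal(m3$cbv[core], 3 * m1$cbv[core], tolerance = 1e-8)
})

test_that("CBV from curve areas matches the direct ratio and shift invariance", {
  times <- seq(0, 48, by = 2)
  aif_curve <- gamma_variate(aif_model(), times)
  data <- array(0, dim = c(1, 2, 1, length(times)))
  data[1, 2, 1, ] <- 0.02 * aif_curve
  data[1, 1, 1, ] <- aif_curve
  series <- ctp_series(data, times, aif_curve, c(1L, 1L, 1L), c(1, 1, 1))
  cbv <- compute_cbv(series)
  expect_equal(cbv[1, 2, 1], 0.02 * (0.73 / 1.05) * 100, tolerance = 1e-10)

  # shifting the shared time axis changes nothing
  series_shift <- ctp_series(data, times + 7, aif_curve, c(1L, 1L, 1L), c(1, 1, 1))
  expect_equal(compute_cbv(series_shift), cbv)
})

test_that("TTP is the earliest argmax in seconds", {
  times <- seq(0, 48, by = 2)
  data <- array(0, dim = c(1, 3, 1, length(times)))
  data[1, 1, 1, 11] <- 5                      # single peak at sample 11 (t = 20 s)
  data[1, 2, 1, c(6, 9)] <- c(7, 7)           # tie: earlier sample wins
  series <- ctp_series(data, times, gamma_variate(aif_model(), times),
                       c(1L, 3L, 1L), c(1, 1, 1))
  ttp <- compute_ttp(series)
  expect_equal(ttp[1, 1, 1], 20)
  expect_equal(ttp[1, 2, 1], 10)
  expect_equal(ttp[1, 3, 1], 0)               # flat curve: first sample, flagged
  expect_true(length(attr(ttp, "flat_voxels")) >= 1)
})
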