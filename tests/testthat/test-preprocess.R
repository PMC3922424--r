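test_that("nuisance extraction is the per-volume mask mean", {
  set.seed(7)
  data <- array(rnorm(4 * 4 * 2 * 9), c(4, 4, 2, 9))
  run <- tiny_run(data)
  one <- array(FALSE, c(4, 4, 2)); one[2, 3, 1] <- TRUE
  nu <- extract_nuisance(run, list(csf = one))
  expect_equal(nu$csf, data[2, 3, 1, ])

  # two voxels holding s and -s cancel to zero
  data2 <- array(0, c(4, 4, 2, 9))
  s <- rnorm(9)
  data2[1, 1, 1, ] <- s
  data2[2, 1, 1, ] <- -s
  two <- array(FALSE, c(4, 4, 2)); two[1:2, 1, 1] <- TRUE
  nu2 <- extract_nuisance(tiny_run(data2), list(wm = two))
  expect_equal(nu2$wm, rep(0, 9))

  # random 10-voxel mask matches an independent recomputation
  msk <- array(FALSE, c(4, 4, 2))
  msk[sample(length(msk), 10)] <- TRUE
  nu3 <- extract_nuisance(run, list(soft_tissue = msk))
  manual <- sapply(seq_len(9), function(t) mean(data[, , , t][msk]))
  expect_equal(nu3$soft_tissue, manual)

  expect_error(extract_nuisance(run, list(csf = array(FALSE, c(4, 4, 2)))),
               "csf")
})

test_that("confound regression produces orthogonal residuals", {
  set.seed(13)
  nt <- 40
  nuis <- matrix(rnorm(nt * 3), nt, 3)
  motion <- matrix(rnorm(nt * 6, sd = 0.01), nt, 6)
  data <- array(rnorm(2 * 2 * 1 * nt), c(2, 2, 1, nt))
  data[1, 1, 1, ] <- nuis[, 1]               # exactly the CSF regressor
  data[2, 1, 1, ] <- 2 * nuis[, 2] + rnorm(nt)
  run <- tiny_run(data, motion = motion, nuisance = nuis)
  out <- regress_confounds(run)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-10)
  expect_lt(abs(cor(out$data[2, 1, 1, ], nuis[, 2])), 1e-10)
  # residuals orthogonal to every regressor at every voxel
  X <- cbind(1, nuis, motion)
  res <- matrix(out$data, 4, nt)
  expect_lt(max(abs(res %*% X)), 1e-8)
})

test_that("regression with null confounds demeans, and is idempotent", {
  set.seed(17)
  nt <- 30
  data <- array(rnorm(8 * nt, mean = 50), c(2, 2, 2, nt))
  run <- tiny_run(data, nuisance = matrix(0, nt, 3))
  out <- suppressWarnings(regress_confounds(run))
  manual <- apply(data, 1:3, function(x) x - mean(x))
  expect_equal(out$data, aperm(manual, c(2, 3, 4, 1)))
  twice <- suppressWarnings(regress_confounds(out))
  expect_equal(twice$data, out$data, tolerance = 1e-8)
})

test_that("rank-deficient designs are reported, not fatal", {
  set.seed(19)
  nt <- 30
  nuis <- matrix(rnorm(nt * 3), nt, 3)
  motion <- matrix(0, nt, 6)  # six constant columns duplicate the intercept
  run <- tiny_run(array(rnorm(8 * nt), c(2, 2, 2, nt)),
                  motion = motion, nuisance = nuis)
  expect_warning(regress_confounds(run), "rank-deficient")
  expect_error(regress_confounds(
    tiny_run(array(rnorm(8 * 5), c(2, 2, 2, 5)),
             motion = matrix(0, 5, 6), nuisance = matrix(0, 5, 3))
  ), "10")
})

test_that("bandpass+detrend removes ramps and keeps in-band sinusoids", {
  nt <- 100
  ramp <- 3 + 0.5 * seq_len(nt)
  run <- tiny_run(array(rep(ramp, each = 8), c(2, 2, 2, nt)), tr = 2)
  out <- bandpass_detrend(run)
  expect_lt(max(abs(out$data)) / (0.5 * nt), 1e-6)

  tr <- 2
  t_sec <- (seq_len(nt) - 1) * tr
  inband <- sin(2 * pi * 0.05 * t_sec)        # 0.05 Hz, TR 2 s: kept
  run_in <- tiny_run(array(rep(inband, each = 8), c(2, 2, 2, nt)), tr = tr)
  out_in <- bandpass_detrend(run_in)
  amp <- (max(out_in$data[1, 1, 1, ]) - min(out_in$data[1, 1, 1, ])) / 2
  expect_gt(amp, 0.95)
  expect_lt(amp, 1.05)

  nt1 <- 200
  t1 <- (seq_len(nt1) - 1) * 1
  outband <- sin(2 * pi * 0.3 * t1)           # 0.3 Hz, TR 1 s: stopped
  run_out <- tiny_run(array(rep(outband, each = 8), c(2, 2, 2, nt1)),
                      tr = 1)
  out_out <- bandpass_detrend(run_out)
  expect_lt(max(abs(out_out$data)), 0.1)

  expect_error(bandpass_detrend(run, high_hz = 0.3), "Nyquist")
})

test_that("the filter is linear", {
  set.seed(23)
  nt <- 60
  x <- array(rnorm(8 * nt), c(2, 2, 2, nt))
  y <- array(rnorm(8 * nt), c(2, 2, 2, nt))
  fx <- bandpass_detrend(tiny_run(x))$data
  fy <- bandpass_detrend(tiny_run(y))$data
  fxy <- bandpass_detrend(tiny_run(2 * x - 3 * y))$data
  expect_equal(fxy, 2 * fx - 3 * fy, tolerance = 1e-10)
})

test_that("framewise displacement follows the sum-of-differences formula", {
  mp <- matrix(0, 10, 6)
  expect_equal(framewise_displacement(mp), rep(0, 10))

  mp2 <- matrix(0, 10, 6)
  mp2[5:10, 2] <- 0.2                 # one 0.2 mm translation step
  fd <- framewise_displacement(mp2)
  expect_equal(fd[5], 0.2)
  expect_equal(fd[-5], rep(0, 9))

  mp3 <- matrix(0, 10, 6)
  mp3[4:10, 5] <- 0.004               # rotation: 0.004 rad * 50 mm = 0.2 mm
  fd3 <- framewise_displacement(mp3)
  expect_equal(fd3[4], 0.2)

  set.seed(29)
  mp4 <- matrix(rnorm(60, sd = 0.05), 10, 6)
  expect_equal(framewise_displacement(mp4), fd_oracle(mp4))
  expect_equal(framewise_displacement(mp4, method = "rms")[3],
               {d <- mp4[3, ] - mp4[2, ]; d[4:6] <- d[4:6] * 50
                sqrt(sum(d^2))})

  mp_bad <- mp4; mp_bad[7, 2] <- NaN
  expect_error(framewise_displacement(mp_bad), "7")
})

test_that("DVARS is the percent RMS volume-to-volume change", {
  data <- array(100, c(2, 2, 2, 6))
  mask <- array(TRUE, c(2, 2, 2))
  expect_equal(dvars(tiny_run(data), mask), rep(0, 6))

  # every in-mask voxel steps by +1% of the mean at t = 5
  data2 <- array(100, c(2, 2, 2, 8))
  data2[, , , 5:8] <- data2[, , , 5:8] + 1
  dv <- dvars(tiny_run(data2), mask)
  ref <- mean(data2)
  expect_equal(dv[5], 1 / ref * 100)
  expect_equal(dv[-5], rep(0, 7))

  run <- random_run(dims = c(4, 4, 2), nt = 12, seed = 31)
  m <- matrix(run$data, 32, 12)
  expect_equal(dvars(run, array(TRUE, c(4, 4, 2))),
               dvars_oracle(m, mean(m)))

  expect_error(dvars(tiny_run(array(0, c(2, 2, 2, 4))), mask), "positive")
})

test_that("scrubbing flags the volume pair spanning each excursion", {
  run <- random_run(dims = c(2, 2, 2), nt = 5, seed = 37)
  fd0 <- rep(0, 5); dv0 <- rep(0, 5)
  sc0 <- scrub(run, fd0, dv0)
  expect_equal(sc0$result$retention_fraction, 1)
  expect_identical(sc0$run$data, run$data)

  # excursion on the transition into (1-based) volume 3
  fd <- c(0, 0, 0.5, 0, 0)
  sc <- scrub(run, fd, dv0)
  expect_identical(sc$result$kept_mask[[1]], c(TRUE, FALSE, FALSE, TRUE, TRUE))
  expect_equal(sc$result$retention_fraction, 0.6)
  expect_identical(sc$run$data, run$data[, , , c(1, 4, 5), drop = FALSE])

  # a DVARS-only excursion flags identically ("either parameter")
  sc_dv <- scrub(run, fd0, fd)
  expect_identical(sc_dv$result$kept_mask[[1]], sc$result$kept_mask[[1]])

  expect_error(scrub(run, rep(1, 5), dv0), "unusable")
})

test_that("scrubbing never increases mean FD on simulated runs", {
  atlas <- small_atlas()
  for (seed in 1:5) {
    spec <- cohort_spec(n_control = 1, n_autism = 1, grid_dims = c(8, 8, 4),
                        n_volumes = 60, seed = 500 + seed)
    co <- simulate_cohort(spec, atlas = atlas)
    for (run in co$runs) {
      pr <- preprocess_run(run, atlas)
      expect_lte(pr$qc$mean_fd_post, pr$qc$mean_fd_pre)
    }
  }
})

test_that("ROI SNR matches its definition and the plausible range", {
  const <- tiny_run(array(100, c(2, 2, 2, 10)))
  expect_warning(snr <- roi_snr(const, array(TRUE, c(2, 2, 2))), "infinite")
  expect_identical(snr, Inf)

  # ROI-mean series with mean 100 and sd 1 gives SNR 100
  series <- 100 + scale(rnorm(50))[, 1]
  data <- array(rep(series, each = 8), c(2, 2, 2, 50))
  expect_equal(roi_snr(tiny_run(data), array(TRUE, c(2, 2, 2))), 100,
               tolerance = 1e-10)

  # default-condition synthetic hubs land in the plausible 72-110 band
  atlas <- small_atlas()
  spec <- cohort_spec(n_control = 3, n_autism = 0, grid_dims = c(8, 8, 4),
                      n_volumes = 120, seed = 611)
  co <- simulate_cohort(spec, atlas = atlas)
  snrs <- sapply(co$runs, function(run) {
    mean(sapply(atlas$hubs$roi, function(r) {
      roi_snr(run, atlas$labels == r)
    }))
  })
  expect_gt(mean(snrs), 72)
  expect_lt(mean(snrs), 110)
})
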