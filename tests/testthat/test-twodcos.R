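test_that("synchronous map matches hand computation and the definition", {
  X <- matrix(c(1, 3, 2, 6), 2, 2)  # rows [1,2] and [3,6]
  expect_equal(synchronousMap(X), matrix(c(2, 4, 4, 8), 2, 2))
  expect_error(synchronousMap(X[1, , drop = FALSE]), "2")

  withr::with_seed(7, {
    for (i in 1:5) {
      R <- matrix(rnorm(6 * 9), 6, 9)
      phi <- synchronousMap(R)
      expect_lt(max(abs(phi - t(phi))), 1e-10)
      expect_gt(min(eigen(phi, symmetric = TRUE,
                          only.values = TRUE)$values), -1e-10)
    }
  })

  # an all-constant band has a zero row/column
  Xc <- cbind(c(1, 2, 3), c(5, 5, 5))
  phi <- synchronousMap(Xc)
  expect_equal(phi[2, ], c(0, 0))
  expect_equal(phi[, 2], c(0, 0))
})

test_that("maps equal the naive double-loop oracle on random matrices", {
  withr::with_seed(11, {
    for (i in 1:3) {
      R <- matrix(rnorm(6 * 9), 6, 9)
      orc <- oracleSyncAsync(R)
      expect_lt(max(abs(synchronousMap(R) - orc$sync)), 1e-10)
      # the implementation antisymmetrizes exactly; the raw oracle has the
      # same content up to that symmetrization
      expect_lt(max(abs(asynchronousMap(R) - (orc$async - t(orc$async)) / 2)),
                1e-10)
    }
  })
})

test_that("asynchronous map vanishes for rank-1 dynamics and is antisymmetric", {
  X <- matrix(c(1, 3, 2, 6), 2, 2)
  expect_lt(max(abs(asynchronousMap(X))), 1e-12)
  withr::with_seed(3, {
    R <- matrix(rnorm(40), 8, 5)
    psi <- asynchronousMap(R)
    expect_lt(max(abs(psi + t(psi))), 1e-10)
    expect_equal(diag(psi), rep(0, 5))
  })
})

test_that("phase-shifted bands follow the sequential-order sign rule", {
  theta <- 2 * pi * (0:71) / 72
  # band 2 is ahead of band 1 by a quarter cycle
  X <- cbind(sin(theta), sin(theta + pi / 2))
  psi <- asynchronousMap(X)
  expect_equal(psi[1, 2], -0.4437177, tolerance = 1e-6)
  # band 2 changes first: with Phi12 >= 0 the rule demands Psi12 < 0
  expect_lt(psi[1, 2], 0)

  # smaller lead with a nonzero synchronous cross-peak
  X2 <- cbind(sin(theta), sin(theta + pi / 3))
  phi2 <- synchronousMap(X2); psi2 <- asynchronousMap(X2)
  expect_gt(phi2[1, 2], 0)
  expect_lt(sign(phi2[1, 2]) * sign(psi2[1, 2]), 0)  # band 2 before band 1
  # reversing the lead flips the rule
  X3 <- cbind(sin(theta + pi / 3), sin(theta))
  expect_gt(sign(synchronousMap(X3)[1, 2]) * sign(asynchronousMap(X3)[1, 2]), 0)
})

test_that("two-trace maps reproduce the closed forms", {
  m <- twoTraceMaps(c(1, 0), c(0, 1), c(500, 600))
  expect_equal(syncMap(m), matrix(c(0.5, 0, 0, 0.5), 2, 2))
  expect_equal(asyncMap(m)[1, 2], 0.5)
  expect_equal(asyncMap(m)[2, 1], -0.5)

  a <- c(0.2, 0.4, 0.1)
  m2 <- twoTraceMaps(a, a, c(1, 2, 3))
  expect_equal(max(abs(asyncMap(m2))), 0)

  b <- c(0.3, 0.2, 0.5)
  m1 <- twoTraceMaps(a, b, c(1, 2, 3))
  m3 <- twoTraceMaps(3 * a, 3 * b, c(1, 2, 3))
  expect_equal(syncMap(m3), 9 * syncMap(m1))
  expect_equal(asyncMap(m3), 9 * asyncMap(m1))

  expect_error(twoTraceMaps(c(1, 2), c(1, 2, 3)), "identical grids")
})

test_that("autopeak extraction thresholds, merges and handles zero maps", {
  mkmaps <- function(d, wl) {
    new("CorrelationMaps", wavelengths = wl, sync = diag(d),
        async = matrix(0, length(d), length(d)), kind = "perturbation_2dcos")
  }
  bs <- autopeakBands(mkmaps(c(0.1, 0.9, 0.2), c(500, 510, 520)),
                      rel_threshold = 0.5)
  expect_equal(bandWavelengths(bs), 510)

  # two equal maxima 3 nm apart merge to the lower wavelength
  bs2 <- autopeakBands(mkmaps(c(0.1, 0.9, 0.1, 0.9, 0.1),
                              c(500, 503, 504, 506, 510)),
                       rel_threshold = 0.5, min_separation_nm = 5)
  expect_equal(bandWavelengths(bs2), 503)

  bs3 <- autopeakBands(mkmaps(rep(0, 4), c(1, 2, 3, 4) + 500))
  expect_length(bandWavelengths(bs3), 0)
})

test_that("autopeaks are invariant to positive scaling of the spectra", {
  ds <- makeToySet(n = 15, noise = 0.001)
  maps1 <- correlationMaps(firstDerivative(ds, "savgol", 11, 2), "trait")
  ds2 <- SpectralSet(spectra(ds) * 0.37, wavelengths(ds), sampleMeta(ds))
  maps2 <- correlationMaps(firstDerivative(ds2, "savgol", 11, 2), "trait")
  expect_identical(bandWavelengths(autopeakBands(maps1)),
                   bandWavelengths(autopeakBands(maps2)))
})

test_that("derivative-2DCOS selection finds a planted band and rejects noise", {
  ds <- makeToySet(n = 30, center = 600, noise = 0.0015, seed = 5)
  bs <- selectBands1Der2DCOS(ds, "trait", derivative_window = 11)
  # the derivative of a Gaussian dip peaks on the flanks, symmetric about
  # the centre; the selected set must bracket the planted band
  wl_sel <- bandWavelengths(bs)
  expect_true(any(wl_sel > 560 & wl_sel < 600) &&
              any(wl_sel > 600 & wl_sel < 640))

  const <- makeToySet(n = 10, trait = rep(2, 10))
  expect_error(selectBands1Der2DCOS(const, "trait"), "constant trait")
})

test_that("trait unrelated to the spectra yields no reproducible band", {
  hits <- lapply(1:10, function(s) {
    ds <- makeNoiseSet(n = 30, seed = s)
    bandWavelengths(selectBands1Der2DCOS(ds, "trait",
                                         derivative_window = 11))
  })
  common <- Reduce(intersect, hits)
  expect_length(common, 0)
})

test_that("two-stage consensus counts support with a strict majority", {
  wl <- seq(500, 700, by = 2)
  n <- 40
  mk <- function(bump600) {
    t(vapply(seq_len(n), function(i) {
      b <- rep(0.35, length(wl))  # flat background: bumps are the only structure
      if (i <= bump600) b <- b - 0.08 * exp(-0.5 * ((wl - 600) / 10)^2)
      b - 0.08 * exp(-0.5 * ((wl - 540) / 10)^2)  # all samples share 540
    }, numeric(length(wl))))
  }
  meta <- data.frame(sample_id = sprintf("p%02d", 1:n))
  dsa <- SpectralSet(mk(21), wl, meta)
  dsb <- SpectralSet(mk(21), wl, meta)
  bs <- selectBands2T2DCOS(dsa, dsb, majority_fraction = 0.5,
                           rel_threshold = 0.02, derivative_window = 11)
  wl_sel <- bandWavelengths(bs)
  # the shared 540-nm feature is supported by every pair; the 600-nm bump
  # by 21 of 40 (> 20, kept under the strict rule)
  expect_true(any(abs(wl_sel - 540) <= 15))
  expect_true(any(abs(wl_sel - 600) <= 15))

  # at 20 of 40 the strict > drops the band
  dsa2 <- SpectralSet(mk(20), wl, meta); dsb2 <- SpectralSet(mk(20), wl, meta)
  bs2 <- selectBands2T2DCOS(dsa2, dsb2, majority_fraction = 0.5,
                            rel_threshold = 0.02, derivative_window = 11)
  expect_false(any(abs(bandWavelengths(bs2) - 600) <= 15))

  # unpaired sample ids are reported
  dsb3 <- SpectralSet(mk(21), wl, data.frame(sample_id = sprintf("q%02d", 1:n)))
  expect_error(selectBands2T2DCOS(dsa, dsb3), "unpaired")
})

test_that("identical stages still give synchronous autopeaks with zero async", {
  ds <- makeToySet(n = 10, noise = 0)
  x <- spectra(firstDerivative(ds, "savgol", 11, 2))
  m <- twoTraceMaps(x[1, ], x[1, ], wavelengths(ds))
  expect_equal(max(abs(asyncMap(m))), 0)
  expect_gt(length(bandWavelengths(autopeakBands(m, rel_threshold = 0.1))), 0)
})

test_that("repeated-selection stability keeps a planted band, counts full-data draws", {
  ds <- makeToySet(n = 40, center = 600, noise = 0.0015, seed = 2)
  st <- repeatedSelectionStability(ds, "trait", fractions = c(0.5, 1),
                                   n_draws = 10, min_count = 8, seed = 1)
  # at fraction 1 every draw is the full data set: supports equal n_draws
  expect_true(all(bandSupport(st[["1"]]$stable) == 10))
  # the planted band flank is stable at both fractions
  for (f in c("0.5", "1")) {
    wl_sel <- bandWavelengths(st[[f]]$stable)
    expect_true(any(wl_sel > 555 & wl_sel < 645))
  }
  # stable-set size is non-increasing in min_count
  cts <- st[["0.5"]]$counts
  expect_gte(sum(cts >= 8), sum(cts >= 9))

  expect_warning(
    repeatedSelectionStability(ds, "trait", fractions = 0.1, n_draws = 10,
                               min_count = 8, seed = 1),
    "skipped")
})
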