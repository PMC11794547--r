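test_that("parameter validation names the offending field", {
  expect_error(prosailParams(LAI = 12), "LAI")
  expect_error(prosailParams(Cab = -1), "Cab")
  expect_error(prosailParams(sza = 95), "sza")
  expect_s3_class(prosailParams(), "ProsailParams")
})

test_that("leaf model produces physical spectra with expected absorber effects", {
  leaf <- prospect5b(prosailParams())
  expect_length(leaf$reflectance, 2101)
  expect_true(all(leaf$reflectance >= 0 & leaf$reflectance <= 1))
  expect_true(all(leaf$reflectance + leaf$transmittance <= 1 + 1e-9))

  at <- function(sp, nm) sp$reflectance[match(nm, sp$wavelength)]
  lo <- prospect5b(prosailParams(Cab = 20))
  hi <- prospect5b(prosailParams(Cab = 60))
  expect_gt(at(lo, 550), at(hi, 550))
  wlo <- prospect5b(prosailParams(Cw = 0.005))
  whi <- prospect5b(prosailParams(Cw = 0.030))
  expect_gt(at(wlo, 1450), at(whi, 1450))
})

test_that("canopy reflectance collapses to the soil line at LAI = 0", {
  for (ps in c(0.3, 0.7)) {
    r <- prosailForward(prosailParams(LAI = 0, psoil = ps))
    expect_equal(unname(r), soilReflectance(ps), tolerance = 1e-12)
  }
})

test_that("canopy reflectance responds monotonically to pigments and water", {
  r670 <- vapply(c(20, 40, 60), function(cab) {
    prosailForward(prosailParams(Cab = cab))[["550"]]
  }, numeric(1))
  expect_true(all(diff(r670) < 0))
  r1450 <- vapply(c(0.008, 0.016, 0.030), function(cw) {
    prosailForward(prosailParams(Cw = cw))[["1450"]]
  }, numeric(1))
  expect_true(all(diff(r1450) < 0))
})

test_that("four-stream diffuse factors match an independent ODE integration", {
  skip_if_not_installed("deSolve")
  p <- prosailParams(LAI = 2.5, Cab = 35, Cw = 0.015, Cm = 0.006, ALA = 50)
  leaf <- prospect5b(p)
  idx <- match(c(550, 800, 1650), leaf$wavelength)
  out <- foursail(leaf$reflectance, leaf$transmittance, p$LAI, p$ALA,
                  p$hs, p$sza, p$vza, p$raa,
                  rsoil = rep(0, 2101))  # black soil isolates the canopy

  # reconstruct the layer coefficients exactly as the solver defines them
  rd <- pi / 180
  lidf <- maizeSPU:::.campbellLIDF(p$ALA, 18L)
  litab <- (seq_len(18) - 0.5) * 90 / 18
  ks <- bf <- 0
  cts <- cos(p$sza * rd)
  for (i in seq_len(18)) {
    vs <- maizeSPU:::.volscatt(p$sza, p$vza, p$raa, litab[i])
    ks <- ks + vs[["chi_s"]] / cts * lidf[i]
    bf <- bf + cos(litab[i] * rd)^2 * lidf[i]
  }
  ddb <- 0.5 * (1 + bf); ddf <- 0.5 * (1 - bf)
  sdb <- 0.5 * (ks + bf); sdf <- 0.5 * (ks - bf)

  for (j in idx) {
    rho <- leaf$reflectance[j]; tau <- leaf$transmittance[j]
    sigb <- ddb * rho + ddf * tau
    att <- 1 - (ddf * rho + ddb * tau)
    sf <- sdf * rho + sdb * tau
    sb <- sdb * rho + sdf * tau
    # two-stream system in downward optical depth x (0 at the top); the
    # upward stream travels against x, so its homogeneous terms flip sign:
    #   dE-/dx = -att E- + sigb E+ + sf Es
    #   dE+/dx = -sigb E- + att E+ - sb Es
    # with Es(x) = E0 exp(-ks x); solved by shooting on E+(0)
    solveBVP <- function(e_minus0, es0) {
      shoot <- function(r0) {
        deriv <- function(x, y, parms) {
          es <- es0 * exp(-ks * x)
          list(c(-att * y[1] + sigb * y[2] + sf * es,
                 -sigb * y[1] + att * y[2] - sb * es))
        }
        sol <- deSolve::ode(c(e_minus0, r0), seq(0, p$LAI, length.out = 201),
                            deriv, NULL, method = "lsoda",
                            rtol = 1e-10, atol = 1e-12)
        list(top_up = unname(r0), bottom_up = unname(sol[nrow(sol), 3]),
             bottom_down = unname(sol[nrow(sol), 2]))
      }
      r0 <- stats::uniroot(function(r) shoot(r)$bottom_up, c(-1, 1),
                           tol = 1e-12)$root
      shoot(r0)
    }
    dd <- solveBVP(1, 0)  # unit diffuse irradiance at the top
    expect_equal(dd$top_up, out$rdd[j], tolerance = 1e-6)
    expect_equal(dd$bottom_down, out$tdd[j], tolerance = 1e-6)
    sd_ <- solveBVP(0, 1)  # unit direct beam at the top
    expect_equal(sd_$top_up, out$rsd[j], tolerance = 1e-6)
    expect_equal(sd_$bottom_down, out$tsd[j], tolerance = 1e-6)
  }
})

test_that("hot-spot single scattering matches direct numerical quadrature", {
  for (geom in list(c(35, 10, 40), c(30, 0, 0), c(45, 20, 120))) {
    for (pars in list(c(ks = 0.7, ko = 0.9, lai = 3, alf = 12),
                      c(ks = 0.5, ko = 0.5, lai = 1.5, alf = 80))) {
      ks <- pars[["ks"]]; ko <- pars[["ko"]]
      lai <- pars[["lai"]]; alf <- pars[["alf"]]
      fhot <- lai * sqrt(ko * ks)
      f <- function(x) exp(-(ko + ks) * lai * x +
                             fhot * (1 - exp(-alf * x)) / alf)
      num <- stats::integrate(f, 0, 1, rel.tol = 1e-10)$value
      got <- maizeSPU:::.sumintHotspot(ks, ko, lai, alf)
      expect_equal(got$sumint, num, tolerance = 2e-3)
      expect_equal(got$tsstoo, f(1), tolerance = 1e-10)
    }
  }
})

test_that("LUT generation is seed-deterministic with consistent responses", {
  rng <- list(LAI = c(1, 5), Cm = c(0.004, 0.008))
  l1 <- generateLUT(rng, n = 10, sampler = "lhs", seed = 9)
  l2 <- generateLUT(rng, n = 10, sampler = "lhs", seed = 9)
  expect_identical(lutReflectance(l1), lutReflectance(l2))
  expect_identical(lutParams(l1), lutParams(l2))
  expect_equal(lutResponse(l1), 100 * lutParams(l1)$LAI * lutParams(l1)$Cm,
               tolerance = 1e-12)
  expect_true(all(lutResponse(l1) >= 0.4 - 1e-9 & lutResponse(l1) <= 4 + 1e-9))
  expect_true(all(lutReflectance(l1) >= 0 & lutReflectance(l1) <= 1))

  # all parameters fixed: identical rows
  lf <- generateLUT(list(LAI = 3, Cm = 0.005), n = 4, seed = 1)
  expect_equal(nrow(lutReflectance(lf)), 4)
  expect_lt(max(apply(lutReflectance(lf), 2, function(v) diff(range(v)))), 1e-12)

  expect_error(generateLUT(list(LAI = c(5, 1)), n = 3), "empty interval")
})

test_that("LUT CSV round trip preserves values", {
  l1 <- generateLUT(list(LAI = c(1, 5), Cm = c(0.004, 0.008)), n = 5,
                    seed = 2, windows = list(c(615, 765)))
  base <- file.path(tempdir(), "lut_test")
  writeLUT(l1, base)
  l2 <- readLUT(base)
  expect_equal(lutReflectance(l2), lutReflectance(l1), tolerance = 1e-12)
  expect_equal(lutResponse(l2), lutResponse(l1), tolerance = 1e-12)
})

test_that("YAML range configs round-trip into LUT generation", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("LAI: [1, 5]", "Cm: [0.004, 0.008]", "psoil: 0.5"), path)
  rng <- readRangesConfig(path)
  expect_equal(rng$LAI, c(1, 5))
  expect_equal(rng$psoil, 0.5)
  lut <- generateLUT(rng, n = 3, seed = 1)
  expect_equal(unique(lutParams(lut)$psoil), 0.5)
  writeLines("NotAParam: [0, 1]", path)
  expect_error(readRangesConfig(path), "unknown parameters")
})

test_that("fixed-parameter calibration recovers a noiseless target", {
  p_true <- prosailParams(Cbrown = 0.35, psoil = 0.7)
  target <- prosailForward(p_true)
  wl <- 400:2500
  win <- defaultModelingWindows()
  sel <- (wl >= 615 & wl <= 765) | (wl >= 990 & wl <= 2500)
  measured <- SpectralSet(matrix(target[sel], 1, sum(sel), byrow = TRUE),
                          wl[sel])
  free_vals <- list(N_struct = 1.5, Cab = 40, Car = 10, Cw = 0.012,
                    Cm = 0.005, LAI = 3, ALA = 55, hs = 0.2, psoil = 0.7)
  fits <- lapply(1:5, function(s) {
    calibrateFixedParams(measured, bounds = list(Cbrown = c(0, 1)),
                         free_values = free_vals, pop = 15, iters = 25,
                         seed = s)
  })
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "objective"))]]
  expect_lte(best$objective, 1e-3)
  expect_lt(abs(best$params$Cbrown - 0.35) / 0.35, 0.20)
  # best-so-far trace never increases
  expect_true(all(diff(best$trace) <= 1e-12))
  expect_error(calibrateFixedParams(measured, list(Cbrown = c(0, 1)),
                                    free_vals, iters = 0), "budget")
})
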