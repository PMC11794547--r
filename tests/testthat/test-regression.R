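test_that("evaluation metrics reproduce hand-computed values", {
  em <- evaluateMetrics(c(1, 2, 3, 4), c(1.5, 2.5, 2.5, 3.5))
  expect_equal(em$RMSE, 0.5)
  expect_equal(em$MAE, 0.5)
  expect_equal(em$RPD, sd(c(1, 2, 3, 4)) / 0.5)
  expect_equal(em$RPD, 2.582, tolerance = 1e-3)

  perfect <- evaluateMetrics(c(1, 2, 3), c(1, 2, 3))
  expect_equal(perfect$R2, 1)
  expect_equal(perfect$RMSE, 0)
  expect_true(is.infinite(perfect$RPD))

  # predicting the mean gives R2 = 0
  obs <- c(2, 4, 6, 8)
  expect_equal(evaluateMetrics(obs, rep(mean(obs), 4))$R2, 0)

  expect_true(is.nan(evaluateMetrics(c(0, 0), c(1, 2))$MAPE))

  # independent formula evaluation on random vectors
  withr::with_seed(8, {
    o <- rnorm(50); p <- o + rnorm(50, 0, 0.3)
  })
  em2 <- evaluateMetrics(o, p)
  expect_equal(em2$R2, 1 - sum((p - o)^2) / sum((o - mean(o))^2),
               tolerance = 1e-10)
  expect_equal(em2$MAPE, mean(abs((p - o) / o)), tolerance = 1e-10)
})

test_that("regressor wrapper is seeded, serializable and validates input", {
  withr::with_seed(1, {
    X <- matrix(runif(200), 40, 5)
    y <- 3 * X[, 1] + rnorm(40, 0, 0.05)
  })
  for (kind in c("SVR", "GBRT", "RF", "ELM", "BPNN", "committee")) {
    m1 <- fitRegressor(kind, X, y, seed = 5)
    m2 <- fitRegressor(kind, X, y, seed = 5)
    expect_identical(predict(m1, X), predict(m2, X), label = kind)
    expect_equal(m1$kind, kind)
  }
  expect_error(fitRegressor("nope", X, y), "unknown")
  expect_error(fitRegressor("RF", X, c(y[-1], NA)), "missing")
  expect_warning(mc <- fitRegressor("RF", X, rep(2, 40)), "degenerate")
  expect_equal(unique(predict(mc, X)), 2)
  expect_error(predict(fitRegressor("RF", X, y), X[, 1:3]), "mismatch")
})

test_that("polynomial fit interpolates exact quadratic data", {
  x <- matrix(1:5, 5, 1)
  y <- (1:5)^2
  m <- fitRegressor("polynomial", x, y, list(degree = 2))
  co <- unname(coef(m$fit))
  expect_equal(co, c(0, 0, 1), tolerance = 1e-9)
})

test_that("ELM has linear capacity, the interpolation property, determinism", {
  withr::with_seed(2, x <- matrix(runif(60), 60, 1))
  y <- 3 * x[, 1] + 1
  m <- fitRegressor("ELM", x, y, list(activation = "linear", n_hidden = 20),
                    seed = 1)
  expect_lt(evaluateMetrics(y, elmPredict(m, x))$RMSE, 1e-6)

  # hidden units >= n on distinct inputs: training residual below 1e-6
  withr::with_seed(3, {
    Xi <- matrix(runif(40), 20, 2)
    yi <- rnorm(20)
  })
  mi <- fitRegressor("ELM", Xi, yi, list(n_hidden = 40), seed = 2)
  expect_lt(max(abs(predict(mi, Xi) - yi)), 1e-6)

  expect_error(fitRegressor("ELM", matrix(numeric(0), 20, 0), yi), "feature")
})

test_that("RF importance finds the informative feature and normalizes", {
  withr::with_seed(4, {
    X <- matrix(rnorm(400), 40, 10)
    y <- X[, 1] + rnorm(40, 0, 0.05)
  })
  colnames(X) <- paste0("f", 1:10)
  m <- fitRegressor("RF", X, y, seed = 1)
  top <- rfImportanceTopK(m, 3)
  expect_equal(top[1], "f1")
  full <- rfImportanceTopK(m, 10)
  expect_equal(sum(attr(full, "importance")), 1, tolerance = 1e-9)
  expect_length(rfImportanceTopK(m, 50), 10)  # k above the feature count
})

test_that("dual-band indices follow the closed forms and pair counts", {
  wl <- c(670, 850)
  ds <- SpectralSet(matrix(c(0.05, 0.5), 1, 2, byrow = TRUE), wl)
  fx <- dualBandIndexFeatures(ds, wl, forms = c("DSI", "RSI", "NDSI"))
  expect_equal(unname(fx$features[1, "NDSI_850_670"]), 0.45 / 0.55,
               tolerance = 1e-9)
  expect_equal(unname(fx$features[1, "DSI_850_670"]), 0.45)
  expect_equal(unname(fx$features[1, "RSI_850_670"]), 10)
  expect_equal(unname(fx$features[1, "RSI_670_850"]), 0.1)

  # 14 bands: 91 unordered DSI pairs, 182 ordered RSI pairs
  wl14 <- seq(500, 760, by = 20)
  ds14 <- SpectralSet(matrix(runif(3 * 14, 0.1, 0.9), 3, 14), wl14)
  expect_equal(ncol(dualBandIndexFeatures(ds14, wl14, "DSI")$features), 91)
  expect_equal(ncol(dualBandIndexFeatures(ds14, wl14, "NDSI")$features), 91)
  expect_equal(ncol(dualBandIndexFeatures(ds14, wl14, "RSI")$features), 182)

  # NDSI bounded whenever both reflectances are positive
  nd <- dualBandIndexFeatures(ds14, wl14, "NDSI")$features
  expect_true(all(nd >= -1 & nd <= 1))

  expect_error(dualBandIndexFeatures(ds14, wl14[1]), "2 bands")
})

test_that("index ranking keeps the top positive and negative correlations", {
  withr::with_seed(6, {
    F <- matrix(rnorm(50 * 30), 50, 30)
    colnames(F) <- paste0("i", 1:30)
    y <- F[, 1] - F[, 2] + rnorm(50, 0, 0.1)
  })
  sel <- rankAndSelectIndices(F, y, top_pos = 10, top_neg = 10)
  expect_lte(ncol(sel$features), 20)
  expect_equal(sel$selected[1], "i1")  # strongest positive first
  expect_true("i2" %in% sel$selected)
  expect_true(all(sel$correlations[1:10] > 0))

  # a feature identical to y ranks first with r = 1
  F2 <- cbind(y = y, F[, 1:5])
  sel2 <- rankAndSelectIndices(F2, y, top_pos = 2, top_neg = 2)
  expect_equal(unname(sel2$correlations[1]), 1, tolerance = 1e-12)

  # orthogonal noise: selected |r| stays small for large n
  hits <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      Fn <- matrix(rnorm(400 * 20), 400, 20)
      colnames(Fn) <- paste0("n", 1:20)
      yn <- rnorm(400)
    })
    max(abs(rankAndSelectIndices(Fn, yn, 5, 5)$correlations))
  }, numeric(1))
  expect_gte(sum(hits < 0.3), 9)
})
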