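# one shared campaign keeps this file fast; the multi-seed recovery rates
# live in test-acceptance.R
camp <- generateCampaign(campaignConfig(seed = 1))
truth <- camp$truth
fill <- camp$stages$filling
milk <- camp$stages$milk
joint <- camp$stages$jointing
dfill <- firstDerivative(fill)
dmilk <- firstDerivative(milk)
djoint <- firstDerivative(joint)
subSet <- function(d, ix) {
  SpectralSet(spectra(d)[ix, , drop = FALSE], wavelengths(d),
              sampleMeta(d)[ix, ], derivative = isDerivative(d))
}
sp <- splitTrainTest(fill, 0.7, stratify_by = "treatment", seed = 1)
tr <- match(sampleMeta(sp$train)$plot_id, truth$plot_id)
te <- setdiff(seq_len(28), tr)

test_that("uptake is the exact unit product of concentration and biomass", {
  expect_equal(uptakeFromConcBiomass(2.5, 4), 10)
  expect_equal(uptakeFromConcBiomass(0, 100), 0)
  expect_equal(uptakeFromConcBiomass(c(1, 2), c(3, 4)), c(3, 8))
  expect_error(uptakeFromConcBiomass(-1, 2), "non-negative")
})

test_that("canopy LPC model trains on selected bands and clips at zero", {
  dpool <- combineSpectralSets(djoint, dfill)
  bs <- selectBands1Der2DCOS(dpool, "LPC", rel_threshold = 0.02)
  out <- predictCanopyLPC(subSet(dpool, c(tr, 28 + tr)), dfill, bs, seed = 1)
  expect_length(out$predictions, 28)
  expect_true(all(out$predictions >= 0))
  expect_gte(evaluateMetrics(sampleMeta(dfill)$LPC[te],
                             out$predictions[te])$R2, 0.5)

  # constant training response yields a constant predictor
  cds <- subSet(dfill, tr)
  SummarizedExperiment::colData(cds)$LPC <- 2
  expect_warning(outc <- predictCanopyLPC(cds, dfill, bs, seed = 1),
                 "degenerate")
  expect_equal(unname(unique(outc$predictions)), 2)

  expect_error(predictCanopyLPC(dfill, dfill, c(10, 20)), "missing")
})

test_that("hybrid leaf-biomass chain filters, augments and recovers", {
  hy <- predictLeafBiomassHybrid(fill, measured_idx = tr,
                                 pool_target = 1500, seed = 1)
  expect_length(hy$predictions, 28)
  # the filtered training set is nonempty and within both constraints
  expect_gt(length(hy$al$selected_candidates), 0)
  expect_true(all(hy$al$log$kept_candidates >= 0))
  em <- evaluateMetrics(truth$leaf_biomass[te], hy$predictions[te])
  expect_gte(em$R2, 0.5)

  # noiseless spectra drawn from the forward model itself: with generous
  # acceptance thresholds and an interpolating ELM the response is
  # recovered almost exactly
  lut <- generateLUT(list(LAI = c(1, 5), Cm = c(0.004, 0.008)),
                     n = 400, seed = 9)
  keep <- 1:40
  ds_sim <- SpectralSet(lutReflectance(lut)[keep, ], lut@wavelengths,
                        data.frame(sample_id = paste0("sim", keep),
                                   leaf_biomass = lutResponse(lut)[keep]))
  hy2 <- suppressWarnings(predictLeafBiomassHybrid(
    ds_sim, candidates = lut,
    cfg = alConfig(K_representative = 15,
                   epsilon_spectral = quantileEps(0.5),
                   epsilon_response = sdEps(3)),
    elm_params = list(n_hidden = 300, lambda = 0, ensemble = 1),
    seed = 2))
  em2 <- evaluateMetrics(lutResponse(lut)[keep], hy2$predictions)
  expect_lt(em2$RMSE, 0.05)
})

test_that("grain model applies the mature-leaf substitution and its bias", {
  bs_g <- selectBands1Der2DCOS(subSet(dmilk, tr), "grain_biomass",
                               rel_threshold = 0.02)
  gr <- predictGrainUptake(subSet(dmilk, tr), dmilk,
                           mature_leaf_P = truth$mature_leaf_conc,
                           bands = bs_g, seed = 1)
  expect_length(gr$grain_P, 28)
  expect_true(all(gr$grain_P >= 0))
  expect_equal(gr$grain_P, truth$mature_leaf_conc * gr$grain_biomass,
               tolerance = 1e-9)
  expect_gte(evaluateMetrics(truth$grain_P[te], gr$grain_P[te])$R2, 0.5)
  # zero grain biomass means zero uptake
  expect_equal(uptakeFromConcBiomass(truth$mature_leaf_conc[1], 0), 0)
  expect_error(predictGrainUptake(dmilk, dmilk, NULL, bs_g), "required")

  # when true grain concentration is 1.2x the leaf value, substituting the
  # leaf value underestimates uptake by about 1 - 1/1.2 = 17%
  camp12 <- generateCampaign(campaignConfig(seed = 1,
                                            grain_conc_equals_leaf = FALSE,
                                            grain_conc_factor = 1.2))
  t12 <- camp12$truth
  sub_uptake <- t12$mature_leaf_conc * t12$grain_biomass
  bias <- mean(1 - sub_uptake / t12$grain_P)
  expect_equal(bias, 1 - 1 / 1.2, tolerance = 1e-9)
})

test_that("stem link fits polynomials, clips and recovers exact data", {
  x <- c(1, 2, 3, 4, 5, 6)
  y_exact <- 0.5 + 0.3 * x + 0.05 * x^2
  link <- fitStemLink(x, y_exact, degree = 2)
  expect_equal(unname(link$coefficients), c(0.5, 0.3, 0.05), tolerance = 1e-9)
  expect_equal(predict(link, c(1.5, 7)),
               0.5 + 0.3 * c(1.5, 7) + 0.05 * c(1.5, 7)^2, tolerance = 1e-9)

  # negative predictions are clipped to zero
  link_neg <- fitStemLink(c(1, 2, 3, 4, 5), c(0.1, 0.2, 0.5, 1, 2), degree = 1)
  expect_equal(predict(link_neg, -50), 0)
  expect_error(fitStemLink(1:3, 1:3, degree = 2), "degree \\+ 2")

  # campaign link recovery: fitted curve within the noise of the truth
  link_c <- fitStemLink(truth$leaf_P, truth$stem_P, degree = 2)
  resid_sd <- sd(predict(link_c, truth$leaf_P) - truth$stem_P)
  expect_lt(resid_sd, 2 * sd(truth$stem_P))
})

test_that("combined prediction is additive, non-negative and evaluated", {
  dpool_tr <- combineSpectralSets(subSet(djoint, tr), subSet(dfill, tr))
  bs_lpc <- selectBands1Der2DCOS(dpool_tr, "LPC", rel_threshold = 0.02)
  lpcF <- predictCanopyLPC(dpool_tr, dfill, bs_lpc,
                           response = "mature_leaf_conc", seed = 1)
  lpcJ <- predictCanopyLPC(dpool_tr, djoint, bs_lpc,
                           response = "mature_leaf_conc", seed = 1)
  lpc <- (lpcF$predictions + lpcJ$predictions) / 2
  hy <- predictLeafBiomassHybrid(fill, measured_idx = tr,
                                 pool_target = 1500, seed = 1)
  bs_g <- selectBands1Der2DCOS(subSet(dmilk, tr), "grain_biomass",
                               rel_threshold = 0.02)
  gr <- predictGrainUptake(subSet(dmilk, tr), dmilk, mature_leaf_P = lpc,
                           bands = bs_g, seed = 1)
  slink <- fitStemLink(truth$leaf_P[tr], truth$stem_P[tr])
  comb <- predictSPUCombined(lpc, hy$predictions, gr$grain_P, slink,
                             plot_id = truth$plot_id)
  expect_equal(comb$SPU, comb$leaf_P + comb$stem_P + comb$grain_P,
               tolerance = 1e-12)
  expect_true(all(comb[c("leaf_P", "stem_P", "grain_P", "SPU")] >= 0))
  expect_gte(evaluateMetrics(truth$SPU[te], comb$SPU[te])$R2, 0.6)

  # full determinism of the composed pipeline
  hyb <- predictLeafBiomassHybrid(fill, measured_idx = tr,
                                  pool_target = 1500, seed = 1)
  expect_identical(hy$predictions, hyb$predictions)
})

test_that("whole-plant baseline guards stages and leakage-free splits", {
  wp <- predictSPUWholePlant(subSet(dfill, tr), dfill, stage = "filling",
                             seed = 1)
  expect_length(wp$predictions, 28)
  expect_error(predictSPUWholePlant(subSet(dfill, tr), dfill,
                                    stage = "harvest"), "unknown stage")
  # the train and test sets of the split are disjoint by construction
  expect_length(intersect(sampleMeta(sp$train)$sample_id,
                          sampleMeta(sp$test)$sample_id), 0)
})
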