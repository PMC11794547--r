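#' Canopy leaf P concentration from derivative-2DCOS bands
#'
#' Trains a regressor (default GBRT, the most size-stable combination for
#' this task) on the reflectance at 2DCOS-selected bands of the derivative
#' spectra and predicts leaf P concentration (g/kg). Negative predictions
#' are clipped at 0 with a warning.
#'
#' @param ds_train,ds_predict Derivative-flagged [SpectralSet-class]
#'   objects; `ds_train` must carry the response column.
#' @param bands A [BandSet-class] from [selectBands1Der2DCOS()]. For
#'   concentration work select with a small `rel_threshold` (0.02): the
#'   derivative variance of structural (NIR/SWIR) bands dwarfs the visible,
#'   and a threshold relative to the global maximum autopeak must be small
#'   enough to retain the pigment-driven visible autopeaks.
#' @param response Trait column used for training (default `"LPC"`).
#' @param kind Regressor kind for [fitRegressor()].
#' @param hyperparams Regressor settings; the default is a shallow,
#'   strongly-regularized gradient boosting configuration suited to
#'   field-campaign sample sizes (tens of plots).
#' @param seed Passed to [fitRegressor()].
#' @return List with `predictions` (named by sample_id), `model`.
#' @export
predictCanopyLPC <- function(ds_train, ds_predict = ds_train, bands,
                             response = "LPC", kind = "GBRT",
                             hyperparams = if (kind == "GBRT")
                               list(max_depth = 2, eta = 0.03,
                                    num_trees = 800, subsample = 0.7)
                             else list(),
                             seed = 1) {
  Xtr <- .bandMatrix(ds_train, bands)
  Xpr <- .bandMatrix(ds_predict, bands)
  y <- sampleMeta(ds_train)[[response]]
  if (is.null(y)) stop("training response '", response, "' not found")
  model <- fitRegressor(kind, Xtr, y, hyperparams, seed)
  pred <- predict(model, Xpr)
  if (any(pred < 0)) {
    warning(sum(pred < 0), " negative concentration predictions clipped at 0")
    pred <- pmax(pred, 0)
  }
  names(pred) <- sampleMeta(ds_predict)$sample_id
  list(predictions = pred, model = model)
}

.bandMatrix <- function(ds, bands) {
  wl_sel <- if (inherits(bands, "BandSet")) bandWavelengths(bands) else
    as.numeric(bands)
  wl <- wavelengths(ds)
  miss <- setdiff(wl_sel, wl)
  if (length(miss)) {
    stop("bands missing from dataset: ", paste(miss, collapse = ", "))
  }
  spectra(ds)[, match(wl_sel, wl), drop = FALSE]
}

#' Hybrid leaf-biomass prediction (radiative transfer + NRBO-AL + ELM)
#'
#' The hybrid inversion chain: an NRBO-archived candidate pool of forward
#' simulations near the measured spectral centroid, the spectral-distance
#' and response-consistency filters, the greedy measured-sample augmentation
#' loop, and finally an extreme learning machine trained on the selected
#' simulated + measured samples.
#'
#' @param ds Measured [SpectralSet-class] (one stage), masked or full grid
#'   (it is masked to `windows` internally).
#' @param measured_idx Indices of samples with measured leaf biomass used
#'   for the active-learning loop (the training plots).
#' @param response Trait column with the measured leaf biomass t/ha.
#' @param candidates Optional pre-built [SimulatedLUT-class] pool on the
#'   masked grid; built by [candidatePoolFromNRBO()] when `NULL`.
#' @param cfg An [alConfig()].
#' @param ranges Parameter ranges for the pool.
#' @param pool_target Candidate pool size when building the pool.
#' @param windows Modeling windows.
#' @param elm_params ELM settings; the default (200 hidden units, ridge
#'   penalty 1, 5-network ensemble) suits the small, noisy training sets
#'   the filters produce. For noiseless matched data an interpolating
#'   configuration (`lambda = 0`, `ensemble = 1`, `n_hidden >=` training
#'   size) recovers the response almost exactly.
#' @param seed Integer seed.
#' @return List with `predictions` (biomass t/ha for every sample of `ds`,
#'   clipped at 0), `model`, `al` (the [alAugmentLoop()] output) and
#'   `candidates`.
#' @export
predictLeafBiomassHybrid <- function(ds, measured_idx = seq_len(ncol(ds)),
                                     response = "leaf_biomass",
                                     candidates = NULL, cfg = alConfig(),
                                     ranges = defaultMaizeRanges(),
                                     pool_target = 2000,
                                     windows = defaultModelingWindows(),
                                     elm_params = list(n_hidden = 200,
                                                       lambda = 1,
                                                       ensemble = 5),
                                     seed = 1) {
  dsm <- maskWindows(ds, windows)
  X <- spectra(dsm)
  y_all <- sampleMeta(dsm)[[response]]
  if (is.null(y_all)) stop("response '", response, "' not found")
  Xm <- X[measured_idx, , drop = FALSE]
  ym <- y_all[measured_idx]
  if (is.null(candidates)) {
    reps0 <- pickRepresentativeSubset(Xm, min(cfg$K_representative,
                                              nrow(Xm) - 1), "kennard_stone")
    candidates <- candidatePoolFromNRBO(Xm[reps0, , drop = FALSE], ranges,
                                        pool_target = pool_target,
                                        seed = seed, windows = windows)
  }
  al <- alAugmentLoop(Xm, ym, candidates, cfg)
  if (!nrow(al$train_X)) {
    stop("empty training set after filtering; increase the epsilon thresholds")
  }
  # ridge-regularized, ensembled ELM by default: the training sets here are
  # small (tens of filtered candidates + measured plots), where a pure
  # pseudoinverse fit interpolates noise
  model <- fitRegressor("ELM", al$train_X, al$train_y, elm_params,
                        seed = seed)
  pred <- pmax(predict(model, X), 0)
  names(pred) <- sampleMeta(dsm)$sample_id
  list(predictions = pred, model = model, al = al, candidates = candidates)
}

#' Organ P uptake from concentration and biomass
#'
#' `g/kg x t/ha` is exactly `kg/ha`, so uptake is the elementwise product.
#'
#' @param conc P concentration, g/kg (>= 0).
#' @param biomass Biomass, t/ha (>= 0).
#' @return Uptake in kg/ha.
#' @examples
#' uptakeFromConcBiomass(2.5, 4) # 10 kg/ha
#' @export
uptakeFromConcBiomass <- function(conc, biomass) {
  if (any(conc < 0) || any(biomass < 0)) {
    stop("concentration and biomass must be non-negative")
  }
  conc * biomass
}

#' Grain P uptake from milk-stage spectra and the substitution rule
#'
#' Grain biomass is predicted from milk-stage derivative spectra at
#' 2DCOS-selected bands; grain P concentration is substituted by the
#' mature-leaf P concentration (most of the grain P pool is re-fixed from
#' the vegetative organs, which makes the mature-leaf concentration a
#' usable proxy). Uptake is their product.
#'
#' @param ds_milk_train,ds_milk_predict Derivative-flagged milk-stage
#'   [SpectralSet-class] objects; training metadata must carry
#'   `grain_biomass`.
#' @param mature_leaf_P Mature-leaf P concentration (g/kg) per predicted
#'   sample (measured, or predicted by [predictCanopyLPC()]).
#' @param bands A [BandSet-class] for the grain-biomass model.
#' @param kind,hyperparams,seed Passed to [fitRegressor()].
#' @return List with `grain_P` (kg/ha), `grain_biomass` (t/ha), `model`.
#' @export
predictGrainUptake <- function(ds_milk_train, ds_milk_predict = ds_milk_train,
                               mature_leaf_P, bands, kind = "committee",
                               hyperparams = list(), seed = 1) {
  if (is.null(mature_leaf_P)) stop("mature-leaf P concentration is required")
  if (length(mature_leaf_P) != ncol(ds_milk_predict)) {
    stop("mature_leaf_P length must match the prediction samples")
  }
  gb <- predictCanopyLPC(ds_milk_train, ds_milk_predict, bands,
                         response = "grain_biomass", kind = kind,
                         hyperparams = hyperparams, seed = seed)
  grain_biomass <- pmax(gb$predictions, 0)
  list(grain_P = uptakeFromConcBiomass(pmax(mature_leaf_P, 0), grain_biomass),
       grain_biomass = grain_biomass, model = gb$model)
}

#' Polynomial link from leaf to stem P uptake
#'
#' Least-squares polynomial (default degree 2) relating measured leaf P
#' uptake to measured stem P uptake; predictions are clipped at 0. A
#' rank-deficient fit falls back to a lower degree with a warning.
#'
#' @param leaf_P_obs,stem_P_obs Measured uptake vectors, kg/ha.
#' @param degree Polynomial degree (1-3).
#' @return An object of class `StemLink` with `coefficients`, `degree`,
#'   `rmse`; use `predict()`.
#' @export
fitStemLink <- function(leaf_P_obs, stem_P_obs, degree = 2) {
  stopifnot(degree %in% 1:3, length(leaf_P_obs) == length(stem_P_obs))
  if (length(leaf_P_obs) < degree + 2) {
    stop("need at least degree + 2 points")
  }
  deg <- degree
  repeat {
    fit <- lm(stem_P_obs ~ poly(leaf_P_obs, deg, raw = TRUE))
    if (!anyNA(coef(fit)) || deg == 1) break
    warning("rank-deficient polynomial; lowering degree to ", deg - 1)
    deg <- deg - 1
  }
  pred <- pmax(as.numeric(predict(fit)), 0)
  structure(list(coefficients = coef(fit), degree = deg,
                 rmse = sqrt(mean((pred - stem_P_obs)^2)), fit = fit),
            class = "StemLink")
}

#' @rdname fitStemLink
#' @param object A `StemLink`.
#' @param newdata Numeric vector of leaf P uptake (kg/ha).
#' @param ... Unused.
#' @export
predict.StemLink <- function(object, newdata, ...) {
  co <- object$coefficients
  x <- as.numeric(newdata)
  pred <- co[1] + Reduce(`+`, lapply(seq_len(object$degree), function(d) {
    co[d + 1] * x^d
  }))
  pmax(as.numeric(pred), 0)
}

#' Combined organ-wise shoot P uptake prediction
#'
#' Composes the organ predictors: leaf P = predicted canopy LPC x hybrid
#' leaf biomass; stem P = polynomial link applied to leaf P; grain P =
#' empirical grain model with the mature-leaf substitution; SPU is their
#' sum (exact by construction).
#'
#' @param lpc Predicted (or measured) canopy LPC g/kg per plot.
#' @param leaf_biomass Hybrid-predicted leaf biomass t/ha per plot.
#' @param grain_P Grain P uptake kg/ha per plot ([predictGrainUptake()]).
#' @param stem_link A fitted [fitStemLink()].
#' @param plot_id Optional plot identifiers.
#' @return A data.frame (`plot_id`, `leaf_P`, `stem_P`, `grain_P`, `SPU`),
#'   all columns non-negative and `SPU = leaf_P + stem_P + grain_P`.
#' @export
predictSPUCombined <- function(lpc, leaf_biomass, grain_P, stem_link,
                               plot_id = NULL) {
  n <- length(lpc)
  stopifnot(length(leaf_biomass) == n, length(grain_P) == n)
  leaf_P <- uptakeFromConcBiomass(pmax(lpc, 0), pmax(leaf_biomass, 0))
  stem_P <- predict(stem_link, leaf_P)
  grain_P <- pmax(grain_P, 0)
  data.frame(
    plot_id = plot_id %||% paste0("plot", seq_len(n)),
    leaf_P = leaf_P, stem_P = stem_P, grain_P = grain_P,
    SPU = leaf_P + stem_P + grain_P
  )
}

#' Run the full organ-wise pipeline on a three-stage campaign
#'
#' Convenience orchestration of the complete workflow on jointing, filling
#' and milk [SpectralSet-class]s sharing plot order: derivative
#' preprocessing, 2DCOS band selection (trained on the training plots
#' only), the canopy-concentration model (averaged over the jointing and
#' filling predictions, matching the mature-leaf definition), the hybrid
#' leaf-biomass inversion, the grain model with the mature-leaf
#' substitution, the polynomial stem link, the organ combination, and the
#' single-stage whole-plant empirical baseline.
#'
#' @param stages Named list with `jointing`, `filling`, `milk`
#'   [SpectralSet-class]s whose metadata carries `LPC`,
#'   `mature_leaf_conc`, `leaf_biomass`, `grain_biomass`, `leaf_P`,
#'   `stem_P` and `SPU` (as [generateCampaign()] produces).
#' @param train_idx Integer indices of the training plots (measured set);
#'   all remaining plots act as the evaluation set.
#' @param pool_target Candidate-pool size for the hybrid branch.
#' @param rel_threshold Autopeak threshold for the band selections.
#' @param seed Integer seed.
#' @return List with `combined` (the [predictSPUCombined()] data.frame over
#'   all plots), `baseline` (whole-plant SPU predictions), `lpc`,
#'   `leaf_biomass`, `grain` and the selected band sets.
#' @export
runCombinedPipeline <- function(stages, train_idx, pool_target = 2000,
                                rel_threshold = 0.02, seed = 1) {
  stopifnot(all(c("jointing", "filling", "milk") %in% names(stages)))
  fill <- stages$filling; joint <- stages$jointing; milk <- stages$milk
  tr <- train_idx
  dfill <- firstDerivative(fill)
  djoint <- firstDerivative(joint)
  dmilk <- firstDerivative(milk)
  subSet <- function(d, ix) {
    SpectralSet(spectra(d)[ix, , drop = FALSE], wavelengths(d),
                sampleMeta(d)[ix, ], derivative = TRUE)
  }
  dpool_tr <- combineSpectralSets(subSet(djoint, tr), subSet(dfill, tr))
  bands_lpc <- selectBands1Der2DCOS(dpool_tr, "LPC", rel_threshold)
  lpcF <- predictCanopyLPC(dpool_tr, dfill, bands_lpc,
                           response = "mature_leaf_conc", seed = seed)
  lpcJ <- predictCanopyLPC(dpool_tr, djoint, bands_lpc,
                           response = "mature_leaf_conc", seed = seed)
  lpc <- (lpcF$predictions + lpcJ$predictions) / 2

  hy <- predictLeafBiomassHybrid(fill, measured_idx = tr,
                                 pool_target = pool_target, seed = seed)

  bands_grain <- selectBands1Der2DCOS(subSet(dmilk, tr), "grain_biomass",
                                      rel_threshold)
  gr <- predictGrainUptake(subSet(dmilk, tr), dmilk, mature_leaf_P = lpc,
                           bands = bands_grain, seed = seed)

  meta <- sampleMeta(fill)
  slink <- fitStemLink(meta$leaf_P[tr], meta$stem_P[tr])
  combined <- predictSPUCombined(lpc, hy$predictions, gr$grain_P, slink,
                                 plot_id = meta$plot_id)
  baseline <- predictSPUWholePlant(subSet(dfill, tr), dfill,
                                   stage = "filling", seed = seed)
  list(combined = combined, baseline = baseline$predictions, lpc = lpc,
       leaf_biomass = hy$predictions, grain = gr,
       bands = list(lpc = bands_lpc, grain = bands_grain),
       stem_link = slink, hybrid = hy)
}

#' Whole-plant empirical SPU baseline from a single stage
#'
#' The direct empirical comparator: derivative-2DCOS band selection against
#' SPU on one growth stage, then a regressor from those bands to SPU.
#'
#' @param ds_train,ds_predict [SpectralSet-class] objects of one stage
#'   (raw; the derivative is taken internally).
#' @param stage Stage label; must match the metadata.
#' @param bands Optional [BandSet-class]; selected against SPU when `NULL`.
#' @param kind,hyperparams,seed Passed to [fitRegressor()].
#' @return List with `predictions` (SPU kg/ha), `model`, `bands`.
#' @export
predictSPUWholePlant <- function(ds_train, ds_predict = ds_train, stage,
                                 bands = NULL, kind = "GBRT",
                                 hyperparams = list(), seed = 1) {
  st_tr <- unique(sampleMeta(ds_train)$stage)
  if (!stage %in% st_tr) {
    stop("unknown stage '", stage, "' (training data has: ",
         paste(st_tr, collapse = ", "), ")")
  }
  dtr <- if (isDerivative(ds_train)) ds_train else firstDerivative(ds_train)
  dpr <- if (isDerivative(ds_predict)) ds_predict else
    firstDerivative(ds_predict)
  if (is.null(bands)) {
    bands <- selectBands1Der2DCOS(dtr, "SPU")
  }
  out <- predictCanopyLPC(dtr, dpr, bands, response = "SPU", kind = kind,
                          hyperparams = hyperparams, seed = seed)
  list(predictions = out$predictions, model = out$model, bands = bands)
}
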