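#' Synthetic field-campaign configuration
#'
#' Defines a multi-treatment phosphorus-fertilization campaign: 7 P-rate
#' treatments x 4 replicate plots observed at the jointing, filling and milk
#' stages (28 plots, 84 spectra). Plant response to P follows a saturating
#' (Michaelis-Menten) curve in LAI, chlorophyll and leaf P concentration;
#' canopy spectra come from [prosailForward()] plus multiplicative noise,
#' additive noise and a smooth low-order baseline wiggle that exercises the
#' derivative preprocessing.
#'
#' @param n_treatments,n_reps Treatment count and replicates per treatment.
#' @param p_rates P application rates (kg P2O5/ha), one per treatment.
#' @param stages Growth stage names, in chronological order.
#' @param lai_max,lai_k Saturating LAI response: `LAI = lai_max * P' /
#'   (P' + lai_k)` with `P' = p_rate + 10` (residual soil P).
#' @param lpc_max,lpc_min LPC (g/kg) range over the P response.
#' @param noise_mult,noise_add Multiplicative (fraction) and additive
#'   (reflectance) noise SDs.
#' @param baseline_amp Amplitude of the smooth polynomial baseline wiggle.
#' @param grain_conc_equals_leaf If `TRUE` (default) the grain P
#'   concentration equals the mature-leaf P concentration (the substitution
#'   rule); otherwise it is `grain_conc_factor` times it.
#' @param grain_conc_factor Ratio of true grain to mature-leaf P
#'   concentration when the substitution rule is switched off.
#' @param seed Integer seed.
#' @return A list of class `CampaignConfig`.
#' @export
campaignConfig <- function(n_treatments = 7, n_reps = 4,
                           p_rates = c(90, 65, 45, 32.5, 9, 9, 9),
                           stages = c("jointing", "filling", "milk"),
                           lai_max = 8.5, lai_k = 45,
                           lpc_max = 3.6, lpc_min = 1.4,
                           noise_mult = 0.01, noise_add = 0.001,
                           baseline_amp = 0.002,
                           grain_conc_equals_leaf = TRUE,
                           grain_conc_factor = 1.0,
                           seed = 1) {
  stopifnot(n_treatments * n_reps >= 20, noise_mult >= 0, noise_add >= 0,
            length(p_rates) == n_treatments)
  structure(as.list(environment()), class = c("CampaignConfig", "list"))
}

#' Generate a synthetic multi-treatment campaign with known truth
#'
#' Draws per-plot biophysical parameters from treatment-dependent
#' distributions, simulates canopy spectra with the radiative-transfer
#' forward model, adds sensor noise, and books a fully consistent truth
#' table: leaf biomass is exactly `100 * LAI * Cm` t/ha, organ P uptake is
#' concentration x biomass per organ, SPU is their sum, and the grain P
#' pool is consistent with re-fixation fractions drawn within 0.50-0.85
#' (leaf) and 0.15-0.50 (stem).
#'
#' Stage progression: LAI and Cm rise from jointing to filling; chlorophyll
#' (and LPC) decline from filling to milk (senescence), which makes the
#' filling stage the most informative single stage.
#'
#' @param cfg A [campaignConfig()].
#' @return A list with `stages` (named list of [SpectralSet-class], one per
#'   stage, traits attached), `truth` (per-plot data.frame with biomass,
#'   concentrations and organ uptake), and `params` (per plot x stage
#'   forward-model parameters).
#' @export
generateCampaign <- function(cfg = campaignConfig()) {
  n_plots <- cfg$n_treatments * cfg$n_reps
  withr::with_seed(cfg$seed, {
    treatment <- rep(paste0("T", seq_len(cfg$n_treatments)), each = cfg$n_reps)
    p_rate <- rep(cfg$p_rates, each = cfg$n_reps)
    plot_id <- sprintf("plot%02d", seq_len(n_plots))
    p_eff <- p_rate + 10  # residual soil P keeps the zero treatments alive

    # plot-level (stage-independent) P response with plot noise
    sat <- p_eff / (p_eff + cfg$lai_k)
    lai_fill <- pmin(cfg$lai_max * sat * (1 + rnorm(n_plots, 0, 0.07)), 9.5)
    lpc_fill <- cfg$lpc_min + (cfg$lpc_max - cfg$lpc_min) * sat *
      (1 + rnorm(n_plots, 0, 0.05))

    # stage multipliers; lai_sd is the stage-specific plot variability:
    # early-growth uncertainty at jointing, and senescence (stay-green)
    # variability at the milk stage, which decouples the milk canopy from
    # the filling stage
    stage_par <- list(
      jointing = list(lai = 0.55, cab_per_lpc = 22, cm = 0.0042,
                      cw = 0.016, lpc = 1.25, lai_sd = 0.05),
      filling = list(lai = 1.00, cab_per_lpc = 24, cm = 0.0055,
                     cw = 0.014, lpc = 1.00, lai_sd = 0.04),
      milk = list(lai = 0.92, cab_per_lpc = 17, cm = 0.0060,
                  cw = 0.010, lpc = 0.82, lai_sd = 0.14)
    )
    stages <- cfg$stages
    wl <- 400:2500

    params <- list(); spectra_by_stage <- list()
    lpc_by_stage <- list()
    for (st in stages) {
      sp <- stage_par[[st]]
      lai <- pmax(lai_fill * sp$lai * (1 + rnorm(n_plots, 0, sp$lai_sd)), 0.2)
      lpc <- pmax(lpc_fill * sp$lpc * (1 + rnorm(n_plots, 0, 0.03)), 0.4)
      cab <- pmin(pmax(sp$cab_per_lpc * lpc *
                         (1 + rnorm(n_plots, 0, 0.04)), 5), 110)
      cm <- pmax(sp$cm * (1 + 0.12 * sat + rnorm(n_plots, 0, 0.04)), 0.002)
      cw <- pmax(sp$cw * (1 + rnorm(n_plots, 0, 0.05)), 0.004)
      car <- pmin(pmax(cab / 4 + rnorm(n_plots, 0, 0.8), 2), 35)
      ala <- pmin(pmax(rnorm(n_plots, 57, 4), 35), 75)
      hs <- pmin(pmax(rnorm(n_plots, 0.18, 0.03), 0.05), 0.5)
      pars <- data.frame(plot_id = plot_id, stage = st, LAI = lai,
                         Cab = cab, Car = car, Cbrown = 0, Cw = cw, Cm = cm,
                         ALA = ala, hs = hs, N_struct = 1.5, psoil = 0.7,
                         sza = 30, vza = 0, raa = 0)
      clean <- matrix(0, n_plots, length(wl))
      for (i in seq_len(n_plots)) {
        p <- prosailParams(N_struct = 1.5, Cab = cab[i], Car = car[i],
                           Cbrown = 0, Cw = cw[i], Cm = cm[i], LAI = lai[i],
                           ALA = ala[i], hs = hs[i], psoil = 0.7)
        clean[i, ] <- .forwardFull(p)
      }
      # sensor noise: multiplicative + additive + smooth baseline wiggle
      x01 <- (wl - 400) / 2100
      noisy <- clean
      for (i in seq_len(n_plots)) {
        base <- cfg$baseline_amp *
          (rnorm(1) + rnorm(1) * x01 + rnorm(1) * (2 * x01^2 - 1))
        noisy[i, ] <- clean[i, ] * (1 + rnorm(length(wl), 0, cfg$noise_mult)) +
          rnorm(length(wl), 0, cfg$noise_add) + base
      }
      noisy <- pmin(pmax(noisy, 0), 1)
      params[[st]] <- pars
      spectra_by_stage[[st]] <- list(clean = clean, noisy = noisy)
      lpc_by_stage[[st]] <- lpc
    }

    # truth table (organ biomass t/ha, concentrations g/kg, uptake kg/ha)
    leaf_biomass <- 100 * params$filling$LAI * params$filling$Cm
    stem_biomass <- pmax(1.15 * leaf_biomass^1.1 *
                           (1 + rnorm(n_plots, 0, 0.07)), 0.1)
    # kernel filling tracks the milk-stage canopy (stay-green leaf area and
    # dry-matter status), so grain mass is driven by the milk-stage
    # parameters, not the filling stage
    milk_leaf_biomass <- 100 * params$milk$LAI * params$milk$Cm
    grain_biomass <- pmax(3.1 * sat^0.25 * milk_leaf_biomass^0.85 *
                            (1 + rnorm(n_plots, 0, 0.04)), 0.1)
    # mature-leaf P concentration = mean over the layer set (upper+middle at
    # jointing; upper+middle+lower at filling)
    mature_leaf_conc <- (lpc_by_stage$jointing + lpc_by_stage$filling) / 2
    stem_conc <- pmax(0.45 * mature_leaf_conc *
                        (1 + rnorm(n_plots, 0, 0.06)), 0.1)
    grain_conc <- if (cfg$grain_conc_equals_leaf) mature_leaf_conc else
      cfg$grain_conc_factor * mature_leaf_conc

    leaf_P <- mature_leaf_conc * leaf_biomass
    stem_P <- stem_conc * stem_biomass
    grain_P <- grain_conc * grain_biomass
    spu <- leaf_P + stem_P + grain_P

    # grain P re-fixation bookkeeping: fractions of the pre-silking leaf and
    # stem pools re-fixed into the grain, drawn within the physiological
    # ranges; pre-silking pools are derived so the balance closes
    frac_leaf <- runif(n_plots, 0.50, 0.85)
    frac_stem <- runif(n_plots, 0.15, 0.50)
    share_leaf <- runif(n_plots, 0.55, 0.75)  # of grain P sourced from leaf
    presilking_leaf_P <- grain_P * share_leaf / frac_leaf
    presilking_stem_P <- grain_P * (1 - share_leaf) / frac_stem

    truth <- data.frame(
      plot_id = plot_id, treatment = treatment, p_rate = p_rate,
      LAI_filling = params$filling$LAI,
      leaf_biomass = leaf_biomass, stem_biomass = stem_biomass,
      grain_biomass = grain_biomass, agb = leaf_biomass + stem_biomass,
      LPC_jointing = lpc_by_stage$jointing,
      LPC_filling = lpc_by_stage$filling,
      LPC_milk = lpc_by_stage$milk,
      mature_leaf_conc = mature_leaf_conc,
      stem_conc = stem_conc, grain_conc = grain_conc,
      leaf_P = leaf_P, stem_P = stem_P, grain_P = grain_P, SPU = spu,
      refix_leaf = frac_leaf, refix_stem = frac_stem,
      presilking_leaf_P = presilking_leaf_P,
      presilking_stem_P = presilking_stem_P
    )

    sets <- list()
    for (st in stages) {
      meta <- data.frame(
        sample_id = paste0(plot_id, "_", st), plot_id = plot_id,
        stage = st, treatment = treatment, p_rate = p_rate,
        LPC = lpc_by_stage[[st]],
        mature_leaf_conc = mature_leaf_conc,
        leaf_biomass = leaf_biomass, agb = truth$agb,
        grain_biomass = grain_biomass,
        leaf_P = leaf_P, stem_P = stem_P, grain_P = grain_P, SPU = spu
      )
      sets[[st]] <- SpectralSet(spectra_by_stage[[st]]$noisy, wl, meta)
      attr(sets[[st]], "clean") <- spectra_by_stage[[st]]$clean
    }
    list(stages = sets, truth = truth, params = do.call(rbind, params))
  })
}

#' Tiny hand-checkable spectral fixture
#'
#' Six samples x twelve bands with a single Gaussian feature whose depth
#' scales linearly with the trait, plus a fixed literal perturbation; small
#' enough that the 2D correlation maps can be verified against direct
#' double-loop summation.
#'
#' @return A [SpectralSet-class] with a numeric `trait` metadata column.
#' @export
workedFixtureSmall <- function() {
  wl <- seq(500, 720, by = 20)
  trait <- c(1, 2, 3, 4, 5, 6)
  depth <- 0.05 * trait
  base <- 0.4 + 0.1 * sin(seq_along(wl) / 3)
  refl <- t(vapply(seq_along(trait), function(i) {
    base - depth[i] * exp(-0.5 * ((wl - 620) / 30)^2)
  }, numeric(length(wl))))
  refl <- round(refl, 6)
  SpectralSet(refl, wl,
              data.frame(sample_id = paste0("f", seq_along(trait)),
                         plot_id = paste0("f", seq_along(trait)),
                         stage = "filling", treatment = "fix",
                         trait = trait))
}
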