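#' Synthetic leaf optical constants (400--2500 nm)
#'
#' Specific absorption coefficient spectra and the leaf refractive index used
#' by [prospect5b()]. These are *synthetic* smooth emulations of published
#' leaf optical constants: each absorber is modelled as a sum of Gaussian
#' absorption features centred on its known wavelengths (chlorophyll a+b in
#' the blue/red, carotenoids below 550 nm, water overtone/combination bands at
#' 970/1200/1450/1790/1940/2270 nm, dry matter C-H/N-H features at
#' 1720/2100/2300 nm) with magnitudes chosen so that typical maize leaf
#' compositions give realistic reflectance dynamics. They are generated in
#' code, not read from any calibrated coefficient file, so absolute
#' reflectances are plausible rather than instrument-grade.
#'
#' @return A data.frame with columns `wavelength` (nm, 400:2500), `nrefrac`
#'   (refractive index), and specific absorption coefficients `kab`
#'   (cm^2/ug), `kcar` (cm^2/ug), `kbrown` (arbitrary/unitless weight),
#'   `kw` (1/cm), `km` (cm^2/g).
#' @examples
#' head(leafOpticalConstants())
#' @export
leafOpticalConstants <- function() {
  cached <- .maizeSPU_cache$leafconst
  if (!is.null(cached)) return(cached)
  wl <- 400:2500
  g <- function(mu, sd) exp(-0.5 * ((wl - mu) / sd)^2)

  nrefrac <- 1.40 + 0.12 * exp(-(wl - 400) / 900)

  # chlorophyll a+b: Soret band near 430 nm, red band near 670 nm, plus a
  # broad in-vivo absorption base keeping green/red-edge sensitivity
  kab <- 0.130 * g(430, 45) + 0.110 * g(670, 38) + 0.008 * g(550, 120)
  # total carotenoids: blue absorption only
  kcar <- 0.120 * g(455, 30) + 0.060 * g(505, 25)
  # brown pigments: broad decaying absorption from the blue edge
  kbrown <- 0.45 * exp(-(wl - 400) / 350)
  # liquid water: overtone/combination bands, rising continuum in the SWIR
  kw <- 0.45 * g(970, 40) + 1.2 * g(1200, 55) + 29 * g(1450, 55) +
    7 * g(1790, 60) + 120 * g(1940, 70) + 45 * g(2270, 90) +
    60 * g(2500, 80) + 25 * plogis((wl - 2350) / 80)
  # dry matter: protein/cellulose/lignin features plus a slow SWIR ramp
  km <- 6 * g(1720, 50) + 12 * g(2100, 80) + 10 * g(2300, 60) +
    5 * g(2480, 80) + 8 * plogis((wl - 1300) / 350) + 0.8

  out <- data.frame(
    wavelength = wl, nrefrac = nrefrac, kab = kab, kcar = kcar,
    kbrown = kbrown, kw = kw, km = km
  )
  .maizeSPU_cache$leafconst <- out
  out
}

#' Synthetic soil reflectance spectrum
#'
#' Smooth dry- and wet-soil reflectance end members mixed by the soil
#' brightness factor `psoil` (1 = dry, 0 = wet), emulating the familiar
#' monotonically rising soil line with weak water-related dips when wet.
#' Synthetic, generated in code (no soil spectral library is bundled).
#'
#' @param psoil Soil brightness factor in \[0, 1\].
#' @return Numeric vector of 2101 reflectances on the 400:2500 nm grid.
#' @export
soilReflectance <- function(psoil = 0.7) {
  stopifnot(is.numeric(psoil), length(psoil) == 1, psoil >= 0, psoil <= 1)
  wl <- 400:2500
  dry <- 0.10 + 0.22 * (1 - exp(-(wl - 400) / 900))
  wet <- 0.55 * dry *
    (1 - 0.12 * exp(-0.5 * ((wl - 1450) / 120)^2)
       - 0.20 * exp(-0.5 * ((wl - 1940) / 140)^2))
  psoil * dry + (1 - psoil) * wet
}

# package-level cache for deterministic, repeatedly-used tables
.maizeSPU_cache <- new.env(parent = emptyenv())
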