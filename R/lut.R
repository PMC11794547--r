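#' Default maize parameter ranges for LUT generation
#'
#' Field-typical maize ranges for the sensitive parameters (LAI, Cab, Car,
#' Cw, Cm, ALA, hs); the remaining parameters are held at the
#' [prosailParams()] defaults unless overridden.
#'
#' @return Named list of `c(lo, hi)` intervals.
#' @export
defaultMaizeRanges <- function() {
  list(LAI = c(0.5, 7), Cab = c(20, 80), Car = c(5, 25),
       Cw = c(0.005, 0.035), Cm = c(0.002, 0.010),
       ALA = c(30, 70), hs = c(0.05, 0.5))
}

#' Generate a forward-simulated look-up table
#'
#' Draws parameter combinations (Latin hypercube or full-factorial grid),
#' runs [prosailForward()] for each, masks the spectra to the modeling
#' windows, and attaches the leaf-biomass response
#' `100 * LAI * Cm` (t/ha).
#'
#' @param ranges Named list: `c(lo, hi)` intervals for free parameters,
#'   scalars for fixed ones. Parameters not named keep their
#'   [prosailParams()] defaults.
#' @param n Number of draws (for `sampler = "grid"`, per-dimension levels
#'   are chosen so the grid size is at least `n`).
#' @param sampler `"lhs"` (maximin Latin hypercube) or `"grid"`.
#' @param seed Integer seed; the LUT is deterministic under
#'   `(sampler, seed)`.
#' @param windows Band windows applied to the simulated spectra
#'   (default [defaultModelingWindows()]; `NULL` keeps the full grid).
#' @return A [SimulatedLUT-class].
#' @export
generateLUT <- function(ranges = defaultMaizeRanges(), n = 1000,
                        sampler = c("lhs", "grid"), seed = 1,
                        windows = defaultModelingWindows()) {
  sampler <- match.arg(sampler)
  stopifnot(n >= 1)
  is_free <- vapply(ranges, length, integer(1)) == 2
  free <- ranges[is_free]
  fixed <- ranges[!is_free]
  for (nmf in names(free)) {
    if (free[[nmf]][2] < free[[nmf]][1]) stop("empty interval for ", nmf)
    if (free[[nmf]][2] == free[[nmf]][1]) {
      fixed[[nmf]] <- free[[nmf]][1]
    }
  }
  free <- free[vapply(free, function(r) r[2] > r[1], logical(1))]
  p <- length(free)
  if (p == 0) {
    U <- matrix(numeric(0), n, 0)
  } else if (sampler == "lhs") {
    U <- withr::with_seed(seed, lhs::randomLHS(n, p))
  } else {
    k <- ceiling(n^(1 / p))
    U <- as.matrix(expand.grid(rep(list(seq(0, 1, length.out = k)), p)))
    U <- U[seq_len(min(nrow(U), max(n, nrow(U)))), , drop = FALSE]
  }
  params <- as.data.frame(matrix(0, nrow(U), p))
  names(params) <- names(free)
  for (j in seq_len(p)) {
    r <- free[[j]]
    params[[j]] <- r[1] + U[, j] * (r[2] - r[1])
  }
  base <- prosailParams()
  for (nmf in names(fixed)) base[[nmf]] <- fixed[[nmf]]
  full <- as.data.frame(base[setdiff(names(base), names(params))],
                        stringsAsFactors = FALSE)
  params <- cbind(params, full[rep(1, max(nrow(params), 1)), , drop = FALSE])
  rownames(params) <- NULL
  if (nrow(U) == 0) params <- params[rep(1, n), , drop = FALSE]

  wl_all <- 400:2500
  sel <- if (is.null(windows)) rep(TRUE, length(wl_all)) else {
    w <- bandWindows(if (is.matrix(windows)) split(windows, row(windows)) else windows)
    Reduce(`|`, lapply(seq_len(nrow(w)), function(i) {
      wl_all >= w[i, 1] & wl_all <= w[i, 2]
    }))
  }
  refl <- matrix(0, nrow(params), sum(sel))
  for (i in seq_len(nrow(params))) {
    pi_ <- params[i, ]
    pp <- prosailParams(N_struct = pi_$N_struct, Cab = pi_$Cab,
                        Car = pi_$Car, Cbrown = pi_$Cbrown, Cw = pi_$Cw,
                        Cm = pi_$Cm, LAI = pi_$LAI, ALA = pi_$ALA,
                        hs = pi_$hs, psoil = pi_$psoil, sza = pi_$sza,
                        vza = pi_$vza, raa = pi_$raa)
    refl[i, ] <- .forwardFull(pp)[sel]
  }
  new("SimulatedLUT", params = params, wavelengths = wl_all[sel],
      reflectance = refl, response = 100 * params$LAI * params$Cm,
      manifest = list(sampler = sampler, seed = seed, n = nrow(params),
                      ranges = ranges,
                      windows = if (is.null(windows)) NULL else
                        bandWindows(if (is.matrix(windows))
                          split(windows, row(windows)) else windows)))
}

# forward run without the per-call validation/class overhead of
# prosailForward (used in LUT loops; parameters already validated)
.forwardFull <- function(p) {
  leaf <- prospect5b(p)
  rsoil <- soilReflectance(p$psoil)
  out <- foursail(leaf$reflectance, leaf$transmittance, p$LAI, p$ALA,
                  p$hs, p$sza, p$vza, p$raa, rsoil)
  pmin(pmax(out$rsot, 0), 1)
}

#' Read parameter ranges / fixed values from a YAML config
#'
#' The config maps parameter names to either a `[lo, hi]` interval (free
#' parameter) or a single number (fixed value), e.g.
#' `LAI: [0.5, 7]` / `psoil: 0.7`. Output feeds [generateLUT()],
#' [candidatePoolFromNRBO()] and [calibrateFixedParams()].
#'
#' @param path YAML file path.
#' @return Named list of numeric scalars and length-2 vectors.
#' @export
readRangesConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(prosailParams())
  bad <- setdiff(names(cfg), known)
  if (length(bad)) {
    stop("unknown parameters in config: ", paste(bad, collapse = ", "))
  }
  lapply(cfg, function(v) {
    v <- as.numeric(unlist(v))
    if (!length(v) %in% 1:2 || anyNA(v)) {
      stop("config entries must be a number or a [lo, hi] interval")
    }
    v
  })
}

#' Write / read a SimulatedLUT as CSV with a manifest
#'
#' @param lut A [SimulatedLUT-class].
#' @param path Base path; writes `<path>.csv` (params + response +
#'   reflectance) and `<path>.manifest.json`.
#' @return Base `path`, invisibly.
#' @export
writeLUT <- function(lut, path) {
  df <- cbind(lutParams(lut), response = lutResponse(lut),
              as.data.frame(lutReflectance(lut)) |>
                stats::setNames(paste0("wl", lut@wavelengths)))
  write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  man <- lut@manifest
  man$wavelengths <- lut@wavelengths
  jsonlite::write_json(man, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeLUT
#' @export
readLUT <- function(path) {
  df <- read.csv(paste0(path, ".csv"), check.names = FALSE)
  man <- jsonlite::read_json(paste0(path, ".manifest.json"),
                             simplifyVector = TRUE)
  wl_cols <- grep("^wl", names(df))
  refl <- as.matrix(df[, wl_cols])
  dimnames(refl) <- NULL
  params <- df[, setdiff(seq_along(df), c(wl_cols, which(names(df) == "response"))),
               drop = FALSE]
  new("SimulatedLUT", params = params,
      wavelengths = as.numeric(man$wavelengths), reflectance = refl,
      response = df$response,
      manifest = man[setdiff(names(man), "wavelengths")])
}
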