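#' Extended FAST global sensitivity indices
#'
#' Variance-based first-order (Si) and total (STi) sensitivity indices by
#' the extended Fourier amplitude sensitivity test. Each parameter is taken
#' in turn as the driver with the maximum frequency
#' `floor((Ns - 1) / (2 * M))`, the complementary parameters receive low
#' frequencies, all parameters are explored along the search curve
#' `x = 0.5 + asin(sin(w s + phi)) / pi` (random phase per curve), and the
#' indices come from the Fourier spectrum of the model output: Si from the
#' driver frequency and its first `M` harmonics, STi as one minus the
#' variance below the complementary cut-off.
#'
#' @param model Function mapping a parameter vector to a scalar.
#' @param ranges Named list of `c(lo, hi)` ranges (>= 2 parameters).
#' @param n_samples Total model evaluations; at least `65 * p`.
#' @param M Interference factor (number of harmonics), default 4.
#' @param seed Integer seed for the random phases.
#' @param threshold Sensitivity flag threshold (default 0.1).
#' @return A data.frame with one row per parameter: `parameter`, `Si`,
#'   `STi`, `sensitive` (`Si > threshold` or `STi > threshold`). A constant
#'   model output yields all-zero indices with a warning.
#' @examples
#' efastIndices(function(x) 2 * x[1] + x[2],
#'              list(a = c(0, 1), b = c(0, 1)), n_samples = 1000)
#' @export
efastIndices <- function(model, ranges, n_samples = NULL, M = 4, seed = 1,
                         threshold = 0.1) {
  p <- length(ranges)
  stopifnot(p >= 2)
  if (is.null(n_samples)) n_samples <- max(65 * p, 1000)
  Ns <- max(ceiling(n_samples / p), 65)
  if (Ns %% 2 == 0) Ns <- Ns + 1  # odd length keeps the spectrum clean
  if (n_samples < 65 * p) stop("n_samples must be at least 65 * p")
  w_max <- floor((Ns - 1) / (2 * M))
  w_comp_max <- max(1, floor(w_max / (2 * M)))
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(hi <= lo)) stop("empty parameter interval")
  s <- pi * (2 * seq_len(Ns) - Ns - 1) / Ns

  Si <- STi <- numeric(p)
  varied <- FALSE
  withr::with_seed(seed, {
    for (i in seq_len(p)) {
      w <- rep(0L, p)
      w[i] <- w_max
      # complementary frequencies spread over 1..w_comp_max for good
      # space-filling of the search curve
      w[-i] <- if (w_comp_max >= p - 1) {
        floor(seq(1, w_comp_max, length.out = p - 1))
      } else {
        (seq_len(p - 1) - 1) %% w_comp_max + 1
      }
      phi <- runif(p, 0, 2 * pi)
      X <- matrix(0, Ns, p)
      for (j in seq_len(p)) {
        g <- 0.5 + asin(sin(w[j] * s + phi[j])) / pi
        X[, j] <- lo[j] + g * (hi[j] - lo[j])
      }
      y <- apply(X, 1, model)
      if (var(y) < 1e-30) { Si[i] <- 0; STi[i] <- 0; next }
      varied <- TRUE
      ft <- stats::fft(y - mean(y))
      half <- (Ns - 1) / 2
      # spectral power at frequency k is |F_k|^2; factor cancels in ratios
      power <- Mod(ft[2:(half + 1)])^2
      D <- sum(power)
      Di <- sum(power[w_max * seq_len(M)])
      Dc <- sum(power[seq_len(min(w_comp_max * M, half))])
      Si[i] <- Di / D
      STi[i] <- 1 - Dc / D
    }
  })
  if (!varied) warning("constant model output: all sensitivity indices 0")
  data.frame(parameter = names(ranges), Si = Si, STi = STi,
             sensitive = Si > threshold | STi > threshold)
}

#' Region-wise EFAST screening of the canopy forward model
#'
#' Runs [efastIndices()] on [prosailForward()] once per spectral region
#' (visible 400-700, near-infrared 700-1300, shortwave-infrared
#' 1300-2500 nm), using mean region reflectance as the scalar output.
#'
#' @param ranges Named list of `c(lo, hi)` ranges for free parameters;
#'   unnamed parameters stay at their [prosailParams()] defaults.
#' @param fixed Named list of fixed parameter values.
#' @param n_samples Evaluations per parameter per region.
#' @inheritParams efastIndices
#' @return Named list of per-region data.frames (`visible`, `nir`, `swir`).
#' @export
efastProsail <- function(ranges, fixed = list(), n_samples = NULL, M = 4,
                         seed = 1, threshold = 0.1) {
  regions <- list(visible = c(400, 700), nir = c(700, 1300),
                  swir = c(1300, 2500))
  wl <- 400:2500
  lapply(regions, function(rg) {
    sel <- wl >= rg[1] & wl <= rg[2]
    f <- function(x) {
      args <- c(as.list(setNames(x, names(ranges))), fixed)
      mean(prosailForward(do.call(prosailParams, args))[sel])
    }
    efastIndices(f, ranges, n_samples, M, seed, threshold)
  })
}

#' Partition parameters into free (sensitive) and fixed sets
#'
#' A parameter is free if its sensitivity index exceeds `threshold` in ANY
#' spectral region; parameters in `always_include` (by default the dry
#' matter content `Cm`, which carries the biomass signal even though its
#' spectral sensitivity is modest) are free regardless.
#'
#' @param reports List of per-region data.frames from [efastIndices()] /
#'   [efastProsail()].
#' @param threshold Sensitivity threshold (default 0.1).
#' @param always_include Parameters forced into the free set.
#' @return List with character vectors `free` and `fixed`.
#' @export
classifySensitiveParams <- function(reports, threshold = 0.1,
                                    always_include = "Cm") {
  if (is.data.frame(reports)) reports <- list(reports)
  params <- reports[[1]]$parameter
  sensitive <- rep(FALSE, length(params))
  for (rep_i in reports) {
    stopifnot(identical(rep_i$parameter, params))
    sensitive <- sensitive | rep_i$Si > threshold | rep_i$STi > threshold
  }
  free <- union(params[sensitive], always_include)
  list(free = intersect(union(params, always_include), free),
       fixed = setdiff(params, free))
}

#' Calibrate fixed forward-model parameters against measured spectra
#'
#' Optimizes the low-sensitivity (fixed) parameters so that the forward
#' simulation matches the mean measured spectrum over the modeling windows,
#' using the sine-cosine chaotic sparrow hybrid ([scassaMinimize()]). The
#' objective is the reflectance RMSE over the masked bands.
#'
#' @param measured A [SpectralSet-class], already masked to the modeling
#'   windows ([maskWindows()]).
#' @param bounds Named list of `c(lo, hi)` bounds for the parameters to
#'   calibrate (the fixed set of [classifySensitiveParams()]).
#' @param free_values Named list of values at which the free parameters are
#'   held during calibration (e.g. field-typical means).
#' @param pop,iters Optimizer budget (iters must be > 0).
#' @param seed Integer seed.
#' @return List with `params` (calibrated values merged into a full
#'   [prosailParams()] record), `objective` (final RMSE) and `trace`
#'   (best-so-far RMSE per iteration, non-increasing).
#' @export
calibrateFixedParams <- function(measured, bounds, free_values = list(),
                                 pop = 30, iters = 100, seed = 1) {
  if (iters <= 0) stop("optimizer budget must be positive")
  target <- colMeans(spectra(measured))
  wl_mask <- wavelengths(measured)
  wl_all <- 400:2500
  sel <- match(wl_mask, wl_all)
  if (anyNA(sel)) stop("measured grid must be a subset of 400:2500 nm")
  nm <- names(bounds)
  lo <- vapply(bounds, `[`, numeric(1), 1)
  hi <- vapply(bounds, `[`, numeric(1), 2)
  obj <- function(x) {
    args <- c(as.list(setNames(x, nm)), free_values)
    p <- do.call(prosailParams, args)
    sqrt(mean((prosailForward(p)[sel] - target)^2))
  }
  res <- scassaMinimize(obj, lo, hi, pop = pop, iters = iters, seed = seed)
  params <- do.call(prosailParams,
                    c(as.list(setNames(res@best_x, nm)), free_values))
  list(params = params, objective = res@best_f, trace = res@history)
}
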