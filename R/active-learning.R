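#' Active-learning configuration
#'
#' Thresholds and budgets of the NRBO-AL sampling strategy. The two epsilon
#' constraints may be absolute values or empirical quantile specifications:
#' `epsilon_spectral = quantileEps(0.05)` sets the spectral threshold to the
#' 5th percentile of candidate-to-representative distances;
#' `epsilon_response = sdEps(0.5)` sets the response threshold to half the
#' standard deviation of the representative responses. Quantile defaults are
#' deliberately tight: the strategy is meant to keep only a small fraction
#' of a large simulated pool.
#'
#' @param epsilon_spectral Positive number, or [quantileEps()].
#' @param epsilon_response Positive number, [quantileEps()] or [sdEps()].
#' @param K_representative Number of representative measured samples.
#' @param max_new_fraction New-sample budget as a fraction of the measured
#'   set size (default 0.10; the loop adds at most
#'   `floor(max_new_fraction * N)` samples).
#' @param distance Distance metric name (only `"euclidean"` implemented).
#' @return A list of class `ALConfig`.
#' @export
alConfig <- function(epsilon_spectral = quantileEps(0.05),
                     epsilon_response = sdEps(0.5),
                     K_representative = 20,
                     max_new_fraction = 0.10,
                     distance = "euclidean") {
  stopifnot(max_new_fraction > 0, max_new_fraction <= 1,
            distance == "euclidean")
  .checkEps(epsilon_spectral); .checkEps(epsilon_response)
  structure(list(epsilon_spectral = epsilon_spectral,
                 epsilon_response = epsilon_response,
                 K_representative = K_representative,
                 max_new_fraction = max_new_fraction,
                 distance = distance),
            class = c("ALConfig", "list"))
}

#' @rdname alConfig
#' @param prob Quantile level in (0, 1).
#' @export
quantileEps <- function(prob) {
  stopifnot(prob > 0, prob < 1)
  structure(list(prob = prob), class = "quantileEps")
}

#' @rdname alConfig
#' @param mult Multiple of the representative-response standard deviation.
#' @export
sdEps <- function(mult) {
  stopifnot(mult > 0)
  structure(list(mult = mult), class = "sdEps")
}

.checkEps <- function(e) {
  if (inherits(e, "quantileEps") || inherits(e, "sdEps")) return(invisible())
  if (!is.numeric(e) || length(e) != 1 || e <= 0) {
    stop("epsilon must be a positive number, quantileEps() or sdEps()")
  }
}

# pairwise Euclidean distances between rows of a and rows of b
.rowDist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

#' Pick a representative measured subset
#'
#' Kennard-Stone (max-min Euclidean distance in spectral space), SPXY
#' (max-min on spectra and response jointly, each distance normalized by its
#' maximum) or simple random selection.
#'
#' @param X Numeric sample x band matrix (or [SpectralSet-class]).
#' @param K Subset size, `K < N`.
#' @param method `"kennard_stone"`, `"spxy"` or `"random"`.
#' @param y Response vector (required for `"spxy"`).
#' @param seed Seed for `"random"` (the two deterministic methods ignore it).
#' @return Integer indices of the selected samples.
#' @export
pickRepresentativeSubset <- function(X, K, method = c("kennard_stone",
                                                      "spxy", "random"),
                                     y = NULL, seed = 1) {
  method <- match.arg(method)
  if (inherits(X, "SpectralSet")) X <- spectra(X)
  X <- as.matrix(X)
  N <- nrow(X)
  if (K >= N) stop("K must be smaller than the number of samples")
  if (method == "random") {
    return(sort(withr::with_seed(seed, sample(N, K))))
  }
  D <- .rowDist(X, X)
  if (method == "spxy") {
    if (is.null(y)) stop("spxy requires the response y")
    Dy <- abs(outer(y, y, "-"))
    D <- D / max(D) + Dy / max(Dy)
  }
  # start from the two most distant samples, then max-min
  sel <- as.integer(arrayInd(which.max(D), dim(D)))
  while (length(sel) < K) {
    rest <- setdiff(seq_len(N), sel)
    dmin <- apply(D[rest, sel, drop = FALSE], 1, min)
    sel <- c(sel, rest[which.max(dmin)])
  }
  sort(sel[seq_len(K)])
}

#' Build a candidate pool near the representative centroid with NRBO
#'
#' Runs [nrboMinimize()] with archiving on the objective
#' `|| forward(theta) - centroid(representatives) ||` over the masked bands,
#' so the archived population sweeps are forward simulations concentrated
#' near the measured spectral centroid. Restarts (with derived seeds) are
#' added until the archive holds at least `pool_target` candidates; exactly
#' `pool_target` are kept.
#'
#' @param representatives Numeric matrix of measured spectra (rows) on the
#'   masked wavelength grid, or a [SpectralSet-class].
#' @param ranges Named parameter ranges as in [generateLUT()].
#' @param pool_target Number of candidates to return.
#' @param pop,iters NRBO budget per restart.
#' @param seed Integer seed.
#' @param windows Modeling windows (must match the representative grid).
#' @return A [SimulatedLUT-class] with `pool_target` rows.
#' @export
candidatePoolFromNRBO <- function(representatives, ranges = defaultMaizeRanges(),
                                  pool_target = 1000, pop = 25, iters = 19,
                                  seed = 1,
                                  windows = defaultModelingWindows()) {
  stopifnot(pool_target >= 1)
  if (inherits(representatives, "SpectralSet")) {
    representatives <- spectra(representatives)
  }
  centroid <- colMeans(representatives)
  wl_all <- 400:2500
  w <- bandWindows(if (is.matrix(windows)) split(windows, row(windows)) else windows)
  sel <- Reduce(`|`, lapply(seq_len(nrow(w)), function(i) {
    wl_all >= w[i, 1] & wl_all <= w[i, 2]
  }))
  if (sum(sel) != length(centroid)) {
    stop("representative grid does not match the modeling windows")
  }
  is_free <- vapply(ranges, length, integer(1)) == 2
  free <- ranges[is_free]
  if (!length(free)) stop("infeasible ranges: no free parameters")
  lo <- vapply(free, `[`, numeric(1), 1)
  hi <- vapply(free, `[`, numeric(1), 2)
  if (any(hi <= lo)) stop("infeasible ranges: empty interval")
  fixed <- ranges[!is_free]
  base <- prosailParams()
  for (nmf in names(fixed)) base[[nmf]] <- fixed[[nmf]]

  spectrumOf <- function(x) {
    p <- base
    for (j in seq_along(free)) p[[names(free)[j]]] <- x[j]
    .forwardFull(p)[sel]
  }
  per_restart <- pop * (iters + 1)
  n_restarts <- ceiling(pool_target / per_restart)
  # cache each evaluated spectrum: archive rows arrive in evaluation order,
  # so the objective can fill the pool reflectance as a side effect
  cache <- new.env(parent = emptyenv())
  cache$refl <- vector("list", n_restarts * per_restart)
  cache$i <- 0L
  obj <- function(x) {
    s <- spectrumOf(x)
    cache$i <- cache$i + 1L
    cache$refl[[cache$i]] <- s
    sqrt(sum((s - centroid)^2))
  }
  archives <- vector("list", n_restarts)
  for (r in seq_len(n_restarts)) {
    res <- nrboMinimize(obj, lo, hi, pop = pop, iters = iters,
                        seed = seed + (r - 1) * 131L, keep_archive = TRUE)
    archives[[r]] <- res@archive
  }
  arch <- do.call(rbind, archives)[seq_len(pool_target), , drop = FALSE]
  params <- arch[, seq_along(free), drop = FALSE]
  names(params) <- names(free)
  for (nmf in setdiff(names(base), names(params))) params[[nmf]] <- base[[nmf]]
  refl <- do.call(rbind, cache$refl[seq_len(pool_target)])
  dimnames(refl) <- NULL
  new("SimulatedLUT", params = params, wavelengths = wl_all[sel],
      reflectance = refl, response = 100 * params$LAI * params$Cm,
      manifest = list(sampler = "nrbo_archive", seed = seed,
                      pool_target = pool_target, pop = pop, iters = iters,
                      ranges = ranges, windows = w))
}

.resolveEpsSpectral <- function(eps, dmin) {
  if (inherits(eps, "quantileEps")) {
    unname(quantile(dmin, eps$prob))
  } else if (inherits(eps, "sdEps")) {
    stop("sdEps applies to the response threshold only")
  } else eps
}

#' Spectral-distance filter (shortest distance to the representatives)
#'
#' Keeps the candidates whose minimum Euclidean distance to any
#' representative spectrum is strictly below the threshold
#' \eqn{d = \min_m \|x_t - x_m\| < \epsilon}.
#'
#' @param candidates A [SimulatedLUT-class] or candidate spectra matrix.
#' @param representatives Matrix (or [SpectralSet-class]) of representative
#'   spectra on the same grid.
#' @param epsilon_spectral Positive threshold or [quantileEps()] on the
#'   distribution of candidate minimum distances.
#' @return Logical vector over candidates (use to subset); attribute
#'   `epsilon` carries the resolved threshold.
#' @export
filterEq1 <- function(candidates, representatives,
                      epsilon_spectral = quantileEps(0.05)) {
  .checkEps(epsilon_spectral)
  Xc <- if (inherits(candidates, "SimulatedLUT")) {
    lutReflectance(candidates)
  } else as.matrix(candidates)
  Xr <- if (inherits(representatives, "SpectralSet")) {
    spectra(representatives)
  } else as.matrix(representatives)
  if (ncol(Xc) != ncol(Xr)) stop("candidate/representative grids differ")
  dmin <- apply(.rowDist(Xc, Xr), 1, min)
  eps <- .resolveEpsSpectral(epsilon_spectral, dmin)
  keep <- dmin < eps  # strict inequality
  attr(keep, "epsilon") <- eps
  attr(keep, "dmin") <- dmin
  keep
}

#' Response-distance filter (regression-consistency constraint)
#'
#' Fits an ordinary least squares model `f` of the measured response on the
#' representative spectra (a small top-variance band subset is used when the
#' band count approaches the representative count, to keep the fit
#' identifiable; a ridge fallback with lambda = 1e-3 handles singular
#' designs) and keeps candidates whose simulated response agrees with the
#' model: \eqn{|f(x_t) - y_t| < \epsilon}.
#'
#' @inheritParams filterEq1
#' @param candidate_y Simulated responses of the candidates (taken from the
#'   [SimulatedLUT-class] if not given).
#' @param representative_y Measured responses of the representatives.
#' @param epsilon_response Positive threshold, [quantileEps()] on
#'   `|f(x_t) - y_t|`, or [sdEps()] on the representative responses.
#' @param max_bands Band-subset ceiling for the regression.
#' @return Logical keep vector with attributes `epsilon` and `model`.
#' @export
filterEq2 <- function(candidates, representatives, representative_y,
                      candidate_y = NULL,
                      epsilon_response = sdEps(0.5), max_bands = NULL) {
  .checkEps(epsilon_response)
  Xc <- if (inherits(candidates, "SimulatedLUT")) {
    lutReflectance(candidates)
  } else as.matrix(candidates)
  if (is.null(candidate_y)) {
    if (!inherits(candidates, "SimulatedLUT")) {
      stop("candidate_y required when candidates is a plain matrix")
    }
    candidate_y <- lutResponse(candidates)
  }
  Xr <- if (inherits(representatives, "SpectralSet")) {
    spectra(representatives)
  } else as.matrix(representatives)
  f <- .fitLinearF(Xr, representative_y, max_bands)
  pred <- .predictLinearF(f, Xc)
  resid <- abs(pred - candidate_y)
  eps <- if (inherits(epsilon_response, "sdEps")) {
    epsilon_response$mult * sd(representative_y)
  } else if (inherits(epsilon_response, "quantileEps")) {
    unname(quantile(resid, epsilon_response$prob))
  } else epsilon_response
  keep <- resid < eps
  attr(keep, "epsilon") <- eps
  attr(keep, "model") <- f
  attr(keep, "resid") <- resid
  keep
}

# multiple linear regression f(x) on a band subset that keeps OLS
# identifiable; ridge fallback for singular designs
.fitLinearF <- function(X, y, max_bands = NULL) {
  n <- nrow(X)
  if (is.null(max_bands)) max_bands <- max(2L, min(ncol(X), floor(n / 2)))
  bands <- if (ncol(X) > max_bands) {
    order(-apply(X, 2, var))[seq_len(max_bands)]
  } else seq_len(ncol(X))
  Xs <- X[, bands, drop = FALSE]
  A <- cbind(1, Xs)
  fit <- tryCatch({
    beta <- qr.coef(qr(A), y)
    if (anyNA(beta)) stop("singular design")
    list(beta = beta, bands = bands, ridge = FALSE)
  }, error = function(e) {
    warning("singular regression design: ridge fallback (lambda = 1e-3)")
    lambda <- 1e-3
    beta <- solve(crossprod(A) + lambda * diag(ncol(A)), crossprod(A, y))
    list(beta = as.numeric(beta), bands = bands, ridge = TRUE)
  })
  fit
}

.predictLinearF <- function(f, X) {
  as.numeric(cbind(1, X[, f$bands, drop = FALSE]) %*% f$beta)
}

#' Greedy active-learning augmentation loop
#'
#' Starting from the representative subset of the measured data, each
#' iteration tentatively adds every unused measured sample, refits the
#' linear model `f` and the response filter, and permanently adds the sample
#' whose inclusion most reduces the validation RMSE of `f` on the held-out
#' measured samples. The loop stops when `floor(max_new_fraction * N)` new
#' samples have been added or no sample improves the RMSE. The resulting
#' training set is the union of the surviving filtered candidates and the
#' selected measured samples.
#'
#' @param measured_X Measured spectra matrix (masked grid) or
#'   [SpectralSet-class].
#' @param measured_y Measured responses (leaf biomass t/ha).
#' @param candidates A [SimulatedLUT-class] candidate pool (typically from
#'   [candidatePoolFromNRBO()]).
#' @param cfg An [alConfig()].
#' @param representatives Optional integer indices of the representative
#'   measured samples (defaults to Kennard-Stone with
#'   `cfg$K_representative`).
#' @return List with `train_X`, `train_y` (selected candidates + selected
#'   measured rows), `selected_candidates` (indices into the pool),
#'   `representatives` (final measured indices), `log` (data.frame:
#'   iteration, added_sample, kept_candidates, rmse) and the resolved
#'   thresholds `epsilon_spectral`, `epsilon_response`.
#' @export
alAugmentLoop <- function(measured_X, measured_y, candidates, cfg = alConfig(),
                          representatives = NULL) {
  if (inherits(measured_X, "SpectralSet")) measured_X <- spectra(measured_X)
  measured_X <- as.matrix(measured_X)
  N <- nrow(measured_X)
  stopifnot(length(measured_y) == N, N >= 3)
  if (is.null(representatives)) {
    representatives <- pickRepresentativeSubset(
      measured_X, min(cfg$K_representative, N - 1), "kennard_stone")
  }
  keep1 <- filterEq1(candidates, measured_X[representatives, , drop = FALSE],
                     cfg$epsilon_spectral)
  eps1 <- attr(keep1, "epsilon")
  Xc <- lutReflectance(candidates)[keep1, , drop = FALSE]
  yc <- lutResponse(candidates)[keep1]
  idx_pool <- which(keep1)

  budget <- floor(cfg$max_new_fraction * N)
  reps <- representatives
  evalState <- function(reps_now) {
    f <- .fitLinearF(measured_X[reps_now, , drop = FALSE],
                     measured_y[reps_now])
    hold <- setdiff(seq_len(N), reps_now)
    rmse <- if (length(hold)) {
      sqrt(mean((.predictLinearF(f, measured_X[hold, , drop = FALSE]) -
                 measured_y[hold])^2))
    } else 0
    list(f = f, rmse = rmse)
  }
  st <- evalState(reps)
  keep2 <- filterEq2(Xc, measured_X[reps, , drop = FALSE], measured_y[reps],
                     candidate_y = yc, epsilon_response = cfg$epsilon_response)
  eps2 <- attr(keep2, "epsilon")
  log_df <- data.frame(iteration = 0L, added_sample = NA_integer_,
                       kept_candidates = sum(keep2), rmse = st$rmse)
  added <- 0L
  while (added < budget) {
    unused <- setdiff(seq_len(N), reps)
    if (!length(unused)) break
    rmses <- vapply(unused, function(i) evalState(c(reps, i))$rmse,
                    numeric(1))
    best <- which.min(rmses)
    if (rmses[best] >= st$rmse) break  # no sample improves validation RMSE
    reps <- c(reps, unused[best])
    added <- added + 1L
    st <- evalState(reps)
    keep2 <- filterEq2(Xc, measured_X[reps, , drop = FALSE],
                       measured_y[reps], candidate_y = yc,
                       epsilon_response = cfg$epsilon_response)
    log_df <- rbind(log_df, data.frame(
      iteration = added, added_sample = unused[best],
      kept_candidates = sum(keep2), rmse = st$rmse))
  }
  sel_cand <- idx_pool[keep2]
  list(
    train_X = rbind(Xc[keep2, , drop = FALSE],
                    measured_X[reps, , drop = FALSE]),
    train_y = c(yc[keep2], measured_y[reps]),
    selected_candidates = sel_cand,
    representatives = sort(reps),
    log = log_df,
    epsilon_spectral = eps1,
    epsilon_response = attr(keep2, "epsilon")
  )
}
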