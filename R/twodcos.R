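#' Synchronous 2D correlation map
#'
#' Generalized two-dimensional correlation spectroscopy: for m spectra
#' ordered along the perturbation variable, the synchronous map is
#' \deqn{\Phi(\nu_1,\nu_2) = \frac{1}{m-1}\sum_j \tilde y_j(\nu_1)\,
#' \tilde y_j(\nu_2)}
#' with \eqn{\tilde y} the column-mean-centred (dynamic) spectra. \eqn{\Phi}
#' is symmetric and positive semidefinite; its diagonal holds the autopeaks.
#'
#' @param ordered_spectra Numeric m x band matrix, rows ordered by the
#'   perturbation variable (ascending).
#' @return Symmetric band x band matrix.
#' @export
synchronousMap <- function(ordered_spectra) {
  x <- as.matrix(ordered_spectra)
  m <- nrow(x)
  if (m < 2) stop("at least 2 ordered spectra are required")
  y <- scale(x, center = TRUE, scale = FALSE)
  crossprod(y) / (m - 1)
}

# Hilbert-Noda transformation matrix: N[j,k] = 0 if j == k, else 1/(pi(k-j))
.hilbertNoda <- function(m) {
  jk <- outer(seq_len(m), seq_len(m), function(j, k) k - j)
  n <- 1 / (pi * jk)
  n[jk == 0] <- 0
  n
}

#' Asynchronous 2D correlation map
#'
#' \deqn{\Psi(\nu_1,\nu_2) = \frac{1}{m-1}\sum_j \tilde y_j(\nu_1)
#' \sum_k N_{jk}\,\tilde y_k(\nu_2)} with the Hilbert-Noda matrix
#' \eqn{N_{jk} = 1/(\pi(k-j))} (0 on the diagonal). Antisymmetric with zero
#' diagonal; identically zero for rank-1 dynamic spectra.
#'
#' @inheritParams synchronousMap
#' @return Antisymmetric band x band matrix.
#' @export
asynchronousMap <- function(ordered_spectra) {
  x <- as.matrix(ordered_spectra)
  m <- nrow(x)
  if (m < 2) stop("at least 2 ordered spectra are required")
  y <- scale(x, center = TRUE, scale = FALSE)
  psi <- crossprod(y, .hilbertNoda(m) %*% y) / (m - 1)
  psi <- (psi - t(psi)) / 2  # remove numerical symmetric residue
  diag(psi) <- 0
  psi
}

#' Two-trace 2D correlation maps (2T2DCOS)
#'
#' Correlation maps built from exactly two spectra a and b (here typically
#' the filling- and milk-stage spectra of one plot):
#' \deqn{\Phi = \tfrac12\left[a(\nu_1)a(\nu_2) + b(\nu_1)b(\nu_2)\right]}
#' \deqn{\Psi = \tfrac12\left[a(\nu_1)b(\nu_2) - a(\nu_2)b(\nu_1)\right]}
#'
#' @param trace_a,trace_b Numeric spectra on identical grids.
#' @param wavelengths Optional wavelength grid (defaults to names or index).
#' @return A [CorrelationMaps-class] with `kind = "two_trace"`.
#' @export
twoTraceMaps <- function(trace_a, trace_b, wavelengths = NULL) {
  a <- as.numeric(trace_a); b <- as.numeric(trace_b)
  if (length(a) != length(b)) stop("traces must be on identical grids")
  if (is.null(wavelengths)) {
    wavelengths <- suppressWarnings(as.numeric(names(trace_a)))
    if (anyNA(wavelengths) || !length(wavelengths)) {
      wavelengths <- seq_along(a)
    }
  }
  sync <- (outer(a, a) + outer(b, b)) / 2
  async <- (outer(a, b) - outer(b, a)) / 2
  diag(async) <- 0
  new("CorrelationMaps", wavelengths = as.numeric(wavelengths),
      sync = sync, async = async, kind = "two_trace")
}

#' Perturbation 2DCOS maps for a trait-ordered SpectralSet
#'
#' Orders the samples by ascending trait value (ties broken by sample_id)
#' and builds the synchronous/asynchronous maps.
#'
#' @param ds A [SpectralSet-class] whose metadata contains `trait`.
#' @param trait Numeric trait column name (the perturbation variable).
#' @return A [CorrelationMaps-class] with `kind = "perturbation_2dcos"`.
#' @export
correlationMaps <- function(ds, trait) {
  meta <- sampleMeta(ds)
  if (!trait %in% names(meta)) stop("trait '", trait, "' not found")
  tv <- meta[[trait]]
  if (!is.numeric(tv) || anyNA(tv)) {
    stop("trait '", trait, "' must be numeric for all samples")
  }
  if (diff(range(tv)) == 0) {
    stop("constant trait: perturbation ordering undefined")
  }
  ord <- order(tv, meta$sample_id)
  x <- spectra(ds)[ord, , drop = FALSE]
  new("CorrelationMaps", wavelengths = wavelengths(ds),
      sync = synchronousMap(x), async = asynchronousMap(x),
      kind = "perturbation_2dcos")
}

#' Extract autopeak bands from a synchronous map
#'
#' Finds local maxima of the autocorrelation (diagonal of \eqn{\Phi}) with
#' intensity at least `rel_threshold` of the largest autopeak; peaks closer
#' than `min_separation_nm` are merged keeping the stronger one (ties keep
#' the lower wavelength).
#'
#' @param maps A [CorrelationMaps-class].
#' @param rel_threshold Fraction of the maximum autopeak (0, 1\].
#' @param min_separation_nm Minimum separation between kept peaks, nm.
#' @return A [BandSet-class] (empty, not an error, for an all-zero diagonal).
#' @export
autopeakBands <- function(maps, rel_threshold = 0.1, min_separation_nm = 10) {
  stopifnot(rel_threshold > 0, rel_threshold <= 1)
  d <- diag(syncMap(maps))
  wl <- maps@wavelengths
  if (max(d) <= 0) {
    return(new("BandSet", wavelengths = numeric(0), support = integer(0),
               provenance = list(method = "autopeak",
                                 rel_threshold = rel_threshold,
                                 min_separation_nm = min_separation_nm)))
  }
  kept <- .pickPeaks(d, wl, rel_threshold, min_separation_nm)
  new("BandSet", wavelengths = wl[kept],
      support = rep(1L, length(kept)),
      provenance = list(method = "autopeak", rel_threshold = rel_threshold,
                        min_separation_nm = min_separation_nm))
}

# local-maxima peak picking on an autocorrelation profile: indices of local
# maxima >= rel_threshold * max, merged within min_separation (larger peak
# wins, ties keep the lower wavelength). Grid-boundary bands are not peak
# candidates: a maximum there cannot be verified on both sides, and the
# one-sided derivative estimate at the ends is the noisiest of the grid.
.pickPeaks <- function(d, wl, rel_threshold, min_separation_nm) {
  nb <- length(d)
  is_peak <- vapply(seq_len(nb), function(i) {
    if (nb >= 3 && (i == 1 || i == nb)) return(FALSE)
    left <- if (i > 1) d[i] >= d[i - 1] else TRUE
    right <- if (i < nb) d[i] >= d[i + 1] else TRUE
    strict <- (i > 1 && d[i] > d[i - 1]) || (i < nb && d[i] > d[i + 1]) ||
      nb == 1
    left && right && strict
  }, logical(1))
  cand <- which(is_peak & d >= rel_threshold * max(d))
  ord <- cand[order(-d[cand], wl[cand])]
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) || all(abs(wl[i] - wl[kept]) >= min_separation_nm)) {
      kept <- c(kept, i)
    }
  }
  sort(kept)
}

#' 1Der-2DCOS band selection
#'
#' The derivative-enhanced 2DCOS pipeline: first derivative of the spectra,
#' samples ordered by the ascending trait (the perturbation), synchronous
#' map, autopeak extraction.
#'
#' @inheritParams correlationMaps
#' @inheritParams autopeakBands
#' @param derivative_window,derivative_poly Savitzky-Golay settings passed to
#'   [firstDerivative()] (skipped if `ds` is already derivative-flagged).
#' @return A [BandSet-class]; provenance records the trait and parameters.
#' @export
selectBands1Der2DCOS <- function(ds, trait, rel_threshold = 0.1,
                                 min_separation_nm = 10,
                                 derivative_window = 15,
                                 derivative_poly = 2) {
  dds <- if (isDerivative(ds)) ds else {
    firstDerivative(ds, "savgol", derivative_window, derivative_poly)
  }
  maps <- correlationMaps(dds, trait)
  bs <- autopeakBands(maps, rel_threshold, min_separation_nm)
  bs@provenance <- c(list(method = "1Der-2DCOS", trait = trait),
                     bs@provenance[-1])
  bs
}

#' Two-stage 2T2DCOS consensus band selection
#'
#' For each sample paired across two growth stages (matched by `sample_id`,
#' i.e. by plot), builds the two-trace maps of the two derivative spectra,
#' extracts autopeak bands, and keeps bands supported by strictly more than
#' `majority_fraction` of the pairs (the filling-milk coupling used for
#' aboveground biomass, where a band must be selected by over half of the
#' samples).
#'
#' Because autopeak positions jitter by a few nanometres between samples
#' (sensor noise moves a derivative extremum slightly), support is counted
#' with a small tolerance: a pair supports a band if it produced an
#' autopeak within `support_tol_nm` of it. Reported band positions are the
#' local maxima of the tolerance-windowed support profile.
#'
#' @param ds_stage_a,ds_stage_b [SpectralSet-class] objects sharing
#'   `sample_id`s.
#' @param majority_fraction Strict support threshold as a fraction of pairs.
#' @param support_tol_nm Peak-position tolerance for support counting.
#' @inheritParams autopeakBands
#' @inheritParams selectBands1Der2DCOS
#' @return A [BandSet-class] with per-band support counts.
#' @export
selectBands2T2DCOS <- function(ds_stage_a, ds_stage_b,
                               majority_fraction = 0.5,
                               rel_threshold = 0.1, min_separation_nm = 10,
                               support_tol_nm = 3,
                               derivative_window = 15, derivative_poly = 2) {
  ids_a <- sampleMeta(ds_stage_a)$sample_id
  ids_b <- sampleMeta(ds_stage_b)$sample_id
  unpaired <- c(setdiff(ids_a, ids_b), setdiff(ids_b, ids_a))
  if (length(unpaired)) {
    stop("unpaired sample_ids: ", paste(unpaired, collapse = ", "))
  }
  if (!identical(wavelengths(ds_stage_a), wavelengths(ds_stage_b))) {
    stop("the two stages must share a wavelength grid")
  }
  da <- if (isDerivative(ds_stage_a)) ds_stage_a else {
    firstDerivative(ds_stage_a, "savgol", derivative_window, derivative_poly)
  }
  db <- if (isDerivative(ds_stage_b)) ds_stage_b else {
    firstDerivative(ds_stage_b, "savgol", derivative_window, derivative_poly)
  }
  xa <- spectra(da)
  xb <- spectra(db)[match(ids_a, ids_b), , drop = FALSE]
  wl <- wavelengths(ds_stage_a)
  hits <- matrix(FALSE, length(ids_a), length(wl))
  for (i in seq_along(ids_a)) {
    # only the synchronous diagonal (a^2 + b^2) / 2 is needed for autopeaks
    d <- (xa[i, ]^2 + xb[i, ]^2) / 2
    if (max(d) <= 0) next
    hits[i, .pickPeaks(d, wl, rel_threshold, min_separation_nm)] <- TRUE
  }
  n <- length(ids_a)
  # windowed support: pair i supports band w if it peaked within the
  # tolerance of w
  step <- median(diff(wl))
  half <- max(0L, round(support_tol_nm / step))
  support <- integer(length(wl))
  for (j in seq_along(wl)) {
    win <- max(1, j - half):min(length(wl), j + half)
    support[j] <- sum(apply(hits[, win, drop = FALSE], 1, any))
  }
  thr <- majority_fraction * n
  kept <- .pickPeaks(support + 1e-9, wl, rel_threshold = 1e-9,
                     min_separation_nm = min_separation_nm)
  kept <- kept[support[kept] > thr]  # strictly more than the majority
  new("BandSet", wavelengths = wl[kept], support = support[kept],
      provenance = list(method = "filling-milk-2T2DCOS",
                        majority_fraction = majority_fraction,
                        n_pairs = n, rel_threshold = rel_threshold,
                        min_separation_nm = min_separation_nm,
                        support_tol_nm = support_tol_nm))
}

#' Repeated-subsampling band-selection stability
#'
#' Draws `n_draws` random subsets at each dataset fraction (stratified by
#' trait quantile bins so subsets track the full trait distribution), runs
#' [selectBands1Der2DCOS()] on each, and reports per-band selection counts
#' together with the stable band set (bands selected in at least
#' `min_count` draws).
#'
#' A draw supports a band if it selected a peak within `support_tol_nm` of
#' it. Unlike the cross-plot consensus of [selectBands2T2DCOS()] (where
#' sensor noise moves peaks between physically distinct samples), the draws
#' here resample the *same* measured dataset, so genuine peaks reproduce at
#' identical grid positions; the default is therefore exact counting
#' (`support_tol_nm = 0`), which also keeps the pure-noise null clean.
#'
#' @inheritParams selectBands1Der2DCOS
#' @param fractions Numeric vector of dataset fractions in (0, 1\].
#' @param n_draws Number of random draws per fraction.
#' @param min_count Minimum selection count for a band to be called stable.
#' @param support_tol_nm Peak-position tolerance for support counting.
#' @param seed Integer seed (subset draws are reproducible under it).
#' @param n_bins Number of trait-quantile strata.
#' @return A list with one element per fraction, each containing `counts`
#'   (named integer vector over selected wavelengths) and `stable`
#'   (a [BandSet-class]). Fractions yielding subsets of fewer than 10
#'   samples are skipped with a warning.
#' @export
repeatedSelectionStability <- function(ds, trait, fractions = c(0.3, 0.6, 1),
                                       n_draws = 10, min_count = 8,
                                       rel_threshold = 0.1,
                                       min_separation_nm = 10,
                                       support_tol_nm = 0,
                                       seed = 1, n_bins = 4) {
  stopifnot(all(fractions > 0), all(fractions <= 1), n_draws >= min_count)
  dds <- if (isDerivative(ds)) ds else firstDerivative(ds)
  meta <- sampleMeta(dds)
  tv <- meta[[trait]]
  n <- nrow(meta)
  bins <- cut(rank(tv, ties.method = "first"),
              breaks = n_bins, labels = FALSE)
  wl <- wavelengths(dds)
  step <- median(diff(wl))
  half <- max(0L, round(support_tol_nm / step))
  out <- list()
  for (f in fractions) {
    size <- floor(f * n + 0.5)
    if (size < 10) {
      warning("fraction ", f, " gives subset of ", size, " < 10; skipped")
      next
    }
    hits <- matrix(FALSE, n_draws, length(wl))
    for (d in seq_len(n_draws)) {
      idx <- withr::with_seed(seed * 10000 + round(f * 1000) + d, {
        if (f >= 1) seq_len(n) else {
          unlist(lapply(split(seq_len(n), bins), function(ix) {
            k <- max(1, floor(f * length(ix) + 0.5))
            sample(ix, min(k, length(ix)))
          }), use.names = FALSE)
        }
      })
      sub <- SpectralSet(spectra(dds)[idx, , drop = FALSE],
                         wl, meta[idx, , drop = FALSE],
                         derivative = TRUE)
      bs <- selectBands1Der2DCOS(sub, trait, rel_threshold,
                                 min_separation_nm)
      hits[d, match(bandWavelengths(bs), wl)] <- TRUE
    }
    support <- integer(length(wl))
    for (j in seq_along(wl)) {
      win <- max(1, j - half):min(length(wl), j + half)
      support[j] <- sum(apply(hits[, win, drop = FALSE], 1, any))
    }
    kept <- .pickPeaks(support + 1e-9, wl, rel_threshold = 1e-9,
                       min_separation_nm = min_separation_nm)
    kept <- kept[support[kept] >= min_count]
    counts <- setNames(support[support > 0], wl[support > 0])
    out[[as.character(f)]] <- list(
      counts = counts,
      stable = new("BandSet", wavelengths = wl[kept],
                   support = support[kept],
                   provenance = list(method = "repeated-1Der-2DCOS",
                                     fraction = f, n_draws = n_draws,
                                     min_count = min_count, trait = trait,
                                     support_tol_nm = support_tol_nm))
    )
  }
  out
}
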