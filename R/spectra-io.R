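#' Construct a SpectralSet
#'
#' @param reflectance Numeric sample x wavelength matrix.
#' @param wavelengths Numeric wavelength grid (nm), strictly increasing after
#'   sorting; columns of `reflectance` are permuted to match.
#' @param meta data.frame of per-sample metadata (one row per sample);
#'   a `sample_id` column is created from rownames when absent.
#' @param derivative Logical; `TRUE` marks derivative spectra (the \[0, 1\]
#'   bound is then not enforced).
#' @return A [SpectralSet-class] object.
#' @examples
#' ss <- SpectralSet(matrix(runif(6), 2, 3), c(500, 600, 700),
#'                   data.frame(sample_id = c("a", "b")))
#' @export
SpectralSet <- function(reflectance, wavelengths,
                        meta = NULL, derivative = FALSE) {
  reflectance <- as.matrix(reflectance)
  wavelengths <- as.numeric(wavelengths)
  if (ncol(reflectance) != length(wavelengths)) {
    stop("reflectance must have one column per wavelength")
  }
  if (anyDuplicated(wavelengths)) stop("duplicate wavelengths")
  ord <- order(wavelengths)
  wavelengths <- wavelengths[ord]
  reflectance <- reflectance[, ord, drop = FALSE]
  n <- nrow(reflectance)
  if (is.null(meta)) {
    meta <- data.frame(sample_id = paste0("s", seq_len(n)))
  }
  meta <- as.data.frame(meta)
  if (nrow(meta) != n) stop("meta row count must equal sample count")
  if (!"sample_id" %in% names(meta)) {
    meta$sample_id <- if (!is.null(rownames(reflectance))) {
      rownames(reflectance)
    } else paste0("s", seq_len(n))
  }
  assay <- t(reflectance)
  dimnames(assay) <- list(as.character(wavelengths), meta$sample_id)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(reflectance = assay),
    rowData = S4Vectors::DataFrame(wavelength = wavelengths),
    colData = S4Vectors::DataFrame(meta, row.names = meta$sample_id)
  )
  new("SpectralSet", se, derivative = isTRUE(derivative))
}

#' Read a wide spectral table (CSV)
#'
#' One row per sample; metadata columns first, then one column per
#' wavelength whose header parses as a number. Off-grid (non-integer)
#' wavelengths are resampled onto the canonical 1 nm integer grid by linear
#' interpolation; wavelength columns given out of order are sorted.
#'
#' @param path CSV file path.
#' @param meta_columns Character vector of metadata column names (all
#'   non-numeric headers are treated as metadata by default).
#' @param derivative Logical flag stored on the result.
#' @return A [SpectralSet-class].
#' @export
loadSpectralTable <- function(path, meta_columns = NULL, derivative = FALSE) {
  df <- read.csv(path, check.names = FALSE)
  wl_num <- suppressWarnings(as.numeric(names(df)))
  is_wl <- !is.na(wl_num)
  if (!is.null(meta_columns)) {
    missing <- setdiff(meta_columns, names(df))
    if (length(missing)) {
      stop("meta columns not found: ", paste(missing, collapse = ", "))
    }
    is_wl <- is_wl & !(names(df) %in% meta_columns)
  }
  if (!any(is_wl)) stop("no wavelength columns found in ", path)
  if (anyDuplicated(wl_num[is_wl])) {
    stop("format error: duplicate wavelength column in ", path)
  }
  refl <- df[, is_wl, drop = FALSE]
  bad <- which(!vapply(refl, is.numeric, logical(1)))
  if (length(bad)) {
    for (j in bad) {
      v <- suppressWarnings(as.numeric(refl[[j]]))
      if (anyNA(v)) {
        row <- which(is.na(v))[1]
        stop("parse error: non-numeric reflectance at row ", row,
             ", column '", names(refl)[j], "'")
      }
      refl[[j]] <- v
    }
  }
  wl <- wl_num[is_wl]
  ord <- order(wl)
  wl <- wl[ord]
  mat <- as.matrix(refl)[, ord, drop = FALSE]
  if (any(abs(wl - round(wl)) > 1e-9)) {
    grid <- seq(ceiling(min(wl)), floor(max(wl)))
    mat <- t(apply(mat, 1, function(y) approx(wl, y, xout = grid)$y))
    wl <- grid
  }
  meta <- df[, !is_wl, drop = FALSE]
  if (!ncol(meta)) meta <- NULL
  SpectralSet(mat, wl, meta, derivative = derivative)
}

#' Write a SpectralSet as a wide CSV table
#'
#' Inverse of [loadSpectralTable()]: metadata columns first, then one column
#' per wavelength.
#'
#' @param ds A [SpectralSet-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeSpectralTable <- function(ds, path) {
  out <- cbind(sampleMeta(ds), as.data.frame(spectra(ds)))
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' First-derivative preprocessing of spectra
#'
#' Computes d(reflectance)/d(wavelength) per sample, either by central finite
#' differences (one-sided at the ends) or by Savitzky-Golay filtering
#' (default window 15, polynomial order 2 - a common choice for field
#' spectroradiometer data).
#'
#' @param ds A [SpectralSet-class] on a uniform wavelength grid.
#' @param method `"savgol"` (default) or `"finite_diff"`.
#' @param window Odd Savitzky-Golay window length (> `poly`).
#' @param poly Savitzky-Golay polynomial order.
#' @return A derivative-flagged [SpectralSet-class] of the same dimensions.
#' @export
firstDerivative <- function(ds, method = c("savgol", "finite_diff"),
                            window = 15, poly = 2) {
  method <- match.arg(method)
  wl <- wavelengths(ds)
  dwl <- diff(wl)
  if (max(abs(dwl - dwl[1])) > 1e-8) {
    stop("first derivative requires a uniform wavelength grid")
  }
  h <- dwl[1]
  x <- spectra(ds)
  if (method == "savgol") {
    if (window %% 2 == 0 || window <= poly) {
      stop("config error: savgol window must be odd and > poly")
    }
    if (ncol(x) < window) stop("fewer bands than the savgol window")
    half <- (window - 1) / 2
    nb <- ncol(x)
    d <- t(apply(x, 1, function(y) {
      dy <- signal::sgolayfilt(y, p = poly, n = window, m = 1, ts = h)
      # the filter start-up transient distorts the first/last half-window;
      # use plain finite differences there instead
      for (j in seq_len(half)) {
        dy[j] <- if (j == 1) (y[2] - y[1]) / h else
          (y[j + 1] - y[j - 1]) / (2 * h)
        jr <- nb - j + 1
        dy[jr] <- if (j == 1) (y[nb] - y[nb - 1]) / h else
          (y[jr + 1] - y[jr - 1]) / (2 * h)
      }
      dy
    }))
  } else {
    nb <- ncol(x)
    d <- matrix(0, nrow(x), nb)
    if (nb >= 3) {
      d[, 2:(nb - 1)] <- (x[, 3:nb] - x[, 1:(nb - 2)]) / (2 * h)
    }
    d[, 1] <- (x[, 2] - x[, 1]) / h
    d[, nb] <- (x[, nb] - x[, nb - 1]) / h
  }
  SpectralSet(d, wl, sampleMeta(ds), derivative = TRUE)
}

#' Normalize a list of band windows
#'
#' @param windows List of `c(lo, hi)` closed intervals in nm, or a 2-column
#'   matrix. Intervals are sorted and overlapping/touching ones merged.
#' @return A 2-column matrix (`lo`, `hi`) of disjoint intervals.
#' @export
bandWindows <- function(windows) {
  if (is.matrix(windows)) windows <- split(windows, row(windows))
  m <- do.call(rbind, lapply(windows, function(w) {
    if (length(w) != 2 || w[1] > w[2]) stop("each window must be c(lo, hi) with lo <= hi")
    as.numeric(w)
  }))
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  for (i in seq_len(nrow(m))[-1]) {
    if (m[i, 1] <= out[nrow(out), 2]) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, ])
    }
  }
  colnames(out) <- c("lo", "hi")
  out
}

#' Default modeling windows for the hybrid inversion
#'
#' The forward-model fit is poor at 400-615 and 765-990 nm, so hybrid
#' modeling is restricted to 615-765 nm and 990-2500 nm by default.
#'
#' @return A 2-column window matrix, see [bandWindows()].
#' @export
defaultModelingWindows <- function() {
  bandWindows(list(c(615, 765), c(990, 2500)))
}

#' Restrict a SpectralSet to band windows
#'
#' @param ds A [SpectralSet-class].
#' @param keep Band windows ([bandWindows()] input or matrix).
#' @return The subset [SpectralSet-class]; wavelength order preserved.
#' @export
maskWindows <- function(ds, keep) {
  keep <- bandWindows(if (is.matrix(keep)) split(keep, row(keep)) else keep)
  wl <- wavelengths(ds)
  sel <- rep(FALSE, length(wl))
  for (i in seq_len(nrow(keep))) {
    sel <- sel | (wl >= keep[i, 1] & wl <= keep[i, 2])
  }
  if (!any(sel)) {
    stop("no wavelengths fall inside windows [",
         paste(apply(keep, 1, paste, collapse = "-"), collapse = ", "), "]")
  }
  SpectralSet(spectra(ds)[, sel, drop = FALSE], wl[sel], sampleMeta(ds),
              derivative = isDerivative(ds))
}

#' Concatenate SpectralSets sharing a wavelength grid
#'
#' Row-binds the samples of several [SpectralSet-class] objects (e.g. the
#' jointing and filling stages, pooled for the canopy LPC model); metadata
#' columns are reduced to the common set.
#'
#' @param ... [SpectralSet-class] objects on identical grids with equal
#'   derivative flags.
#' @return A single [SpectralSet-class].
#' @export
combineSpectralSets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1)
  wl <- wavelengths(sets[[1]])
  der <- isDerivative(sets[[1]])
  for (s in sets[-1]) {
    if (!identical(wavelengths(s), wl)) stop("wavelength grids differ")
    if (!identical(isDerivative(s), der)) stop("derivative flags differ")
  }
  metas <- lapply(sets, sampleMeta)
  common <- Reduce(intersect, lapply(metas, names))
  SpectralSet(do.call(rbind, lapply(sets, spectra)), wl,
              do.call(rbind, lapply(metas, `[`, common)),
              derivative = der)
}

#' Deterministic train/test split
#'
#' Train size is `floor(ratio * n + 0.5)`; when `stratify_by` names a
#' metadata column the split is drawn per stratum (strata with fewer than
#' two samples are kept whole in the training set, with a warning).
#'
#' @param ds A [SpectralSet-class].
#' @param ratio Training fraction in (0, 1).
#' @param stratify_by Metadata column name or `NULL`.
#' @param seed Integer seed; the split is reproducible under it.
#' @return List with elements `train` and `test` ([SpectralSet-class]),
#'   a disjoint, exhaustive partition of the input samples.
#' @export
splitTrainTest <- function(ds, ratio = 0.7, stratify_by = NULL, seed = 1) {
  stopifnot(ratio > 0, ratio < 1)
  n <- ncol(ds)
  meta <- sampleMeta(ds)
  idx_train <- withr::with_seed(seed, {
    if (is.null(stratify_by)) {
      sample(n, floor(ratio * n + 0.5))
    } else {
      if (!stratify_by %in% names(meta)) {
        stop("stratification column '", stratify_by, "' not found")
      }
      strata <- split(seq_len(n), meta[[stratify_by]])
      unlist(lapply(strata, function(ix) {
        if (length(ix) < 2) {
          warning("stratum with fewer than 2 samples kept whole in train")
          return(ix)
        }
        sample(ix, floor(ratio * length(ix) + 0.5))
      }), use.names = FALSE)
    }
  })
  idx_train <- sort(idx_train)
  idx_test <- setdiff(seq_len(n), idx_train)
  x <- spectra(ds)
  list(
    train = SpectralSet(x[idx_train, , drop = FALSE], wavelengths(ds),
                        meta[idx_train, , drop = FALSE],
                        derivative = isDerivative(ds)),
    test = SpectralSet(x[idx_test, , drop = FALSE], wavelengths(ds),
                       meta[idx_test, , drop = FALSE],
                       derivative = isDerivative(ds))
  )
}
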