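#' Fit a regressor
#'
#' Uniform wrapper over the regressors used across the empirical and hybrid
#' branches: support vector regression (`"SVR"`, via e1071), gradient
#' boosting (`"GBRT"`, via xgboost), a single-hidden-layer back-propagation
#' network (`"BPNN"`, via nnet, 16 units by default), random forest
#' (`"RF"`, via ranger with impurity importance), an extreme learning
#' machine (`"ELM"`, implemented here: random fixed hidden layer +
#' Moore-Penrose output weights) and `"polynomial"` (least-squares
#' polynomial in a single feature). Fits are reproducible under `seed`.
#'
#' @param kind One of `"SVR"`, `"GBRT"`, `"BPNN"`, `"RF"`, `"ELM"`,
#'   `"polynomial"`, or `"committee"` (the average of the SVR, GBRT and RF
#'   predictions - a simple committee that damps the variance any single
#'   learner shows on field-campaign sample sizes).
#' @param X Numeric feature matrix (n x p), no missing values.
#' @param y Numeric response, length n.
#' @param hyperparams Named list overriding the per-kind defaults
#'   (`ELM`: `n_hidden = 100`, `activation = "sigmoid"`; `RF`/`GBRT`:
#'   `num_trees = 500`; `BPNN`: `size = 16`, `maxit = 500`;
#'   `polynomial`: `degree = 2`).
#' @param seed Integer seed.
#' @return An object of class `spuRegressor` with a [predict][stats::predict]
#'   method; carries `kind`, `hyperparams` and `seed` for serialization.
#' @export
fitRegressor <- function(kind, X, y, hyperparams = list(), seed = 1) {
  kinds <- c("SVR", "GBRT", "BPNN", "RF", "ELM", "polynomial", "committee")
  if (!kind %in% kinds) {
    stop("unknown regressor kind '", kind, "' (use one of ",
         paste(kinds, collapse = ", "), ")")
  }
  X <- as.matrix(X)
  if (ncol(X) == 0) stop("at least one feature is required")
  stopifnot(nrow(X) >= 5, length(y) == nrow(X))
  if (anyNA(X) || anyNA(y)) stop("missing values are not allowed")
  if (var(y) == 0) {
    warning("degenerate response (zero variance): constant predictor")
    fit <- list(constant = y[1])
    return(structure(list(kind = "constant", fit = fit,
                          hyperparams = hyperparams, seed = seed,
                          p = ncol(X)),
                     class = "spuRegressor"))
  }
  if (kind == "committee") {
    members <- lapply(c("GBRT", "SVR", "RF"), function(k) {
      fitRegressor(k, X, y,
                   hyperparams = hyperparams[[k]] %||%
                     (if (k == "GBRT") list(max_depth = 2, eta = 0.03,
                                            num_trees = 800,
                                            subsample = 0.7) else list()),
                   seed = seed)
    })
    return(structure(list(kind = "committee", fit = members,
                          hyperparams = hyperparams, seed = seed,
                          p = ncol(X)),
                     class = "spuRegressor"))
  }
  hp <- hyperparams
  fit <- withr::with_seed(seed, switch(kind,
    SVR = e1071::svm(X, y,
                     kernel = hp$kernel %||% "radial",
                     cost = hp$cost %||% 10,
                     gamma = hp$gamma %||% (1 / ncol(X)),
                     epsilon = hp$epsilon %||% 0.01),
    GBRT = xgboost::xgboost(x = X, y = y,
                            nrounds = hp$num_trees %||% 500,
                            max_depth = hp$max_depth %||% 4,
                            learning_rate = hp$eta %||% 0.05,
                            subsample = hp$subsample %||% 0.8,
                            nthreads = 1, seed = seed,
                            verbosity = 0),
    BPNN = nnet::nnet(X, y, size = hp$size %||% 16, linout = TRUE,
                      maxit = hp$maxit %||% 500,
                      decay = hp$decay %||% 1e-4,
                      MaxNWts = 1e5, trace = FALSE),
    RF = ranger::ranger(y = y,
                        x = as.data.frame(X),
                        num.trees = hp$num_trees %||% 500,
                        mtry = hp$mtry %||% max(1, floor(ncol(X) / 3)),
                        importance = "impurity",
                        num.threads = 1,
                        verbose = FALSE,
                        seed = seed),
    ELM = .fitELM(X, y, n_hidden = hp$n_hidden %||% 100,
                  activation = hp$activation %||% "sigmoid",
                  lambda = hp$lambda %||% 0,
                  ensemble = hp$ensemble %||% 1),
    polynomial = {
      if (ncol(X) != 1) stop("polynomial regression expects one feature")
      degree <- hp$degree %||% 2
      df <- data.frame(x = X[, 1], y = y)
      lm(y ~ poly(x, degree, raw = TRUE), data = df)
    }
  ))
  structure(list(kind = kind, fit = fit, hyperparams = hp, seed = seed,
                 p = ncol(X)),
             class = "spuRegressor")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Extreme learning machine: fixed random hidden layer(s), least-squares
# output weights via the Moore-Penrose pseudoinverse (lambda = 0) or a
# ridge-regularized solve (lambda > 0). Features are standardized so the
# random projections are scale-free; `ensemble` independent networks can be
# averaged to damp the random-projection variance.
.fitELM <- function(X, y, n_hidden = 100, activation = "sigmoid",
                    lambda = 0, ensemble = 1) {
  mu <- colMeans(X)
  sdv <- apply(X, 2, sd); sdv[sdv == 0] <- 1
  Xs <- sweep(sweep(X, 2, mu), 2, sdv, "/")
  d <- ncol(X)
  act <- switch(activation,
                sigmoid = function(z) 1 / (1 + exp(-z)),
                linear = identity,
                tanh = tanh,
                stop("unknown ELM activation '", activation, "'"))
  nets <- lapply(seq_len(ensemble), function(e) {
    W <- matrix(runif(n_hidden * d, -1, 1), n_hidden, d)
    b <- runif(n_hidden, -1, 1)
    H <- act(Xs %*% t(W) + matrix(b, nrow(X), n_hidden, byrow = TRUE))
    beta <- if (lambda > 0) {
      solve(crossprod(H) + lambda * diag(n_hidden), crossprod(H, y))
    } else {
      MASS::ginv(H) %*% y
    }
    list(W = W, b = b, beta = beta)
  })
  list(nets = nets, mu = mu, sd = sdv, act = activation)
}

.predictELM <- function(fit, X) {
  Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sd, "/")
  act <- switch(fit$act,
                sigmoid = function(z) 1 / (1 + exp(-z)),
                linear = identity, tanh = tanh)
  preds <- lapply(fit$nets, function(nt) {
    H <- act(Xs %*% t(nt$W) + matrix(nt$b, nrow(X), nrow(nt$W),
                                     byrow = TRUE))
    as.numeric(H %*% nt$beta)
  })
  Reduce(`+`, preds) / length(preds)
}

#' @rdname fitRegressor
#' @param object A fitted `spuRegressor`.
#' @param newdata Feature matrix with the training feature count.
#' @param ... Unused.
#' @export
predict.spuRegressor <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  if (object$kind != "polynomial" && ncol(X) != object$p) {
    stop("feature count mismatch: model expects ", object$p,
         ", got ", ncol(X))
  }
  switch(object$kind,
    constant = rep(object$fit$constant, nrow(X)),
    committee = {
      preds <- lapply(object$fit, predict, newdata = X)
      Reduce(`+`, preds) / length(preds)
    },
    SVR = as.numeric(predict(object$fit, X)),
    GBRT = as.numeric(predict(object$fit, X)),
    BPNN = as.numeric(predict(object$fit, X)),
    RF = predict(object$fit, as.data.frame(X),
                 num.threads = 1)$predictions,
    ELM = .predictELM(object$fit, X),
    polynomial = as.numeric(predict(object$fit,
                                    data.frame(x = X[, 1])))
  )
}

#' ELM prediction helper
#'
#' Convenience wrapper equivalent to `predict()` on an `"ELM"`
#' [fitRegressor()] model.
#'
#' @param model A fitted `spuRegressor` of kind `"ELM"`.
#' @param X Feature matrix.
#' @return Numeric predictions `H(X) %*% beta`.
#' @export
elmPredict <- function(model, X) {
  if (!inherits(model, "spuRegressor") ||
      !model$kind %in% c("ELM", "constant")) {
    stop("model must be a fitted ELM regressor")
  }
  predict(model, X)
}

#' Dual-band index features
#'
#' Builds difference (DSI = R_i - R_j), ratio (RSI = R_i / R_j) and
#' normalized-difference (NDSI = (R_i - R_j) / (R_i + R_j)) indices for band
#' pairs of a [BandSet-class]. DSI and NDSI are computed on unordered pairs
#' with i the longer wavelength (so 14 bands give 91 features per form);
#' RSI uses ordered pairs (182). RSI pairs whose denominator band has
#' |R| < 1e-6 anywhere are dropped with a warning.
#'
#' @param ds A [SpectralSet-class] containing every requested band.
#' @param bands A [BandSet-class] (or numeric wavelengths).
#' @param forms Subset of `c("DSI", "RSI", "NDSI")`.
#' @return A list with `features` (n x k matrix, named like `DSI_850_670`)
#'   and `info` (data.frame: form, band_i, band_j).
#' @export
dualBandIndexFeatures <- function(ds, bands, forms = c("DSI", "RSI", "NDSI")) {
  forms <- match.arg(forms, several.ok = TRUE)
  wl_sel <- if (inherits(bands, "BandSet")) bandWavelengths(bands) else
    as.numeric(bands)
  if (length(wl_sel) < 2) stop("at least 2 bands are required")
  wl <- wavelengths(ds)
  missing <- setdiff(wl_sel, wl)
  if (length(missing)) {
    stop("bands not on the dataset grid: ", paste(missing, collapse = ", "))
  }
  R <- spectra(ds)[, match(wl_sel, wl), drop = FALSE]
  colnames(R) <- as.character(wl_sel)
  n <- nrow(R)
  feats <- list(); info <- list()
  addf <- function(name, values, form, bi, bj) {
    feats[[name]] <<- values
    info[[name]] <<- data.frame(form = form, band_i = bi, band_j = bj)
  }
  wl_sorted <- sort(wl_sel)
  for (a in seq_along(wl_sorted)) {
    for (b in seq_len(a - 1)) {
      bi <- wl_sorted[a]; bj <- wl_sorted[b]  # i = longer wavelength
      Ri <- R[, as.character(bi)]; Rj <- R[, as.character(bj)]
      if ("DSI" %in% forms) {
        addf(paste0("DSI_", bi, "_", bj), Ri - Rj, "DSI", bi, bj)
      }
      if ("NDSI" %in% forms) {
        addf(paste0("NDSI_", bi, "_", bj), (Ri - Rj) / (Ri + Rj),
             "NDSI", bi, bj)
      }
      if ("RSI" %in% forms) {
        for (pair in list(c(bi, bj), c(bj, bi))) {
          num <- R[, as.character(pair[1])]
          den <- R[, as.character(pair[2])]
          if (any(abs(den) < 1e-6)) {
            warning("RSI pair ", pair[1], "/", pair[2],
                    " dropped: near-zero denominator")
            next
          }
          addf(paste0("RSI_", pair[1], "_", pair[2]), num / den,
               "RSI", pair[1], pair[2])
        }
      }
    }
  }
  list(features = do.call(cbind, feats),
       info = do.call(rbind, c(info, list(make.row.names = FALSE))))
}

#' Rank dual-band indices by correlation and keep the extremes
#'
#' Pearson-correlates every index with the response and keeps the
#' `top_pos` most positively and `top_neg` most negatively correlated
#' features (ties broken by |r|, then feature order). If fewer
#' positive/negative features exist than requested, what exists is returned
#' with a warning.
#'
#' @param features n x k feature matrix (from [dualBandIndexFeatures()]).
#' @param y Response vector (n >= 3).
#' @param top_pos,top_neg Counts of positively/negatively correlated
#'   features to keep.
#' @return List with `features` (subset matrix), `correlations` (named r
#'   values) and `selected` (column names).
#' @export
rankAndSelectIndices <- function(features, y, top_pos = 10, top_neg = 10) {
  stopifnot(length(y) >= 3, nrow(features) == length(y))
  r <- suppressWarnings(as.numeric(cor(features, y)))
  r[is.na(r)] <- 0
  names(r) <- colnames(features)
  pos <- which(r > 0); neg <- which(r < 0)
  if (length(pos) < top_pos || length(neg) < top_neg) {
    warning("fewer positive/negative correlated features than requested")
  }
  pick_pos <- pos[order(-r[pos], pos)][seq_len(min(top_pos, length(pos)))]
  pick_neg <- neg[order(r[neg], neg)][seq_len(min(top_neg, length(neg)))]
  sel <- c(pick_pos, pick_neg)
  list(features = features[, sel, drop = FALSE],
       correlations = r[sel], selected = colnames(features)[sel])
}

#' Top-k bands by random-forest importance
#'
#' @param model A fitted `spuRegressor` of kind `"RF"` (impurity
#'   importance), or a ranger fit.
#' @param k Number of bands/features to return (all if `k` exceeds the
#'   feature count).
#' @return Character vector of feature names, descending importance; the
#'   `importance` attribute carries the matching normalized importances
#'   (all features' normalized importances sum to 1).
#' @export
rfImportanceTopK <- function(model, k = 30) {
  fit <- if (inherits(model, "spuRegressor")) model$fit else model
  if (!inherits(fit, "ranger")) stop("model must be a random forest fit")
  imp <- sort(ranger::importance(fit), decreasing = TRUE)
  imp <- imp / sum(imp)
  out <- names(imp)[seq_len(min(k, length(imp)))]
  attr(out, "importance") <- unname(imp[seq_along(out)])
  out
}

#' Regression evaluation metrics
#'
#' R2 (1 - SSE/SST), RMSE, MAE, MAPE (mean |e|/|y| over nonzero observed)
#' and RPD (sample SD of the observed values over RMSE; > 2 is commonly
#' read as adequate for quantification).
#'
#' @param y_obs,y_pred Numeric vectors of equal length (n >= 2).
#' @return A one-row data.frame: `R2`, `RMSE`, `MAE`, `MAPE`, `RPD`, `n`.
#'   `RPD` is `Inf` when RMSE is 0; `MAPE` is `NaN` when every observation
#'   is 0.
#' @examples
#' evaluateMetrics(c(1, 2, 3, 4), c(1.5, 2.5, 2.5, 3.5))
#' @export
evaluateMetrics <- function(y_obs, y_pred) {
  stopifnot(length(y_obs) == length(y_pred), length(y_obs) >= 2)
  e <- y_pred - y_obs
  n <- length(y_obs)
  sse <- sum(e^2)
  sst <- sum((y_obs - mean(y_obs))^2)
  rmse <- sqrt(sse / n)
  nz <- y_obs != 0
  data.frame(
    R2 = 1 - sse / sst,
    RMSE = rmse,
    MAE = mean(abs(e)),
    MAPE = if (any(nz)) mean(abs(e[nz]) / abs(y_obs[nz])) else NaN,
    RPD = if (rmse > 0) sd(y_obs) / rmse else Inf,
    n = n
  )
}
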