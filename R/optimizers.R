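.clampBounds <- function(x, lower, upper) pmin(pmax(x, lower), upper)

# Mantegna's algorithm for Levy-flight step lengths, stability index beta
.levyStep <- function(d, beta = 1.5) {
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
              (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- rnorm(d, 0, sigma_u)
  v <- rnorm(d)
  u / abs(v)^(1 / beta)
}

.newOptResult <- function(best_x, best_f, history, archive) {
  new("OptResult", best_x = best_x, best_f = best_f,
      history = history,
      archive = if (is.null(archive)) data.frame() else archive)
}

#' Newton-Raphson-based optimizer (NRBO)
#'
#' Population metaheuristic built around a Newton-Raphson Search Rule - each
#' member takes a quasi-Newton step whose curvature term is estimated from
#' the population's best and worst members - plus a Trap Avoidance Operator
#' applied with probability `deciding_factor` to escape local minima.
#' Selection is greedy (a member moves only if the candidate improves), so
#' the best-so-far history is non-increasing. Every evaluated point is
#' clamped to the bounds; with `keep_archive = TRUE` all `pop * (iters + 1)`
#' evaluations are returned, which the active-learning candidate pool reuses.
#'
#' The published description leaves some constants open; here the
#' deciding factor defaults to 0.6, the step-shrink schedule is
#' `delta = (1 - 2 it / iters)^5`, and the trap operator mixes the best and
#' the population-mean positions with uniform random weights.
#'
#' @param objective Function mapping a numeric vector to a scalar.
#' @param lower,upper Numeric bound vectors (finite, equal length).
#' @param pop Population size (>= 4).
#' @param iters Number of iterations (0 returns the best initial member).
#' @param deciding_factor Probability of applying the trap-avoidance move.
#' @param seed Integer seed; the run is deterministic under it.
#' @param keep_archive Keep all evaluated (x, f) pairs.
#' @return An [OptResult-class].
#' @examples
#' r <- nrboMinimize(function(x) sum(x^2), rep(-5, 2), rep(5, 2),
#'                   pop = 10, iters = 20, seed = 1)
#' @export
nrboMinimize <- function(objective, lower, upper, pop = 30, iters = 200,
                         deciding_factor = 0.6, seed = 1,
                         keep_archive = FALSE) {
  stopifnot(pop >= 4, length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)),
            all(upper >= lower))
  d <- length(lower)
  withr::with_seed(seed, {
    X <- matrix(runif(pop * d, rep(lower, each = pop), rep(upper, each = pop)),
                pop, d)
    f <- apply(X, 1, objective)
    arch <- if (keep_archive) list(cbind(X, f = f)) else NULL
    best_i <- which.min(f)
    best_x <- X[best_i, ]; best_f <- f[best_i]
    history <- if (iters == 0) best_f else numeric(iters)
    for (it in seq_len(iters)) {
      delta <- (1 - 2 * it / iters)^5
      worst_i <- which.max(f)
      xw <- X[worst_i, ]; xb <- best_x
      Xmean <- colMeans(X)
      newX <- X
      for (i in seq_len(pop)) {
        r12 <- sample(setdiff(seq_len(pop), i), 2)
        xn <- X[i, ]
        # Newton-Raphson search rule: step ~ f'(x)/f''(x) estimated from
        # the spread between the worst and best members
        dx <- runif(d) * abs(xb - xn)
        denom <- 2 * (xw + xb - 2 * xn)
        denom[abs(denom) < 1e-12] <- 1e-12
        nrsr <- rnorm(d) * (xw - xb) * dx / denom
        rho <- runif(1) * (xb - xn) + runif(1) * (X[r12[1], ] - X[r12[2], ])
        x1 <- xn - nrsr + rho
        x2 <- xb - nrsr + rho
        r1 <- runif(1); r2 <- runif(1)
        cand <- r1 * (r1 * x1 + (1 - r1) * x2) + (1 - r1) * x2
        cand <- cand - r2 * delta * (x2 - x1)
        # trap avoidance operator
        if (runif(1) < deciding_factor) {
          theta1 <- runif(1, -1, 1); theta2 <- runif(1, -0.5, 0.5)
          mu1 <- 3 * runif(1); mu2 <- runif(1)
          cand <- if (runif(1) < 0.5) {
            cand + theta1 * (mu1 * xb - mu2 * xn) +
              theta2 * delta * (mu1 * Xmean - mu2 * xn)
          } else {
            xb + theta1 * (mu1 * xb - mu2 * xn) +
              theta2 * delta * (mu1 * Xmean - mu2 * xn)
          }
        }
        newX[i, ] <- .clampBounds(cand, lower, upper)
      }
      newf <- apply(newX, 1, objective)
      if (keep_archive) arch[[length(arch) + 1]] <- cbind(newX, f = newf)
      improve <- newf < f
      X[improve, ] <- newX[improve, , drop = FALSE]
      f[improve] <- newf[improve]
      if (min(f) < best_f) {
        best_f <- min(f); best_x <- X[which.min(f), ]
      }
      history[it] <- best_f
    }
    archive <- NULL
    if (keep_archive) {
      archive <- as.data.frame(do.call(rbind, arch))
      names(archive) <- c(paste0("x", seq_len(d)), "f")
    }
    .newOptResult(best_x, best_f, history, archive)
  })
}

#' Sine-cosine chaotic sparrow search hybrid (SCA-SSA)
#'
#' Sparrow search algorithm with logistic-map chaotic initialization,
#' producer updates blended with sine-cosine operators, Mantegna Levy-flight
#' perturbation (beta = 1.5) of the scroungers, and an alarm/scout stage.
#' Greedy selection keeps the best-so-far history non-increasing; all points
#' are clamped to the bounds. Used to calibrate the fixed (low-sensitivity)
#' radiative-transfer parameters.
#'
#' @inheritParams nrboMinimize
#' @param producer_fraction Fraction of the population acting as producers.
#' @param alarm_fraction Fraction acting as scouts reacting to danger.
#' @return An [OptResult-class].
#' @export
scassaMinimize <- function(objective, lower, upper, pop = 30, iters = 200,
                           producer_fraction = 0.2, alarm_fraction = 0.1,
                           seed = 1, keep_archive = FALSE) {
  stopifnot(pop >= 4, length(lower) == length(upper),
            all(is.finite(lower)), all(is.finite(upper)))
  d <- length(lower)
  withr::with_seed(seed, {
    # logistic-map chaotic initialization
    z <- runif(d, 0.1, 0.9)
    X <- matrix(0, pop, d)
    for (i in seq_len(pop)) {
      z <- 4 * z * (1 - z)
      X[i, ] <- lower + z * (upper - lower)
    }
    f <- apply(X, 1, objective)
    arch <- if (keep_archive) list(cbind(X, f = f)) else NULL
    best_i <- which.min(f)
    best_x <- X[best_i, ]; best_f <- f[best_i]
    history <- if (iters == 0) best_f else numeric(iters)
    n_prod <- max(2, round(producer_fraction * pop))
    n_scout <- max(1, round(alarm_fraction * pop))
    for (it in seq_len(iters)) {
      ord <- order(f)
      X <- X[ord, , drop = FALSE]; f <- f[ord]
      worst_x <- X[pop, ]
      newX <- X
      a <- 2 - 2 * it / iters  # sine-cosine amplitude decay
      ST <- 0.8
      R2 <- runif(1)
      for (i in seq_len(n_prod)) {
        r1 <- a * runif(1); r2 <- runif(1, 0, 2 * pi); r3 <- runif(1, 0, 2)
        # producer: sine-cosine move toward the current best
        move <- if (runif(1) < 0.5) {
          r1 * sin(r2) * abs(r3 * best_x - X[i, ])
        } else {
          r1 * cos(r2) * abs(r3 * best_x - X[i, ])
        }
        newX[i, ] <- if (R2 < ST) X[i, ] + move else {
          X[i, ] + rnorm(1) * 1
        }
      }
      xp <- newX[1, ]  # best producer position
      for (i in seq((n_prod + 1), pop)) {
        if (i > pop / 2) {
          # worst-off scroungers fly elsewhere (Levy flight around worst)
          newX[i, ] <- worst_x + .levyStep(d) * abs(X[i, ] - worst_x) * 0.05
        } else {
          A <- sample(c(-1, 1), d, replace = TRUE)
          newX[i, ] <- xp + abs(X[i, ] - xp) * A * 0.5 * .levyStep(d) * 0.1
        }
      }
      scouts <- sample(pop, n_scout)
      for (i in scouts) {
        if (f[i] > best_f) {
          newX[i, ] <- best_x + rnorm(d) * abs(X[i, ] - best_x)
        } else {
          newX[i, ] <- X[i, ] + runif(1, -1, 1) * abs(X[i, ] - worst_x) /
            (abs(f[i] - f[pop]) + 1e-12) * 1e-2
        }
      }
      for (i in seq_len(pop)) newX[i, ] <- .clampBounds(newX[i, ], lower, upper)
      newf <- apply(newX, 1, objective)
      if (keep_archive) arch[[length(arch) + 1]] <- cbind(newX, f = newf)
      improve <- newf < f
      X[improve, ] <- newX[improve, , drop = FALSE]
      f[improve] <- newf[improve]
      if (min(f) < best_f) {
        best_f <- min(f); best_x <- X[which.min(f), ]
      }
      history[it] <- best_f
    }
    archive <- NULL
    if (keep_archive) {
      archive <- as.data.frame(do.call(rbind, arch))
      names(archive) <- c(paste0("x", seq_len(d)), "f")
    }
    .newOptResult(best_x, best_f, history, archive)
  })
}
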