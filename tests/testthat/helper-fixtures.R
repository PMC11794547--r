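# small in-code fixtures shared across the test files

# tiny spectral set: n samples on a short uniform grid, one Gaussian band
# whose depth scales with the trait, plus optional white noise
makeToySet <- function(n = 20, wl = seq(500, 700, by = 2), center = 600,
                       depth_per_trait = 0.02, noise = 0, seed = 1,
                       trait = NULL) {
  withr::with_seed(seed, {
    if (is.null(trait)) trait <- seq_len(n)
    base <- 0.35 + 0.05 * sin(seq_along(wl) / 5)
    refl <- t(vapply(seq_len(n), function(i) {
      pmin(pmax(base - depth_per_trait * trait[i] *
                  exp(-0.5 * ((wl - center) / 15)^2) +
                  rnorm(length(wl), 0, noise), 0), 1)
    }, numeric(length(wl))))
    SpectralSet(refl, wl,
                data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                           plot_id = sprintf("s%02d", seq_len(n)),
                           stage = "filling", treatment = "t",
                           trait = trait))
  })
}

# pure-noise spectral set with a trait unrelated to the spectra
makeNoiseSet <- function(n = 40, wl = seq(500, 800, by = 2), seed = 1) {
  withr::with_seed(seed, {
    refl <- matrix(runif(n * length(wl), 0.3, 0.5), n, length(wl))
    SpectralSet(refl, wl,
                data.frame(sample_id = sprintf("s%02d", seq_len(n)),
                           plot_id = sprintf("s%02d", seq_len(n)),
                           stage = "filling", treatment = "t",
                           trait = rnorm(n)))
  })
}

# naive double-loop 2DCOS oracle (independent of the matrix implementation)
oracleSyncAsync <- function(X) {
  m <- nrow(X); nb <- ncol(X)
  Y <- sweep(X, 2, colMeans(X))
  N <- outer(seq_len(m), seq_len(m),
             function(j, k) ifelse(j == k, 0, 1 / (pi * (k - j))))
  sync <- matrix(0, nb, nb); async <- matrix(0, nb, nb)
  for (v1 in seq_len(nb)) {
    for (v2 in seq_len(nb)) {
      s <- 0; a <- 0
      for (j in seq_len(m)) {
        s <- s + Y[j, v1] * Y[j, v2]
        a <- a + Y[j, v1] * sum(N[j, ] * Y[, v2])
      }
      sync[v1, v2] <- s / (m - 1)
      async[v1, v2] <- a / (m - 1)
    }
  }
  list(sync = sync, async = async)
}
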