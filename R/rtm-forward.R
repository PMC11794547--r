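#' PROSAIL parameter record
#'
#' Validates and assembles the leaf (PROSPECT-5B) and canopy (4SAIL)
#' parameters of the coupled forward model.
#'
#' @param N_struct Leaf mesophyll structure parameter (unitless, >= 1).
#' @param Cab Chlorophyll a+b content, ug/cm^2.
#' @param Car Total carotenoid content, ug/cm^2.
#' @param Cbrown Brown pigment content (unitless).
#' @param Cw Equivalent water thickness, cm.
#' @param Cm Dry matter content, g/cm^2.
#' @param LAI Leaf area index, m^2/m^2 (<= 10).
#' @param ALA Average leaf inclination angle, degrees (0-90).
#' @param hs Hot-spot size parameter (unitless).
#' @param psoil Soil brightness factor in \[0, 1\].
#' @param sza,vza Solar / view zenith angles, degrees (0-89).
#' @param raa Relative azimuth angle, degrees (0-360).
#' @return A named list of class `ProsailParams`.
#' @examples
#' p <- prosailParams(LAI = 3, Cab = 40)
#' @export
prosailParams <- function(N_struct = 1.5, Cab = 40, Car = 10, Cbrown = 0,
                          Cw = 0.012, Cm = 0.005, LAI = 3, ALA = 55,
                          hs = 0.2, psoil = 0.7,
                          sza = 30, vza = 0, raa = 0) {
  p <- list(
    N_struct = N_struct, Cab = Cab, Car = Car, Cbrown = Cbrown,
    Cw = Cw, Cm = Cm, LAI = LAI, ALA = ALA, hs = hs, psoil = psoil,
    sza = sza, vza = vza, raa = raa
  )
  .validateProsailParams(p)
  class(p) <- c("ProsailParams", "list")
  p
}

.validateProsailParams <- function(p) {
  chk <- function(field, lo, hi) {
    v <- p[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < lo || v > hi) {
      stop("parameter '", field, "' out of range [", lo, ", ", hi, "]: ",
           format(v), call. = FALSE)
    }
  }
  chk("N_struct", 1, 4); chk("Cab", 0, 120); chk("Car", 0, 40)
  chk("Cbrown", 0, 2); chk("Cw", 0, 0.1); chk("Cm", 0, 0.05)
  chk("LAI", 0, 10); chk("ALA", 5, 85); chk("hs", 0, 1)
  chk("psoil", 0, 1); chk("sza", 0, 89); chk("vza", 0, 89)
  chk("raa", 0, 360)
  invisible(TRUE)
}

# vectorized exponential integral E1(x), x > 0 (Abramowitz & Stegun
# 5.1.53 / 5.1.56; absolute error < 2e-7, ample for reflectance work)
.expintE1 <- function(x) {
  out <- numeric(length(x))
  lo <- x <= 1
  if (any(lo)) {
    xl <- x[lo]
    out[lo] <- -log(xl) - 0.57721566 + xl * (0.99999193 + xl *
      (-0.24991055 + xl * (0.05519968 + xl *
      (-0.00976004 + xl * 0.00107857))))
  }
  if (any(!lo)) {
    xh <- x[!lo]
    num <- xh * (xh * (xh * (xh + 8.5733287401) + 18.059016973) +
                 8.6347608925) + 0.2677737343
    den <- xh * (xh * (xh * (xh + 9.5733223454) + 25.6329561486) +
                 21.0996530827) + 3.9584969228
    out[!lo] <- exp(-xh) / xh * num / den
  }
  out
}

# average transmissivity of a dielectric interface at incidence `theta`
# (degrees) for refractive index n (Stern's integral, as used by the
# generalized plate model)
.tav <- function(theta, n) {
  if (theta == 0) return(4 * n / (n + 1)^2)
  thetar <- theta * pi / 180
  n2 <- n^2
  ax <- (n + 1)^2 / 2
  bx <- -(n2 - 1)^2 / 4
  st2 <- sin(thetar)^2
  b2 <- st2 - (n2 + 1) / 2
  b1 <- if (abs(theta - 90) < 1e-9) 0 else sqrt(b2^2 + bx)
  b0 <- b1 - b2
  ts <- (bx^2 / (6 * b0^3) + bx / b0 - b0 / 2) -
        (bx^2 / (6 * ax^3) + bx / ax - ax / 2)
  tp1 <- -2 * n2 * (b0 - ax) / (n2 + 1)^2
  tp2 <- -2 * n2 * (n2 + 1) * log(b0 / ax) / (n2 - 1)^2
  tp3 <- n2 * (1 / b0 - 1 / ax) / 2
  tp4 <- 16 * n2^2 * (n2^2 + 1) *
    log((2 * (n2 + 1) * b0 - (n2 - 1)^2) /
        (2 * (n2 + 1) * ax - (n2 - 1)^2)) / ((n2 + 1)^3 * (n2 - 1)^2)
  tp5 <- 16 * n2^3 *
    (1 / (2 * (n2 + 1) * b0 - (n2 - 1)^2) -
     1 / (2 * (n2 + 1) * ax - (n2 - 1)^2)) / (n2 + 1)^3
  (ts + tp1 + tp2 + tp3 + tp4 + tp5) / (2 * st2)
}

#' Leaf reflectance and transmittance (generalized plate model)
#'
#' PROSPECT-5B-style leaf optics: total absorption is the sum of the five
#' absorbers weighted by the synthetic specific absorption coefficients of
#' [leafOpticalConstants()], divided among `N_struct` elementary plates; the
#' N-layer solution follows the Stokes system of the generalized plate model.
#'
#' @param p A [prosailParams()] record (canopy fields are ignored).
#' @return A list with numeric vectors `wavelength`, `reflectance`,
#'   `transmittance` on the 400:2500 nm grid.
#' @export
prospect5b <- function(p) {
  .validateProsailParams(p)
  const <- leafOpticalConstants()
  N <- p$N_struct
  k <- (p$Cab * const$kab + p$Car * const$kcar + p$Cbrown * const$kbrown +
        p$Cw * const$kw + p$Cm * const$km) / N
  k <- pmax(k, 0)
  # isotropic transmission of one elementary plate interior
  trans <- rep(1, length(k))
  pos <- k > 0
  trans[pos] <- (1 - k[pos]) * exp(-k[pos]) + k[pos]^2 * .expintE1(k[pos])

  nr <- const$nrefrac
  tavs <- .maizeSPU_cache$tav
  if (is.null(tavs)) {
    tavs <- list(t12 = vapply(nr, .tav, numeric(1), theta = 40),
                 t90 = vapply(nr, .tav, numeric(1), theta = 90))
    .maizeSPU_cache$tav <- tavs
  }
  t12 <- tavs$t12
  tav90 <- tavs$t90
  t21 <- tav90 / nr^2
  r21 <- 1 - t21
  x <- t12 / tav90
  y <- x * (tav90 - 1) + 1 - t12
  ra <- 1 - t12 + (t12 * t21 * r21 * trans^2) / (1 - r21^2 * trans^2)
  ta <- t12 * t21 * trans / (1 - r21^2 * trans^2)
  r90 <- (ra - y) / x
  t90 <- ta / x

  # Stokes solution for the remaining N-1 layers
  rq <- r90^2; tq <- t90^2
  delta <- sqrt(pmax((tq - rq - 1)^2 - 4 * rq, 0))
  beta <- (1 + rq - tq - delta) / (2 * r90)
  va <- (1 + rq - tq + delta) / (2 * r90)
  arg <- beta * (va - r90) / (va * pmax(beta - r90, 1e-14))
  vb <- sqrt(pmax(arg, 1e-14))
  vbNN <- vb^(N - 1)
  vbNNinv <- 1 / vbNN
  vainv <- 1 / va
  s1 <- ta * t90 * (vbNN - vbNNinv)
  s2 <- ta * (va - vainv)
  s3 <- va * vbNN - vainv * vbNNinv - r90 * (vbNN - vbNNinv)
  refl <- pmin(pmax(ra + s1 / s3, 0), 1)
  tran <- pmin(pmax(s2 / s3, 0), 1)
  list(wavelength = const$wavelength, reflectance = refl,
       transmittance = tran)
}

# Campbell ellipsoidal leaf inclination distribution for mean leaf angle
# `ala` (degrees); returns frequencies for 18 five-degree angle classes.
.campbellLIDF <- function(ala, n_classes = 18L) {
  excent <- exp(-1.6184e-5 * ala^3 + 2.1145e-3 * ala^2 -
                1.2390e-1 * ala + 3.2491)
  freq <- numeric(n_classes)
  for (i in seq_len(n_classes)) {
    tl1 <- (i - 1) * (90 / n_classes) * pi / 180
    tl2 <- i * (90 / n_classes) * pi / 180
    x1 <- excent / sqrt(1 + excent^2 * tan(tl1)^2)
    x2 <- excent / sqrt(1 + excent^2 * tan(tl2)^2)
    if (abs(excent - 1) < 1e-9) {
      freq[i] <- abs(cos(tl1) - cos(tl2))
    } else {
      alph <- excent / sqrt(abs(1 - excent^2))
      alph2 <- alph^2
      if (excent > 1) {
        alpx1 <- sqrt(alph2 + x1^2); alpx2 <- sqrt(alph2 + x2^2)
        dum <- x1 * alpx1 + alph2 * log(x1 + alpx1)
        freq[i] <- abs(dum - (x2 * alpx2 + alph2 * log(x2 + alpx2)))
      } else {
        almx1 <- sqrt(alph2 - x1^2); almx2 <- sqrt(alph2 - x2^2)
        dum <- x1 * almx1 + alph2 * asin(x1 / alph)
        freq[i] <- abs(dum - (x2 * almx2 + alph2 * asin(x2 / alph)))
      }
    }
  }
  freq / sum(freq)
}

# bidirectional scattering geometry factors for one leaf zenith class
.volscatt <- function(tts, tto, psi, ttl) {
  rd <- pi / 180
  cts <- cos(tts * rd); cto <- cos(tto * rd)
  sts <- sin(tts * rd); sto <- sin(tto * rd)
  cospsi <- cos(psi * rd); psir <- psi * rd
  costl <- cos(ttl * rd); sintl <- sin(ttl * rd)
  cs <- costl * cts; co <- costl * cto
  ss <- sintl * sts; so <- sintl * sto
  cosbts <- if (abs(ss) > 1e-6) -cs / ss else 5
  cosbto <- if (abs(so) > 1e-6) -co / so else 5
  if (abs(cosbts) < 1) { bts <- acos(cosbts); ds <- ss
  } else { bts <- pi; ds <- cs }
  chi_s <- 2 / pi * ((bts - pi / 2) * cs + sin(bts) * ss)
  if (abs(cosbto) < 1) { bto <- acos(cosbto); do_ <- so
  } else if (tto < 90) { bto <- pi; do_ <- co
  } else { bto <- 0; do_ <- -co }
  chi_o <- 2 / pi * ((bto - pi / 2) * co + sin(bto) * so)
  btran1 <- abs(bts - bto)
  btran2 <- pi - abs(bts + bto - pi)
  if (psir <= btran1) { bt1 <- psir; bt2 <- btran1; bt3 <- btran2
  } else {
    bt1 <- btran1
    if (psir <= btran2) { bt2 <- psir; bt3 <- btran2
    } else { bt2 <- btran2; bt3 <- psir }
  }
  t1 <- 2 * cs * co + ss * so * cospsi
  t2 <- if (bt2 > 0) sin(bt2) * (2 * ds * do_ + ss * so * cos(bt1) * cos(bt3)) else 0
  denom <- 2 * pi^2
  c(chi_s = max(chi_s, 0), chi_o = max(chi_o, 0),
    frho = max(((pi - bt2) * t1 + t2) / denom, 0),
    ftau = max((-bt2 * t1 + t2) / denom, 0))
}

.Jfunc1 <- function(k, l, t) {
  del <- (k - l) * t
  out <- numeric(length(l))
  big <- abs(del) > 1e-3
  out[big] <- (exp(-l[big] * t) - exp(-k * t)) / (k - l[big])
  out[!big] <- 0.5 * t * (exp(-k * t) + exp(-l[!big] * t)) *
    (1 - del[!big]^2 / 12)
  out
}

.Jfunc2 <- function(k, l, t) (1 - exp(-(k + l) * t)) / (k + l)

# 20-step log-spaced quadrature of the hot-spot bidirectional gap
# probability integral int_0^1 exp(-(ko+ks) L x + fhot (1-e^{-alf x})/alf) dx
.sumintHotspot <- function(ks, ko, lai, alf) {
  fhot <- lai * sqrt(ko * ks)
  x1 <- 0; y1 <- 0; f1 <- 1
  fint <- (1 - exp(-alf)) * 0.05
  sumint <- 0
  for (istep in 1:20) {
    x2 <- if (istep < 20) -log(1 - istep * fint) / alf else 1
    y2 <- -(ko + ks) * lai * x2 + fhot * (1 - exp(-alf * x2)) / alf
    f2 <- exp(y2)
    sumint <- sumint + (f2 - f1) * (x2 - x1) / (y2 - y1)
    x1 <- x2; y1 <- y2; f1 <- f2
  }
  list(sumint = sumint, tsstoo = f1)
}

#' 4SAIL canopy bidirectional reflectance
#'
#' Four-stream SAIL canopy reflectance for a homogeneous turbid-medium
#' canopy over a Lambertian soil, with the hot-spot correction of the
#' single-scattering term. Used internally by [prosailForward()]; exposed
#' for testing against independent solutions of the two-stream system.
#'
#' @param rho,tau Leaf reflectance/transmittance spectra (same grid).
#' @param lai Leaf area index.
#' @param ala Average leaf angle, degrees.
#' @param hotspot Hot-spot parameter.
#' @param tts,tto,psi Solar zenith, view zenith, relative azimuth (degrees).
#' @param rsoil Soil reflectance spectrum on the same grid.
#' @return List with the four-flux reflectance/transmittance factors
#'   (`rdd`, `tdd`, `rsd`, `tsd`, `rdo`, `tdo`, `rso`, `tss`, `too`) and the
#'   top-of-canopy directional reflectance `rsot` including the soil.
#' @export
foursail <- function(rho, tau, lai, ala, hotspot, tts, tto, psi, rsoil) {
  stopifnot(length(rho) == length(tau), length(rho) == length(rsoil))
  rd <- pi / 180
  cts <- cos(tts * rd); cto <- cos(tto * rd)
  ctscto <- cts * cto
  tants <- tan(tts * rd); tanto <- tan(tto * rd)
  cospsi <- cos(psi * rd)
  dso <- sqrt(tants^2 + tanto^2 - 2 * tants * tanto * cospsi)

  n_cl <- 18L
  lidf <- .campbellLIDF(ala, n_cl)
  litab <- ((seq_len(n_cl) - 0.5) * 90 / n_cl)
  ks <- ko <- bf <- sob <- sof <- 0
  for (i in seq_len(n_cl)) {
    vs <- .volscatt(tts, tto, psi, litab[i])
    ks <- ks + vs[["chi_s"]] / cts * lidf[i]
    ko <- ko + vs[["chi_o"]] / cto * lidf[i]
    bf <- bf + cos(litab[i] * rd)^2 * lidf[i]
    sob <- sob + vs[["frho"]] * pi / ctscto * lidf[i]
    sof <- sof + vs[["ftau"]] * pi / ctscto * lidf[i]
  }
  sdb <- 0.5 * (ks + bf); sdf <- 0.5 * (ks - bf)
  dob <- 0.5 * (ko + bf); dof <- 0.5 * (ko - bf)
  ddb <- 0.5 * (1 + bf);  ddf <- 0.5 * (1 - bf)

  sigb <- ddb * rho + ddf * tau
  sigf <- ddf * rho + ddb * tau
  att <- 1 - sigf
  m <- sqrt(pmax((att + sigb) * (att - sigb), 0))
  sb <- sdb * rho + sdf * tau; sf <- sdf * rho + sdb * tau
  vb <- dob * rho + dof * tau; vf <- dof * rho + dob * tau
  w <- sob * rho + sof * tau

  nb <- length(rho)
  if (lai <= 0) {
    one <- rep(1, nb); zero <- rep(0, nb)
    return(list(rdd = zero, tdd = one, rsd = zero, tsd = zero,
                rdo = zero, tdo = zero, rso = zero, tss = 1, too = 1,
                rsot = rsoil))
  }

  sigb <- pmax(sigb, 1e-12)
  e1 <- exp(-m * lai); e2 <- e1^2
  rinf <- (att - m) / sigb
  rinf2 <- rinf^2
  re <- rinf * e1
  denom <- 1 - rinf2 * e2
  J1ks <- .Jfunc1(ks, m, lai); J2ks <- .Jfunc2(ks, m, lai)
  J1ko <- .Jfunc1(ko, m, lai); J2ko <- .Jfunc2(ko, m, lai)
  Ps <- (sf + sb * rinf) * J1ks
  Qs <- (sf * rinf + sb) * J2ks
  Pv <- (vf + vb * rinf) * J1ko
  Qv <- (vf * rinf + vb) * J2ko
  rdd <- rinf * (1 - e2) / denom
  tdd <- (1 - rinf2) * e1 / denom
  tsd <- (Ps - re * Qs) / denom
  rsd <- (Qs - re * Ps) / denom
  tdo <- (Pv - re * Qv) / denom
  rdo <- (Qv - re * Pv) / denom
  tss <- exp(-ks * lai); too <- exp(-ko * lai)

  # multiple-scattering part of the bidirectional reflectance
  z <- .Jfunc2(ks, ko, lai)
  g1 <- (z - J1ks * too) / (ko + m)
  g2 <- (z - J1ko * tss) / (ks + m)
  Tv1 <- (vf * rinf + vb) * g1
  Tv2 <- (vf + vb * rinf) * g2
  T1 <- Tv1 * (sf + sb * rinf)
  T2 <- Tv2 * (sf * rinf + sb)
  T3 <- (rdo * Qs + tdo * Ps) * rinf
  rsod <- (T1 + T2 - T3) / (1 - rinf2)

  # hot-spot corrected single scattering
  alf <- 1e6
  if (hotspot > 0) alf <- (dso / hotspot) * 2 / (ks + ko)
  alf <- min(alf, 200)
  if (alf < 1e-12) {
    tsstoo <- tss
    sumint <- (1 - tss) / (ks * lai)
  } else {
    hot <- .sumintHotspot(ks, ko, lai, alf)
    sumint <- hot$sumint
    tsstoo <- hot$tsstoo
  }
  rsos <- w * lai * sumint
  rso <- rsos + rsod

  dn <- 1 - rsoil * rdd
  rsodt <- ((tss + tsd) * tdo + (tsd + tss * rsoil * rdd) * too) * rsoil / dn + rsod
  rsost <- rsos + tsstoo * rsoil
  rsot <- rsost + rsodt
  list(rdd = rdd, tdd = tdd, rsd = rsd, tsd = tsd, rdo = rdo, tdo = tdo,
       rso = rso, tss = tss, too = too, rsot = rsot)
}

#' Coupled leaf-canopy forward simulation
#'
#' Runs the PROSPECT-5B-style leaf model and the 4SAIL canopy model for one
#' parameter record and returns the top-of-canopy directional reflectance on
#' the 400--2500 nm, 1 nm grid (2101 values in \[0, 1\]).
#'
#' @param p A [prosailParams()] record.
#' @return Numeric vector of 2101 canopy reflectances, named by wavelength.
#' @examples
#' r <- prosailForward(prosailParams(LAI = 3))
#' @export
prosailForward <- function(p) {
  if (!inherits(p, "ProsailParams")) p <- do.call(prosailParams, as.list(p))
  .validateProsailParams(p)
  leaf <- prospect5b(p)
  rsoil <- soilReflectance(p$psoil)
  out <- foursail(leaf$reflectance, leaf$transmittance, p$LAI, p$ALA,
                  p$hs, p$sza, p$vza, p$raa, rsoil)
  r <- pmin(pmax(out$rsot, 0), 1)
  names(r) <- leaf$wavelength
  r
}
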