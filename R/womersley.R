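# Frequency-domain (Womersley) profile function for oscillatory flow in a
# rigid-walled circular duct, F_J(alpha) = 2 J1(z) / (z J0(z)) with
# z = i^(3/2) alpha and alpha = r sqrt(omega/nu) the Womersley number.
#
# R's besselJ only accepts real arguments, so the ratio J1/J0 on the ray
# arg(z) = 3*pi/4 is evaluated here directly: a power series in z^2/4 for
# moderate |z| and the Hankel asymptotic expansion, rearranged so that the
# exponentially large factor cancels, for large |z|.

# J1(z)/J0(z) via the two power series (|z| <= 14)
.bessel_ratio_series <- function(z) {
  w <- -(z * z) / 4          # series variable with sign absorbed
  num <- rep(1 + 0i, length(z))  # sum w^k / (k! (k+1)!) * k-terms
  den <- rep(1 + 0i, length(z))
  tn <- rep(1 + 0i, length(z))
  td <- rep(1 + 0i, length(z))
  for (k in 1:60) {
    td <- td * w / (k * k)
    tn <- tn * w / (k * (k + 1))
    den <- den + td
    num <- num + tn
  }
  (z / 2) * num / den
}

# J1(z)/J0(z) via Hankel expansions with the e^{Im z} factor cancelled
# (valid for large |z|, 0 < arg z < pi)
.bessel_ratio_asymp <- function(z) {
  pq <- function(nu) {
    mu <- 4 * nu^2
    # P and Q asymptotic series in 1/(8z)
    a <- rep(1 + 0i, length(z)); P <- a; Q <- rep(0 + 0i, length(z))
    term <- rep(1 + 0i, length(z))
    z8 <- 1 / (8 * z)
    # first few terms; |z| > 14 makes truncation error < 1e-12
    f <- function(k) (mu - (2 * k - 1)^2)
    t1 <- f(1) * z8;                 Q <- Q + t1
    t2 <- t1 * f(2) * z8 / 2;        P <- P - t2
    t3 <- t2 * f(3) * z8 / 3;        Q <- Q - t3
    t4 <- t3 * f(4) * z8 / 4;        P <- P + t4
    t5 <- t4 * f(5) * z8 / 5;        Q <- Q + t5
    t6 <- t5 * f(6) * z8 / 6;        P <- P - t6
    list(P = P, Q = Q)
  }
  b0 <- pq(0); b1 <- pq(1)
  ee <- exp(2i * z)                 # exponentially small for Im z > 0
  th0 <- pi / 4; th1 <- 3 * pi / 4  # theta_nu = nu*pi/2 + pi/4
  e0p <- exp(1i * th0); e0m <- exp(-1i * th0)
  e1p <- exp(1i * th1); e1m <- exp(-1i * th1)
  # cos(chi) ~ (E/2)(e^{i th} + ee e^{-i th}),
  # sin(chi) ~ (E/2i)(ee e^{-i th} - e^{i th}); the E/2 factor cancels
  num <- b1$P * (e1p + ee * e1m) - b1$Q * (ee * e1m - e1p) / 1i
  den <- b0$P * (e0p + ee * e0m) - b0$Q * (ee * e0m - e0p) / 1i
  num / den
}

#' Womersley profile function
#'
#' Evaluates F_J = 2 J1(z) / (z J0(z)) with z = i^(3/2) alpha for real
#' Womersley numbers alpha >= 0.  F_J -> 1 as alpha -> 0 (quasi-static
#' Poiseuille regime) and F_J -> 0 as alpha -> infinity (flat inertial
#' profile).
#'
#' @param alpha Womersley number(s), alpha = r sqrt(omega / nu).
#' @return complex vector of the same length.
#' @export
womersley_fj <- function(alpha) {
  stopifnot(all(is.finite(alpha)), all(alpha >= 0))
  out <- complex(length(alpha))
  z <- alpha * exp(3i * pi / 4)
  small <- alpha <= 14 & alpha > 0
  big <- alpha > 14
  if (any(small)) out[small] <- (2 / z[small]) * .bessel_ratio_series(z[small])
  if (any(big))   out[big]   <- (2 / z[big]) * .bessel_ratio_asymp(z[big])
  out[alpha == 0] <- 1 + 0i
  out
}
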