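## Distributional utilities for the variational posteriors:
## gamma expectations and generalized inverse Gaussian (GIG) expectations
## computed through overflow-safe modified Bessel functions of the second
## kind.

#' Log of the modified Bessel function of the second kind
#'
#' Computes \eqn{\log K_\nu(x)} safely for large orders and small arguments,
#' where the direct `besselK()` overflows.  Uses `besselK(expon.scaled =
#' TRUE)` when the scaled value is finite, and otherwise the uniform (Debye)
#' large-order asymptotic expansion with four correction terms, accurate to
#' roughly \eqn{\nu^{-5}} relative error (the expansion is only reached for
#' \eqn{\nu \gtrsim 50}, where this is far below 1e-8).
#'
#' @param nu order (any real; \eqn{K_{-\nu} = K_\nu}).
#' @param x argument, must be positive.
#' @return `log(besselK(x, nu))` as a numeric vector.
#' @export
log_besselK <- function(nu, x) {
  if (any(x <= 0)) stop("besselK argument must be positive")
  n <- max(length(nu), length(x))
  nu <- rep_len(abs(nu), n)
  x <- rep_len(x, n)
  out <- numeric(n)
  for (i in seq_len(n)) {
    b <- suppressWarnings(besselK(x[i], nu[i], expon.scaled = TRUE))
    if (is.finite(b) && b > 0) {
      out[i] <- log(b) - x[i]
    } else {
      out[i] <- log_besselK_debye(nu[i], x[i])
    }
  }
  out
}

## Uniform asymptotic expansion of K_nu(nu*z) for large nu (Abramowitz &
## Stegun 9.7.8), with Debye polynomials u_1..u_4.
log_besselK_debye <- function(nu, x) {
  if (nu < 10) stop("Debye expansion requested for small order nu=", nu)
  z <- x / nu
  s <- sqrt(1 + z^2)
  t <- 1 / s
  eta <- s + log(z / (1 + s))
  u1 <- (3 * t - 5 * t^3) / 24
  u2 <- (81 * t^2 - 462 * t^4 + 385 * t^6) / 1152
  u3 <- (30375 * t^3 - 369603 * t^5 + 765765 * t^7 - 425425 * t^9) / 414720
  u4 <- (4465125 * t^4 - 94121676 * t^6 + 349922430 * t^8 -
           446185740 * t^10 + 185910725 * t^12) / 39813120
  series <- 1 - u1 / nu + u2 / nu^2 - u3 / nu^3 + u4 / nu^4
  0.5 * log(pi / (2 * nu)) - 0.25 * log(1 + z^2) - nu * eta + log(series)
}

#' Gamma variational factor
#'
#' Light-weight container for a gamma distribution in shape/rate
#' parameterization, as used for the activity and scale posteriors.
#'
#' @param shape,rate positive numeric vectors.
#' @return list with class `"gamma_q"`.
#' @export
gamma_q <- function(shape, rate) {
  if (any(!is.finite(shape)) || any(shape <= 0) ||
      any(!is.finite(rate)) || any(rate <= 0))
    stop("gamma_q requires finite positive shape and rate")
  structure(list(shape = shape, rate = rate), class = "gamma_q")
}

#' Expectations of a gamma distribution
#'
#' @param q a [gamma_q()] object.
#' @return list with elements `mean` (= shape/rate) and `mean_log`
#'   (= digamma(shape) - log(rate)).
#' @export
gamma_expectations <- function(q) {
  stopifnot(inherits(q, "gamma_q"))
  list(mean = q$shape / q$rate,
       mean_log = digamma(q$shape) - log(q$rate))
}

## Entropy of Gamma(a, b) (natural log).
gamma_entropy <- function(shape, rate) {
  shape - log(rate) + lgamma(shape) + (1 - shape) * digamma(shape)
}

#' GIG variational factor
#'
#' Generalized inverse Gaussian distribution with density proportional to
#' \eqn{x^{\lambda-1} \exp(-(\chi/x + \psi x)/2)} on \eqn{x > 0}; the
#' variational posterior family of the chromatin openness variables.
#'
#' @param lam real order \eqn{\lambda}.
#' @param chi,psi positive parameters \eqn{\chi}, \eqn{\psi}.
#' @return list with class `"gig_q"`.
#' @export
gig_q <- function(lam, chi, psi) {
  if (any(!is.finite(chi)) || any(chi <= 0))
    stop("gig_q requires finite positive chi")
  if (any(!is.finite(psi)) || any(psi <= 0))
    stop("gig_q requires finite positive psi")
  if (any(!is.finite(lam))) stop("gig_q requires finite lambda")
  structure(list(lam = lam, chi = chi, psi = psi), class = "gig_q")
}

#' Expectations of a GIG distribution
#'
#' With \eqn{\eta = \sqrt{\chi\psi}}, uses the moment identity
#' \eqn{E[x^a] = (\chi/\psi)^{a/2} K_{\lambda+a}(\eta) / K_\lambda(\eta)}.
#' `inv_mean` is computed from \eqn{K_{\lambda-1}} directly rather than via
#' the recurrence \eqn{K_{\lambda+1} = K_{\lambda-1} + (2\lambda/\eta)
#' K_\lambda}, which would cancel catastrophically in the gamma limit
#' \eqn{\chi \to 0}.  `mean_log` is \eqn{\partial_\lambda \log K_\lambda(\eta)
#' + \frac12 \log(\chi/\psi)}, with the Bessel derivative taken by a central
#' finite difference (step 1e-4) on the log scale; no closed form exists.
#'
#' @param q a [gig_q()] object (parameters may be vectors).
#' @return list of numeric vectors `mean`, `inv_mean`, `mean_log`.
#' @export
gig_expectations <- function(q) {
  stopifnot(inherits(q, "gig_q"))
  lam <- q$lam; chi <- q$chi; psi <- q$psi
  n <- max(length(lam), length(chi), length(psi))
  lam <- rep_len(lam, n); chi <- rep_len(chi, n); psi <- rep_len(psi, n)
  eta <- sqrt(chi * psi)
  lk0 <- log_besselK(lam, eta)
  lkp <- log_besselK(lam + 1, eta)
  lkm <- log_besselK(lam - 1, eta)
  half_lr <- 0.5 * (log(chi) - log(psi))
  mean <- exp(half_lr + lkp - lk0)
  inv_mean <- exp(-half_lr + lkm - lk0)
  h <- 1e-4
  dlogk <- (log_besselK(lam + h, eta) - log_besselK(lam - h, eta)) / (2 * h)
  mean_log <- dlogk + half_lr
  if (any(!is.finite(mean)) || any(!is.finite(inv_mean)) ||
      any(!is.finite(mean_log)))
    stop("non-finite GIG expectation (lambda=", lam[which(!is.finite(mean))[1]],
         ")")
  list(mean = mean, inv_mean = inv_mean, mean_log = mean_log)
}

## log normalizer: the GIG density is
##   exp((lam-1) log x - (chi/x + psi x)/2 - logZ)
## with logZ = -lam/2 * log(psi/chi) + log(2 K_lam(eta)).
gig_log_normalizer <- function(lam, chi, psi) {
  eta <- sqrt(chi * psi)
  -0.5 * lam * (log(psi) - log(chi)) + log(2) + log_besselK(lam, eta)
}

## Entropy of the GIG: -E[log q] = logZ - (lam-1) E[log x]
##                                 + (chi E[1/x] + psi E[x]) / 2
gig_entropy <- function(lam, chi, psi, ex) {
  gig_log_normalizer(lam, chi, psi) - (lam - 1) * ex$mean_log +
    0.5 * (chi * ex$inv_mean + psi * ex$mean)
}
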