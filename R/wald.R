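#' Wald (inverse-Gaussian) first-passage time distribution
#'
#' Density, distribution function and random generation for the first-passage
#' time of a single-boundary drift-diffusion process (drift `v`, within-trial
#' noise SD `s`, absorbing boundary at `a > 0`, started at 0). For `v > 0`
#' this is the inverse-Gaussian distribution with mean `a/v` and shape
#' `(a/s)^2`. For `v <= 0` the distribution is *defective*: the process
#' reaches the boundary only with probability `exp(2*v*a/s^2)` (1 when
#' `v = 0`), and `pwald()` converges to that mass rather than to 1.
#'
#' These are the building blocks of the race architectures: each accumulator
#' of a racing diffusion has Wald-distributed finishing times, and the race
#' likelihood combines densities with survivor functions of the competitors.
#'
#' @param t time in seconds; the density is 0 for `t <= 0`.
#' @param a boundary (evidence units), must be positive.
#' @param v drift rate (evidence units per second); any sign.
#' @param s within-trial noise SD. Fixed at 1 in all model fits (it is the
#'   scaling parameter of the framework); exposed for completeness.
#' @param n number of samples.
#' @return `dwald()` the density (1/s), `pwald()` the CDF, `rwald()` samples;
#'   `rwald()` encodes "accumulator never reaches the boundary" as `Inf`.
#' @examples
#' dwald(1, a = 1, v = 1)          # 1/sqrt(2*pi)
#' pwald(Inf, a = 1, v = -1)       # defective mass exp(-2)
#' mean(rwald(1e4, a = 1, v = 2))  # ~ a/v = 0.5
#' @export
dwald <- function(t, a, v, s = 1) {
  if (any(a <= 0)) stop("wald boundary `a` must be positive", call. = FALSE)
  n <- max(length(t), length(a), length(v), length(s))
  t <- rep_len(t, n); a <- rep_len(a, n); v <- rep_len(v, n); s <- rep_len(s, n)
  out <- numeric(n)
  ok <- is.finite(t) & t > 0
  ti <- t[ok]; ai <- a[ok]; vi <- v[ok]; si <- s[ok]
  out[ok] <- ai / sqrt(2 * pi * ti^3) / si *
    exp(-(ai - vi * ti)^2 / (2 * ti * si^2))
  out
}

#' @rdname dwald
#' @export
pwald <- function(t, a, v, s = 1) {
  if (any(a <= 0)) stop("wald boundary `a` must be positive", call. = FALSE)
  n <- max(length(t), length(a), length(v), length(s))
  t <- rep_len(t, n); a <- rep_len(a, n); v <- rep_len(v, n); s <- rep_len(s, n)
  out <- numeric(n)
  inf <- is.infinite(t) & t > 0
  # limiting absorption mass: 1 for v >= 0, exp(2 v a / s^2) otherwise
  out[inf] <- ifelse(v[inf] >= 0, 1, exp(2 * v[inf] * a[inf] / s[inf]^2))
  ok <- is.finite(t) & t > 0
  if (any(ok)) {
    ti <- t[ok]; ai <- a[ok]; vi <- v[ok]; si <- s[ok]
    sq <- si * sqrt(ti)
    # second term computed on the log scale: exp(2va) can overflow while the
    # product with the far-tail normal CDF stays finite
    lg <- 2 * vi * ai / si^2 + pnorm(-(vi * ti + ai) / sq, log.p = TRUE)
    out[ok] <- pnorm((vi * ti - ai) / sq) + exp(lg)
  }
  out
}

#' @rdname dwald
#' @export
rwald <- function(n, a, v, s = 1) {
  if (any(a <= 0)) stop("wald boundary `a` must be positive", call. = FALSE)
  a <- rep_len(a / s, n)          # reduce to s = 1 by rescaling evidence
  v <- rep_len(v / s, n)
  out <- rep(Inf, n)
  pos <- v > 0
  zer <- v == 0
  neg <- v < 0
  if (any(pos)) out[pos] <- rinvgauss_ms(sum(pos), a[pos] / v[pos], a[pos]^2)
  if (any(zer)) out[zer] <- (a[zer] / rnorm(sum(zer)))^2  # Levy law
  if (any(neg)) {
    # reaches the boundary with prob exp(2 v a); conditional on absorption the
    # passage time is the inverse Gaussian with the drift sign flipped
    fin <- runif(sum(neg)) < exp(2 * v[neg] * a[neg])
    idx <- which(neg)[fin]
    if (length(idx)) out[idx] <- rinvgauss_ms(length(idx), a[idx] / abs(v[idx]), a[idx]^2)
  }
  out
}

# Michael-Schucany-Haas inverse-Gaussian sampler, mean mu, shape lambda
rinvgauss_ms <- function(n, mu, lambda) {
  mu <- rep_len(mu, n); lambda <- rep_len(lambda, n)
  z <- rnorm(n)^2
  x <- mu + mu^2 * z / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * z + mu^2 * z^2)
  swap <- runif(n) >= mu / (mu + x)
  x[swap] <- mu[swap]^2 / x[swap]
  x
}
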