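#' Drift rate from a Q-value difference
#'
#' Maps the trial's learned value difference onto the mean rate of evidence
#' accumulation of the diffusion decision model. The default link is linear,
#' `v = w * (Q1 - Q2)`. The non-linear link saturates at `±vmax`,
#' `v = 2 * vmax / (1 + exp(-w * dq)) - vmax`, an antisymmetric sigmoid with
#' slope `w * vmax / 2` at `dq = 0`; it leaves drift rates bounded no matter
#' how large the learned value contrast becomes.
#'
#' @param qdiff value difference `Q1 - Q2` (option 1 minus option 2).
#' @param w weight on the value difference (1/s per unit value).
#' @param vmax optional ceiling of the non-linear link; `NULL` selects the
#'   linear link.
#' @return drift rate(s), positive when option 1 has the higher value.
#' @export
ddm_drift <- function(qdiff, w, vmax = NULL) {
  if (is.null(vmax)) {
    w * qdiff
  } else {
    2 * vmax / (1 + exp(-w * qdiff)) - vmax
  }
}

# ---- Wiener first-passage density ------------------------------------------
#
# Internal parametrization: boundary separation A, relative start w in (0,1),
# drift v toward the upper boundary, unit diffusion. The density of absorption
# at the *lower* boundary factorizes into exp(-v*A*w - v^2 t/2) times the
# zero-drift density, which is evaluated by whichever of the classical
# small-time / large-time series needs fewer terms (truncation error <= 1e-8).
# Normally distributed drift variability (SD eta) replaces the exponential
# prefactor by its closed-form Gaussian integral.

wiener_series0 <- function(tau, w, err = 1e-8) {
  # zero-drift, unit-boundary lower-bound density on the normalized time scale
  out <- numeric(length(tau))
  ok <- tau > 0
  tau_ok <- tau[ok]; w_ok <- rep_len(w, length(tau))[ok]
  ks <- rep(2, length(tau_ok))
  c1 <- 2 * sqrt(2 * pi * tau_ok) * err
  i <- c1 < 1
  ks[i] <- pmax(2 + sqrt(-2 * tau_ok[i] * log(c1[i])), sqrt(tau_ok[i]) + 1)
  kl <- pmax(rep(1, length(tau_ok)), 1 / (pi * sqrt(tau_ok)))
  c2 <- pi * tau_ok * err
  i <- c2 < 1
  kl[i] <- pmax(sqrt(-2 * log(c2[i]) / (pi^2 * tau_ok[i])), kl[i])

  val <- numeric(length(tau_ok))
  small <- ks < kl
  if (any(small)) {
    ts <- tau_ok[small]; wsm <- w_ok[small]
    K <- ceiling((max(ks[small]) - 1) / 2)
    acc <- 0
    for (k in seq(-K, K)) {
      u <- wsm + 2 * k
      acc <- acc + u * exp(-u^2 / (2 * ts))
    }
    val[small] <- acc / sqrt(2 * pi * ts^3)
  }
  if (any(!small)) {
    tl <- tau_ok[!small]; wl <- w_ok[!small]
    K <- ceiling(max(kl[!small]))
    acc <- 0
    for (k in seq_len(K)) {
      acc <- acc + k * exp(-k^2 * pi^2 * tl / 2) * sin(k * pi * wl)
    }
    val[!small] <- pi * acc
  }
  out[ok] <- pmax(val, 0)
  out
}

wiener_lower <- function(t, v, A, w, eta = 0) {
  # lower-boundary defective FPT density; eta = SD of normal drift variability
  tau <- t / A^2
  base <- wiener_series0(tau, w) / A^2
  if (all(eta == 0)) {
    pre <- exp(-v * A * w - v^2 * t / 2)
  } else {
    eta <- rep_len(eta, length(t))
    pre <- ifelse(
      eta > 0,
      1 / sqrt(1 + eta^2 * t) *
        exp((eta^2 * A^2 * w^2 - 2 * v * A * w - v^2 * t) / (2 * (1 + eta^2 * t))),
      exp(-v * A * w - v^2 * t / 2)
    )
  }
  base * pre
}

#' Defective first-passage density of the diffusion decision model
#'
#' Joint density of response and response time for a Wiener process with
#' symmetric boundaries at `+a` and `-a`, unbiased start (`z = 0`), drift `v`
#' toward the upper boundary, and unit within-trial noise. Choice 1 is the
#' upper boundary, choice 2 the lower. The two defective densities jointly
#' integrate to 1. Between-trial variabilities follow the conventions of the
#' value-learning variants: `sv` scales drift variability *proportionally*
#' (trial drift ~ Normal(v, (|v|*sv)^2), closed form), `sz` is the uniform
#' start-point range as a fraction of the full boundary separation (Gauss
#' quadrature), and `st0` a uniform non-decision-time range in seconds
#' (Gauss quadrature).
#'
#' @param rt response time in seconds.
#' @param choice 1 (upper boundary) or 2 (lower boundary).
#' @param v drift rate toward the upper boundary.
#' @param a boundary magnitude (> 0); boundaries sit at `+a` and `-a`.
#' @param t0 non-decision time in seconds; density is 0 for `rt <= t0`.
#' @param sv,sz,st0 between-trial variability parameters (0 disables each).
#' @return defective density values (1/s).
#' @examples
#' integrate(dddm, 0, Inf, choice = 1, v = 1, a = 1, t0 = 0)$value # ~0.8808
#' @export
dddm <- function(rt, choice, v, a, t0, sv = 0, sz = 0, st0 = 0) {
  if (any(a <= 0)) stop("boundary `a` must be positive", call. = FALSE)
  if (any(sz < 0 | sz >= 1)) stop("`sz` must lie in [0, 1)", call. = FALSE)
  n <- max(length(rt), length(choice), length(v), length(a), length(t0),
           length(sv), length(sz), length(st0))
  rt <- rep_len(rt, n); choice <- rep_len(choice, n); v <- rep_len(v, n)
  a <- rep_len(a, n); t0 <- rep_len(t0, n); sv <- rep_len(sv, n)
  sz <- rep_len(sz, n); st0 <- rep_len(st0, n)

  # upper boundary == lower boundary of the sign-flipped process
  vv <- v * (1 - 2 * (choice == 1))
  A <- 2 * a
  eta <- abs(v) * sv

  dens_at <- function(td, wmid) {
    # density of decision time td at relative start wmid, sz-averaged
    f <- function(w_off) wiener_lower(pmax(td, 0), vv, A, wmid + w_off, eta)
    res <- numeric(length(td))
    use <- sz > 0
    if (any(!use)) res[!use] <- f(0)[!use]
    if (any(use)) {
      gq <- statmod::gauss.quad(16, kind = "legendre")
      acc <- 0
      for (j in seq_along(gq$nodes)) {
        w_off <- gq$nodes[j] * sz / 2   # uniform on +/- sz/2 around wmid
        acc <- acc + gq$weights[j] / 2 * f(w_off)
      }
      res[use] <- acc[use]
    }
    res * (td > 0)
  }

  wmid <- 0.5  # unbiased start; choice-1 flip keeps w symmetric
  if (all(st0 <= 0) && all(sz <= 0)) {
    td <- rt - t0
    return(wiener_lower(pmax(td, 0), vv, A, wmid, eta) * (td > 0))
  }
  out <- numeric(n)
  no_st0 <- st0 <= 0
  if (any(no_st0)) {
    td <- rt - t0
    out[no_st0] <- dens_at(td, wmid)[no_st0]
  }
  if (any(!no_st0)) {
    gq <- statmod::gauss.quad(32, kind = "legendre")
    acc <- 0
    for (j in seq_along(gq$nodes)) {
      tj <- t0 + (gq$nodes[j] + 1) / 2 * st0   # uniform on (t0, t0 + st0)
      acc <- acc + gq$weights[j] / 2 * dens_at(rt - tj, wmid)
    }
    out[!no_st0] <- acc[!no_st0]
  }
  out
}

#' Choice probability of the diffusion decision model
#'
#' Probability of terminating at the upper boundary (choice 1) for symmetric
#' boundaries `+/- a`, unbiased start and drift `v`: `1 / (1 + exp(-2 v a))`.
#' With between-trial variabilities the probability is obtained by
#' integrating the defective density numerically.
#'
#' @inheritParams dddm
#' @export
ddm_prob_upper <- function(v, a, sv = 0, sz = 0, st0 = 0) {
  if (sv == 0 && sz == 0) {
    if (v == 0) return(0.5)
    1 / (1 + exp(-2 * v * a))
  } else {
    stats::integrate(function(t) dddm(t, 1, v, a, t0 = 0, sv = sv, sz = sz),
                     0, Inf, rel.tol = 1e-8)$value
  }
}

#' Sample responses and response times from the diffusion decision model
#'
#' Draws (choice, rt) pairs consistent with [dddm()] by numerical inversion
#' of the defective first-passage distributions on an adaptive time grid.
#' Between-trial variabilities are part of the inverted marginal density
#' (`sv`, `sz`) or added per draw (`st0`).
#'
#' @inheritParams dddm
#' @param n number of trials to draw.
#' @param grid_n resolution of the inversion grid.
#' @return a tibble with columns `choice` (1 = upper) and `rt` (seconds).
#' @export
rddm <- function(n, v, a, t0, sv = 0, sz = 0, st0 = 0, grid_n = 4096) {
  stopifnot(length(v) == 1, length(a) == 1)
  # expand the grid horizon until (virtually) all probability mass is covered
  tmax <- max(4 * (2 * a)^2, 2)
  repeat {
    tg <- seq(0, tmax, length.out = grid_n + 1)[-1]
    d1 <- dddm(tg, 1, v, a, t0 = 0, sv = sv, sz = sz)
    d2 <- dddm(tg, 2, v, a, t0 = 0, sv = sv, sz = sz)
    dt <- tg[2] - tg[1]
    m1 <- cumsum(d1) * dt
    m2 <- cumsum(d2) * dt
    tot <- m1[length(m1)] + m2[length(m2)]
    if (tot >= 1 - 1e-5 || tmax > 1e4) break
    tmax <- tmax * 2
  }
  p1 <- m1[length(m1)] / tot
  ch <- ifelse(runif(n) < p1, 1L, 2L)
  rt <- numeric(n)
  u <- runif(n)
  i1 <- ch == 1L
  if (any(i1)) rt[i1] <- stats::approx(m1 / m1[length(m1)], tg, xout = u[i1],
                                       ties = "ordered", rule = 2)$y
  if (any(!i1)) rt[!i1] <- stats::approx(m2 / m2[length(m2)], tg, xout = u[!i1],
                                         ties = "ordered", rule = 2)$y
  rt <- rt + t0 + if (st0 > 0) runif(n, 0, st0) else 0
  tibble::tibble(choice = ch, rt = rt)
}
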