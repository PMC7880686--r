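#' Accumulator drift rates from learned values
#'
#' Link functions mapping the current Q-values of a stimulus set onto the
#' drift rates of a racing-diffusion architecture.
#'
#' * `drift_rd()`: independent race — each option's accumulator runs at
#'   `V0 + w * Q_i`, an urgency baseline plus weighted evidence.
#' * `drift_ard2()`: two-alternative advantage race —
#'   `v1 = V0 + wd * (Q1 - Q2) + ws * (Q1 + Q2)` and symmetrically for `v2`.
#'   Setting `ws = 0` gives the limited ("lARD") variant driven by value
#'   differences only.
#' * `drift_ard2_ei()`: the same drifts in the excitation/inhibition
#'   parametrization `v_i = V0 + we * Q_own - wi * Q_other`, with
#'   `we = wd + ws` and `wi = wd - ws`.
#' * `drift_ard_multi()`: three-alternative advantage race with one
#'   accumulator per *directional* option pair; returns the six drifts for
#'   pairs 1-2, 1-3, 2-1, 2-3, 3-1, 3-2, where
#'   `v_{i-j} = V0 + wd * (Qi - Qj) + ws * (Qi + Qj)`.
#'
#' @param q numeric vector of Q-values (length 2, or 3 for
#'   `drift_ard_multi()`), or a matrix with one row per trial.
#' @param V0 urgency: evidence-independent baseline input (>= 0).
#' @param w,wd,ws,we,wi weights on the evidence terms.
#' @return drift rates: a vector for vector input, a matrix (trials x
#'   accumulators) for matrix input. `drift_ard_multi()` names the
#'   accumulators by their directional pair.
#' @export
drift_rd <- function(q, V0, w) {
  V0 + w * q
}

#' @rdname drift_rd
#' @export
drift_ard2 <- function(q, V0, wd, ws = 0) {
  q <- rbind(q)
  stopifnot(ncol(q) == 2)
  out <- cbind(V0 + wd * (q[, 1] - q[, 2]) + ws * (q[, 1] + q[, 2]),
               V0 + wd * (q[, 2] - q[, 1]) + ws * (q[, 1] + q[, 2]))
  if (nrow(out) == 1) drop(out) else out
}

#' @rdname drift_rd
#' @export
drift_ard2_ei <- function(q, V0, we, wi) {
  q <- rbind(q)
  stopifnot(ncol(q) == 2)
  out <- cbind(V0 + we * q[, 1] - wi * q[, 2],
               V0 + we * q[, 2] - wi * q[, 1])
  if (nrow(out) == 1) drop(out) else out
}

#' @rdname drift_rd
#' @export
drift_ard_multi <- function(q, V0, wd, ws = 0) {
  q <- rbind(q)
  stopifnot(ncol(q) == 3)
  pairs <- winall_pairs()
  out <- sapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs$own[r]; j <- pairs$other[r]
    V0 + wd * (q[, i] - q[, j]) + ws * (q[, i] + q[, j])
  })
  out <- rbind(out)
  colnames(out) <- pairs$label
  if (nrow(out) == 1) out[1, ] else out
}

# directional pair layout of the six three-alternative accumulators
winall_pairs <- function() {
  data.frame(own   = c(1L, 1L, 2L, 2L, 3L, 3L),
             other = c(2L, 3L, 1L, 3L, 1L, 2L),
             label = c("1-2", "1-3", "2-1", "2-3", "3-1", "3-2"))
}

#' Defective density of a two-alternative racing diffusion
#'
#' Joint density of (response, response time) when two single-boundary
#' diffusions race toward a common threshold `a`: the winner's Wald density
#' times the loser's survivor function, shifted by the non-decision time.
#' With `st0 > 0` the density is averaged over a uniform non-decision window
#' `(t0, t0 + st0)` by 32-node Gauss-Legendre quadrature. Negative drifts are
#' allowed; survivor terms then use the defective Wald CDF and the summed
#' choice probabilities fall below 1 (stalled races).
#'
#' @param rt response time in seconds.
#' @param choice index of the winning accumulator (1 or 2).
#' @param v1,v2 drift rates of accumulators 1 and 2.
#' @param a common threshold (> 0).
#' @param t0 non-decision time (s).
#' @param st0 uniform non-decision-time range (s); 0 disables.
#' @return defective density values (1/s).
#' @export
drace2 <- function(rt, choice, v1, v2, a, t0, st0 = 0) {
  n <- max(length(rt), length(choice), length(v1), length(v2), length(a),
           length(t0), length(st0))
  rt <- rep_len(rt, n); choice <- rep_len(choice, n)
  v1 <- rep_len(v1, n); v2 <- rep_len(v2, n)
  a <- rep_len(a, n); t0 <- rep_len(t0, n); st0 <- rep_len(st0, n)
  c1 <- choice == 1
  vw <- v2 + (v1 - v2) * c1
  vl <- v1 + (v2 - v1) * c1
  core <- function(td) {
    ok <- td > 0
    out <- numeric(n)
    out[ok] <- dwald(td[ok], a[ok], vw[ok]) * (1 - pwald(td[ok], a[ok], vl[ok]))
    out
  }
  if (all(st0 <= 0)) return(core(rt - t0))
  gq <- statmod::gauss.quad(32, kind = "legendre")
  acc <- 0
  for (j in seq_along(gq$nodes)) {
    tj <- t0 + (gq$nodes[j] + 1) / 2 * st0
    acc <- acc + gq$weights[j] / 2 * core(rt - tj)
  }
  base <- core(rt - t0)
  ifelse(st0 > 0, acc, base)
}

#' Defective density of the three-alternative Win-All advantage race
#'
#' Six accumulators (one per directional option pair) race toward a common
#' threshold. An option wins once *both* of its accumulators have finished
#' while every other option still has at least one unfinished accumulator;
#' the decision time is the finishing time of the *slower* of the two winning
#' accumulators. For option i with competitors j, k the density at decision
#' time t is
#' `[f_ij(t) F_ik(t) + f_ik(t) F_ij(t)] * (1 - F_jk(t) F_ji(t)) * (1 - F_kj(t) F_ki(t))`
#' with Wald densities f and CDFs F. The three defective densities integrate
#' to 1 when all six drifts are positive.
#'
#' @param rt response time in seconds.
#' @param choice winning option (1, 2 or 3).
#' @param v six drift rates in pair order 1-2, 1-3, 2-1, 2-3, 3-1, 3-2:
#'   a vector, or a matrix with one row per trial.
#' @inheritParams drace2
#' @export
dwinall <- function(rt, choice, v, a, t0, st0 = 0) {
  v <- rbind(v)
  if (ncol(v) != 6) stop("`v` must supply six accumulator drifts", call. = FALSE)
  n <- max(length(rt), length(choice), nrow(v), length(a), length(t0), length(st0))
  rt <- rep_len(rt, n); choice <- rep_len(choice, n)
  a <- rep_len(a, n); t0 <- rep_len(t0, n); st0 <- rep_len(st0, n)
  if (nrow(v) != n) v <- v[rep_len(seq_len(nrow(v)), n), , drop = FALSE]
  pairs <- winall_pairs()
  col_of <- function(own, other) which(pairs$own == own & pairs$other == other)

  core <- function(td) {
    ok <- td > 0
    out <- numeric(n)
    if (!any(ok)) return(out)
    td <- td[ok]; ch <- choice[ok]; aa <- a[ok]; vv <- v[ok, , drop = FALSE]
    res <- numeric(length(td))
    for (i in 1:3) {
      sel <- ch == i
      if (!any(sel)) next
      others <- setdiff(1:3, i)
      j <- others[1]; k <- others[2]
      tdi <- td[sel]; ai <- aa[sel]; vi <- vv[sel, , drop = FALSE]
      f_ij <- dwald(tdi, ai, vi[, col_of(i, j)])
      f_ik <- dwald(tdi, ai, vi[, col_of(i, k)])
      F_ij <- pwald(tdi, ai, vi[, col_of(i, j)])
      F_ik <- pwald(tdi, ai, vi[, col_of(i, k)])
      own <- f_ij * F_ik + f_ik * F_ij   # slower of the two winners at t
      block <- rep(1, length(tdi))
      for (m in others) {
        rest <- setdiff(1:3, m)
        Fm <- pwald(tdi, ai, vi[, col_of(m, rest[1])]) *
              pwald(tdi, ai, vi[, col_of(m, rest[2])])
        block <- block * (1 - Fm)
      }
      res[sel] <- own * block
    }
    out[ok] <- res
    out
  }
  if (all(st0 <= 0)) return(core(rt - t0))
  gq <- statmod::gauss.quad(32, kind = "legendre")
  acc <- 0
  for (jj in seq_along(gq$nodes)) {
    tj <- t0 + (gq$nodes[jj] + 1) / 2 * st0
    acc <- acc + gq$weights[jj] / 2 * core(rt - tj)
  }
  ifelse(st0 > 0, acc, core(rt - t0))
}

#' Analytic choice probabilities of a race
#'
#' Integrates the defective densities over time by adaptive quadrature with
#' an exponential mapping of the tail. With any negative drifts the
#' probabilities may sum to less than 1 (the race can stall).
#'
#' @inheritParams drace2
#' @inheritParams dwinall
#' @param architecture `"race2"` or `"winall"`.
#' @param v drift vector: 2 accumulators for `"race2"`, 6 for `"winall"`.
#' @return named numeric vector of per-option probabilities.
#' @export
race_choice_prob <- function(v, a, architecture = c("race2", "winall")) {
  architecture <- match.arg(architecture)
  n_opt <- if (architecture == "race2") 2L else 3L
  dens <- function(t, i) {
    if (architecture == "race2") drace2(t, i, v[1], v[2], a, t0 = 0)
    else dwinall(t, i, v, a, t0 = 0)
  }
  vapply(seq_len(n_opt), function(i) {
    stats::integrate(function(u) dens(-log(u), i) / u, 0, 1,
                     rel.tol = 1e-8, subdivisions = 400L)$value
  }, numeric(1))
}

#' Simulate a race between Wald accumulators
#'
#' Draws exact first-passage times for each accumulator ([rwald()]) and
#' applies the stopping rule: first past the threshold for the independent /
#' advantage race, Win-All (both of an option's accumulators finished, slower
#' one sets the decision time) for the three-alternative architecture.
#' Accumulators that never finish are `Inf`; a trial where no option can win
#' yields `choice = NA` and `rt = NA` (a stalled race).
#'
#' @param n number of trials.
#' @param v drift rates: length 2 for a two-accumulator race, length 6 (pair
#'   order 1-2, 1-3, 2-1, 2-3, 3-1, 3-2) for the Win-All race; or a matrix
#'   with one row per trial.
#' @inheritParams drace2
#' @return tibble with columns `choice` and `rt`.
#' @export
rrace <- function(n, v, a, t0, st0 = 0) {
  v <- rbind(v)
  k <- ncol(v)
  if (!k %in% c(2L, 6L)) stop("`v` must have 2 or 6 columns", call. = FALSE)
  if (nrow(v) != n) v <- v[rep_len(seq_len(nrow(v)), n), , drop = FALSE]
  tt <- matrix(rwald(n * k, a, as.vector(v)), n, k)
  if (k == 2L) {
    choice <- ifelse(tt[, 1] <= tt[, 2], 1L, 2L)
    dt <- pmin(tt[, 1], tt[, 2])
  } else {
    # per-option completion time = slower of its two accumulators
    done <- cbind(pmax(tt[, 1], tt[, 2]),
                  pmax(tt[, 3], tt[, 4]),
                  pmax(tt[, 5], tt[, 6]))
    choice <- max.col(-done, ties.method = "first")
    dt <- done[cbind(seq_len(n), choice)]
  }
  stalled <- !is.finite(dt)
  choice[stalled] <- NA_integer_
  rt <- dt + t0 + if (any(st0 > 0)) runif(n, 0, st0) else 0
  rt[stalled] <- NA_real_
  tibble::tibble(choice = choice, rt = rt)
}

# Euler-discretized race simulator (dt = 1e-3 s). Slow; kept as an
# independent cross-check of the exact samplers in the test suite. The
# threshold is pulled in by 0.5826 * s * sqrt(dt) (continuity correction for
# discretely monitored barrier crossing), which removes the leading-order
# discretization bias in first-passage times.
rrace_euler <- function(n, v, a, t0, dt = 1e-3, t_max = 20) {
  v <- rbind(v)
  k <- ncol(v)
  if (nrow(v) != n) v <- v[rep_len(seq_len(nrow(v)), n), , drop = FALSE]
  a <- a - 0.5826 * sqrt(dt)
  steps <- ceiling(t_max / dt)
  x <- matrix(0, n, k)
  fin <- matrix(Inf, n, k)
  sdt <- sqrt(dt)
  for (s in seq_len(steps)) {
    x <- x + v * dt + matrix(rnorm(n * k, sd = sdt), n, k)
    hit <- x >= a & !is.finite(fin)
    fin[hit] <- s * dt
    if (all(is.finite(fin))) break
  }
  if (k == 2L) {
    choice <- ifelse(fin[, 1] <= fin[, 2], 1L, 2L)
    dtime <- pmin(fin[, 1], fin[, 2])
  } else {
    done <- cbind(pmax(fin[, 1], fin[, 2]),
                  pmax(fin[, 3], fin[, 4]),
                  pmax(fin[, 5], fin[, 6]))
    choice <- max.col(-done, ties.method = "first")
    dtime <- done[cbind(seq_len(n), choice)]
  }
  bad <- !is.finite(dtime)
  choice[bad] <- NA_integer_
  rt <- dtime + t0
  rt[bad] <- NA_real_
  tibble::tibble(choice = choice, rt = rt)
}
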