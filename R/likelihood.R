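# Preprocess one subject's trial table for repeated likelihood evaluation.
prep_subject <- function(trials, model, q0 = 0) {
  if (is.unsorted(trials$trial)) stop("trials must be sorted by `trial`", call. = FALSE)
  sets <- unique(trials$set_id)
  has_rt <- if ("rt" %in% names(trials)) !is.na(trials$rt) else
    rep(FALSE, nrow(trials))
  cue <- if ("cue" %in% names(trials)) as.character(trials$cue) else
    rep("none", nrow(trials))
  list(
    n = nrow(trials),
    n_sets = length(sets),
    set_idx = match(trials$set_id, sets),
    choice = as.integer(trials$choice),
    outcome = as.numeric(trials$outcome),
    rt = as.numeric(if ("rt" %in% names(trials)) trials$rt else NA),
    spd = cue == "SPD",
    resp = has_rt & !is.na(trials$choice),
    chosen = !is.na(trials$choice),
    q0 = q0
  )
}

# Pre-feedback Q-values for all trials, vectorized over chains.
# Returns a list of J matrices (n_trials x n_chains).
q_traj_chains <- function(prep, alpha, J) {
  nch <- length(alpha)
  Q <- matrix(prep$q0, nch, prep$n_sets * J)
  qall <- matrix(NA_real_, prep$n, nch * J)  # per trial: J option blocks of nch
  set_idx <- prep$set_idx; choice <- prep$choice; outcome <- prep$outcome
  opt_cols <- seq_len(J)
  for (t in seq_len(prep$n)) {
    base <- (set_idx[t] - 1L) * J
    qall[t, ] <- Q[, base + opt_cols]
    ch <- choice[t]
    if (!is.na(ch)) {
      cidx <- base + ch
      Q[, cidx] <- Q[, cidx] + alpha * (outcome[t] - Q[, cidx])
    }
  }
  lapply(seq_len(J), function(j) qall[, (j - 1L) * nch + seq_len(nch), drop = FALSE])
}

# Subject log-likelihood for a matrix of sampling-scale parameter vectors
# (one row per chain). Returns a vector of log-likelihoods.
loglik_chains <- function(prep, theta, model) {
  nch <- nrow(theta)
  p <- function(nm) if (nm %in% colnames(theta)) theta[, nm] else NULL
  alpha <- pnorm(theta[, "alpha"])
  J <- model$n_options
  qpre <- q_traj_chains(prep, alpha, J)
  obs <- which(if (model$architecture == "softmax") prep$chosen else prep$resp)
  n_obs <- length(obs)
  if (n_obs == 0) return(rep(0, nch))
  ch <- prep$choice[obs]
  expand <- function(x) matrix(x, n_obs, nch, byrow = TRUE)

  if (model$architecture == "softmax") {
    beta <- expand(theta[, "beta"])
    qs <- lapply(qpre, function(m) m[obs, , drop = FALSE])
    xs <- lapply(qs, function(q) beta * q)
    mx <- Reduce(pmax, xs)
    denom <- Reduce(`+`, lapply(xs, function(x) exp(x - mx)))
    xch <- xs[[1]]
    for (j in seq_len(J)[-1]) {
      rows <- ch == j
      xch[rows, ] <- xs[[j]][rows, , drop = FALSE]
    }
    ll <- (xch - mx) - log(denom)
    return(colSums(ll))
  }

  rt <- matrix(prep$rt[obs], n_obs, nch)
  chm <- matrix(ch, n_obs, nch)
  a <- expand(theta[, "a"])
  t0 <- expand(theta[, "t0"])
  st0 <- if (!is.null(p("st0"))) expand(theta[, "st0"]) else 0
  spd <- prep$spd[obs]
  vary <- model$condition_vary
  if ("a" %in% vary) a[spd, ] <- a[spd, , drop = FALSE] *
    (1 + expand(theta[, "m_a"])[spd, , drop = FALSE])
  vmult <- matrix(1, n_obs, nch)
  if ("v" %in% vary) vmult[spd, ] <- 1 + expand(theta[, "m_v"])[spd, , drop = FALSE]

  dens <- switch(model$architecture,
    rl_ddm = {
      qd <- qpre[[1]][obs, , drop = FALSE] - qpre[[2]][obs, , drop = FALSE]
      v <- if (model$nonlinear) {
        vmax <- expand(theta[, "vmax"])
        2 * vmax / (1 + exp(-expand(theta[, "w"]) * qd)) - vmax
      } else expand(theta[, "w"]) * qd
      v <- v * vmult
      dddm(rt, chm, v, a, t0,
           sv = if (model$sv) expand(theta[, "sv"]) else 0,
           sz = if (model$sz) expand(theta[, "sz"]) else 0,
           st0 = st0)
    },
    rl_rd = {
      V0 <- expand(theta[, "V0"])
      if ("V0" %in% vary) V0[spd, ] <- V0[spd, , drop = FALSE] *
        (1 + expand(theta[, "m_V0"])[spd, , drop = FALSE])
      w <- expand(theta[, "w"])
      v1 <- (V0 + w * qpre[[1]][obs, , drop = FALSE]) * vmult
      v2 <- (V0 + w * qpre[[2]][obs, , drop = FALSE]) * vmult
      drace2(rt, chm, v1, v2, a, t0, st0)
    },
    rl_lard = ,
    rl_ard = {
      V0 <- expand(theta[, "V0"])
      if ("V0" %in% vary) V0[spd, ] <- V0[spd, , drop = FALSE] *
        (1 + expand(theta[, "m_V0"])[spd, , drop = FALSE])
      wd <- expand(theta[, "wd"])
      ws <- if (model$architecture == "rl_ard") expand(theta[, "ws"]) else 0
      q1 <- qpre[[1]][obs, , drop = FALSE]
      q2 <- qpre[[2]][obs, , drop = FALSE]
      v1 <- (V0 + wd * (q1 - q2) + ws * (q1 + q2)) * vmult
      v2 <- (V0 + wd * (q2 - q1) + ws * (q1 + q2)) * vmult
      drace2(rt, chm, v1, v2, a, t0, st0)
    },
    rl_ard_winall = {
      V0 <- expand(theta[, "V0"])
      wd <- expand(theta[, "wd"])
      ws <- expand(theta[, "ws"])
      qs <- lapply(qpre, function(m) m[obs, , drop = FALSE])
      pairs <- winall_pairs()
      v <- matrix(NA_real_, n_obs * nch, 6)
      for (r in seq_len(6)) {
        i <- pairs$own[r]; j <- pairs$other[r]
        v[, r] <- as.vector((V0 + wd * (qs[[i]] - qs[[j]]) +
                               ws * (qs[[i]] + qs[[j]])) * vmult)
      }
      dwinall(as.vector(rt), as.vector(chm), v, as.vector(a),
              as.vector(t0), as.vector(if (is.matrix(st0)) st0 else matrix(st0, n_obs, nch)))
    }
  )
  dens <- matrix(pmax(dens, 1e-10), n_obs, nch)
  colSums(log(dens))
}

#' Trial-level log-likelihood for one subject
#'
#' Composes the delta-rule value trajectory (replayed from the subject's
#' *observed* choices and outcomes) with the per-trial defective density of
#' the observed response and response time under the model's decision
#' architecture. Per-trial densities are floored at 1e-10, so responses
#' faster than the non-decision time degrade the fit rather than abort it.
#' Trials without a recorded response still update Q-values (the outcome was
#' shown) but contribute no density. Soft-max models use the log choice
#' probability only.
#'
#' @param trials one subject's trial table (see [simulate_experiment()] for
#'   the columns), sorted by `trial`.
#' @param model an [model_spec()] object.
#' @param params named numeric vector of natural-scale parameter values
#'   (`alpha` as a probability, not probit).
#' @param q0 initial Q-value.
#' @return the scalar log-likelihood.
#' @export
log_likelihood_subject <- function(trials, model, params, q0 = 0) {
  stopifnot(all(model$params %in% names(params)))
  theta <- matrix(params[model$params], 1, model$n_free,
                  dimnames = list(NULL, model$params))
  theta <- to_sampling_scale(theta, model$params)
  prep <- prep_subject(trials, model, q0 = q0)
  as.numeric(loglik_chains(prep, theta, model))
}
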