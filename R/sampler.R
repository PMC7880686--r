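#' Sampler settings for hierarchical DE-MCMC
#'
#' Defaults follow the estimation scheme the models were designed for: the
#' number of chains is three times the number of free parameters,
#' differential-evolution proposals use scale `gamma = 2.38 / sqrt(2 d)`
#' with a small uniform jitter, and migration (ring-copying of whole chain
#' states, Metropolis-accepted) happens with probability 0.05 per iteration
#' during burn-in only. After sampling, chains failing the Gelman-Rubin
#' threshold trigger automatic extension: the stored draws are treated as
#' additional burn-in and sampling restarts, up to `max_extend` times.
#'
#' Before the hierarchical run, each subject is fit independently for
#' `n_init` iterations (DE-MCMC against the likelihood times the prior);
#' the hierarchical chains start from those states, with group-level means
#' and SDs initialized from the across-subject spread. This standard
#' staging keeps the group-level SDs from collapsing onto an uninformed
#' initial cluster (the hierarchical funnel) and shortens burn-in.
#'
#' @param n_chains number of chains (default `3 * n_free`, set at fit time).
#' @param n_burn,n_sample burn-in and retained iterations per chain.
#' @param n_init per-subject independent initialization iterations.
#' @param migration_prob per-iteration probability of a migration step
#'   during burn-in.
#' @param de_jitter half-width of the uniform jitter added to DE proposals.
#' @param psrf_target Gelman-Rubin threshold for automatic extension.
#' @param max_extend maximum number of automatic extensions.
#' @export
sampler_config <- function(n_chains = NULL, n_burn = 500, n_sample = 1000,
                           n_init = 200, migration_prob = 0.05,
                           de_jitter = 1e-3, psrf_target = 1.03,
                           max_extend = 2) {
  list(n_chains = n_chains, n_burn = n_burn, n_sample = n_sample,
       n_init = n_init, migration_prob = migration_prob,
       de_jitter = de_jitter, psrf_target = psrf_target,
       max_extend = max_extend)
}

#' Fit a hierarchical RL-EAM by differential-evolution MCMC
#'
#' Estimates group- and subject-level posteriors of a
#' reinforcement-learning evidence-accumulation model. Each parameter has an
#' independent truncated-normal population distribution (mean and SD
#' sampled; truncation bounds shared with the priors of
#' [default_priors()]); learning rates are sampled on the probit scale.
#' Proposals are differential-evolution moves `theta + gamma (theta_m -
#' theta_n) + eps` built from two other randomly chosen chains, accepted by
#' Metropolis-Hastings on the hierarchical target; subject blocks and the
#' group block alternate within every iteration. The run is deterministic
#' given `seed`.
#'
#' @param data trial table covering one or more subjects (columns `subject`,
#'   `trial`, `set_id`, `choice`, `rt`, `outcome`, and `cue` for designs
#'   with cue conditions).
#' @param model an [model_spec()] object.
#' @param priors prior tibble as produced by [default_priors()].
#' @param config settings from [sampler_config()].
#' @param seed integer seed.
#' @param q0 initial Q-value used when replaying the learning trajectories.
#' @return an object of class `rleam_fit`; see [tidy.rleam_fit()],
#'   [glance.rleam_fit()], [gelman_rubin()], [bpic()],
#'   [posterior_predict()].
#' @export
run_sampler <- function(data, model, priors = default_priors(model),
                        config = sampler_config(), seed = 1, q0 = 0) {
  stopifnot(inherits(model, "rleam_model"))
  P <- model$n_free
  params <- model$params
  stopifnot(identical(priors$param, params))
  D <- config$n_chains %||% (3L * P)
  if (D < 2 * P + 1) stop("DE-MCMC needs at least 2 * n_params + 1 chains", call. = FALSE)
  subjects <- unique(data$subject)
  S <- length(subjects)
  preps <- lapply(subjects, function(s)
    prep_subject(data[data$subject == s, , drop = FALSE], model, q0 = q0))
  min_rt <- vapply(preps, function(pr) {
    r <- pr$rt[pr$resp]
    if (length(r)) min(r) else Inf
  }, numeric(1))

  lb <- priors$lb; ub <- priors$ub
  gamma_s <- 2.38 / sqrt(2 * P)
  gamma_g <- 2.38 / sqrt(2 * 2)  # per-parameter (mu, sigma) blocks
  jit <- config$de_jitter

  log_prior_group_p <- function(mu_p, sig_p, p) {
    # prior log density of one parameter's hyper pair, per chain
    out <- dtnorm(mu_p, priors$mean[p], priors$sd[p], lb[p], ub[p], log = TRUE) +
      dgamma(sig_p, 1, 1, log = TRUE)
    out[!is.finite(out)] <- -Inf
    out
  }
  log_pop_p <- function(x, mu_p, sig_p, p) {
    # population log density of one parameter's subject values, per chain
    dtnorm(x, mu_p, sig_p, lb[p], ub[p], log = TRUE)
  }
  valid_theta <- function(th) {
    ok <- rep(TRUE, nrow(th))
    for (p in seq_len(P)) ok <- ok & th[, p] >= lb[p] & th[, p] <= ub[p]
    ok & apply(is.finite(th), 1, all)
  }

  with_seed(seed, {
    # ---- initialization: prior draws shrunk toward the prior mean --------
    init_theta <- function(n, s = NULL) {
      th <- matrix(NA_real_, n, P, dimnames = list(NULL, params))
      for (p in seq_len(P)) {
        th[, p] <- rtnorm(n, priors$mean[p], priors$sd[p] / 5, lb[p], ub[p])
      }
      if (!is.null(s) && "t0" %in% params && is.finite(min_rt[s])) {
        cap <- max(0.03, 0.8 * min_rt[s])
        th[, "t0"] <- pmin(th[, "t0"], cap)
      }
      th
    }
    mu <- init_theta(D)
    sig <- matrix(pmax(abs(rnorm(D * P, 0.2, 0.1)), 0.05), D, P)
    th <- array(NA_real_, c(D, S, P), dimnames = list(NULL, NULL, params))
    ll <- matrix(NA_real_, D, S)
    for (s in seq_len(S)) {
      tries <- 0
      repeat {
        cand <- init_theta(D, s)
        l <- loglik_chains(preps[[s]], cand, model)
        bad <- !is.finite(l)
        if (!any(bad) || tries > 50) {
          if (any(bad)) stop("could not initialize finite likelihoods", call. = FALSE)
          th[, s, ] <- cand
          ll[, s] <- l
          break
        }
        tries <- tries + 1
        keep <- which(!bad)
        if (length(keep)) {
          cand[bad, ] <- cand[sample(rep(keep, 2), sum(bad)), , drop = FALSE]
          th[, s, ] <- cand
          ll[, s] <- loglik_chains(preps[[s]], cand, model)
          break
        }
      }
    }
    # Chains update in two blocks: each block proposes with DE directions
    # built from the *other* (frozen) block, so simultaneous moves cannot
    # contract the population (snapshot-parallel updates bias dispersion).
    chain_halves <- function() {
      perm <- sample(D)
      list(perm[seq_len(D %/% 2)], perm[(D %/% 2 + 1):D])
    }
    partners <- function(upd, fix) {
      r1 <- fix[sample.int(length(fix), length(upd), replace = TRUE)]
      r2 <- vapply(r1, function(x) {
        pick <- fix[fix != x]
        pick[sample.int(length(pick), 1)]
      }, numeric(1))
      cbind(r1, r2)
    }

    # ---- stage 1: independent per-subject runs against the prior ---------
    if (config$n_init > 0) {
      lpri_th <- function(thmat) {
        out <- numeric(nrow(thmat))
        for (p in seq_len(P)) {
          out <- out + dtnorm(thmat[, p], priors$mean[p], priors$sd[p],
                              lb[p], ub[p], log = TRUE)
        }
        out
      }
      for (s in seq_len(S)) {
        cur <- matrix(th[, s, ], D, P, dimnames = list(NULL, params))
        cur_ll <- ll[, s]
        cur_tgt <- cur_ll + lpri_th(cur)
        for (it in seq_len(config$n_init)) {
          hv <- chain_halves()
          for (h in 1:2) {
            upd <- hv[[h]]; nupd <- length(upd)
            idx <- partners(upd, hv[[3 - h]])
            prop <- cur[upd, , drop = FALSE] +
              gamma_s * (cur[idx[, 1], , drop = FALSE] -
                         cur[idx[, 2], , drop = FALSE]) +
              matrix(runif(nupd * P, -jit, jit), nupd, P)
            ok <- valid_theta(prop)
            ll_new <- rep(-Inf, nupd)
            if (any(ok)) ll_new[ok] <- loglik_chains(preps[[s]],
                                                     prop[ok, , drop = FALSE], model)
            tgt_new <- ll_new + lpri_th(prop)
            acc <- log(runif(nupd)) < tgt_new - cur_tgt[upd]
            acc[!is.finite(tgt_new)] <- FALSE
            ua <- upd[acc]
            if (length(ua)) {
              cur[ua, ] <- prop[acc, , drop = FALSE]
              cur_ll[ua] <- ll_new[acc]
              cur_tgt[ua] <- tgt_new[acc]
            }
          }
        }
        th[, s, ] <- cur
        ll[, s] <- cur_ll
      }
      # group state from the across-subject spread of the stage-1 states
      for (p in seq_len(P)) {
        thp <- matrix(th[, , p], D, S)
        mu[, p] <- pmin(pmax(rowMeans(thp), lb[p]), ub[p])
        spread <- apply(thp, 1, stats::sd)
        spread[!is.finite(spread) | spread < 0.05] <- 0.05
        sig[, p] <- spread
      }
    }

    # caches: per-parameter population densities and hyper-prior terms
    lpop <- array(NA_real_, c(D, S, P))
    for (s in seq_len(S)) for (p in seq_len(P)) {
      lpop[, s, p] <- log_pop_p(th[, s, p], mu[, p], sig[, p], p)
    }
    lgrp <- sapply(seq_len(P), function(p) log_prior_group_p(mu[, p], sig[, p], p))
    lgrp <- matrix(lgrp, D, P)
    acc_count <- c(subject = 0, group = 0)
    try_count <- c(subject = 0, group = 0)

    subject_step <- function() {
      for (s in seq_len(S)) {
        hv <- chain_halves()
        cur <- matrix(th[, s, ], D, P, dimnames = list(NULL, params))
        for (h in 1:2) {
          upd <- hv[[h]]; nupd <- length(upd)
          idx <- partners(upd, hv[[3 - h]])
          prop <- cur[upd, , drop = FALSE] +
            gamma_s * (cur[idx[, 1], , drop = FALSE] -
                       cur[idx[, 2], , drop = FALSE]) +
            matrix(runif(nupd * P, -jit, jit), nupd, P)
          ok <- valid_theta(prop)
          ll_new <- rep(-Inf, nupd)
          if (any(ok)) ll_new[ok] <- loglik_chains(preps[[s]],
                                                   prop[ok, , drop = FALSE], model)
          lpop_new <- sapply(seq_len(P), function(p)
            log_pop_p(prop[, p], mu[upd, p], sig[upd, p], p))
          lpop_new <- matrix(lpop_new, nupd, P)
          dnew <- ll_new + rowSums(lpop_new)
          dold <- ll[upd, s] + rowSums(matrix(lpop[upd, s, ], nupd, P))
          acc <- log(runif(nupd)) < dnew - dold
          acc[!is.finite(dnew)] <- FALSE
          try_count["subject"] <<- try_count["subject"] + nupd
          acc_count["subject"] <<- acc_count["subject"] + sum(acc)
          ua <- upd[acc]
          if (length(ua)) {
            cur[ua, ] <- prop[acc, , drop = FALSE]
            th[ua, s, ] <<- prop[acc, , drop = FALSE]
            ll[ua, s] <<- ll_new[acc]
            lpop[ua, s, ] <<- lpop_new[acc, , drop = FALSE]
          }
        }
      }
    }

    group_step <- function() {
      # blocked per parameter: joint DE move on that parameter's (mu, sigma)
      for (p in seq_len(P)) {
        hv <- chain_halves()
        for (h in 1:2) {
          upd <- hv[[h]]; nupd <- length(upd)
          x <- cbind(mu[, p], sig[, p])
          idx <- partners(upd, hv[[3 - h]])
          prop <- x[upd, , drop = FALSE] +
            gamma_g * (x[idx[, 1], , drop = FALSE] -
                       x[idx[, 2], , drop = FALSE]) +
            matrix(runif(nupd * 2, -jit, jit), nupd, 2)
          lgrp_new <- log_prior_group_p(prop[, 1], prop[, 2], p)
          thp <- matrix(th[upd, , p], nupd, S)
          lpop_new <- matrix(-Inf, nupd, S)
          fin <- is.finite(lgrp_new)
          if (any(fin)) {
            for (s in seq_len(S)) {
              lpop_new[fin, s] <- log_pop_p(thp[fin, s], prop[fin, 1],
                                            prop[fin, 2], p)
            }
          }
          tgt_new <- lgrp_new + rowSums(lpop_new)
          tgt_old <- lgrp[upd, p] + rowSums(matrix(lpop[upd, , p], nupd, S))
          acc <- log(runif(nupd)) < tgt_new - tgt_old
          acc[!is.finite(tgt_new)] <- FALSE
          try_count["group"] <<- try_count["group"] + nupd
          acc_count["group"] <<- acc_count["group"] + sum(acc)
          ua <- upd[acc]
          if (length(ua)) {
            mu[ua, p] <<- prop[acc, 1]
            sig[ua, p] <<- prop[acc, 2]
            lgrp[ua, p] <<- lgrp_new[acc]
            lpop[ua, , p] <<- lpop_new[acc, , drop = FALSE]
          }
        }
      }
    }

    migrate_step <- function() {
      k <- sample(2:max(2, ceiling(D / 2)), 1)
      ring <- sample(D, k)
      # chain ring[i] proposes to adopt the full state of ring[i + 1]
      post <- rowSums(lgrp) + rowSums(matrix(lpop, D, S * P)) + rowSums(ll)
      donor <- c(ring[-1], ring[1])
      acc <- log(runif(k)) < post[donor] - post[ring]
      if (any(acc)) {
        src <- donor[acc]; dst <- ring[acc]
        mu[dst, ] <<- mu[src, , drop = FALSE]
        sig[dst, ] <<- sig[src, , drop = FALSE]
        th[dst, , ] <<- th[src, , , drop = FALSE]
        ll[dst, ] <<- ll[src, , drop = FALSE]
        lpop[dst, , ] <<- lpop[src, , , drop = FALSE]
        lgrp[dst, ] <<- lgrp[src, , drop = FALSE]
      }
    }

    unstick <- function() {
      # replace chains stranded far below the population's typical posterior
      # density with copies of healthy chains (end of burn-in only)
      post <- rowSums(lgrp) + rowSums(matrix(lpop, D, S * P)) + rowSums(ll)
      bad <- which(post < stats::median(post) - 50)
      good <- setdiff(seq_len(D), bad)
      if (length(bad) && length(good) >= 2) {
        src <- good[sample.int(length(good), length(bad), replace = TRUE)]
        mu[bad, ] <<- mu[src, , drop = FALSE]
        sig[bad, ] <<- sig[src, , drop = FALSE]
        th[bad, , ] <<- th[src, , , drop = FALSE]
        ll[bad, ] <<- ll[src, , drop = FALSE]
        lpop[bad, , ] <<- lpop[src, , , drop = FALSE]
        lgrp[bad, ] <<- lgrp[src, , drop = FALSE]
      }
    }

    run_iters <- function(n, burnin, store) {
      if (store) {
        mu_out <- array(NA_real_, c(n, D, P), dimnames = list(NULL, NULL, params))
        sig_out <- array(NA_real_, c(n, D, P), dimnames = list(NULL, NULL, params))
        th_out <- array(NA_real_, c(n, D, S, P))
        ll_out <- matrix(NA_real_, n, D)
      }
      for (it in seq_len(n)) {
        if (burnin && runif(1) < config$migration_prob) migrate_step()
        subject_step()
        group_step()
        if (store) {
          mu_out[it, , ] <- mu
          sig_out[it, , ] <- sig
          th_out[it, , , ] <- th
          ll_out[it, ] <- rowSums(ll)
        }
      }
      if (store) list(mu = mu_out, sigma = sig_out, theta = th_out, loglik = ll_out)
    }

    if (config$n_burn > 0) {
      run_iters(config$n_burn, burnin = TRUE, store = FALSE)
      unstick()
    }
    extensions <- 0L
    if (config$n_sample == 0) {
      # snapshot of the (possibly initial) state, no moves
      draws <- list(
        mu = array(mu, c(1, D, P), dimnames = list(NULL, NULL, params)),
        sigma = array(sig, c(1, D, P), dimnames = list(NULL, NULL, params)),
        theta = array(th, c(1, D, S, P)),
        loglik = matrix(rowSums(ll), 1, D))
      gr <- list(psrf = stats::setNames(rep(NA_real_, 2 * P),
                                        c(paste0("mu_", params), paste0("sigma_", params))),
                 mpsrf = NA_real_)
    } else {
      draws <- run_iters(config$n_sample, burnin = FALSE, store = TRUE)
      repeat {
        gr <- gelman_rubin(group_draw_array(draws, params))
        if (max(gr$psrf, gr$mpsrf, na.rm = TRUE) <= config$psrf_target ||
            extensions >= config$max_extend) break
        extensions <- extensions + 1L
        draws <- run_iters(config$n_sample, burnin = FALSE, store = TRUE)
      }
    }

    structure(list(
      model = model, priors = priors, config = config, seed = seed,
      subjects = subjects, params = params, n_chains = D,
      n_sample = config$n_sample, extensions = extensions,
      draws = draws, preps = preps, data = data, q0 = q0,
      accept_rate = acc_count / pmax(try_count, 1),
      psrf = gr
    ), class = "rleam_fit")
  })
}

# iterations x chains x (2P) array of group-level draws, for diagnostics
group_draw_array <- function(draws, params) {
  n <- dim(draws$mu)[1]; D <- dim(draws$mu)[2]; P <- dim(draws$mu)[3]
  out <- array(NA_real_, c(n, D, 2 * P),
               dimnames = list(NULL, NULL,
                               c(paste0("mu_", params), paste0("sigma_", params))))
  out[, , seq_len(P)] <- draws$mu
  out[, , P + seq_len(P)] <- draws$sigma
  out
}

#' @export
print.rleam_fit <- function(x, ...) {
  cat("<rleam_fit> ", x$model$architecture, ": ", length(x$subjects),
      " subjects, ", x$n_chains, " chains x ", dim(x$draws$mu)[1],
      " retained iterations\n", sep = "")
  cat("  max PSRF ", round(max(x$psrf$psrf), 3), " (multivariate ",
      round(x$psrf$mpsrf, 3), "), extensions: ", x$extensions, "\n", sep = "")
  invisible(x)
}

#' Gelman-Rubin convergence diagnostic
#'
#' Potential scale reduction factors comparing between- to within-chain
#' variance, with the sampling-variability degrees-of-freedom correction,
#' plus the multivariate PSRF (largest eigenvalue of the pooled
#' within/between covariance ratio).
#'
#' @param x draws: an iterations x chains matrix, or an iterations x chains
#'   x parameters array.
#' @return list with `psrf` (named per-parameter vector) and `mpsrf`
#'   (`NA` for a single parameter).
#' @export
gelman_rubin <- function(x) {
  if (length(dim(x)) == 2) x <- array(x, c(dim(x), 1))
  n <- dim(x)[1]; m <- dim(x)[2]; P <- dim(x)[3]
  if (n < 2 || m < 2) stop("need at least 2 iterations and 2 chains", call. = FALSE)
  psrf <- numeric(P)
  for (p in seq_len(P)) {
    xp <- x[, , p]                     # n x m
    xbar <- colMeans(xp)
    s2 <- apply(xp, 2, stats::var)
    W <- mean(s2)
    B <- n * stats::var(xbar)
    muhat <- mean(xbar)
    sig2hat <- (n - 1) * W / n + B / n
    V <- sig2hat + B / (m * n)
    var_w <- stats::var(s2) / m
    var_b <- 2 * B^2 / (m - 1)
    cov_wb <- (n / m) * (stats::cov(s2, xbar^2) - 2 * muhat * stats::cov(s2, xbar))
    var_V <- ((n - 1)^2 * var_w + (1 + 1 / m)^2 * var_b +
                2 * (n - 1) * (1 + 1 / m) * cov_wb) / n^2
    df_adj <- if (var_V > 0) { df_V <- 2 * V^2 / var_V; (df_V + 3) / (df_V + 1) } else 1
    psrf[p] <- sqrt(df_adj * V / W)
  }
  names(psrf) <- dimnames(x)[[3]] %||% paste0("par", seq_len(P))
  mpsrf <- NA_real_
  if (P > 1) {
    Wm <- matrix(0, P, P); Bm <- matrix(0, P, P)
    means <- matrix(NA_real_, m, P)
    for (ch in seq_len(m)) {
      xc <- x[, ch, ]
      Wm <- Wm + stats::cov(xc)
      means[ch, ] <- colMeans(xc)
    }
    Wm <- Wm / m
    Bm <- n * stats::cov(means)
    emax <- max(Re(eigen(solve(Wm, Bm / n), only.values = TRUE)$values))
    mpsrf <- sqrt((n - 1) / n + (1 + 1 / P) * emax)
  }
  list(psrf = psrf, mpsrf = mpsrf)
}

#' Bayesian predictive information criterion
#'
#' Deviance-based model-selection score with a doubled complexity penalty:
#' `BPIC = Dbar + 2 pD`, where `Dbar` is the posterior mean deviance
#' (`-2 log L`), `pD = Dbar - Dhat`, and `Dhat` the deviance at the
#' posterior mean of the subject-level parameters. Lower is better.
#'
#' @param fit an [run_sampler()] fit.
#' @return list with `bpic`, `dbar`, `dhat`, `pd`.
#' @export
bpic <- function(fit) {
  ll <- fit$draws$loglik                 # iterations x chains, summed over subjects
  dbar <- mean(-2 * ll)
  thbar <- apply(fit$draws$theta, c(3, 4), mean)  # S x P posterior means
  colnames(thbar) <- fit$params
  dhat <- -2 * sum(vapply(seq_along(fit$preps), function(s) {
    loglik_chains(fit$preps[[s]], thbar[s, , drop = FALSE], fit$model)
  }, numeric(1)))
  pd <- dbar - dhat
  list(bpic = dbar + 2 * pd, dbar = dbar, dhat = dhat, pd = pd)
}

#' Compare fitted models by BPIC
#'
#' @param ... named `rleam_fit` objects.
#' @return tibble sorted by BPIC (best first), with `delta_bpic` relative
#'   to the best model.
#' @export
compare_models <- function(...) {
  fits <- list(...)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) f$model$architecture, character(1))
  }
  tab <- purrr::map_dfr(names(fits), function(nm) {
    b <- bpic(fits[[nm]])
    tibble::tibble(model = nm, bpic = b$bpic, dbar = b$dbar, pd = b$pd)
  })
  tab <- dplyr::arrange(tab, .data$bpic)
  tab$delta_bpic <- tab$bpic - tab$bpic[1]
  tab
}
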