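#' Tidy a hierarchical model fit
#'
#' Posterior summaries in a tibble, one row per parameter. `level =
#' "group"` returns the population means (`mu_*`) and SDs (`sigma_*`);
#' `level = "subject"` returns per-subject parameter summaries. Learning
#' rates are reported on the natural (probability) scale.
#'
#' @param x an `rleam_fit`.
#' @param level `"group"` or `"subject"`.
#' @param ... unused.
#' @return a tibble with `term` (and `subject` for subject level),
#'   `estimate` (posterior median), `mean`, `sd`, `conf.low`, `conf.high`
#'   (95% central interval).
#' @method tidy rleam_fit
#' @export
tidy.rleam_fit <- function(x, level = c("group", "subject"), ...) {
  level <- match.arg(level)
  params <- x$params
  summarize_draws <- function(v, term, subject = NA_integer_) {
    tibble::tibble(term = term, subject = subject,
                   estimate = stats::median(v), mean = mean(v),
                   sd = stats::sd(v),
                   conf.low = unname(stats::quantile(v, 0.025)),
                   conf.high = unname(stats::quantile(v, 0.975)))
  }
  nat <- function(v, p) if (p == "alpha") pnorm(v) else v
  if (level == "group") {
    out <- purrr::map_dfr(seq_along(params), function(p) {
      dplyr::bind_rows(
        summarize_draws(nat(as.vector(x$draws$mu[, , p]), params[p]),
                        paste0("mu_", params[p])),
        summarize_draws(as.vector(x$draws$sigma[, , p]),
                        paste0("sigma_", params[p]))
      )
    })
    dplyr::select(out, -"subject")
  } else {
    purrr::map_dfr(seq_along(x$subjects), function(s) {
      purrr::map_dfr(seq_along(params), function(p) {
        summarize_draws(nat(as.vector(x$draws$theta[, , s, p]), params[p]),
                        params[p], subject = x$subjects[s])
      })
    })
  }
}

#' Glance at a hierarchical model fit
#'
#' @param x an `rleam_fit`.
#' @param ... unused.
#' @return one-row tibble: architecture, numbers of subjects/parameters/
#'   chains/iterations, max univariate and multivariate PSRF, and BPIC.
#' @method glance rleam_fit
#' @export
glance.rleam_fit <- function(x, ...) {
  b <- bpic(x)
  tibble::tibble(
    architecture = x$model$architecture,
    n_subjects = length(x$subjects),
    n_free = x$model$n_free,
    n_chains = x$n_chains,
    n_iter = dim(x$draws$mu)[1],
    max_psrf = max(x$psrf$psrf),
    mpsrf = x$psrf$mpsrf,
    bpic = b$bpic,
    p_d = b$pd
  )
}

#' @method tidy rleam_recovery
#' @export
tidy.rleam_recovery <- function(x, ...) x$correlations

#' @method glance rleam_recovery
#' @export
glance.rleam_recovery <- function(x, ...) {
  tibble::tibble(
    architecture = x$fit$model$architecture,
    n_subjects = nrow(x$generating),
    min_cor = min(x$correlations$cor_spearman),
    median_cor = stats::median(x$correlations$cor_spearman)
  )
}

#' Extract raw posterior draws
#'
#' Long-format draws for downstream tooling: one row per retained
#' iteration, chain and term. Group level exposes `mu_*` and `sigma_*`
#' terms; subject level one term per subject and parameter. Values are on
#' the sampling scale (learning rates on probit scale) unless
#' `natural = TRUE`.
#'
#' @param fit an `rleam_fit`.
#' @param level `"group"` or `"subject"`.
#' @param natural report learning rates as probabilities.
#' @return tibble with `chain`, `iteration`, `term`, (`subject`,) `value`.
#' @export
posterior_draws <- function(fit, level = c("group", "subject"),
                            natural = FALSE) {
  level <- match.arg(level)
  params <- fit$params
  nat <- function(v, p) if (natural && p == "alpha") pnorm(v) else v
  grid <- function(m) {
    tibble::tibble(iteration = rep(seq_len(nrow(m)), ncol(m)),
                   chain = rep(seq_len(ncol(m)), each = nrow(m)),
                   value = as.vector(m))
  }
  if (level == "group") {
    purrr::map_dfr(seq_along(params), function(p) {
      dplyr::bind_rows(
        dplyr::mutate(grid(nat(fit$draws$mu[, , p], params[p])),
                      term = paste0("mu_", params[p])),
        dplyr::mutate(grid(fit$draws$sigma[, , p]),
                      term = paste0("sigma_", params[p]))
      )
    })
  } else {
    purrr::map_dfr(seq_along(fit$subjects), function(s) {
      purrr::map_dfr(seq_along(params), function(p) {
        dplyr::mutate(grid(nat(fit$draws$theta[, , s, p], params[p])),
                      term = params[p], subject = fit$subjects[s])
      })
    })
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
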