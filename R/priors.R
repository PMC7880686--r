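#' Default hierarchical priors
#'
#' Vague priors on the group-level means of each parameter, on the sampling
#' scale. Learning rates are sampled on the probit scale with a normal
#' prior (mean -1.6, SD 5); decision parameters get wide normals truncated
#' to their support: threshold `a ~ N(3, 5)` on (0, Inf), non-decision time
#' `t0 ~ N(0.3, 0.5)` on (0.025, 1) s, the diffusion-model weight
#' `w ~ N(2, 5)`, the race weight `w ~ N(9, 5)`, advantage weights
#' `wd ~ N(9, 5)` and `ws ~ N(0, 3)`, urgency `V0 ~ N(2, 5)` on (0, Inf),
#' and condition multipliers `m ~ N(0, 5)` on (-1, Inf). All group-level
#' SDs share a Gamma(1, 1) prior. The same truncation bounds are used for
#' the (truncated-normal) population distributions of subject parameters.
#'
#' @param model an [model_spec()] object.
#' @return tibble with columns `param`, `mean`, `sd`, `lb`, `ub`
#'   (sampling scale; `alpha` rows refer to the probit scale).
#' @export
default_priors <- function(model) {
  p <- model$params
  spec <- lapply(p, function(nm) {
    base <- sub("^(m)_.*", "\\1", nm)
    switch(base,
      alpha = c(-1.6, 5, -Inf, Inf),
      a     = c(3, 5, 0, Inf),
      t0    = c(0.3, 0.5, 0.025, 1),
      w     = if (model$architecture == "rl_ddm") c(2, 5, -Inf, Inf)
              else c(9, 5, -Inf, Inf),
      wd    = c(9, 5, -Inf, Inf),
      ws    = c(0, 3, -Inf, Inf),
      V0    = c(2, 5, 0, Inf),
      beta  = c(1, 5, 0, Inf),
      vmax  = c(2, 5, 0, Inf),
      sv    = c(0.1, 0.1, 0, Inf),
      sz    = c(0.1, 0.1, 0, 0.5),
      st0   = c(0.1, 0.1, 0, Inf),
      m     = c(0, 5, -1, Inf),
      stop("no default prior for parameter ", nm)
    )
  })
  m <- do.call(rbind, spec)
  tibble::tibble(param = p, mean = m[, 1], sd = m[, 2], lb = m[, 3], ub = m[, 4])
}

# natural <-> sampling scale for a parameter matrix (columns named)
to_sampling_scale <- function(theta, params) {
  if ("alpha" %in% params) theta[, "alpha"] <- qnorm(theta[, "alpha"])
  theta
}

to_natural_scale <- function(theta, params) {
  if ("alpha" %in% params) theta[, "alpha"] <- pnorm(theta[, "alpha"])
  theta
}
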