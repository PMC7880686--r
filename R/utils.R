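`%||%` <- function(x, y) if (is.null(x)) y else x

# truncated normal density / sampler on [lb, ub]; vectorized, log density
dtnorm <- function(x, mean, sd, lb = -Inf, ub = Inf, log = FALSE) {
  n <- max(length(x), length(mean), length(sd), length(lb), length(ub))
  x <- rep_len(x, n); mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  lz <- log(pnorm(ub, mean, sd) - pnorm(lb, mean, sd))
  out <- dnorm(x, mean, sd, log = TRUE) - lz
  out[x < lb | x > ub] <- -Inf
  out[!is.finite(lz)] <- -Inf
  if (log) out else exp(out)
}

rtnorm <- function(n, mean, sd, lb = -Inf, ub = Inf) {
  mean <- rep_len(mean, n); sd <- rep_len(sd, n)
  lb <- rep_len(lb, n); ub <- rep_len(ub, n)
  plo <- pnorm(lb, mean, sd)
  phi <- pnorm(ub, mean, sd)
  qnorm(plo + runif(n) * (phi - plo), mean, sd)
}

# run code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
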