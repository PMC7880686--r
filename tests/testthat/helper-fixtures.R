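# Shared fixtures, built in code at test time.

ard_params <- c(alpha = 0.13, a = 2.14, t0 = 0.11, V0 = 2.46, wd = 2.25,
                ws = 0.36)

# hand-built two-option trial table with fixed choices/outcomes
toy_trials <- function(n = 10, set_id = "pairA", seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    subject = 1L, block = 1L, trial = seq_len(n), set_id = set_id,
    cue = "none", choice = sample(1:2, n, replace = TRUE),
    rt = runif(n, 0.3, 1.2), outcome = sample(0:1, n, replace = TRUE),
    reward = NA_integer_, too_late = FALSE
  ))
}

# Monte-Carlo standard error of a proportion
se_prop <- function(p, n) sqrt(p * (1 - p) / n)

# order-statistics percentile oracle (linear interpolation of sorted values),
# written independently of stats::quantile
sort_percentile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# one small hierarchical ARD fit shared across test files (built lazily)
.fixture_env <- new.env()
small_ard_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    model <- model_spec("rl_ard")
    design <- make_design("exp1", seed = 301)
    gen <- withr::with_seed(302,
      draw_subject_params(model, default_group_params(model, "exp1"), 5))
    sim <- simulate_experiment(design, model, gen, seed = 303)
    fit <- run_sampler(sim, model,
                       config = sampler_config(n_burn = 500, n_sample = 400,
                                               max_extend = 0),
                       seed = 304)
    .fixture_env$fit <- fit
    .fixture_env$gen <- gen
    .fixture_env$design <- design
    .fixture_env$sim <- sim
  }
  .fixture_env
}
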