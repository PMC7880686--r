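#' Learning-curve summaries in trial bins
#'
#' Splits each subject's trials, in presentation order, into `n_bins`
#' equal-count bins (any remainder goes to the earliest bins), computes
#' per-bin accuracy and the 10th/50th/90th RT percentiles separately for
#' correct and error responses, then averages the per-subject summaries
#' across subjects. Error percentiles in bins with fewer than 3 error
#' trials are treated as missing rather than reported as unstable
#' estimates. Trials without a recorded RT are excluded from the RT
#' percentiles (and from accuracy).
#'
#' @param trials trial table with `subject`, `trial`, `rt`, and a logical
#'   `correct` column (chose the currently-best option; see
#'   [simulate_experiment()]).
#' @param n_bins number of bins (default 10).
#' @return a tibble of class `rleam_bins`: `bin`, `n`, `accuracy`,
#'   `rt_correct_p10/p50/p90`, `rt_error_p10/p50/p90`.
#' @export
bin_summaries <- function(trials, n_bins = 10) {
  per_subject <- trials |>
    dplyr::group_by(.data$subject) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(bin = bin_index(dplyr::n(), n_bins)) |>
    dplyr::filter(!is.na(.data$rt), !is.na(.data$correct)) |>
    dplyr::group_by(.data$subject, .data$bin) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy = mean(.data$correct),
      rt_correct_p10 = pctl(.data$rt[.data$correct], 0.1, min_n = 1),
      rt_correct_p50 = pctl(.data$rt[.data$correct], 0.5, min_n = 1),
      rt_correct_p90 = pctl(.data$rt[.data$correct], 0.9, min_n = 1),
      rt_error_p10 = pctl(.data$rt[!.data$correct], 0.1, min_n = 3),
      rt_error_p50 = pctl(.data$rt[!.data$correct], 0.5, min_n = 3),
      rt_error_p90 = pctl(.data$rt[!.data$correct], 0.9, min_n = 3),
      .groups = "drop"
    )
  out <- per_subject |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      n = sum(.data$n),
      dplyr::across(dplyr::starts_with(c("accuracy", "rt_")),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  out[is.na(out)] <- NA  # NaN from all-missing cells -> NA
  class(out) <- c("rleam_bins", class(out))
  out
}

bin_index <- function(n, n_bins) {
  base <- n %/% n_bins
  rem <- n %% n_bins
  rep(seq_len(n_bins), times = base + (seq_len(n_bins) <= rem))
}

pctl <- function(x, p, min_n = 1) {
  x <- x[!is.na(x)]
  if (length(x) < min_n) return(NA_real_)
  unname(stats::quantile(x, p, type = 7))
}

#' Posterior-predictive check of a fitted model
#'
#' Draws joint posterior samples of all subject-level parameters, simulates
#' the full experimental design once per draw, summarizes each simulated
#' data set with [bin_summaries()], and forms 95% credible envelopes
#' (2.5%-97.5% quantiles across draws of the subject-averaged summaries).
#'
#' @param fit an [run_sampler()] fit.
#' @param design the design to simulate (typically the one behind the data).
#' @param n_draws number of posterior draws (default 100).
#' @param seed integer seed.
#' @param observed optional trial table overlaid as the observed data.
#' @param n_bins bins passed to [bin_summaries()].
#' @return object of class `rleam_ppc`: list with `draws` (per-draw bin
#'   summaries), `envelope` (per bin and statistic: `lower`, `upper`,
#'   `median`), and `observed` (bin summaries or `NULL`).
#' @export
posterior_predict <- function(fit, design, n_draws = 100, seed = 1,
                              observed = NULL, n_bins = 10) {
  draws <- fit$draws
  n_iter <- dim(draws$theta)[1]; D <- dim(draws$theta)[2]
  S <- dim(draws$theta)[3]
  with_seed(seed, {
    pick_it <- sample(n_iter, n_draws, replace = n_draws > n_iter)
    pick_ch <- sample(D, n_draws, replace = TRUE)
    sims <- purrr::map_dfr(seq_len(n_draws), function(i) {
      th <- draws$theta[pick_it[i], pick_ch[i], , , drop = TRUE]
      th <- matrix(th, S, fit$model$n_free, dimnames = list(NULL, fit$params))
      th <- to_natural_scale(th, fit$params)
      subj <- dplyr::bind_cols(tibble::tibble(subject = seq_len(S)),
                               tibble::as_tibble(th))
      sim <- simulate_experiment(design, fit$model, subj)
      dplyr::mutate(bin_summaries(sim, n_bins = n_bins), draw = i)
    })
    stats_long <- sims |>
      tidyr::pivot_longer(-c("bin", "n", "draw"),
                          names_to = "statistic", values_to = "value")
    env <- stats_long |>
      dplyr::group_by(.data$bin, .data$statistic) |>
      dplyr::summarise(
        lower = pctl(.data$value, 0.025),
        median = pctl(.data$value, 0.5),
        upper = pctl(.data$value, 0.975),
        .groups = "drop"
      )
    obs <- if (!is.null(observed)) bin_summaries(observed, n_bins = n_bins)
    structure(list(draws = sims, envelope = env, observed = obs,
                   n_draws = n_draws), class = "rleam_ppc")
  })
}

#' @export
print.rleam_ppc <- function(x, ...) {
  cat("<rleam_ppc> ", x$n_draws, " posterior draws, ",
      length(unique(x$envelope$bin)), " bins\n", sep = "")
  invisible(x)
}

#' Align reversal-learning trials on the reversal point
#'
#' Re-indexes each block's trials relative to the trial at which the reward
#' contingencies reversed (trial 0 = first reversed trial, negative indices
#' before), and labels `choice_a`: whether the response picked the option
#' that was the high-probability option *before* the reversal. A pure
#' re-indexing — no trials are added or dropped.
#'
#' @param trials trial table from an exp3-style simulation (or real data
#'   with matching columns).
#' @param design the [make_design()] object that generated the trials; must
#'   contain reversals.
#' @return the input with `rel_trial` and `choice_a` columns added.
#' @export
reversal_align <- function(trials, design) {
  if (is.null(design$reversals)) {
    stop("design has no reversals to align on", call. = FALSE)
  }
  trials |>
    dplyr::group_by(.data$subject, .data$block) |>
    dplyr::arrange(.data$trial, .by_group = TRUE) |>
    dplyr::mutate(trial_in_block = dplyr::row_number()) |>
    dplyr::ungroup() |>
    dplyr::left_join(design$reversals, by = "block") |>
    dplyr::mutate(rel_trial = .data$trial_in_block - .data$reversal_trial,
                  choice_a = .data$choice == 1L) |>
    dplyr::select(-"trial_in_block", -"reversal_trial")
}

#' Screen subjects for above-chance accuracy
#'
#' Flags subjects for exclusion when their overall accuracy is not credibly
#' above chance. Two modes: `"cutoff"` applies the conventional fixed
#' accuracy thresholds for these paradigms (0.55 for two-alternative,
#' 0.37 for three-alternative designs, both corresponding to p < 0.05);
#' `"binomial"` runs a one-sided exact binomial test of accuracy >
#' 1/n_options at level `alpha`.
#'
#' @param trials trial table with `subject` and `correct`.
#' @param n_options options per trial (2 or 3).
#' @param method `"cutoff"` (default) or `"binomial"`.
#' @param cutoff override the default accuracy cutoff.
#' @param alpha significance level for the binomial test.
#' @return tibble: `subject`, `n`, `accuracy`, `keep`.
#' @export
exclusion_screen <- function(trials, n_options = 2,
                             method = c("cutoff", "binomial"),
                             cutoff = NULL, alpha = 0.05) {
  method <- match.arg(method)
  acc <- trials |>
    dplyr::filter(!is.na(.data$correct)) |>
    dplyr::group_by(.data$subject) |>
    dplyr::summarise(n = dplyr::n(), k = sum(.data$correct),
                     accuracy = mean(.data$correct), .groups = "drop")
  if (method == "cutoff") {
    cutoff <- cutoff %||% if (n_options == 2) 0.55 else 0.37
    acc$keep <- acc$accuracy > cutoff
  } else {
    acc$keep <- vapply(seq_len(nrow(acc)), function(i) {
      stats::binom.test(acc$k[i], acc$n[i], p = 1 / n_options,
                        alternative = "greater")$p.value < alpha
    }, logical(1))
  }
  dplyr::select(acc, -"k")
}

#' Parameter-recovery study
#'
#' Draws generating subject parameters from group distributions, simulates
#' the design, fits the model hierarchically, and reports per-parameter
#' Spearman rank correlations between generating values and posterior
#' medians of the subject-level estimates. Deterministic per seed.
#'
#' @param model an [model_spec()] object.
#' @param design an [make_design()] object.
#' @param n_subjects number of simulated subjects.
#' @param seed integer seed for generation and fitting.
#' @param group generating group distribution (tibble `param`, `mean`,
#'   `sd`); defaults to [default_group_params()] for the design.
#' @param config sampler settings.
#' @return object of class `rleam_recovery`: list with `correlations`
#'   (tibble `param`, `cor_spearman`), `scatter` (generating vs recovered
#'   per subject), and the underlying `fit`.
#' @export
recovery_study <- function(model, design, n_subjects, seed = 1,
                           group = NULL,
                           config = sampler_config()) {
  experiment <- if (design$name %in% c("exp1", "exp2", "exp3", "exp4"))
    design$name else "exp1"
  group <- group %||% default_group_params(model, experiment)
  gen <- with_seed(seed, draw_subject_params(model, group, n_subjects))
  sim <- simulate_experiment(design, model, gen, seed = seed + 1L)
  fit <- run_sampler(sim, model, config = config, seed = seed + 2L)
  med <- apply(fit$draws$theta, c(3, 4), stats::median)  # S x P, sampling scale
  colnames(med) <- fit$params
  med <- to_natural_scale(med, fit$params)
  scatter <- purrr::map_dfr(fit$params, function(p) {
    tibble::tibble(param = p, subject = gen$subject,
                   generating = gen[[p]], recovered = med[, p])
  })
  cors <- scatter |>
    dplyr::group_by(.data$param) |>
    dplyr::summarise(cor_spearman = stats::cor(.data$generating, .data$recovered,
                                               method = "spearman"),
                     .groups = "drop")
  structure(list(correlations = cors, scatter = scatter, fit = fit,
                 generating = gen), class = "rleam_recovery")
}

#' @export
print.rleam_recovery <- function(x, ...) {
  cat("<rleam_recovery> ", x$fit$model$architecture, ", ",
      nrow(x$generating), " subjects\n", sep = "")
  print(x$correlations)
  invisible(x)
}
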