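#' Delta-rule update of a Q-value vector
#'
#' Applies one step of the delta rule to the chosen option:
#' `Q_chosen <- Q_chosen + alpha * (reward - Q_chosen)`. Only the chosen
#' option's value changes; the increment is the learning rate times the
#' reward prediction error.
#'
#' @param q numeric vector of current Q-values for one stimulus set.
#' @param choice index of the chosen option (1-based).
#' @param reward observed outcome, typically coded on `[0, 1]`.
#' @param alpha learning rate in `[0, 1]`.
#' @return the updated Q-value vector.
#' @examples
#' update_q(c(0.5, 0.2), choice = 1, reward = 1, alpha = 0.1)
#' @export
update_q <- function(q, choice, reward, alpha) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(choice) || choice < 1 || choice > length(q) ||
      choice != round(choice)) {
    stop("`choice` must index into `q`", call. = FALSE)
  }
  q[choice] <- q[choice] + alpha * (reward - q[choice])
  q
}

#' Per-trial Q-values along a sequence of trials
#'
#' Replays the delta rule over a trial table and returns, for every trial,
#' the Q-values *as they stood when the trial was presented* (before that
#' trial's feedback). These pre-feedback values are what drive the decision
#' process on the trial, so they are the values the trial likelihoods use.
#' Stimulus sets are learned independently; learning uses the `outcome`
#' column (the probabilistic result shown to the learner) rather than the
#' earned reward, so late trials with forfeited rewards still teach.
#'
#' @param trials a data frame with columns `set_id`, `choice`, `outcome`,
#'   and `trial` (within-subject trial counter); one subject's data, sorted
#'   by `trial`.
#' @param alpha learning rate in `[0, 1]`.
#' @param n_options number of options per set (2 or 3).
#' @param q0 initial Q-value, shared by all options (default 0; the fits
#'   behind the default parameter tables kept it fixed there).
#' @return a tibble with one row per trial: `set_id`, `trial`, and `q1`,
#'   `q2` (and `q3` for three-option sets) holding the pre-feedback values.
#' @export
q_trajectory <- function(trials, alpha, n_options = 2, q0 = 0) {
  if (alpha < 0 || alpha > 1) stop("`alpha` must lie in [0, 1]", call. = FALSE)
  if (is.unsorted(trials$trial, strictly = FALSE)) {
    stop("`trials` must be sorted by `trial`", call. = FALSE)
  }
  sets <- unique(trials$set_id)
  qs <- matrix(q0, length(sets), n_options, dimnames = list(sets, NULL))
  n <- nrow(trials)
  out <- matrix(NA_real_, n, n_options)
  set_idx <- match(trials$set_id, sets)
  choice <- trials$choice
  outcome <- trials$outcome
  for (t in seq_len(n)) {
    k <- set_idx[t]
    out[t, ] <- qs[k, ]
    ch <- choice[t]
    if (!is.na(ch)) {
      qs[k, ch] <- qs[k, ch] + alpha * (outcome[t] - qs[k, ch])
    }
  }
  colnames(out) <- paste0("q", seq_len(n_options))
  dplyr::bind_cols(
    tibble::tibble(set_id = trials$set_id, trial = trials$trial),
    tibble::as_tibble(out)
  )
}

#' Soft-max choice probabilities
#'
#' The baseline (RT-free) choice rule: option i is chosen with probability
#' proportional to `exp(beta * Q_i)`, with inverse temperature `beta`
#' controlling exploitation. Computed via log-sum-exp so that extreme
#' `beta * Q` values do not overflow. In the two-option case this is the
#' logistic function of `beta * (Q1 - Q2)`.
#'
#' @param q numeric vector of Q-values.
#' @param beta inverse temperature (>= 0).
#' @return vector of choice probabilities summing to 1.
#' @examples
#' softmax_probs(c(0.5, 0), beta = 2.82)
#' @export
softmax_probs <- function(q, beta) {
  if (beta < 0) stop("`beta` must be non-negative", call. = FALSE)
  x <- beta * q
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

#' Probit-scale transform of the learning rate
#'
#' Learning rates are estimated on an unconstrained probit scale; these
#' helpers map between the two: `alpha = pnorm(alpha_probit)`.
#'
#' @param alpha learning rate in (0, 1).
#' @param alpha_probit unconstrained probit-scale value.
#' @export
alpha_to_probit <- function(alpha) stats::qnorm(alpha)

#' @rdname alpha_to_probit
#' @export
probit_to_alpha <- function(alpha_probit) stats::pnorm(alpha_probit)
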