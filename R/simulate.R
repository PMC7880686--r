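#' Simulate an instrumental-learning experiment closed-loop
#'
#' Runs the decide-feedback-learn loop of a reinforcement-learning
#' evidence-accumulation model over a task design: on every trial the
#' current (pre-feedback) Q-values set the accumulator drift rates, a
#' response and RT are drawn from the decision architecture, the chosen
#' option's probabilistic outcome is drawn from its current reward
#' probability (reversal-aware), the deadline rule converts the outcome
#' into an earned reward (late responses forfeit it), and the delta rule
#' updates the chosen option's Q-value from the *outcome* — late trials
#' still teach. Races whose accumulators all stall (possible under negative
#' drifts) are recorded with missing RT and `too_late = TRUE` and do not
#' update values.
#'
#' @param design an [make_design()] object.
#' @param model an [model_spec()] object; its option count must match the
#'   design.
#' @param params subject parameters on the natural scale: a named vector
#'   (shared by all subjects), or a tibble with a `subject` column and one
#'   column per model parameter (e.g. from [draw_subject_params()]).
#' @param n_subjects number of subjects when `params` is a named vector.
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @param q0 initial Q-value for every option.
#' @param keep_q also return the pre-feedback Q-values that drove each
#'   decision (columns `q1`, `q2`, ...), for closed-loop verification.
#' @return a tibble with one row per trial: `subject`, `block`, `trial`,
#'   `set_id`, `cue`, `choice`, `rt`, `outcome`, `reward`, `too_late`, plus
#'   a `correct` flag (chose the option with the currently highest reward
#'   probability).
#' @examples
#' d <- make_design("exp1", seed = 1)
#' m <- model_spec("rl_ard")
#' p <- c(alpha = 0.13, a = 2.14, t0 = 0.11, V0 = 2.46, wd = 2.25, ws = 0.36)
#' sim <- simulate_experiment(d, m, p, n_subjects = 2, seed = 1)
#' @export
simulate_experiment <- function(design, model, params, n_subjects = 1,
                                seed = NULL, q0 = 0, keep_q = FALSE) {
  if (model$n_options != design$n_options) {
    stop("model expects ", model$n_options, " options but design `", design$name,
         "` has ", design$n_options, call. = FALSE)
  }
  if (is.data.frame(params)) {
    missing <- setdiff(model$params, names(params))
    if (length(missing)) stop("params lacks: ", paste(missing, collapse = ", "),
                              call. = FALSE)
    subj_tab <- params
  } else {
    stopifnot(all(model$params %in% names(params)))
    subj_tab <- dplyr::bind_cols(
      tibble::tibble(subject = seq_len(n_subjects)),
      tibble::as_tibble(as.list(params[model$params]))[rep(1, n_subjects), ]
    )
  }
  with_seed(seed, {
    purrr::map_dfr(seq_len(nrow(subj_tab)), function(s) {
      pars <- as.list(subj_tab[s, setdiff(names(subj_tab), "subject")])
      sim_one_subject(design, model, pars, subject = subj_tab$subject[s],
                      q0 = q0, keep_q = keep_q)
    })
  })
}

sim_one_subject <- function(design, model, pars, subject, q0 = 0,
                            keep_q = FALSE) {
  J <- design$n_options
  tr <- design$trials
  n <- nrow(tr)
  sets <- design$sets
  set_ids <- sets$set_id
  pmat_base <- as.matrix(sets[, paste0("p", seq_len(J))])
  Q <- matrix(q0, length(set_ids), J)
  rev_tab <- design$reversals
  arch <- model$architecture
  vary <- model$condition_vary

  choice <- integer(n); rt <- numeric(n); outcome <- integer(n)
  reward <- integer(n); too_late <- logical(n); correct <- logical(n)
  qpre <- if (keep_q) matrix(NA_real_, n, J) else NULL

  for (t in seq_len(n)) {
    k <- match(tr$set_id[t], set_ids)
    q <- Q[k, ]
    if (keep_q) qpre[t, ] <- q
    cue <- tr$cue[t]
    eff <- if (length(vary)) {
      map_conditions(unlist(pars), vary, cue)
    } else c(unlist(pars), v_mult = 1)
    gp <- function(nm) if (nm %in% names(eff)) unname(eff[[nm]]) else NA_real_
    a <- gp("a")
    vm <- gp("v_mult")
    st0 <- if (model$st0) gp("st0") else 0

    res <- switch(arch,
      softmax = {
        pr <- softmax_probs(q, gp("beta"))
        list(choice = sample.int(J, 1, prob = pr), rt = NA_real_)
      },
      rl_ddm = {
        v <- ddm_drift(q[1] - q[2], gp("w"),
                       vmax = if (model$nonlinear) gp("vmax") else NULL) * vm
        d <- rddm(1, v, a, gp("t0"),
                  sv = if (model$sv) gp("sv") else 0,
                  sz = if (model$sz) gp("sz") else 0,
                  st0 = st0, grid_n = 1024)
        list(choice = d$choice, rt = d$rt)
      },
      rl_rd = {
        v <- drift_rd(q, gp("V0"), gp("w")) * vm
        d <- rrace(1, v, a, gp("t0"), st0)
        list(choice = d$choice, rt = d$rt)
      },
      rl_lard = ,
      rl_ard = {
        ws <- if (arch == "rl_ard") gp("ws") else 0
        v <- drift_ard2(q, gp("V0"), gp("wd"), ws) * vm
        d <- rrace(1, v, a, gp("t0"), st0)
        list(choice = d$choice, rt = d$rt)
      },
      rl_ard_winall = {
        v <- drift_ard_multi(q, gp("V0"), gp("wd"), gp("ws")) * vm
        d <- rrace(1, v, a, gp("t0"), st0)
        list(choice = d$choice, rt = d$rt)
      }
    )
    ch <- res$choice
    probs <- if (!is.null(rev_tab)) {
      rv <- rev_tab$reversal_trial[rev_tab$block == tr$block[t]]
      if (length(rv) == 1 && tr$trial_in_block[t] >= rv) rev(pmat_base[k, ])
      else pmat_base[k, ]
    } else pmat_base[k, ]

    if (is.na(ch)) {  # stalled race: no response, nothing to learn from
      choice[t] <- NA_integer_; rt[t] <- NA_real_
      outcome[t] <- NA_integer_; reward[t] <- 0L
      too_late[t] <- TRUE; correct[t] <- NA
      next
    }
    choice[t] <- ch
    rt[t] <- res$rt
    out_t <- rbinom(1, 1, probs[ch])
    late <- !is.na(res$rt) && res$rt > tr$deadline[t]
    outcome[t] <- out_t
    too_late[t] <- late
    reward[t] <- if (late) 0L else out_t
    correct[t] <- probs[ch] == max(probs)
    Q[k, ch] <- Q[k, ch] + gp("alpha") * (out_t - Q[k, ch])
  }

  out <- tibble::tibble(subject = subject, block = tr$block, trial = tr$trial,
                        set_id = tr$set_id, cue = tr$cue, choice = choice,
                        rt = rt, outcome = outcome, reward = reward,
                        too_late = too_late, correct = correct)
  if (keep_q) {
    colnames(qpre) <- paste0("q", seq_len(J))
    out <- dplyr::bind_cols(out, tibble::as_tibble(qpre))
  }
  out
}
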