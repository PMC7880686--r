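#' Instantiate an instrumental-learning task design
#'
#' Builds the trial-by-trial structure of one of four probabilistic
#' instrumental-learning paradigms (or a custom one):
#'
#' * `exp1` — baseline two-alternative learning: 4 stimulus pairs with
#'   reward probabilities 0.8/0.2, 0.7/0.3, 0.65/0.35, 0.6/0.4, each shown
#'   52 times in one block of 208 uniformly interleaved trials; response
#'   deadline 2 s (a late response forfeits the earned reward but the
#'   outcome is still shown).
#' * `exp2` — speed-accuracy cueing: 3 pairs (0.8/0.2, 0.7/0.3, 0.6/0.4),
#'   324 trials over 3 blocks, each trial preceded by a SPD or ACC cue
#'   (randomly interleaved, balanced within block); the speed deadline is
#'   0.6 s, accuracy trials keep the 2 s deadline.
#' * `exp3` — reversal learning: 4 blocks of 128 trials, two pairs
#'   (0.8/0.2, 0.7/0.3) per block; at one trial per block, drawn uniformly
#'   from block trials 61-68, the reward probabilities within each pair
#'   swap for the rest of the block.
#' * `exp4` — three-alternative choice: 3 blocks of 144 trials, four
#'   triplets (0.8/0.25/0.25, 0.7/0.3/0.3, 0.7/0.15/0.15, 0.6/0.2/0.2)
#'   crossing difficulty with reward magnitude, 36 presentations per
#'   triplet per block.
#'
#' Option 1 of every set is the (pre-reversal) high-probability option, so
#' "correct" means choosing option 1 under the current contingency.
#'
#' @param name design name (`"exp1"`, `"exp2"`, `"exp3"`, `"exp4"`).
#' @param seed integer seed controlling interleaving, cue order and
#'   reversal draws; the caller's RNG state is left untouched.
#' @param deadline response deadline in seconds for un-cued / ACC trials.
#' @return an object of class `rleam_design`: a list with `name`,
#'   `n_options`, `sets` (tibble of per-option reward probabilities),
#'   `trials` (tibble: `block`, `trial`, `trial_in_block`, `set_id`, `cue`,
#'   `deadline`), and `reversals` (tibble or `NULL`).
#' @export
make_design <- function(name = c("exp1", "exp2", "exp3", "exp4"), seed = NULL,
                        deadline = 2) {
  name <- match.arg(name)
  with_seed(seed, {
    switch(name,
      exp1 = {
        sets <- tibble::tibble(set_id = paste0("pair", 1:4),
                               p1 = c(0.80, 0.70, 0.65, 0.60),
                               p2 = c(0.20, 0.30, 0.35, 0.40))
        order <- sample(rep(sets$set_id, each = 52))
        trials <- tibble::tibble(block = 1L, trial = seq_along(order),
                                 trial_in_block = seq_along(order),
                                 set_id = order, cue = "none",
                                 deadline = deadline)
        new_design(name, 2L, sets, trials, NULL)
      },
      exp2 = {
        sets <- tibble::tibble(set_id = paste0("pair", 1:3),
                               p1 = c(0.80, 0.70, 0.60),
                               p2 = c(0.20, 0.30, 0.40))
        per_block <- 108L
        trials <- purrr::map_dfr(1:3, function(b) {
          ord <- sample(rep(sets$set_id, each = per_block / 3))
          cues <- sample(rep(c("SPD", "ACC"), each = per_block / 2))
          tibble::tibble(block = b, trial_in_block = seq_len(per_block),
                         set_id = ord, cue = cues,
                         deadline = ifelse(cues == "SPD", 0.6, deadline))
        })
        trials$trial <- seq_len(nrow(trials))
        new_design(name, 2L, sets, trials[, c("block", "trial", "trial_in_block",
                                              "set_id", "cue", "deadline")], NULL)
      },
      exp3 = {
        sets <- tibble::tibble(set_id = paste0("pair", 1:2),
                               p1 = c(0.80, 0.70),
                               p2 = c(0.20, 0.30))
        trials <- purrr::map_dfr(1:4, function(b) {
          ord <- sample(rep(sets$set_id, each = 64))
          tibble::tibble(block = b, trial_in_block = 1:128, set_id = ord,
                         cue = "none", deadline = deadline)
        })
        trials$trial <- seq_len(nrow(trials))
        reversals <- tibble::tibble(block = 1:4,
                                    reversal_trial = sample(61:68, 4, replace = TRUE))
        new_design(name, 2L, sets, trials[, c("block", "trial", "trial_in_block",
                                              "set_id", "cue", "deadline")], reversals)
      },
      exp4 = {
        sets <- tibble::tibble(set_id = paste0("triplet", 1:4),
                               p1 = c(0.80, 0.70, 0.70, 0.60),
                               p2 = c(0.25, 0.30, 0.15, 0.20),
                               p3 = c(0.25, 0.30, 0.15, 0.20))
        trials <- purrr::map_dfr(1:3, function(b) {
          ord <- sample(rep(sets$set_id, each = 36))
          tibble::tibble(block = b, trial_in_block = 1:144, set_id = ord,
                         cue = "none", deadline = deadline)
        })
        trials$trial <- seq_len(nrow(trials))
        new_design(name, 3L, sets, trials[, c("block", "trial", "trial_in_block",
                                              "set_id", "cue", "deadline")], NULL)
      }
    )
  })
}

new_design <- function(name, n_options, sets, trials, reversals) {
  structure(list(name = name, n_options = n_options, sets = sets,
                 trials = trials, reversals = reversals),
            class = "rleam_design")
}

#' @export
print.rleam_design <- function(x, ...) {
  cat("<rleam_design> ", x$name, ": ", nrow(x$trials), " trials, ",
      nrow(x$sets), " stimulus sets, ", x$n_options, " options\n", sep = "")
  invisible(x)
}

#' Reward probabilities in effect at a given trial
#'
#' Applies the design's reversal rule: from the block's drawn reversal trial
#' onward the per-option reward probabilities within each set are swapped
#' (e.g. a 0.8/0.2 pair becomes 0.2/0.8), so each probability vector is
#' reversed exactly once per block. Designs without reversals return the
#' base probabilities unchanged; swapping twice restores the original
#' schedule.
#'
#' @param design an [make_design()] object.
#' @param block block number.
#' @param trial_in_block within-block trial index.
#' @return tibble of per-set reward probabilities effective at that trial.
#' @export
reversal_apply <- function(design, block, trial_in_block) {
  sets <- design$sets
  if (is.null(design$reversals)) return(sets)
  rev_trial <- design$reversals$reversal_trial[design$reversals$block == block]
  if (length(rev_trial) == 1 && trial_in_block >= rev_trial) {
    sets <- swap_reward_probs(sets)
  }
  sets
}

# reverse each set's option probabilities (an involution)
swap_reward_probs <- function(sets) {
  pcols <- grep("^p[0-9]+$", names(sets), value = TRUE)
  sets[pcols] <- sets[rev(pcols)]
  sets
}

#' Serialize a design to YAML
#'
#' @param design an [make_design()] object.
#' @param path file path; the companion `design_from_yaml()` restores it.
#' @export
design_to_yaml <- function(design, path) {
  yaml::write_yaml(list(design = list(
    name = design$name,
    n_options = design$n_options,
    sets = lapply(seq_len(nrow(design$sets)), function(i) as.list(design$sets[i, ])),
    trials = lapply(design$trials, function(col) if (is.numeric(col)) col else as.character(col)),
    reversals = if (is.null(design$reversals)) NULL else as.list(design$reversals)
  )), path)
  invisible(path)
}

#' @rdname design_to_yaml
#' @export
design_from_yaml <- function(path) {
  d <- yaml::read_yaml(path)$design
  new_design(d$name, as.integer(d$n_options),
             dplyr::bind_rows(lapply(d$sets, tibble::as_tibble)),
             tibble::as_tibble(d$trials),
             if (is.null(d$reversals)) NULL else tibble::as_tibble(d$reversals))
}
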