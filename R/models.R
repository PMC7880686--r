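#' Specify a reinforcement-learning evidence-accumulation model
#'
#' A model spec bundles the decision architecture, its free parameters, any
#' between-trial variability components, and an optional condition map that
#' lets chosen parameters differ proportionally between cue conditions
#' (speed vs accuracy emphasis). The spec defines the trial likelihood used
#' by [log_likelihood_subject()] and [run_sampler()], and the trial
#' generator used by [simulate_experiment()].
#'
#' Baseline architectures and their free parameters:
#' * `softmax`: `alpha, beta` — choice-only baseline, no RTs.
#' * `rl_ddm`: `alpha, a, t0, w` — diffusion between boundaries `+/- a`
#'   driven by the Q-value difference.
#' * `rl_rd`: `alpha, a, t0, V0, w` — independent racing diffusion.
#' * `rl_lard`: `alpha, a, t0, V0, wd` — advantage race, difference term only.
#' * `rl_ard`: `alpha, a, t0, V0, wd, ws` — full advantage race.
#' * `rl_ard_winall`: same six parameters, three options, six directional
#'   accumulators with the Win-All stopping rule.
#'
#' DDM variability variants add `vmax` (non-linear value link), `sv`
#' (proportional drift variability), `sz` (uniform start-point range,
#' relative to the full boundary separation), and `st0` (uniform
#' non-decision-time range).
#'
#' @param architecture one of `"softmax"`, `"rl_ddm"`, `"rl_rd"`,
#'   `"rl_lard"`, `"rl_ard"`, `"rl_ard_winall"`.
#' @param nonlinear use the saturating value link (adds `vmax`; DDM only).
#' @param sv,sz,st0 include the corresponding between-trial variability as a
#'   free parameter (DDM: all three; race models: `st0` only).
#' @param condition_vary character subset of `c("a", "V0", "v")`: parameters
#'   that get a proportional speed-condition multiplier `m_<par>`, so that
#'   e.g. `a_spd = (1 + m_a) * a_acc`.
#' @return an object of class `rleam_model`.
#' @examples
#' model_spec("rl_ard")$n_free   # 6
#' @export
model_spec <- function(architecture = c("rl_ard", "rl_lard", "rl_rd", "rl_ddm",
                                        "rl_ard_winall", "softmax"),
                       nonlinear = FALSE, sv = FALSE, sz = FALSE, st0 = FALSE,
                       condition_vary = NULL) {
  architecture <- match.arg(architecture)
  params <- switch(architecture,
    softmax       = c("alpha", "beta"),
    rl_ddm        = c("alpha", "a", "t0", "w"),
    rl_rd         = c("alpha", "a", "t0", "V0", "w"),
    rl_lard       = c("alpha", "a", "t0", "V0", "wd"),
    rl_ard        = c("alpha", "a", "t0", "V0", "wd", "ws"),
    rl_ard_winall = c("alpha", "a", "t0", "V0", "wd", "ws")
  )
  if (nonlinear) {
    if (architecture != "rl_ddm") stop("non-linear link is a DDM variant", call. = FALSE)
    params <- c(params, "vmax")
  }
  if (sv || sz) {
    if (architecture != "rl_ddm") stop("sv/sz are DDM variants", call. = FALSE)
    if (sv) params <- c(params, "sv")
    if (sz) params <- c(params, "sz")
  }
  if (st0) {
    if (architecture == "softmax") stop("softmax has no non-decision time", call. = FALSE)
    params <- c(params, "st0")
  }
  if (!is.null(condition_vary)) {
    bad <- setdiff(condition_vary, c("a", "V0", "v"))
    if (length(bad)) stop("unknown condition parameters: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    if ("V0" %in% condition_vary && !"V0" %in% params)
      stop("model has no V0 parameter to vary", call. = FALSE)
    params <- c(params, paste0("m_", condition_vary))
  }
  structure(
    list(architecture = architecture,
         n_options = if (architecture == "rl_ard_winall") 3L else 2L,
         n_accumulators = switch(architecture,
           rl_ard_winall = 6L, rl_ddm = 1L, softmax = 0L, 2L),
         params = params,
         n_free = length(params),
         nonlinear = nonlinear,
         sv = sv, sz = sz, st0 = st0,
         condition_vary = condition_vary %||% character(0)),
    class = "rleam_model"
  )
}

#' @export
print.rleam_model <- function(x, ...) {
  cat("<rleam_model> ", x$architecture, "\n", sep = "")
  cat("  options: ", x$n_options, ", accumulators: ", x$n_accumulators, "\n", sep = "")
  cat("  free parameters (", x$n_free, "): ", paste(x$params, collapse = ", "),
      "\n", sep = "")
  if (length(x$condition_vary))
    cat("  speed-condition multipliers on: ",
        paste(x$condition_vary, collapse = ", "), "\n", sep = "")
  invisible(x)
}

# natural-scale support of each parameter; alpha is sampled on probit scale
param_bounds <- function(param) {
  lb <- c(alpha = 0, a = 0, t0 = 0.025, V0 = 0, w = -Inf, wd = -Inf, ws = -Inf,
          beta = 0, vmax = 0, sv = 0, sz = 0, st0 = 0)
  ub <- c(alpha = 1, a = Inf, t0 = 1, V0 = Inf, w = Inf, wd = Inf, ws = Inf,
          beta = Inf, vmax = Inf, sv = Inf, sz = 0.5, st0 = Inf)
  base <- sub("^m_.*", "m", param)
  out <- cbind(lb = ifelse(base == "m", -1, unname(lb[param])),
               ub = ifelse(base == "m", Inf, unname(ub[param])))
  rownames(out) <- param
  out
}

#' Proportional condition scaling of decision parameters
#'
#' Under speed emphasis, selected parameters are scaled proportionally from
#' their accuracy-condition values: `x_spd = (1 + m_x) * x_acc`, with the
#' multiplier constrained above -1 so scaled values stay positive. Accuracy
#' trials use the base values unchanged. The drift multiplier `m_v` is
#' returned as `v_mult`, to be applied to the final accumulation rates.
#'
#' @param params named numeric vector of base (accuracy-condition) parameter
#'   values, including any `m_a`, `m_V0`, `m_v` multipliers.
#' @param condition_vary which parameters vary (`"a"`, `"V0"`, `"v"`).
#' @param cue `"SPD"` or `"ACC"` (anything else counts as accuracy).
#' @return the effective parameter vector for the trial, with an added
#'   `v_mult` element (1 on accuracy trials).
#' @examples
#' map_conditions(c(a = 1.82, m_a = -0.4286), "a", "SPD")[["a"]]  # ~1.04
#' @export
map_conditions <- function(params, condition_vary, cue) {
  out <- params
  out[["v_mult"]] <- 1
  if (identical(cue, "SPD")) {
    for (p in condition_vary) {
      m <- params[[paste0("m_", p)]]
      if (m <= -1) stop("condition multiplier must exceed -1", call. = FALSE)
      if (p == "v") out[["v_mult"]] <- 1 + m
      else out[[p]] <- (1 + m) * params[[p]]
    }
  }
  out
}

#' Canonical group-level parameter values per paradigm
#'
#' Across-subject means and SDs used as the package's reference description
#' of typical human performance in these paradigms (and as the generating
#' distributions for simulation and recovery studies). Values are on the
#' natural scale; subject parameters are drawn from normals truncated to
#' each parameter's support.
#'
#' @param model an [model_spec()] object.
#' @param experiment paradigm the values describe: `"exp1"` (baseline
#'   two-alternative learning), `"exp3"` (reversal learning) or `"exp4"`
#'   (three-alternative). `"exp2"` uses the exp1 values for base parameters.
#' @return tibble with columns `param`, `mean`, `sd`.
#' @export
default_group_params <- function(model, experiment = "exp1") {
  arch <- model$architecture
  key <- paste(arch, experiment, sep = ".")
  tab <- list(
    "rl_ddm.exp1"  = c(alpha = 0.14, a = 1.48, t0 = 0.30, w = 3.21),
    "rl_rd.exp1"   = c(alpha = 0.12, a = 2.16, t0 = 0.10, V0 = 1.92, w = 3.09),
    "rl_lard.exp1" = c(alpha = 0.13, a = 2.05, t0 = 0.12, V0 = 2.48, wd = 2.36),
    "rl_ard.exp1"  = c(alpha = 0.13, a = 2.14, t0 = 0.11, V0 = 2.46, wd = 2.25, ws = 0.36),
    "softmax.exp3" = c(alpha = 0.40, beta = 2.82),
    "rl_ddm.exp3"  = c(alpha = 0.38, a = 1.37, t0 = 0.24, w = 2.72),
    "rl_ard.exp3"  = c(alpha = 0.35, a = 1.48, t0 = 0.13, V0 = 1.86, wd = 1.52, ws = 0.23),
    "rl_ard_winall.exp4" = c(alpha = 0.10, a = 1.6, t0 = 0.07, V0 = 1.14, wd = 1.6, ws = 0.15)
  )
  sds <- list(
    "rl_ddm.exp1"  = c(alpha = 0.11, a = 0.19, t0 = 0.06, w = 1.11),
    "rl_rd.exp1"   = c(alpha = 0.08, a = 0.27, t0 = 0.04, V0 = 0.42, w = 1.32),
    "rl_lard.exp1" = c(alpha = 0.12, a = 0.24, t0 = 0.05, V0 = 0.43, wd = 0.95),
    "rl_ard.exp1"  = c(alpha = 0.11, a = 0.26, t0 = 0.04, V0 = 0.59, wd = 0.78, ws = 0.79),
    "softmax.exp3" = c(alpha = 0.14, beta = 1.1),
    "rl_ddm.exp3"  = c(alpha = 0.14, a = 0.24, t0 = 0.07, w = 1.16),
    "rl_ard.exp3"  = c(alpha = 0.15, a = 0.34, t0 = 0.08, V0 = 0.51, wd = 0.63, ws = 0.25),
    "rl_ard_winall.exp4" = c(alpha = 0.04, a = 0.33, t0 = 0.05, V0 = 0.22, wd = 0.36, ws = 0.26)
  )
  if (experiment == "exp2") key <- paste(arch, "exp1", sep = ".")
  if (is.null(tab[[key]])) {
    # fall back to the paradigm the architecture has canonical values for
    fallback <- if (arch == "softmax") "exp3" else "exp1"
    key <- paste(arch, fallback, sep = ".")
  }
  if (is.null(tab[[key]])) {
    stop("no canonical values for ", arch, " at ", experiment, call. = FALSE)
  }
  m <- tab[[key]]; s <- sds[[key]]
  base <- tibble::tibble(param = names(m), mean = unname(m), sd = unname(s))
  extra <- setdiff(model$params, base$param)
  if (length(extra)) {
    # variability / multiplier parameters: modest defaults on their scale
    em <- vapply(extra, function(p) switch(sub("_.*", "", p),
      vmax = 2.8, sv = 0.3, sz = 0.1, st0 = 0.1, m = -0.2), numeric(1))
    es <- vapply(extra, function(p) switch(sub("_.*", "", p),
      vmax = 0.7, sv = 0.1, sz = 0.05, st0 = 0.05, m = 0.1), numeric(1))
    base <- dplyr::bind_rows(base,
      tibble::tibble(param = extra, mean = unname(em), sd = unname(es)))
  }
  base[match(model$params, base$param), ]
}

#' Draw subject-level parameters from group distributions
#'
#' Subject parameters are independent normals truncated to each parameter's
#' support (learning rates to (0, 1), thresholds to (0, Inf), non-decision
#' times to (0.025, 1), and so on).
#'
#' @param model an [model_spec()] object.
#' @param group tibble with `param`, `mean`, `sd` (see
#'   [default_group_params()]).
#' @param n_subjects number of subjects.
#' @return tibble with a `subject` column and one column per parameter.
#' @export
draw_subject_params <- function(model, group, n_subjects) {
  stopifnot(setequal(group$param, model$params))
  b <- param_bounds(group$param)
  draws <- lapply(seq_len(nrow(group)), function(i) {
    rtnorm(n_subjects, group$mean[i], group$sd[i], b[i, "lb"], b[i, "ub"])
  })
  names(draws) <- group$param
  dplyr::bind_cols(tibble::tibble(subject = seq_len(n_subjects)),
                   tibble::as_tibble(draws))
}
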