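#' Plot learning-curve bin summaries
#'
#' Accuracy over trial bins alongside correct/error RT percentiles
#' (10th/50th/90th), the standard at-a-glance view of learning dynamics in
#' these paradigms.
#'
#' @param object an `rleam_bins` tibble from [bin_summaries()].
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot rleam_bins
#' @export
autoplot.rleam_bins <- function(object, ...) {
  long <- object |>
    tidyr::pivot_longer(dplyr::starts_with("rt_"),
                        names_to = c("response", "percentile"),
                        names_pattern = "rt_(correct|error)_p(\\d+)",
                        values_to = "rt")
  acc <- dplyr::distinct(long, .data$bin, .data$accuracy) |>
    dplyr::mutate(panel = "accuracy", value = .data$accuracy)
  rts <- long |>
    dplyr::mutate(panel = paste0("RT (", .data$response, ")"),
                  value = .data$rt)
  ggplot2::ggplot(rts, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$percentile,
                                    linetype = .data$percentile),
                       na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE, size = 0.8) +
    ggplot2::geom_line(data = acc, colour = "steelblue") +
    ggplot2::geom_point(data = acc, colour = "steelblue", size = 0.8) +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "trial bin", y = NULL, linetype = "percentile") +
    ggplot2::theme_minimal()
}

#' Plot a posterior-predictive check
#'
#' Credible envelopes of the model-implied bin summaries, with the observed
#' summaries overlaid when available.
#'
#' @param object an `rleam_ppc` from [posterior_predict()].
#' @param statistics which summary statistics to show.
#' @param ... unused.
#' @method autoplot rleam_ppc
#' @export
autoplot.rleam_ppc <- function(object,
                               statistics = c("accuracy", "rt_correct_p10",
                                              "rt_correct_p50", "rt_correct_p90"),
                               ...) {
  env <- dplyr::filter(object$envelope, .data$statistic %in% statistics)
  p <- ggplot2::ggplot(env, ggplot2::aes(x = .data$bin)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$median), colour = "steelblue") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = "trial bin", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(object$observed)) {
    obs <- object$observed |>
      tidyr::pivot_longer(-c("bin", "n"), names_to = "statistic",
                          values_to = "value") |>
      dplyr::filter(.data$statistic %in% statistics)
    p <- p + ggplot2::geom_point(data = obs, ggplot2::aes(y = .data$value),
                                 na.rm = TRUE) +
      ggplot2::geom_line(data = obs, ggplot2::aes(y = .data$value),
                         na.rm = TRUE)
  }
  p
}

#' Plot parameter recovery
#'
#' Generating against recovered subject-level parameter values, one panel
#' per parameter, with rank correlations in the panel labels.
#'
#' @param object an `rleam_recovery` from [recovery_study()].
#' @param ... unused.
#' @method autoplot rleam_recovery
#' @export
autoplot.rleam_recovery <- function(object, ...) {
  lab <- object$correlations |>
    dplyr::mutate(label = sprintf("%s (rho = %.2f)", .data$param,
                                  .data$cor_spearman))
  dat <- dplyr::left_join(object$scatter, lab, by = "param")
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$generating, y = .data$recovered)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~label, scales = "free") +
    ggplot2::labs(x = "generating value", y = "posterior median") +
    ggplot2::theme_minimal()
}

#' Plot posterior chain traces of group-level parameters
#'
#' @param object an `rleam_fit`.
#' @param ... unused.
#' @method autoplot rleam_fit
#' @export
autoplot.rleam_fit <- function(object, ...) {
  arr <- group_draw_array(object$draws, object$params)
  dn <- dimnames(arr)[[3]]
  dat <- purrr::map_dfr(seq_along(dn), function(p) {
    m <- arr[, , p]
    tibble::tibble(iteration = rep(seq_len(nrow(m)), ncol(m)),
                   chain = factor(rep(seq_len(ncol(m)), each = nrow(m))),
                   term = dn[p], value = as.vector(m))
  })
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$iteration, y = .data$value,
                                    colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2, show.legend = FALSE) +
    ggplot2::facet_wrap(~term, scales = "free_y") +
    ggplot2::labs(x = "iteration", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
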