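#' Read and write trial tables
#'
#' The on-disk interchange format is a UTF-8 comma-delimited file with
#' header `subject,block,trial,set_id,cue,choice,rt,outcome,reward,too_late`
#' (RT in seconds, missing RT as an empty field). Extra columns such as
#' `correct` survive a round trip.
#'
#' @param path file path.
#' @param trials trial tibble (see [simulate_experiment()]).
#' @return `read_trials()` returns a tibble sorted by subject and trial.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  req <- c("subject", "block", "trial", "set_id", "cue", "choice", "rt",
           "outcome", "reward", "too_late")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("trial file lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  df$too_late <- as.logical(df$too_late)
  if ("correct" %in% names(df)) df$correct <- as.logical(df$correct)
  tibble::as_tibble(df) |>
    dplyr::arrange(.data$subject, .data$trial)
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read and write model parameter files
#'
#' Named parameter values (natural scale) serialized as a flat YAML map.
#'
#' @param params named numeric vector or one-row data frame.
#' @param path file path.
#' @export
params_to_yaml <- function(params, path) {
  if (is.data.frame(params)) params <- unlist(params[1, , drop = TRUE])
  yaml::write_yaml(as.list(params), path)
  invisible(path)
}

#' @rdname params_to_yaml
#' @export
params_from_yaml <- function(path) {
  unlist(yaml::read_yaml(path))
}
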