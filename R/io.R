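#' Read and write trial CSV files
#'
#' The on-disk trial format is a UTF-8 CSV with header columns
#' `subject_id, group, trial_index, block, opponent, choice,
#' opponent_choice, reward`; choices are spelled `"swerve"` /
#' `"go_straight"` and opponents `"HCO"` / `"LCO"`. Foreign exports with
#' different column names can be adapted via `col_map`.
#'
#' Rows with a missing choice (e.g. lapses in a timed response window) are
#' dropped and counted; the count is reported in a message and attached as
#' the `n_dropped` attribute. When a payoff matrix is supplied (or found as
#' an attribute), the reward column is cross-checked against it and
#' mismatching rows raise an error.
#'
#' @param path CSV file path.
#' @param payoff Optional [payoff_matrix()] for reward validation.
#' @param col_map Optional named character vector mapping the standard
#'   column names to the file's names, e.g. `c(subject_id = "id")`.
#' @return A trial tibble ordered by subject and trial index.
#' @export
read_trials <- function(path, payoff = NULL, col_map = NULL) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(raw)) {
        stop("mapped column '", col_map[[std]], "' not found in ", path,
             call. = FALSE)
      }
      names(raw)[names(raw) == col_map[[std]]] <- std
    }
  }
  required <- c("subject_id", "group", "trial_index", "block", "opponent",
                "choice", "opponent_choice", "reward")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  raw <- raw[required]
  drop <- is.na(raw$choice) | raw$choice == ""
  n_dropped <- sum(drop)
  if (n_dropped > 0) {
    message(n_dropped, " row(s) with missing choice dropped")
    raw <- raw[!drop, ]
  }
  choice_to_int(raw$choice)          # label validation (errors on unknowns)
  choice_to_int(raw$opponent_choice)
  opponent_to_int(raw$opponent)
  raw <- dplyr::arrange(raw, .data$subject_id, .data$trial_index)
  nonmono <- raw |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(ok = all(diff(.data$trial_index) > 0), .groups = "drop")
  if (any(!nonmono$ok)) {
    stop("non-monotone trial_index for subject(s): ",
         paste(nonmono$subject_id[!nonmono$ok], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(payoff)) {
    expected <- payoff(payoff, raw$choice, raw$opponent_choice)
    bad <- which(abs(raw$reward - expected) > 1e-9)
    if (length(bad) > 0) {
      stop("reward inconsistent with payoff matrix in row(s): ",
           paste(head(bad, 10), collapse = ", "),
           if (length(bad) > 10) " ..." else "", call. = FALSE)
    }
    attr(raw, "payoff") <- payoff
  }
  out <- tibble::as_tibble(raw)
  attr(out, "n_dropped") <- n_dropped
  if (!is.null(payoff)) attr(out, "payoff") <- payoff
  out
}

#' @rdname read_trials
#' @param trials A trial tibble.
#' @return `write_trials()` returns `path` invisibly.
#' @export
write_trials <- function(trials, path) {
  required <- c("subject_id", "group", "trial_index", "block", "opponent",
                "choice", "opponent_choice", "reward")
  stopifnot(all(required %in% names(trials)))
  readr::write_csv(trials[required], path)
  invisible(path)
}
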