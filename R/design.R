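#' Study designs for the repeated Chicken game
#'
#' Two session layouts are supported. `"study1"` is the preschool design:
#' each subject faces each opponent in four contiguous blocks of 10 trials
#' (80 trials total), opponent order counterbalanced across subjects, with
#' the simplified loss-free payoff matrix. `"study2"` is the school-age
#' design: 50 trials per opponent interleaved in a uniformly random order
#' (100 trials total) with the full payoff matrix including losses; blocks of
#' 20 consecutive trials serve as analysis bins.
#'
#' For the full-matrix design, rewards are divided by `reward_scale`
#' (default 10) before entering the delta-rule value update so that the
#' inverse temperature lives on a comparable scale across designs; belief
#' models always use raw matrix units.
#'
#' @param study `"study1"` or `"study2"`.
#' @param payoff Optional [payoff_matrix()] overriding the preset.
#' @param reward_scale Optional divisor applied to rewards in the
#'   reward-family value update.
#' @return A `chick_design` object.
#' @examples
#' d <- make_design("study1")
#' d$n_trials
#' @export
make_design <- function(study = c("study1", "study2"), payoff = NULL,
                        reward_scale = NULL) {
  study <- match.arg(study)
  d <- if (study == "study1") {
    list(study = "study1", schedule = "blocked_counterbalanced",
         n_blocks = 4L, trials_per_block = 10L, trials_per_opponent = 40L,
         n_trials = 80L, payoff = payoff %||% payoff_study1(),
         reward_scale = reward_scale %||% 1)
  } else {
    list(study = "study2", schedule = "interleaved_random",
         n_blocks = 5L, trials_per_block = 20L, trials_per_opponent = 50L,
         n_trials = 100L, payoff = payoff %||% payoff_study2(),
         reward_scale = reward_scale %||% 10)
  }
  structure(d, class = "chick_design")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.chick_design <- function(x, ...) {
  cat(sprintf("Chicken-game design '%s': %d trials (%d per opponent), %s\n",
              x$study, x$n_trials, x$trials_per_opponent, x$schedule))
  print(x$payoff)
  invisible(x)
}

#' Opponent schedule for a session
#'
#' Builds the ordered sequence of opponent labels for one session. For the
#' blocked design the chosen first opponent fills the first half of the
#' session; for the interleaved design the fixed multiset of 50 HCO and 50
#' LCO trials is placed in a uniformly random order.
#'
#' @param design A [make_design()] object.
#' @param seed Optional integer seed (interleaved design only); the schedule
#'   is a pure function of `(design, first, seed)`.
#' @param first First opponent in the blocked design (`"HCO"` or `"LCO"`).
#' @return Character vector of opponent labels, one per trial.
#' @export
opponent_schedule <- function(design, seed = NULL, first = c("HCO", "LCO")) {
  stopifnot(inherits(design, "chick_design"))
  first <- match.arg(first)
  if (design$schedule == "blocked_counterbalanced") {
    second <- setdiff(OPPONENTS, first)
    rep(c(first, second), each = design$trials_per_opponent)
  } else {
    with_seed_if(seed, sample(rep(OPPONENTS, each = design$trials_per_opponent)))
  }
}

# analysis block index per trial: within-opponent blocks of `trials_per_block`
# for the blocked design, bins of consecutive trials for the interleaved one
block_index <- function(design, opponents) {
  if (design$schedule == "blocked_counterbalanced") {
    within <- stats::ave(seq_along(opponents), opponents, FUN = seq_along)
    as.integer(ceiling(within / design$trials_per_block))
  } else {
    as.integer(ceiling(seq_along(opponents) / design$trials_per_block))
  }
}
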