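#' Chicken-game payoff matrices
#'
#' A payoff matrix holds the four symmetric outcomes of the 2x2 Chicken game
#' from the focal player's perspective: `ss` (both swerve), `sg` (self
#' swerves, opponent goes straight), `gs` (self goes straight, opponent
#' swerves) and `gg` (both go straight). The same matrix describes both
#' players.
#'
#' Two presets are provided. The preschool task uses a simplified matrix
#' without losses satisfying `gs > ss = sg > gg` (payoffs in "flowers":
#' 3, 1, 1, 0). The school-age task uses a full matrix with losses satisfying
#' `gs > ss > sg > gg`, where a mutual crash costs 30 points; the remaining
#' entries are not uniquely pinned down by the task description, so the
#' preset (30, 10, -10, -30) is a documented reconstruction and every
#' downstream formula is derived from whatever matrix is configured.
#'
#' @param ss,sg,gs,gg Numeric payoffs for the four (own, opponent) action
#'   pairs.
#' @return An object of class `chick_payoff` (a named numeric vector).
#' @examples
#' payoff_study1()
#' payoff(payoff_study1(), "go_straight", "swerve")
#' @export
payoff_matrix <- function(ss, sg, gs, gg) {
  m <- c(ss = ss, sg = sg, gs = gs, gg = gg)
  stopifnot(all(is.finite(m)))
  structure(m, class = "chick_payoff")
}

#' @rdname payoff_matrix
#' @export
payoff_study1 <- function() payoff_matrix(ss = 1, sg = 1, gs = 3, gg = 0)

#' @rdname payoff_matrix
#' @export
payoff_study2 <- function() payoff_matrix(ss = 10, sg = -10, gs = 30, gg = -30)

#' @export
print.chick_payoff <- function(x, ...) {
  cat("Chicken-game payoff matrix (own perspective)\n")
  m <- matrix(c(x[["ss"]], x[["sg"]], x[["gs"]], x[["gg"]]), 2, 2, byrow = TRUE,
              dimnames = list(self = CHOICES, opponent = CHOICES))
  print(m)
  invisible(x)
}

#' Payoff received for an action pair
#'
#' Looks up the focal player's payoff for their own choice and the opponent's
#' choice. Vectorised over both choice arguments.
#'
#' @param matrix A [payoff_matrix()].
#' @param choice,opponent_choice Character vectors with entries `"swerve"` or
#'   `"go_straight"`.
#' @return Numeric vector of payoffs.
#' @export
payoff <- function(matrix, choice, opponent_choice) {
  stopifnot(inherits(matrix, "chick_payoff"))
  own <- choice_to_int(choice)
  opp <- choice_to_int(opponent_choice)
  key <- paste0(ifelse(own == 1L, "s", "g"), ifelse(opp == 1L, "s", "g"))
  unname(matrix[key])
}

# EV(p) = A + B * p for the belief families, where p is the believed
# probability that the opponent swerves:
#   V_swerve = p*ss + (1-p)*sg,  V_go = p*gs + (1-p)*gg
#   EV = V_swerve - V_go = (sg - gg) + p * ((ss - gs) - (sg - gg))
ev_coefs <- function(matrix) {
  stopifnot(inherits(matrix, "chick_payoff"))
  c(A = unname(matrix[["sg"]] - matrix[["gg"]]),
    B = unname((matrix[["ss"]] - matrix[["gs"]]) - (matrix[["sg"]] - matrix[["gg"]])))
}

#' Programmed opponent policies
#'
#' The task pits the participant against two pre-programmed opponents: a
#' high-competitive opponent (`HCO`) that goes straight with probability 0.70
#' and a low-competitive opponent (`LCO`) that goes straight with probability
#' 0.30, independently on every trial.
#'
#' @param label `"HCO"` or `"LCO"`, or pass `p_go_straight` directly for a
#'   custom policy.
#' @param p_go_straight Probability in \[0, 1\] of choosing go-straight.
#' @return A `chick_policy` object.
#' @export
opponent_policy <- function(label = c("HCO", "LCO"), p_go_straight = NULL) {
  label <- match.arg(label)
  if (is.null(p_go_straight)) {
    p_go_straight <- if (label == "HCO") 0.70 else 0.30
  }
  stopifnot(is.numeric(p_go_straight), length(p_go_straight) == 1,
            p_go_straight >= 0, p_go_straight <= 1)
  structure(list(label = label, p_go_straight = p_go_straight),
            class = "chick_policy")
}

#' Sample opponent choices from a policy
#'
#' Draws independent Bernoulli choices from an opponent policy.
#'
#' @param policy A [opponent_policy()].
#' @param n Number of draws.
#' @param seed Optional integer seed; when given the draws are a pure
#'   function of the seed.
#' @return Character vector of `"swerve"` / `"go_straight"`.
#' @export
sample_opponent_choice <- function(policy, n = 1, seed = NULL) {
  stopifnot(inherits(policy, "chick_policy"))
  with_seed_if(seed, {
    go <- runif(n) < policy$p_go_straight
    ifelse(go, "go_straight", "swerve")
  })
}
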