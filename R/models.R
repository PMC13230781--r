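#' The model bank
#'
#' Twelve models of trial-by-trial choice in the two-opponent Chicken game,
#' organised in families:
#'
#' * `M0` — non-learning baseline: the delta rule with learning rate fixed at
#'   0, leaving only the inverse temperature `beta`. With zero initial values
#'   it predicts P(swerve) = 0.5 on every trial.
#' * `M1-1/2/3` — reward-based (Rescorla-Wagner) learning: own action values
#'   are nudged toward received rewards. `M1-1` has one learning rate
#'   `alpha`, `M1-2` opponent-specific rates `alpha_h`/`alpha_l`, `M1-3`
#'   additionally a swerve-preference bias `theta`.
#' * `M2-1/2/3` — belief-based (fictitious-play) learning: the subject tracks
#'   each opponent's swerve probability `p` (initialised at 0.5) and converts
#'   it to action values through the payoff matrix.
#' * `M3-1/2/3` — second-order belief learning: the belief update gains an
#'   influence term `kappa * (Q_t - q_t)` where `q_t` is the opponent's
#'   inferred probability that the subject swerves.
#' * `M4-1/2` — preference-only baselines for the reward and belief families:
#'   no updating; the expected-value difference is frozen at its initial
#'   value so choice probability is constant at `plogis(beta * EV0 + theta)`.
#'
#' Parameter bounds: `alpha`, `alpha_h`, `alpha_l`, `kappa` in \[0, 1\];
#' `beta` in \[0, 10\]; `theta` unbounded.
#'
#' @param name Canonical model label, e.g. `"M1-3"`.
#' @return `model_spec()` returns an `rl_model_spec`; `model_bank()` a named
#'   list of all twelve specs.
#' @examples
#' model_spec("M2-3")$params
#' names(model_bank())
#' @export
model_spec <- function(name) {
  if (inherits(name, "rl_model_spec")) return(name)
  bank <- bank_table()
  if (!name %in% names(bank)) {
    stop("unknown model '", name, "'; available: ",
         paste(names(bank), collapse = ", "), call. = FALSE)
  }
  bank[[name]]
}

#' @rdname model_spec
#' @export
model_bank <- function() bank_table()

bank_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    mk <- function(name, family, family_group, family_code, n_alphas,
                   has_theta, has_kappa, frozen) {
      pn <- character(0)
      if (n_alphas == 1) pn <- "alpha"
      if (n_alphas == 2) pn <- c("alpha_h", "alpha_l")
      if (has_kappa) pn <- c(pn, "kappa")
      pn <- c(pn, "beta")
      if (has_theta) pn <- c(pn, "theta")
      lower <- ifelse(pn == "beta", 0, ifelse(pn == "theta", -Inf, 0))
      upper <- ifelse(pn == "beta", 10, ifelse(pn == "theta", Inf, 1))
      structure(list(
        name = name, family = family, family_group = family_group,
        n_alphas = n_alphas, has_theta = has_theta, has_kappa = has_kappa,
        frozen = frozen,
        codes = as.integer(c(family_code, n_alphas, has_theta, has_kappa, frozen)),
        params = tibble::tibble(param = pn, lower = lower, upper = upper,
                                bounded = is.finite(lower))
      ), class = "rl_model_spec")
    }
    cache <<- list(
      "M0"   = mk("M0",   "none",      "M0", 0, 0, FALSE, FALSE, FALSE),
      "M1-1" = mk("M1-1", "reward",    "M1", 0, 1, FALSE, FALSE, FALSE),
      "M1-2" = mk("M1-2", "reward",    "M1", 0, 2, FALSE, FALSE, FALSE),
      "M1-3" = mk("M1-3", "reward",    "M1", 0, 2, TRUE,  FALSE, FALSE),
      "M2-1" = mk("M2-1", "belief",    "M2", 1, 1, FALSE, FALSE, FALSE),
      "M2-2" = mk("M2-2", "belief",    "M2", 1, 2, FALSE, FALSE, FALSE),
      "M2-3" = mk("M2-3", "belief",    "M2", 1, 2, TRUE,  FALSE, FALSE),
      "M3-1" = mk("M3-1", "belief2",   "M3", 2, 1, FALSE, TRUE,  FALSE),
      "M3-2" = mk("M3-2", "belief2",   "M3", 2, 2, FALSE, TRUE,  FALSE),
      "M3-3" = mk("M3-3", "belief2",   "M3", 2, 2, TRUE,  TRUE,  FALSE),
      "M4-1" = mk("M4-1", "pref_only", "M4", 0, 0, TRUE,  FALSE, TRUE),
      "M4-2" = mk("M4-2", "pref_only", "M4", 1, 0, TRUE,  FALSE, TRUE)
    )
    cache
  }
})

#' @export
print.rl_model_spec <- function(x, ...) {
  cat(sprintf("Model %s (family: %s; parameters: %s)\n", x$name, x$family,
              paste(x$params$param, collapse = ", ")))
  invisible(x)
}

# validate and order a named parameter vector against a spec
check_params <- function(spec, params) {
  params <- unlist(params)
  missing <- setdiff(spec$params$param, names(params))
  if (length(missing) > 0) {
    stop("model ", spec$name, " needs parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- params[spec$params$param]
  bad <- out < spec$params$lower | out > spec$params$upper
  if (any(bad)) {
    stop("parameter(s) out of range for ", spec$name, ": ",
         paste(spec$params$param[bad], collapse = ", "), call. = FALSE)
  }
  out
}

#' Initial learner state
#'
#' Creates the per-opponent state carried across a session: action values
#' `v` (reward family, initialised at 0 for both actions) and believed
#' swerve probability `p` (belief families, initialised at 0.5). State for
#' one opponent is never altered by trials against the other.
#'
#' @param model A model name or [model_spec()].
#' @param payoff A [payoff_matrix()] (used to freeze EV for the
#'   preference-only baselines).
#' @return An `rl_state` list with elements `v` (2 x 2 matrix,
#'   opponent x action) and `p` (length-2 vector).
#' @export
init_state <- function(model, payoff = payoff_study1()) {
  spec <- model_spec(model)
  structure(list(
    v = matrix(0, 2, 2, dimnames = list(OPPONENTS, c("go_straight", "swerve"))),
    p = c(HCO = 0.5, LCO = 0.5)
  ), class = "rl_state")
}

#' Delta-rule update of action values
#'
#' Moves the chosen action's value for the current opponent toward the
#' received reward by fraction `alpha` (`V <- V + alpha * (R - V)`); the
#' unchosen action's value is left untouched.
#'
#' @param state An [init_state()] object.
#' @param opponent `"HCO"` or `"LCO"`.
#' @param choice The subject's choice (`"swerve"`/`"go_straight"`).
#' @param reward Received payoff.
#' @param alpha Learning rate in \[0, 1\].
#' @param reward_scale Divisor applied to `reward` before the update.
#' @return The updated state.
#' @export
reward_update <- function(state, opponent, choice, reward, alpha,
                          reward_scale = 1) {
  stopifnot(alpha >= 0, alpha <= 1)
  v <- state$v[opponent, choice]
  state$v[opponent, choice] <- v + alpha * (reward / reward_scale - v)
  state
}

#' Fictitious-play belief update
#'
#' Moves the believed swerve probability of the current opponent toward the
#' observed action (`p <- p + alpha * (O - p)`, with `O = 1` for swerve).
#'
#' @inheritParams reward_update
#' @param opponent_choice The opponent's observed choice.
#' @return The updated state.
#' @export
belief_update <- function(state, opponent, opponent_choice, alpha) {
  stopifnot(alpha >= 0, alpha <= 1)
  o <- choice_to_int(opponent_choice)
  state$p[opponent] <- state$p[opponent] + alpha * (o - state$p[opponent])
  state
}

#' Inferred second-order swerve probability
#'
#' The opponent's inferred probability `q` that the subject will swerve,
#' obtained by inverting the subject's own softmax policy at the current
#' belief: `q` solves `beta * EV(q) = logit(p)` where `EV(q) = A + B * q`
#' with `A = sg - gg` and `B = (ss - gs) - (sg - gg)` from the configured
#' payoff matrix. Under the loss-free preset this reduces exactly to the
#' closed form `q = 1/3 + log((1 - p) / p) / (3 * beta)`.
#'
#' @param p Believed swerve probability (clipped to `[1e-6, 1 - 1e-6]`).
#' @param beta Inverse temperature (> 0).
#' @param payoff A [payoff_matrix()].
#' @return Numeric vector of inferred probabilities (may fall outside
#'   \[0, 1\] for extreme beliefs; consumed as-is by the influence term).
#' @export
second_order_q <- function(p, beta, payoff = payoff_study1()) {
  ab <- ev_coefs(payoff)
  if (abs(ab[["B"]]) < 1e-12) {
    stop("degenerate payoff matrix: belief has no effect on expected value",
         call. = FALSE)
  }
  stopifnot(beta > 0)
  p <- pmin(pmax(p, 1e-6), 1 - 1e-6)
  (qlogis(p) / beta - ab[["A"]]) / ab[["B"]]
}

#' Second-order belief update
#'
#' Augments the fictitious-play update with an influence term:
#' `p <- p + alpha * (O - p) + kappa * (Q - q)` where `Q` is the subject's
#' own action and `q` the opponent's inferred swerve probability from
#' [second_order_q()] (computed at the pre-update belief). The result is
#' clipped to `[1e-6, 1 - 1e-6]`.
#'
#' @inheritParams belief_update
#' @param choice The subject's own choice on this trial.
#' @param kappa Influence weight in \[0, 1\].
#' @param beta Inverse temperature used to invert the policy.
#' @param payoff A [payoff_matrix()].
#' @return The updated state.
#' @export
belief2_update <- function(state, opponent, opponent_choice, choice, alpha,
                           kappa, beta, payoff = payoff_study1()) {
  stopifnot(alpha >= 0, alpha <= 1, kappa >= 0, kappa <= 1)
  o <- choice_to_int(opponent_choice)
  q_own <- choice_to_int(choice)
  p <- state$p[opponent]
  q <- second_order_q(p, beta, payoff)
  p_new <- p + alpha * (o - p) + kappa * (q_own - q)
  state$p[opponent] <- pmin(pmax(p_new, 1e-6), 1 - 1e-6)
  state
}

#' Expected-value difference favouring swerve
#'
#' For the reward family, `EV = V_swerve - V_go_straight` from the stored
#' action values. For the belief families the action values are derived from
#' the payoff matrix (`V_swerve = p*ss + (1-p)*sg`,
#' `V_go = p*gs + (1-p)*gg`), which collapses to `EV = 1 - 3p` under the
#' loss-free preset.
#'
#' @inheritParams reward_update
#' @param model A model name or [model_spec()].
#' @param payoff A [payoff_matrix()].
#' @return Scalar expected-value difference.
#' @export
expected_value <- function(model, state, opponent, payoff = payoff_study1()) {
  spec <- model_spec(model)
  if (spec$codes[1] == 0) {
    unname(state$v[opponent, "swerve"] - state$v[opponent, "go_straight"])
  } else {
    ab <- ev_coefs(payoff)
    unname(ab[["A"]] + ab[["B"]] * state$p[opponent])
  }
}

#' Softmax choice probability
#'
#' `P(swerve) = plogis(beta * EV + theta)`. Models without a preference term
#' use `theta = 0`; the preference-only baselines evaluate this at the frozen
#' initial EV for the whole session.
#'
#' @param model A model name or [model_spec()].
#' @param ev Expected-value difference favouring swerve.
#' @param beta Inverse temperature in \[0, 10\].
#' @param theta Swerve-preference bias (ignored for models without one).
#' @return Probability of choosing swerve, strictly inside (0, 1).
#' @export
choice_prob <- function(model, ev, beta, theta = 0) {
  spec <- model_spec(model)
  stopifnot(beta >= 0, beta <= 10)
  if (!spec$has_theta) theta <- 0
  plogis(beta * ev + theta)
}

#' Session log-likelihood
#'
#' Replays a session under a model and parameter set: at each trial the
#' choice probability is computed from the current learner state, the log
#' probability of the observed choice is accumulated, and the state is then
#' updated with the observed choices and reward. Two-learning-rate models
#' select `alpha_h` or `alpha_l` by the trial's opponent.
#'
#' @param model A model name or [model_spec()].
#' @param params Named numeric vector (natural scale) with the model's
#'   parameters.
#' @param trials A trial tibble for a single subject (see
#'   [simulate_session()]), ordered by `trial_index`.
#' @param payoff A [payoff_matrix()]; defaults to the tibble's `payoff`
#'   attribute.
#' @param reward_scale Reward divisor for the delta-rule update; defaults to
#'   the tibble's design attribute, else 1.
#' @param pointwise Return the per-trial log-likelihood vector instead of
#'   the total.
#' @return Total log-likelihood (scalar) or per-trial vector.
#' @export
session_loglik <- function(model, params, trials, payoff = NULL,
                           reward_scale = NULL, pointwise = FALSE) {
  spec <- model_spec(model)
  params <- check_params(spec, params)
  payoff <- payoff %||% attr(trials, "payoff") %||% payoff_study1()
  reward_scale <- reward_scale %||% attr(trials, "design")$reward_scale %||% 1
  if (length(unique(trials$subject_id)) > 1) {
    stop("session_loglik() expects a single subject's trials", call. = FALSE)
  }
  trials <- dplyr::arrange(trials, .data$trial_index)
  ab <- ev_coefs(payoff)
  out <- cpp_session_loglik(
    spec$codes, unname(params),
    opponent_to_int(trials$opponent), choice_to_int(trials$choice),
    choice_to_int(trials$opponent_choice), as.numeric(trials$reward),
    ab[["A"]], ab[["B"]], reward_scale, pointwise)
  if (pointwise) out else out[[1]]
}
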