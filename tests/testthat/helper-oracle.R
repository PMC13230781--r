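# Independent brute-force replay of every model's likelihood, written
# directly from the update and choice equations with its own arithmetic
# (explicit action-value tables, belief vectors, and a numeric root-find for
# the second-order inversion). Used only as a cross-check of the package's
# likelihood code.

oracle_session_ll <- function(name, params, trials, payoff,
                              reward_scale = 1, pointwise = FALSE) {
  p <- as.list(params)
  ss <- payoff[["ss"]]; sg <- payoff[["sg"]]
  gs <- payoff[["gs"]]; gg <- payoff[["gg"]]
  two_rates <- name %in% c("M1-2", "M1-3", "M2-2", "M2-3", "M3-2", "M3-3")
  one_rate <- name %in% c("M1-1", "M2-1", "M3-1")
  reward_like <- name %in% c("M0", "M1-1", "M1-2", "M1-3")
  belief_like <- name %in% c("M2-1", "M2-2", "M2-3")
  second_order <- name %in% c("M3-1", "M3-2", "M3-3")
  frozen <- name %in% c("M4-1", "M4-2")
  theta <- if (name %in% c("M1-3", "M2-3", "M3-3", "M4-1", "M4-2"))
    p$theta else 0
  beta <- p$beta

  V <- list(HCO = c(swerve = 0, go_straight = 0),
            LCO = c(swerve = 0, go_straight = 0))
  pb <- c(HCO = 0.5, LCO = 0.5)
  ll <- numeric(nrow(trials))
  for (i in seq_len(nrow(trials))) {
    o <- trials$opponent[i]
    ch <- trials$choice[i]
    och <- trials$opponent_choice[i]
    alpha <- if (two_rates) {
      if (o == "HCO") p$alpha_h else p$alpha_l
    } else if (one_rate) p$alpha else 0

    ev <- if (name == "M4-1") {
      0
    } else if (name == "M4-2") {
      (0.5 * ss + 0.5 * sg) - (0.5 * gs + 0.5 * gg)
    } else if (reward_like) {
      V[[o]][["swerve"]] - V[[o]][["go_straight"]]
    } else {
      (pb[[o]] * ss + (1 - pb[[o]]) * sg) -
        (pb[[o]] * gs + (1 - pb[[o]]) * gg)
    }
    x <- beta * ev + theta
    s <- if (ch == "swerve") x else -x
    ll[i] <- if (s >= 0) -log1p(exp(-s)) else s - log1p(exp(s))

    if (frozen || name == "M0") next
    if (reward_like) {
      r <- trials$reward[i] / reward_scale
      V[[o]][[ch]] <- V[[o]][[ch]] + alpha * (r - V[[o]][[ch]])
    } else {
      O <- as.numeric(och == "swerve")
      if (belief_like) {
        pb[[o]] <- pb[[o]] + alpha * (O - pb[[o]])
      } else if (second_order) {
        pc <- min(max(pb[[o]], 1e-6), 1 - 1e-6)
        # q solves beta * EV(q) = log(p / (1 - p)) for the opponent's
        # inferred swerve probability; found numerically
        f <- function(q) {
          beta * ((q * ss + (1 - q) * sg) - (q * gs + (1 - q) * gg)) -
            log(pc / (1 - pc))
        }
        q <- stats::uniroot(f, c(-1e6, 1e6), tol = 1e-12)$root
        Q <- as.numeric(ch == "swerve")
        pb[[o]] <- pb[[o]] + alpha * (O - pb[[o]]) + p$kappa * (Q - q)
        pb[[o]] <- min(max(pb[[o]], 1e-6), 1 - 1e-6)
      }
    }
  }
  if (pointwise) ll else sum(ll)
}

# random valid parameters for a bank model
random_params <- function(name, rng_beta = c(0.2, 8)) {
  spec <- model_spec(name)
  vals <- vapply(seq_len(nrow(spec$params)), function(j) {
    p <- spec$params$param[j]
    if (p == "beta") runif(1, rng_beta[1], rng_beta[2])
    else if (p == "theta") rnorm(1)
    else runif(1)
  }, 0)
  setNames(vals, spec$params$param)
}

# a short random session tibble with valid rewards
random_session <- function(n_trials, payoff, design = NULL, id = "s01") {
  opp <- sample(c("HCO", "LCO"), n_trials, replace = TRUE)
  ch <- sample(c("swerve", "go_straight"), n_trials, replace = TRUE)
  och <- sample(c("swerve", "go_straight"), n_trials, replace = TRUE)
  tibble::tibble(
    subject_id = id, group = "test", trial_index = seq_len(n_trials),
    block = 1L, opponent = opp, choice = ch, opponent_choice = och,
    reward = payoff(payoff, ch, och))
}

# small cohort for fit-level tests
tiny_cohort <- function(n = 5, model = "M1-1", study = "study1", seed = 1) {
  generate_cohort(cohort_spec(n, make_design(study), model, seed = seed))
}

tiny_config <- function(chains = 2, warmup = 150, iter = 150) {
  sampler_preset("ci", chains = chains, warmup = warmup, iter = iter)
}
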