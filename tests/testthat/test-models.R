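test_that("the bank enumerates twelve models with the declared parameters", {
  bank <- model_bank()
  expect_length(bank, 12)
  expect_equal(model_spec("M0")$params$param, "beta")
  expect_equal(model_spec("M1-2")$params$param, c("alpha_h", "alpha_l", "beta"))
  expect_equal(model_spec("M3-3")$params$param,
               c("alpha_h", "alpha_l", "kappa", "beta", "theta"))
  expect_equal(model_spec("M4-2")$params$param, c("beta", "theta"))
  expect_error(model_spec("M5"), "unknown model")
})

test_that("state initialisation and the baseline choice rule", {
  st <- init_state("M2-1")
  expect_equal(unname(st$p), c(0.5, 0.5))
  expect_true(all(st$v == 0))
  # zero EV gives a coin flip for any temperature
  expect_equal(choice_prob("M0", 0, beta = 7), 0.5)
  expect_equal(expected_value("M1-1", init_state("M1-1"), "HCO"), 0)
})

test_that("delta-rule update moves only the chosen action's value", {
  st <- init_state("M1-1")
  st2 <- reward_update(st, "HCO", "swerve", reward = 1, alpha = 0.5)
  expect_equal(st2$v["HCO", "swerve"], 0.5)
  expect_equal(st2$v["HCO", "go_straight"], 0)
  expect_equal(st2$v["LCO", "swerve"], 0)
  # zero learning rate and zero prediction error leave the state unchanged
  expect_equal(reward_update(st, "HCO", "swerve", 1, alpha = 0)$v, st$v)
  expect_equal(reward_update(st2, "HCO", "swerve", 0.5, alpha = 0.9)$v, st2$v)
  expect_error(reward_update(st, "HCO", "swerve", 1, alpha = 1.2))
})

test_that("belief update follows the fictitious-play rule", {
  st <- init_state("M2-1")
  expect_equal(unname(belief_update(st, "HCO", "swerve", 0.2)$p["HCO"]), 0.6)
  expect_equal(unname(belief_update(st, "LCO", "go_straight", 1)$p["LCO"]), 0)
  # state for one opponent never leaks into the other
  expect_equal(unname(belief_update(st, "HCO", "swerve", 0.2)$p["LCO"]), 0.5)
})

test_that("second-order inversion matches the closed form and round-trips", {
  p1 <- payoff_study1()
  expect_equal(second_order_q(0.5, beta = 0.1, p1), 1/3)
  expect_equal(second_order_q(0.5, beta = 9, p1), 1/3)

  grid <- seq(0.01, 0.99, length.out = 101)
  for (beta in c(0.5, 2, 8)) {
    closed <- 1/3 + log((1 - grid) / grid) / (3 * beta)
    expect_equal(second_order_q(grid, beta, p1), closed, tolerance = 1e-12)
    # inverting back through the softmax recovers the belief
    q <- second_order_q(grid, beta, p1)
    ev <- (q * p1[["ss"]] + (1 - q) * p1[["sg"]]) -
      (q * p1[["gs"]] + (1 - q) * p1[["gg"]])
    expect_equal(plogis(beta * ev), grid, tolerance = 1e-10)
  }
  expect_error(second_order_q(0.4, 1, payoff_matrix(1, 0, 1, 0)), "degenerate")
})

test_that("second-order update includes the influence term and clips", {
  st <- init_state("M3-1")
  st2 <- belief2_update(st, "HCO", "swerve", "swerve", alpha = 0.2,
                        kappa = 0.1, beta = 2)
  expect_equal(unname(st2$p["HCO"]), 0.6 + 0.1 * (1 - 1/3), tolerance = 1e-12)
  # zero influence weight reduces to plain belief updating
  st3 <- belief2_update(st, "LCO", "go_straight", "swerve", alpha = 0.3,
                        kappa = 0, beta = 2)
  expect_equal(st3$p, belief_update(st, "LCO", "go_straight", 0.3)$p)
  # beliefs stay strictly inside the unit interval
  stx <- init_state("M3-1")
  stx$p["HCO"] <- 0.999999
  sty <- belief2_update(stx, "HCO", "swerve", "swerve", 1, 1, 0.5)
  expect_true(sty$p["HCO"] >= 1e-6 && sty$p["HCO"] <= 1 - 1e-6)
})

test_that("belief-family EV comes from the configured matrix", {
  st <- init_state("M2-1")
  st$p["HCO"] <- 0
  expect_equal(expected_value("M2-1", st, "HCO"), 1)
  st$p["HCO"] <- 1/3
  expect_equal(expected_value("M2-1", st, "HCO"), 0, tolerance = 1e-12)
  # arbitrary matrix: equals the direct value difference on a grid
  pm <- payoff_matrix(ss = 4, sg = -2, gs = 11, gg = -7)
  for (p in seq(0, 1, 0.1)) {
    st$p["LCO"] <- p
    direct <- (p * 4 + (1 - p) * (-2)) - (p * 11 + (1 - p) * (-7))
    expect_equal(expected_value("M2-1", st, "LCO", pm), direct,
                 tolerance = 1e-12)
  }
})

test_that("softmax choice rule and its limits", {
  expect_equal(choice_prob("M1-1", ev = 1, beta = 1), 1 / (1 + exp(-1)))
  expect_equal(choice_prob("M1-3", ev = 1, beta = 1, theta = 0),
               0.73106, tolerance = 1e-4)
  expect_gt(choice_prob("M1-3", ev = 0, beta = 1, theta = 30), 0.9999)
  # theta is inert for models without a preference term
  expect_equal(choice_prob("M1-1", 0.5, 2, theta = 5),
               choice_prob("M1-1", 0.5, 2))
})

test_that("session log-likelihood matches the brute-force oracle", {
  withr::local_seed(42)
  for (pay in list(payoff_study1(), payoff_study2())) {
    rscale <- if (pay[["gg"]] < 0) 10 else 1
    for (name in names(model_bank())) {
      for (rep in 1:4) {
        tr <- random_session(30, pay)
        pars <- random_params(name)
        got <- session_loglik(name, pars, tr, payoff = pay,
                              reward_scale = rscale)
        want <- oracle_session_ll(name, pars, tr, pay, reward_scale = rscale)
        expect_equal(got, want, tolerance = 1e-10,
                     label = paste("loglik", name))
        pw <- session_loglik(name, pars, tr, payoff = pay,
                             reward_scale = rscale, pointwise = TRUE)
        expect_equal(sum(pw), got, tolerance = 1e-10)
        expect_true(all(pw <= 0))
      }
    }
  }
})

test_that("the non-learning model has the closed-form likelihood", {
  tr <- random_session(80, payoff_study1())
  expect_equal(session_loglik("M0", c(beta = 4.2), tr, payoff_study1()),
               80 * log(0.5))
})

test_that("nested models coincide at the boundary parameter values", {
  withr::local_seed(7)
  tr <- random_session(40, payoff_study1())
  ll <- function(m, p) session_loglik(m, p, tr, payoff_study1())
  expect_equal(ll("M1-1", c(alpha = 0.3, beta = 2)),
               ll("M1-2", c(alpha_h = 0.3, alpha_l = 0.3, beta = 2)))
  expect_equal(ll("M1-2", c(alpha_h = 0.2, alpha_l = 0.6, beta = 2)),
               ll("M1-3", c(alpha_h = 0.2, alpha_l = 0.6, beta = 2, theta = 0)))
  expect_equal(ll("M2-2", c(alpha_h = 0.2, alpha_l = 0.6, beta = 2)),
               ll("M3-2", c(alpha_h = 0.2, alpha_l = 0.6, kappa = 0, beta = 2)))
  # preference-only baselines equal their family with learning switched off
  expect_equal(ll("M4-1", c(beta = 2, theta = 0.4)),
               ll("M1-3", c(alpha_h = 0, alpha_l = 0, beta = 2, theta = 0.4)))
  expect_equal(ll("M4-2", c(beta = 2, theta = 0.4)),
               ll("M2-3", c(alpha_h = 0, alpha_l = 0, beta = 2, theta = 0.4)))
})

test_that("per-opponent state is invariant to how trials interleave", {
  withr::local_seed(13)
  tr <- random_session(60, payoff_study2())
  # regroup rows while preserving each opponent's own trial order
  keep_within <- unlist(split(seq_len(60), tr$opponent), use.names = FALSE)
  perm <- tr[keep_within, ]
  perm$trial_index <- seq_len(60)
  for (name in c("M1-3", "M2-3", "M3-3")) {
    pars <- random_params(name)
    expect_equal(
      session_loglik(name, pars, tr, payoff_study2(), reward_scale = 10),
      session_loglik(name, pars, perm, payoff_study2(), reward_scale = 10),
      tolerance = 1e-10)
  }
})

test_that("likelihood stays finite at extreme valid parameters", {
  tr <- random_session(50, payoff_study2())
  ll <- session_loglik("M3-3",
                       c(alpha_h = 1, alpha_l = 0, kappa = 1, beta = 10,
                         theta = 8),
                       tr, payoff_study2(), reward_scale = 10)
  expect_true(is.finite(ll))
})
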