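test_that("design presets reproduce the two study layouts", {
  d1 <- make_design("study1")
  expect_equal(d1$n_trials, 80L)
  expect_equal(d1$trials_per_opponent * 2L, d1$n_trials)
  expect_equal(d1$n_blocks * d1$trials_per_block, d1$trials_per_opponent)

  d2 <- make_design("study2")
  expect_equal(d2$n_trials, 100L)
  expect_equal(d2$trials_per_opponent, 50L)

  expect_error(make_design("study3"))
})

test_that("payoff presets satisfy the printed orderings and values", {
  p1 <- payoff_study1()
  expect_true(p1[["gs"]] > p1[["ss"]] && p1[["ss"]] == p1[["sg"]] &&
                p1[["sg"]] > p1[["gg"]])
  expect_equal(payoff(p1, "go_straight", "swerve"), 3)
  expect_equal(payoff(p1, "go_straight", "go_straight"), 0)
  expect_equal(payoff(p1, "swerve", "swerve"), 1)

  p2 <- payoff_study2()
  expect_true(p2[["gs"]] > p2[["ss"]] && p2[["ss"]] > p2[["sg"]] &&
                p2[["sg"]] > p2[["gg"]])
  expect_equal(payoff(p2, "go_straight", "go_straight"), -30)
})

test_that("opponent schedules honour the design", {
  d1 <- make_design("study1")
  sch <- opponent_schedule(d1, first = "HCO")
  expect_equal(sch[1:40], rep("HCO", 40))
  expect_equal(sch[41:80], rep("LCO", 40))
  sch_l <- opponent_schedule(d1, first = "LCO")
  expect_equal(sch_l[1:40], rep("LCO", 40))

  d2 <- make_design("study2")
  sch2 <- opponent_schedule(d2, seed = 3)
  expect_equal(sum(sch2 == "HCO"), 50)
  expect_equal(sum(sch2 == "LCO"), 50)
  expect_identical(sch2, opponent_schedule(d2, seed = 3))
  expect_false(identical(sch2, opponent_schedule(d2, seed = 4)))
})

test_that("interleaved schedules are exchangeable across seeds", {
  d2 <- make_design("study2")
  first_is_hco <- vapply(1:400, function(s) {
    opponent_schedule(d2, seed = s)[1] == "HCO"
  }, TRUE)
  # each position is HCO in about half of schedules
  expect_gt(mean(first_is_hco), 0.4)
  expect_lt(mean(first_is_hco), 0.6)
})

test_that("opponent policies draw go-straight at the programmed rates", {
  always <- opponent_policy("HCO", p_go_straight = 1)
  expect_true(all(sample_opponent_choice(always, 50, seed = 1) == "go_straight"))

  hco <- sample_opponent_choice(opponent_policy("HCO"), 10000, seed = 2)
  lco <- sample_opponent_choice(opponent_policy("LCO"), 10000, seed = 2)
  se3 <- 3 * sqrt(0.7 * 0.3 / 10000)
  expect_lt(abs(mean(hco == "go_straight") - 0.70), se3)
  expect_lt(abs(mean(lco == "go_straight") - 0.30), se3)
})

test_that("simulated sessions are deterministic and internally consistent", {
  d <- make_design("study2")
  pars <- c(alpha_h = 0.4, alpha_l = 0.2, beta = 2, theta = 0.3)
  s1 <- simulate_session("M2-3", pars, d, seed = 11)
  s2 <- simulate_session("M2-3", pars, d, seed = 11)
  expect_identical(s1$choice, s2$choice)
  expect_identical(s1$opponent, s2$opponent)
  # rewards are reproducible from choices and the matrix alone
  expect_equal(s1$reward, payoff(d$payoff, s1$choice, s1$opponent_choice))
  expect_equal(s1$trial_index, 1:100)
})

test_that("the non-learning baseline chooses at chance", {
  d <- make_design("study1")
  swerves <- vapply(1:40, function(s) {
    mean(simulate_session("M0", c(beta = 5), d, seed = s)$choice == "swerve")
  }, 0)
  expect_lt(abs(mean(swerves) - 0.5), 3 * sqrt(0.25 / (40 * 80)))
})

test_that("cohort generation matches the sampling design", {
  spec <- cohort_spec(52, make_design("study1"), "M1-2", seed = 21)
  co <- generate_cohort(spec)
  counts <- dplyr::count(co$trials, subject_id)
  expect_equal(nrow(counts), 52)
  expect_true(all(counts$n == 80))
  # learning rates respect their bounds after the probit mapping
  expect_true(all(co$params$alpha_h >= 0 & co$params$alpha_h <= 1))
  expect_true(all(co$params$beta >= 0 & co$params$beta <= 10))
  # even counterbalancing of the first opponent
  firsts <- co$trials |>
    dplyr::filter(trial_index == 1) |>
    dplyr::pull(opponent)
  expect_equal(sum(firsts == "HCO"), 26)

  # degenerate group spread collapses every subject onto one parameter set
  co0 <- generate_cohort(cohort_spec(6, make_design("study1"), "M1-2",
                                     group_sds = c(alpha_h = 0, alpha_l = 0,
                                                   beta = 0), seed = 3))
  expect_equal(nrow(dplyr::distinct(co0$params[-1])), 1)

  # same spec, same cohort
  expect_identical(generate_cohort(spec)$trials$choice, co$trials$choice)
})

test_that("block cooperation rates are per-subject proportions", {
  d <- make_design("study1")
  s <- simulate_session("M1-1", c(alpha = 0.3, beta = 2), d, seed = 2)
  s$choice <- "swerve"
  r <- block_cooperation_rates(s)
  expect_true(all(r$swerve_rate == 1))
  expect_equal(nrow(r), 8)  # 2 opponents x 4 blocks

  s$choice <- rep(c("swerve", "go_straight"), 40)
  r2 <- block_cooperation_rates(s)
  expect_true(all(r2$swerve_rate == 0.5))

  # a block with no trials for an opponent comes back as missing
  r3 <- block_cooperation_rates(dplyr::filter(s, !(opponent == "LCO" & block == 4)))
  expect_true(is.na(r3$swerve_rate[r3$opponent == "LCO" & r3$block == 4]))
})

test_that("belief learners cooperate more with the competitive opponent late on", {
  co <- generate_cohort(cohort_spec(30, make_design("study1"), "M2-3", seed = 8))
  late <- block_cooperation_rates(co$trials) |>
    dplyr::filter(block == 4) |>
    dplyr::group_by(opponent) |>
    dplyr::summarise(rate = mean(swerve_rate))
  expect_gt(late$rate[late$opponent == "HCO"],
            late$rate[late$opponent == "LCO"])
})
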