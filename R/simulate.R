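#' Simulate one session
#'
#' Plays a full session forward under a model: on each trial the opponent's
#' choice is drawn from its policy, the subject's choice from the model's
#' current softmax probability, the payoff is assigned from the matrix, and
#' the learner state is updated with the experienced outcome.
#'
#' @param model A model name or [model_spec()].
#' @param params Named numeric vector of natural-scale parameters.
#' @param design A [make_design()] object.
#' @param seed Optional integer seed; the session is a pure function of
#'   `(model, params, design, first, seed)`.
#' @param subject_id Subject identifier stored in the output.
#' @param group Group label stored in the output.
#' @param first First opponent for the blocked design.
#' @param opponent_sequence Optional pre-specified opponent label sequence
#'   (overrides the schedule; used for replay-style simulation).
#' @param opponent_choices Optional pre-specified opponent choices (the
#'   subject then plays against a fixed opponent record).
#' @return A trial tibble with columns `subject_id`, `group`, `trial_index`,
#'   `block`, `opponent`, `choice`, `opponent_choice`, `reward`, carrying the
#'   design and payoff matrix as attributes.
#' @examples
#' s <- simulate_session("M2-3",
#'   c(alpha_h = 0.4, alpha_l = 0.3, beta = 2, theta = 0.3),
#'   make_design("study1"), seed = 1)
#' @export
simulate_session <- function(model, params, design, seed = NULL,
                             subject_id = "s01", group = "synthetic",
                             first = c("HCO", "LCO"),
                             opponent_sequence = NULL,
                             opponent_choices = NULL) {
  spec <- model_spec(model)
  params <- check_params(spec, params)
  stopifnot(inherits(design, "chick_design"))
  first <- match.arg(first)
  with_seed_if(seed, {
    opp <- opponent_sequence %||% opponent_schedule(design, first = first)
    n <- length(opp)
    sim <- forward_sim(spec, params, opponent_to_int(opp), design$payoff,
                       design$reward_scale,
                       opp_choice_int = if (is.null(opponent_choices)) NULL
                                        else choice_to_int(opponent_choices))
    trials <- tibble::tibble(
      subject_id = subject_id, group = group, trial_index = seq_len(n),
      block = block_index(design, opp), opponent = opp,
      choice = CHOICES[2 - sim$choice],
      opponent_choice = CHOICES[2 - sim$opp_choice],
      reward = payoff(design$payoff, CHOICES[2 - sim$choice],
                      CHOICES[2 - sim$opp_choice]))
    attr(trials, "design") <- design
    attr(trials, "payoff") <- design$payoff
    trials
  })
}

# Core forward pass shared by simulation and posterior predictive checks.
# Works in integer coding (opp: HCO = 0 / LCO = 1; choices: swerve = 1).
# Returns sampled choices, opponent choices and the per-trial P(swerve).
forward_sim <- function(spec, params, opp_int, payoff, reward_scale,
                        opp_choice_int = NULL) {
  n <- length(opp_int)
  ab <- ev_coefs(payoff)
  a <- rep(0, 2)
  if (spec$n_alphas == 1) a[] <- params[["alpha"]]
  if (spec$n_alphas == 2) a <- c(params[["alpha_h"]], params[["alpha_l"]])
  beta <- params[["beta"]]
  theta <- if (spec$has_theta) params[["theta"]] else 0
  kappa <- if (spec$has_kappa) params[["kappa"]] else 0
  fam <- spec$codes[1]
  if (is.null(opp_choice_int)) {
    p_go <- ifelse(opp_int == 0L, 0.70, 0.30)
    opp_choice_int <- as.integer(runif(n) >= p_go)
  }
  v <- matrix(0, 2, 2)            # [opponent + 1, action + 1]
  pbel <- c(0.5, 0.5)
  ev_frozen <- if (fam == 0) 0 else ab[["A"]] + 0.5 * ab[["B"]]
  choice <- integer(n)
  pswerve <- numeric(n)
  for (t in seq_len(n)) {
    o <- opp_int[t] + 1L
    ev <- if (spec$frozen) ev_frozen
          else if (fam == 0) v[o, 2] - v[o, 1]
          else ab[["A"]] + ab[["B"]] * pbel[o]
    P <- plogis(beta * ev + theta)
    pswerve[t] <- P
    ch <- as.integer(runif(1) < P)
    choice[t] <- ch
    if (!spec$frozen && spec$n_alphas > 0) {
      if (fam == 0) {
        r <- c(payoff[["gg"]], payoff[["gs"]],
               payoff[["sg"]], payoff[["ss"]])[2 * ch + opp_choice_int[t] + 1]
        r <- r / reward_scale
        v[o, ch + 1] <- v[o, ch + 1] + a[o] * (r - v[o, ch + 1])
      } else if (fam == 1) {
        pbel[o] <- pbel[o] + a[o] * (opp_choice_int[t] - pbel[o])
      } else {
        p0 <- min(max(pbel[o], 1e-6), 1 - 1e-6)
        q <- (qlogis(p0) / max(beta, 1e-12) - ab[["A"]]) / ab[["B"]]
        p_new <- pbel[o] + a[o] * (opp_choice_int[t] - pbel[o]) +
          kappa * (ch - q)
        pbel[o] <- min(max(p_new, 1e-6), 1 - 1e-6)
      }
    }
  }
  list(choice = choice, opp_choice = opp_choice_int, p_swerve = pswerve)
}

#' Specify a synthetic cohort
#'
#' A cohort specification names the generating model, the session design and
#' the group-level parameter distribution. Per-subject raw parameters are
#' drawn from `Normal(group_means, group_sds)` on the unconstrained scale and
#' mapped into their bounds with the same probit transform used during
#' inference ([transform_to_bounds()]), so simulated populations live in
#' exactly the space the sampler assumes.
#'
#' Default group means correspond to learning rates around 0.31, inverse
#' temperature around 2.1, swerve preference 0.3 and influence weight around
#' 0.21, with raw-scale spread 0.5.
#'
#' @param n_subjects Number of subjects.
#' @param design A [make_design()] object.
#' @param model Generating model name or [model_spec()].
#' @param group_means,group_sds Optional named vectors (raw scale) per free
#'   parameter.
#' @param group Group label.
#' @param seed Integer seed; the cohort is a pure function of the spec.
#' @return A `chick_cohort_spec` object.
#' @export
cohort_spec <- function(n_subjects, design, model, group_means = NULL,
                        group_sds = NULL, group = "synthetic", seed = 1L) {
  spec <- model_spec(model)
  stopifnot(n_subjects >= 1, inherits(design, "chick_design"))
  defaults <- default_group_params(spec)
  gm <- defaults$mean
  gs <- defaults$sd
  if (!is.null(group_means)) gm[names(group_means)] <- group_means
  if (!is.null(group_sds)) gs[names(group_sds)] <- group_sds
  stopifnot(all(gs >= 0))
  structure(list(n_subjects = as.integer(n_subjects), design = design,
                 model = spec, group_means = gm, group_sds = gs,
                 group = group, seed = as.integer(seed)),
            class = "chick_cohort_spec")
}

default_group_params <- function(spec) {
  pn <- spec$params$param
  mean <- setNames(rep(0, length(pn)), pn)
  mean[grepl("^alpha", pn)] <- -0.5   # ~ 0.31 after probit mapping to [0, 1]
  mean[pn == "kappa"] <- -0.8         # ~ 0.21
  mean[pn == "beta"] <- -0.8          # ~ 2.1 on [0, 10]
  mean[pn == "theta"] <- 0.3
  list(mean = mean, sd = setNames(rep(0.5, length(pn)), pn))
}

#' Generate a synthetic cohort
#'
#' Draws per-subject parameters from the cohort's group-level distribution
#' and simulates one session per subject. In the blocked design the first
#' opponent alternates across subjects (even counterbalancing); in the
#' interleaved design every subject gets an independent random schedule.
#'
#' @param spec A [cohort_spec()].
#' @return A list of class `rl_cohort` with `trials` (all subjects' trials,
#'   one long tibble) and `params` (ground-truth per-subject natural-scale
#'   parameters, for recovery studies).
#' @examples
#' co <- generate_cohort(cohort_spec(4, make_design("study1"), "M1-3", seed = 7))
#' dplyr::count(co$trials, subject_id)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "chick_cohort_spec"))
  ms <- spec$model
  pt <- ms$params
  withr::with_seed(spec$seed, {
    ids <- sprintf("s%03d", seq_len(spec$n_subjects))
    raw <- vapply(pt$param, function(p) {
      rnorm(spec$n_subjects, spec$group_means[[p]], spec$group_sds[[p]])
    }, numeric(spec$n_subjects))
    raw <- matrix(raw, nrow = spec$n_subjects,
                  dimnames = list(NULL, pt$param))
    nat <- raw
    for (j in seq_len(ncol(nat))) {
      nat[, j] <- transform_to_bounds(raw[, j], pt$lower[j], pt$upper[j])
    }
    sessions <- lapply(seq_len(spec$n_subjects), function(i) {
      simulate_session(ms, nat[i, ], spec$design,
                       subject_id = ids[i], group = spec$group,
                       first = if (i %% 2 == 1) "HCO" else "LCO")
    })
    trials <- dplyr::bind_rows(sessions)
    attr(trials, "design") <- spec$design
    attr(trials, "payoff") <- spec$design$payoff
    params <- tibble::as_tibble(nat)
    params$subject_id <- ids
    params <- dplyr::relocate(params, "subject_id")
    structure(list(trials = trials, params = params, spec = spec),
              class = "rl_cohort")
  })
}

#' @export
print.rl_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d trials, model %s (%s)\n",
              x$spec$n_subjects, x$spec$design$n_trials, x$spec$model$name,
              x$spec$design$study))
  invisible(x)
}

#' Block-wise cooperation rates
#'
#' The proportion of swerve choices per subject, opponent and analysis
#' block. Blocks with no trials for an opponent yield a missing rate.
#'
#' @param trials A trial tibble (any number of subjects).
#' @return A tibble with `subject_id`, `opponent`, `block`, `n_trials`,
#'   `swerve_rate`.
#' @export
block_cooperation_rates <- function(trials) {
  stopifnot(nrow(trials) > 0)
  trials |>
    dplyr::group_by(.data$subject_id, .data$opponent, .data$block) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     swerve_rate = mean(.data$choice == "swerve"),
                     .groups = "drop") |>
    tidyr::complete(.data$subject_id, .data$opponent, .data$block,
                    fill = list(n_trials = 0L, swerve_rate = NA_real_))
}
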