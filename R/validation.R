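#' Posterior predictive check
#'
#' Simulates choice data from the fitted posterior and correlates the
#' simulated cooperation-rate series with the observed one at the trial
#' level, separately per opponent. For each replicate, one retained
#' posterior draw is sampled per subject and the subject's session is
#' re-played against the recorded opponent-choice sequence (the opponent's
#' behaviour is conditioned on, isolating the participant model); the
#' model's per-trial swerve probabilities are averaged across subjects at
#' each within-opponent trial position and then across replicates.
#'
#' `mode = "draws"` integrates over the posterior (fresh draws each
#' replicate); `mode = "point"` uses the posterior-mean parameters for every
#' replicate.
#'
#' @param fit An `rl_fit`.
#' @param trials Trial data to check against; defaults to the fitted data.
#' @param n_replicates Number of posterior replicates.
#' @param seed Integer seed.
#' @param mode `"draws"` or `"point"`.
#' @return An `rl_ppc` with per-opponent correlations `r_HCO`, `r_LCO`
#'   (missing, with a reason, when either series has zero variance) and the
#'   observed/simulated series.
#' @export
posterior_predictive_check <- function(fit, trials = NULL, n_replicates = 100,
                                       seed = NULL,
                                       mode = c("draws", "point")) {
  stopifnot(inherits(fit, "rl_fit"))
  mode <- match.arg(mode)
  trials <- trials %||% fit$data
  trials <- dplyr::arrange(trials, .data$subject_id, .data$trial_index)
  spec <- fit$model
  pt <- spec$params
  K <- nrow(pt)
  ids <- fit$subject_ids
  nat <- fit$draws[, -(seq_len(2 * K)), drop = FALSE]
  nat_mean <- colMeans(nat)

  # within-opponent trial position per row
  trials <- trials |>
    dplyr::group_by(.data$subject_id, .data$opponent) |>
    dplyr::mutate(.opp_pos = dplyr::row_number()) |>
    dplyr::ungroup()

  by_subj <- split(trials, factor(trials$subject_id, levels = ids))
  sims <- with_seed_if(seed, {
    lapply(seq_len(n_replicates), function(r) {
      p_all <- numeric(nrow(trials))
      pos <- 1
      for (s in seq_along(ids)) {
        ts <- by_subj[[s]]
        draw <- if (mode == "draws") sample.int(nrow(nat), 1) else 0
        params <- if (mode == "point") {
          setNames(nat_mean[paste0(pt$param, "[", ids[s], "]")], pt$param)
        } else {
          setNames(nat[draw, paste0(pt$param, "[", ids[s], "]")], pt$param)
        }
        sim <- forward_sim(spec, params, opponent_to_int(ts$opponent),
                           fit$payoff, fit$reward_scale,
                           opp_choice_int = choice_to_int(ts$opponent_choice))
        p_all[pos:(pos + nrow(ts) - 1)] <- sim$p_swerve
        pos <- pos + nrow(ts)
      }
      p_all
    })
  })
  trials$.p_sim <- Reduce(`+`, sims) / n_replicates

  series <- trials |>
    dplyr::group_by(.data$opponent, .data$.opp_pos) |>
    dplyr::summarise(observed = mean(.data$choice == "swerve"),
                     simulated = mean(.data$.p_sim), .groups = "drop")

  cors <- lapply(OPPONENTS, function(o) {
    s <- series[series$opponent == o, ]
    if (nrow(s) < 3 || sd(s$observed) < 1e-12 || sd(s$simulated) < 1e-12) {
      list(r = NA_real_,
           note = "zero variance in observed or simulated series")
    } else {
      list(r = cor(s$observed, s$simulated), note = NA_character_)
    }
  })
  names(cors) <- OPPONENTS
  structure(list(
    model = spec$name, r_HCO = cors$HCO$r, r_LCO = cors$LCO$r,
    notes = c(HCO = cors$HCO$note, LCO = cors$LCO$note),
    series = series, n_replicates = n_replicates, mode = mode),
    class = "rl_ppc")
}

#' @export
print.rl_ppc <- function(x, ...) {
  cat(sprintf("Posterior predictive check for %s (%d replicates, %s mode)\n",
              x$model, x$n_replicates, x$mode))
  cat(sprintf("  trial-level r: HCO = %s, LCO = %s\n",
              format(x$r_HCO, digits = 3), format(x$r_LCO, digits = 3)))
  bad <- !is.na(x$notes)
  if (any(bad)) cat("  note:", paste(names(x$notes)[bad], x$notes[bad],
                                     collapse = "; "), "\n")
  invisible(x)
}

#' @export
tidy.rl_ppc <- function(x, ...) x$series

#' @export
glance.rl_ppc <- function(x, ...) {
  tibble::tibble(model = x$model, r_HCO = x$r_HCO, r_LCO = x$r_LCO,
                 n_replicates = x$n_replicates, mode = x$mode)
}

#' Model recovery
#'
#' Simulates cohorts from each generating model, fits every candidate model
#' to each synthetic dataset, and tallies how often each candidate wins by
#' LOOIC: a confusion matrix whose diagonal dominance indicates that the
#' bank's models are mutually distinguishable at the given design and
#' cohort size.
#'
#' @param models Character vector of bank model names used both as
#'   generators and candidates.
#' @param design A [make_design()] object.
#' @param n_subjects Subjects per synthetic cohort.
#' @param n_datasets_per_model Synthetic datasets per generating model.
#' @param config [sampler_preset()] used for the (many) fits; the reduced
#'   preset is the intended choice here.
#' @param group_means,group_sds Optional raw-scale group parameter settings
#'   passed to [cohort_spec()].
#' @param seed Integer seed.
#' @return An `rl_recovery` with the confusion `matrix` (rows = generating
#'   model, columns = best-fitting model, rows sum to 1), a long `table`,
#'   and a per-dataset `log`.
#' @export
model_recovery <- function(models, design, n_subjects = 15,
                           n_datasets_per_model = 10,
                           config = sampler_preset("ci"),
                           group_means = NULL, group_sds = NULL, seed = 1L) {
  stopifnot(length(models) >= 2, n_datasets_per_model >= 1)
  seeds <- withr::with_seed(seed, matrix(
    sample.int(2^31 - 1, 2 * length(models) * n_datasets_per_model),
    ncol = 2))
  wins <- matrix(0, length(models), length(models),
                 dimnames = list(generator = models, winner = models))
  log <- list()
  row <- 0
  for (gi in seq_along(models)) {
    for (d in seq_len(n_datasets_per_model)) {
      row <- row + 1
      co <- generate_cohort(cohort_spec(n_subjects, design, models[gi],
                                        group_means = group_means,
                                        group_sds = group_sds,
                                        seed = seeds[row, 1]))
      looic <- rep(NA_real_, length(models))
      for (mi in seq_along(models)) {
        fit_seed <- (seeds[row, 2] + mi) %% (2^31 - 1)
        fit <- try(fit_hierarchical(co$trials, models[mi], config = config,
                                    seed = fit_seed), silent = TRUE)
        if (inherits(fit, "try-error")) next
        looic[mi] <- psis_loo(fit)$looic
      }
      if (all(is.na(looic))) {
        log[[row]] <- tibble::tibble(generator = models[gi], dataset = d,
                                     winner = NA_character_,
                                     status = "all fits failed")
        next
      }
      win <- models[which.min(looic)]
      wins[gi, win] <- wins[gi, win] + 1
      log[[row]] <- tibble::tibble(generator = models[gi], dataset = d,
                                   winner = win, status = "ok")
    }
  }
  prob <- sweep(wins, 1, pmax(rowSums(wins), 1), "/")
  table <- tibble::as_tibble(as.data.frame.table(prob, responseName = "prob"))
  structure(list(matrix = prob, counts = wins, table = table,
                 log = dplyr::bind_rows(log),
                 n_datasets_per_model = n_datasets_per_model),
            class = "rl_recovery")
}

#' @export
print.rl_recovery <- function(x, ...) {
  cat("Model recovery confusion matrix (rows: generating model)\n")
  print(round(x$matrix, 2))
  invisible(x)
}

#' @export
tidy.rl_recovery <- function(x, ...) x$table

#' Parameter recovery
#'
#' Repeatedly samples ground-truth group-level parameters uniformly from
#' declared ranges, simulates a cohort, refits the same model, and
#' correlates the recovered posterior means of the group-level parameters
#' with the truths across iterations. The study's procedure uses 30
#' iterations; fewer can be requested for desk-scale checks.
#'
#' @param model Model name or [model_spec()].
#' @param design A [make_design()] object.
#' @param n_subjects Subjects per simulated cohort.
#' @param n_iterations Number of simulate-and-refit iterations (>= 2).
#' @param ranges Optional named list of `c(lower, upper)` natural-scale
#'   ranges for the uniform ground-truth draws; defaults to each bounded
#'   parameter's declared range and `[-1, 1]` for the unbounded swerve
#'   preference (matching its standard-normal prior mass).
#' @param group_sd_raw Raw-scale between-subject spread of the simulated
#'   cohorts.
#' @param config [sampler_preset()] for the refits.
#' @param seed Integer seed.
#' @return An `rl_param_recovery` with per-parameter correlations and the
#'   per-iteration truth/recovered records.
#' @export
parameter_recovery <- function(model, design, n_subjects = 40,
                               n_iterations = 30, ranges = NULL,
                               group_sd_raw = 0.4,
                               config = sampler_preset("ci"), seed = 1L) {
  spec <- model_spec(model)
  stopifnot(n_iterations >= 2)
  pt <- spec$params
  default_range <- function(p, lo, hi) {
    if (is.finite(lo)) c(lo, hi) else c(-1, 1)
  }
  rng <- lapply(seq_len(nrow(pt)),
                function(j) default_range(pt$param[j], pt$lower[j], pt$upper[j]))
  names(rng) <- pt$param
  if (!is.null(ranges)) rng[names(ranges)] <- ranges
  degenerate <- vapply(rng, function(r) diff(range(r)) <= 0, TRUE)

  seeds <- withr::with_seed(seed, matrix(
    sample.int(2^31 - 1, 3 * n_iterations), ncol = 3))
  recs <- list()
  for (it in seq_len(n_iterations)) {
    truth_nat <- withr::with_seed(seeds[it, 1], vapply(rng, function(r) {
      runif(1, r[1], r[2])
    }, 0))
    truth_raw <- vapply(seq_len(nrow(pt)), function(j) {
      bounds_to_raw(truth_nat[[j]], pt$lower[j], pt$upper[j])
    }, 0)
    co <- generate_cohort(cohort_spec(
      n_subjects, design, spec, group_means = setNames(truth_raw, pt$param),
      group_sds = setNames(rep(group_sd_raw, nrow(pt)), pt$param),
      seed = seeds[it, 2]))
    fit <- try(fit_hierarchical(co$trials, spec, config = config,
                                seed = seeds[it, 3], pointwise = FALSE),
               silent = TRUE)
    if (inherits(fit, "try-error")) {
      recs[[it]] <- tibble::tibble(iteration = it, param = pt$param,
                                   truth = unname(truth_nat),
                                   recovered = NA_real_, status = "fit failed")
      next
    }
    est <- tidy(fit, level = "group")
    recovered <- est$estimate[match(pt$param, est$term)]
    recs[[it]] <- tibble::tibble(iteration = it, param = pt$param,
                                 truth = unname(truth_nat),
                                 recovered = recovered, status = "ok")
  }
  records <- dplyr::bind_rows(recs)
  cors <- records |>
    dplyr::filter(.data$status == "ok") |>
    dplyr::group_by(.data$param) |>
    dplyr::summarise(
      correlation = if (dplyr::n() >= 2 && sd(.data$truth) > 1e-12 &&
                        sd(.data$recovered) > 1e-12)
        cor(.data$truth, .data$recovered) else NA_real_,
      n_ok = dplyr::n(), .groups = "drop")
  cors$degenerate_range <- degenerate[cors$param]
  structure(list(model = spec$name, correlations = cors, records = records,
                 n_iterations = n_iterations),
            class = "rl_param_recovery")
}

#' @export
print.rl_param_recovery <- function(x, ...) {
  cat(sprintf("Parameter recovery for %s (%d iterations)\n", x$model,
              x$n_iterations))
  print(x$correlations)
  invisible(x)
}

#' @export
tidy.rl_param_recovery <- function(x, ...) x$correlations
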