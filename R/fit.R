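#' Map unbounded draws into parameter bounds
#'
#' The probit transform used throughout simulation and inference: a raw
#' unconstrained value is mapped to `lower + (upper - lower) * pnorm(raw)`.
#' Unbounded parameters (the swerve preference) pass through unchanged.
#' `bounds_to_raw()` is the inverse; natural values are nudged off the exact
#' bounds before `qnorm` so the inverse stays finite.
#'
#' @param raw Numeric vector of unconstrained values.
#' @param lower,upper Bounds (`-Inf`/`Inf` for unbounded).
#' @return Numeric vector on the natural scale.
#' @examples
#' transform_to_bounds(0, 0, 10)  # midpoint: 5
#' @export
transform_to_bounds <- function(raw, lower, upper) {
  if (!is.finite(lower) || !is.finite(upper)) return(raw)
  stopifnot(lower < upper)
  lower + (upper - lower) * pnorm(raw)
}

#' @rdname transform_to_bounds
#' @param value Natural-scale values to map back.
#' @export
bounds_to_raw <- function(value, lower, upper) {
  if (!is.finite(lower) || !is.finite(upper)) return(value)
  stopifnot(lower < upper)
  u <- (value - lower) / (upper - lower)
  qnorm(pmin(pmax(u, 0.005), 0.995))
}

#' Sampler presets
#'
#' `"full"` reproduces the study's sampler settings: 4 chains of 3000 warmup
#' and 1000 retained iterations (4000 draws). `"ci"` is a reduced preset for
#' desk-scale work: 2 chains of 500/500.
#'
#' @param preset `"full"` or `"ci"`, or pass the three counts directly.
#' @param chains,warmup,iter Optional overrides.
#' @return A `chick_sampler_config` list.
#' @export
sampler_preset <- function(preset = c("full", "ci"), chains = NULL,
                           warmup = NULL, iter = NULL) {
  preset <- match.arg(preset)
  cfg <- if (preset == "full") list(chains = 4L, warmup = 3000L, iter = 1000L)
         else list(chains = 2L, warmup = 500L, iter = 500L)
  cfg$chains <- as.integer(chains %||% cfg$chains)
  cfg$warmup <- as.integer(warmup %||% cfg$warmup)
  cfg$iter <- as.integer(iter %||% cfg$iter)
  cfg$preset <- preset
  if (cfg$chains < 1 || cfg$warmup < 0 || cfg$iter < 1) {
    stop("invalid sampler configuration", call. = FALSE)
  }
  structure(cfg, class = "chick_sampler_config")
}

#' Hierarchical prior specification
#'
#' One `(mu, sigma)` hyperparameter pair per free parameter: group mean
#' `mu ~ Normal(0, mu_scale)` and group spread `sigma ~ half-Cauchy(0,
#' sigma_scale)`, with defaults 1 and 3.
#'
#' @param model A model name or [model_spec()].
#' @param mu_scale,sigma_scale Positive prior scales, recycled across
#'   parameters.
#' @return A tibble with one row per free parameter.
#' @export
hier_prior <- function(model, mu_scale = 1, sigma_scale = 3) {
  spec <- model_spec(model)
  stopifnot(all(mu_scale > 0), all(sigma_scale > 0))
  tibble::tibble(param = spec$params$param,
                 mu_scale = rep_len(mu_scale, nrow(spec$params)),
                 sigma_scale = rep_len(sigma_scale, nrow(spec$params)))
}

#' Fit a model to a cohort by hierarchical MCMC
#'
#' Estimates a bank model on multi-subject trial data with a non-centered
#' hierarchy: subject-level raw parameters are `mu + sigma * z`, mapped into
#' their bounds by the probit transform, with `mu ~ N(0, 1)` and
#' `sigma ~ half-Cauchy(0, 3)` by default. Posterior sampling uses
#' univariate slice sampling within a Gibbs sweep. Per-draw, per-trial
#' log-likelihoods of the observed choices are retained for PSIS-LOO.
#'
#' @param data A trial tibble covering one or more subjects (see
#'   [simulate_session()] / [read_trials()]).
#' @param model A model name or [model_spec()].
#' @param payoff A [payoff_matrix()]; defaults to the data's attribute.
#' @param config A [sampler_preset()]; default is the full preset.
#' @param prior A [hier_prior()] tibble.
#' @param seed Integer seed. If omitted, one is drawn and recorded in the
#'   result.
#' @param reward_scale Reward divisor for the delta-rule update; defaults to
#'   the data's design attribute, else 1.
#' @param pointwise Keep the draws x trials pointwise log-likelihood matrix
#'   (needed for LOO; disable to save memory in large recovery loops).
#' @return An `rl_fit` object; see [tidy.rl_fit()], [glance.rl_fit()],
#'   [check_convergence()], [psis_loo()].
#' @export
fit_hierarchical <- function(data, model, payoff = NULL,
                             config = sampler_preset("full"),
                             prior = NULL, seed = NULL, reward_scale = NULL,
                             pointwise = TRUE) {
  spec <- model_spec(model)
  stopifnot(inherits(config, "chick_sampler_config"))
  payoff <- payoff %||% attr(data, "payoff") %||% payoff_study1()
  reward_scale <- reward_scale %||% attr(data, "design")$reward_scale %||% 1
  prior <- prior %||% hier_prior(spec)
  stopifnot(nrow(data) > 0)
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)

  data <- dplyr::arrange(data, .data$subject_id, .data$trial_index)
  ids <- unique(data$subject_id)
  S <- length(ids)
  counts <- as.integer(table(factor(data$subject_id, levels = ids)))
  offsets <- c(0L, cumsum(counts))
  pt <- spec$params
  pr <- prior[match(pt$param, prior$param), ]
  ab <- ev_coefs(payoff)

  res <- withr::with_seed(seed, cpp_fit_hier(
    spec$codes, offsets, opponent_to_int(data$opponent),
    choice_to_int(data$choice), choice_to_int(data$opponent_choice),
    as.numeric(data$reward), pt$lower, pt$upper, as.integer(pt$bounded),
    pr$mu_scale, pr$sigma_scale, ab[["A"]], ab[["B"]], reward_scale,
    config$chains, config$warmup, config$iter))

  K <- nrow(pt)
  colnames(res$mu) <- paste0("mu_", pt$param)
  colnames(res$sigma) <- paste0("sigma_", pt$param)
  colnames(res$nat) <- paste0(rep(pt$param, times = S), "[",
                              rep(ids, each = K), "]")
  draws <- cbind(res$mu, res$sigma, res$nat)

  fit <- structure(list(
    model = spec, draws = draws, chain = res$chain,
    subject_ids = ids, param_names = pt$param, config = config,
    prior = pr, seed = seed, payoff = payoff, reward_scale = reward_scale,
    data = data, offsets = offsets, diagnostics = NULL,
    pointwise_ll = NULL), class = "rl_fit")

  fit$diagnostics <- convergence_table(fit)
  if (pointwise) {
    fit$pointwise_ll <- compute_pointwise(fit)
  }
  fit
}

compute_pointwise <- function(fit) {
  pt <- fit$model$params
  ab <- ev_coefs(fit$payoff)
  nat <- fit$draws[, -(seq_len(2 * nrow(pt))), drop = FALSE]
  ll <- cpp_pointwise_ll(
    fit$model$codes, nat, fit$offsets,
    opponent_to_int(fit$data$opponent), choice_to_int(fit$data$choice),
    choice_to_int(fit$data$opponent_choice), as.numeric(fit$data$reward),
    nrow(pt), ab[["A"]], ab[["B"]], fit$reward_scale)
  attr(ll, "obs") <- tibble::tibble(subject_id = fit$data$subject_id,
                                    trial_index = fit$data$trial_index)
  ll
}

#' @export
print.rl_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("Hierarchical fit of %s: %d subjects, %d trials, %d draws (%d chains)\n",
              x$model$name, g$n_subjects, g$n_trials, g$n_draws, g$n_chains))
  cat(sprintf("max split-Rhat = %.3f (%s)\n", g$max_rhat,
              if (g$converged) "converged" else "NOT converged"))
  print(tidy(x))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Convergence diagnostics
# ---------------------------------------------------------------------------

# Split-Rhat of one parameter: each chain is halved, then the usual
# between/within variance ratio is computed over the 2 * n_chains pieces.
split_rhat_vec <- function(x, chain) {
  pieces <- list()
  for (c in unique(chain)) {
    xc <- x[chain == c]
    n <- length(xc)
    half <- floor(n / 2)
    pieces <- c(pieces, list(xc[seq_len(half)], xc[(n - half + 1):n]))
  }
  n <- min(lengths(pieces))
  pieces <- lapply(pieces, function(p) p[seq_len(n)])
  m <- length(pieces)
  means <- vapply(pieces, mean, 0)
  vars <- vapply(pieces, var, 0)
  W <- mean(vars)
  B_over_n <- var(means)
  if (!is.finite(W) || W <= 1e-300) return(1)
  sqrt(((n - 1) / n * W + B_over_n) / W)
}

# Effective sample size via Geyer's initial positive sequence, pooled over
# chains (rank-free classic version).
ess_vec <- function(x, chain) {
  chains <- lapply(unique(chain), function(c) x[chain == c])
  n <- min(lengths(chains))
  chains <- lapply(chains, function(p) p[seq_len(n)] - mean(p[seq_len(n)]))
  if (n < 4) return(NA_real_)
  max_lag <- min(n - 2, 500)
  acov <- sapply(chains, function(xc) {
    sapply(0:max_lag, function(l) {
      sum(xc[seq_len(n - l)] * xc[(1 + l):n]) / n
    })
  })
  acov <- rowMeans(as.matrix(acov))
  if (acov[1] <= 1e-300) return(length(x))
  rho <- acov / acov[1]
  s <- 0
  lag <- 1
  while (lag + 1 <= length(rho)) {
    pair <- rho[lag + 1] + (if (lag + 2 <= length(rho)) rho[lag + 2] else 0)
    if (pair < 0) break
    s <- s + pair
    lag <- lag + 2
  }
  ess <- length(x) / (1 + 2 * s)
  min(ess, length(x))
}

convergence_table <- function(fit) {
  draws <- fit$draws
  tibble::tibble(
    param = colnames(draws),
    rhat = apply(draws, 2, split_rhat_vec, chain = fit$chain),
    ess = apply(draws, 2, ess_vec, chain = fit$chain))
}

#' Convergence check by split-Rhat
#'
#' Computes split-Rhat for every group- and subject-level parameter and
#' declares convergence when the maximum is below the threshold (1.1, the
#' usual rule for this class of model).
#'
#' @param fit An `rl_fit`.
#' @param threshold Convergence bound on split-Rhat.
#' @return A list with `pass` (logical), `max_rhat` and the per-parameter
#'   `table`.
#' @export
check_convergence <- function(fit, threshold = 1.1) {
  stopifnot(inherits(fit, "rl_fit"))
  if (length(unique(fit$chain)) < 2) {
    stop("split-Rhat needs at least 2 chains", call. = FALSE)
  }
  tab <- fit$diagnostics %||% convergence_table(fit)
  max_rhat <- max(tab$rhat)
  list(pass = max_rhat < threshold, max_rhat = max_rhat, table = tab)
}

#' Pointwise log-likelihood array
#'
#' Per-draw log-likelihood of every observed choice, reshaped to a
#' draws x subjects x trials array when all subjects share a session length
#' (otherwise the draws x observations matrix with an `obs` attribute).
#'
#' @param fit An `rl_fit` fitted with `pointwise = TRUE`.
#' @return A 3-d array or matrix of log-probabilities.
#' @export
extract_pointwise_ll <- function(fit) {
  stopifnot(inherits(fit, "rl_fit"))
  ll <- fit$pointwise_ll %||% compute_pointwise(fit)
  counts <- diff(fit$offsets)
  if (length(unique(counts)) == 1) {
    arr <- array(ll, dim = c(nrow(ll), counts[1], length(fit$subject_ids)))
    arr <- aperm(arr, c(1, 3, 2))
    dimnames(arr) <- list(NULL, fit$subject_ids, NULL)
    return(arr)
  }
  ll
}

#' @describeIn fit_hierarchical Posterior summaries. `level = "group"` gives
#'   the hyperparameters (raw-scale `mu_*`, spreads `sigma_*`) plus the
#'   natural-scale group location `<param>` obtained by averaging the
#'   transformed group mean over draws; `level = "subject"` the per-subject
#'   natural-scale parameters.
#' @param x An `rl_fit`.
#' @param level `"group"` or `"subject"`.
#' @param ... Unused.
#' @export
tidy.rl_fit <- function(x, level = c("group", "subject"), ...) {
  level <- match.arg(level)
  pt <- x$model$params
  K <- nrow(pt)
  if (level == "group") {
    cols <- x$draws[, seq_len(2 * K), drop = FALSE]
    loc <- vapply(seq_len(K), function(k) {
      transform_to_bounds(x$draws[, k], pt$lower[k], pt$upper[k])
    }, numeric(nrow(x$draws)))
    colnames(loc) <- pt$param
    cols <- cbind(cols, loc)
  } else {
    cols <- x$draws[, -(seq_len(2 * K)), drop = FALSE]
  }
  diag <- x$diagnostics
  tibble::tibble(
    term = colnames(cols),
    estimate = colMeans(cols),
    std.error = apply(cols, 2, sd),
    conf.low = apply(cols, 2, quantile, 0.025),
    conf.high = apply(cols, 2, quantile, 0.975),
    rhat = diag$rhat[match(colnames(cols), diag$param)],
    ess = diag$ess[match(colnames(cols), diag$param)])
}

#' @describeIn fit_hierarchical One-row fit summary.
#' @export
glance.rl_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name, family = x$model$family_group,
    n_subjects = length(x$subject_ids), n_trials = nrow(x$data),
    n_draws = nrow(x$draws), n_chains = length(unique(x$chain)),
    max_rhat = max(x$diagnostics$rhat),
    converged = max(x$diagnostics$rhat) < 1.1, seed = x$seed)
}

#' Serialize / restore a fit
#'
#' Writes the posterior draws, diagnostics and configuration of a fit to a
#' directory of plain-text files (CSV + JSON), and reads them back. The
#' trial data and pointwise log-likelihoods are not serialized; re-fit or
#' keep the original object where LOO is still needed.
#'
#' @param fit An `rl_fit`.
#' @param dir Target directory (created if missing).
#' @return `write_fit()` the directory path, invisibly; `read_fit()` a list
#'   with `draws`, `chain`, `diagnostics`, `config`.
#' @export
write_fit <- function(fit, dir) {
  stopifnot(inherits(fit, "rl_fit"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(tibble::as_tibble(fit$draws), file.path(dir, "draws.csv"))
  readr::write_csv(fit$diagnostics, file.path(dir, "diagnostics.csv"))
  meta <- list(model = fit$model$name, seed = fit$seed,
               chains = fit$config$chains, warmup = fit$config$warmup,
               iter = fit$config$iter, chain = fit$chain,
               subject_ids = fit$subject_ids,
               payoff = as.list(unclass(fit$payoff)),
               reward_scale = fit$reward_scale,
               package_version = as.character(utils::packageVersion("chickrl")),
               timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(meta, file.path(dir, "config.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_fit
#' @export
read_fit <- function(dir) {
  draws <- as.matrix(readr::read_csv(file.path(dir, "draws.csv"),
                                     show_col_types = FALSE))
  diagnostics <- readr::read_csv(file.path(dir, "diagnostics.csv"),
                                 show_col_types = FALSE)
  config <- jsonlite::read_json(file.path(dir, "config.json"),
                                simplifyVector = TRUE)
  list(draws = draws, chain = config$chain, diagnostics = diagnostics,
       config = config)
}
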