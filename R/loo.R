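#' Pareto-smoothed importance-sampling LOO
#'
#' Leave-one-out expected log predictive density (elpd) per observation
#' (one observation = one trial), estimated from posterior draws by
#' importance sampling with Pareto-smoothed weights: the largest importance
#' ratios of each observation are replaced by expected order statistics of a
#' generalized Pareto distribution fitted to the tail (Zhang-Stephens
#' estimator with a weak shape prior), then truncated at the raw maximum.
#' `looic = -2 * elpd_loo`. Observations whose Pareto shape exceeds 0.7 are
#' flagged as unreliable.
#'
#' @param x An `rl_fit` (fitted with `pointwise = TRUE`) or a draws x
#'   observations matrix of pointwise log-likelihoods.
#' @param model Optional model label for the summary.
#' @param ... Unused.
#' @return An `rl_loo` object with `elpd_loo`, `se_elpd_loo`, `looic`,
#'   `se_looic`, a `pointwise` tibble (`elpd_i`, `pareto_k`) and `n_bad_k`.
#' @export
psis_loo <- function(x, model = NULL, ...) {
  if (inherits(x, "rl_fit")) {
    model <- model %||% x$model$name
    ll <- x$pointwise_ll %||% compute_pointwise(x)
  } else {
    ll <- x
  }
  if (!all(is.finite(ll))) stop("non-finite pointwise log-likelihoods",
                                call. = FALSE)
  N <- ncol(ll)
  elpd_i <- numeric(N)
  k_i <- numeric(N)
  for (i in seq_len(N)) {
    p <- psis_smooth(-ll[, i])     # log importance ratios are -log p(y_i | theta)
    lw <- p$lw - logsumexp(p$lw)   # normalized log weights
    elpd_i[i] <- logsumexp(lw + ll[, i])
    k_i[i] <- p$k
  }
  elpd <- sum(elpd_i)
  se <- sqrt(N * var(elpd_i))
  structure(list(
    model = model %||% "model", elpd_loo = elpd, se_elpd_loo = se,
    looic = -2 * elpd, se_looic = 2 * se,
    pointwise = tibble::tibble(elpd_i = elpd_i, pareto_k = k_i),
    n_bad_k = sum(k_i > 0.7), n_obs = N, n_draws = nrow(ll)),
    class = "rl_loo")
}

#' @export
print.rl_loo <- function(x, ...) {
  cat(sprintf("PSIS-LOO for %s: elpd_loo = %.2f (SE %.2f), looic = %.2f\n",
              x$model, x$elpd_loo, x$se_elpd_loo, x$looic))
  if (x$n_bad_k > 0) {
    cat(sprintf("  %d of %d observations with Pareto k > 0.7\n",
                x$n_bad_k, x$n_obs))
  }
  invisible(x)
}

#' @export
glance.rl_loo <- function(x, ...) {
  tibble::tibble(model = x$model, elpd_loo = x$elpd_loo,
                 se_elpd_loo = x$se_elpd_loo, looic = x$looic,
                 se_looic = x$se_looic, n_bad_k = x$n_bad_k,
                 n_obs = x$n_obs)
}

# Pareto-smooth one vector of log importance ratios; returns unnormalized
# log weights and the fitted tail shape (-Inf when the ratios are constant
# or the tail is too short to fit).
psis_smooth <- function(lr) {
  S <- length(lr)
  lr <- lr - max(lr)
  M <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  if (diff(range(lr)) < 1e-12 || M < 5) {
    return(list(lw = lr, k = -Inf))
  }
  ord <- order(lr)
  tail_ids <- ord[(S - M + 1):S]
  cutoff <- lr[ord[S - M]]
  exc <- exp(lr[tail_ids]) - exp(cutoff)
  if (max(exc) <= 0) return(list(lw = lr, k = -Inf))
  fit <- gpd_fit(exc)
  if (is.finite(fit$k)) {
    pr <- (seq_len(M) - 0.5) / M
    qq <- qgpd(pr, fit$k, fit$sigma) + exp(cutoff)
    lr[tail_ids[order(lr[tail_ids])]] <- log(qq)
    lr <- pmin(lr, 0)
  }
  list(lw = lr, k = fit$k)
}

# Zhang & Stephens (2009) profile-posterior estimator of the generalized
# Pareto shape/scale, with the weak shape regularization used in standard
# LOO practice.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  if (n < 5 || x[n] <= 0) return(list(k = -Inf, sigma = NA_real_))
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  xstar <- x[max(1, floor(n / 4 + 0.5))]
  if (xstar <= 0) xstar <- x[n] / 2
  theta <- 1 / x[n] + (1 - sqrt(m / (jj - 0.5))) / (3 * xstar)
  k_j <- vapply(theta, function(th) -mean(log1p(-th * x)), 0)
  l_j <- n * (log(theta / k_j) + k_j - 1)
  ok <- is.finite(l_j)
  if (!any(ok)) return(list(k = -Inf, sigma = NA_real_))
  w <- exp(l_j[ok] - logsumexp(l_j[ok]))
  theta_hat <- sum(theta[ok] * w)
  k <- mean(log1p(-theta_hat * x))
  sigma <- -k / theta_hat
  # weak prior pulling the shape toward 0.5 in small tails
  k <- (k * n + 5) / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

#' Stacking weights
#'
#' Simplex-constrained weights over models maximizing the summed log of the
#' weighted leave-one-out predictive density,
#' `sum_i log( sum_m w_m exp(elpd_im) )`. Optimization runs on the softmax
#' scale starting from uniform weights, so exactly tied models keep the
#' uniform split.
#'
#' @param x A list of `rl_loo` objects, `rl_fit` objects, or pointwise
#'   log-likelihood matrices sharing the same observations.
#' @return Named numeric vector of weights (non-negative, summing to 1).
#' @export
stacking_weights <- function(x) {
  lpd <- pointwise_elpd_matrix(x)
  M <- ncol(lpd)
  if (M < 2) stop("stacking needs at least two models", call. = FALSE)
  obj <- function(eta) {
    w <- softmax(c(0, eta))
    -sum(apply(lpd, 1, function(r) logsumexp(r + log(w))))
  }
  eta0 <- rep(0, M - 1)
  opt <- optim(eta0, obj, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-12))
  w <- softmax(c(0, opt$par))
  setNames(w, colnames(lpd))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# obs x models matrix of pointwise LOO elpd values
pointwise_elpd_matrix <- function(x) {
  stopifnot(is.list(x), length(x) >= 1)
  cols <- lapply(seq_along(x), function(i) {
    xi <- x[[i]]
    if (inherits(xi, "rl_fit")) xi <- psis_loo(xi)
    if (inherits(xi, "rl_loo")) return(xi$pointwise$elpd_i)
    psis_loo(xi)$pointwise$elpd_i
  })
  n <- unique(lengths(cols))
  if (length(n) != 1) stop("models were evaluated on different observation sets",
                           call. = FALSE)
  out <- do.call(cbind, cols)
  colnames(out) <- names(x) %||% paste0("model", seq_along(x))
  out
}

#' Family-level model comparison
#'
#' Reproduces the two-stage selection logic: the learning-model families
#' (reward M1, belief M2, second-order M3) are first aggregated internally
#' by stacking, the stacked leave-one-out predictive score of each family is
#' compared across families, and the winning family's member with the
#' lowest LOOIC is selected. The non-learning (M0) and preference-only (M4)
#' baselines are reported alongside but never win the family contest.
#' Pairwise elpd differences against the best model are reported with
#' standard errors and flagged non-decisive when smaller than twice their
#' SE.
#'
#' @param fits Named list of `rl_fit` objects (names default to each fit's
#'   model) sharing the same data; precomputed `rl_loo` objects are also
#'   accepted (names must be bank model labels).
#' @return An `rl_comparison` with a per-model `table`, per-family
#'   `families` scores, `selected_family`, `selected_model` and a `tie`
#'   flag (ties are reported, not broken).
#' @export
family_comparison <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 1)
  if (is.null(names(fits)) || any(names(fits) == "")) {
    names(fits) <- vapply(fits, function(f) {
      if (inherits(f, "rl_fit")) f$model$name else stop("unnamed non-fit input")
    }, "")
  }
  loos <- lapply(names(fits), function(nm) {
    xi <- fits[[nm]]
    if (inherits(xi, "rl_loo")) {
      xi$model <- nm
      xi
    } else {
      psis_loo(xi, model = nm)
    }
  })
  names(loos) <- names(fits)
  n_obs <- unique(vapply(loos, function(l) l$n_obs, 0))
  if (length(n_obs) != 1) stop("fits cover different observation sets",
                               call. = FALSE)

  tab <- dplyr::bind_rows(lapply(loos, glance))
  tab$family <- vapply(tab$model, function(m) model_spec(m)$family_group, "")

  elpd_mat <- vapply(loos, function(l) l$pointwise$elpd_i, numeric(n_obs))

  # within-family stacking over the learning families present
  learn_fams <- intersect(c("M1", "M2", "M3"), unique(tab$family))
  fam_scores <- lapply(learn_fams, function(fam) {
    members <- tab$model[tab$family == fam]
    if (length(members) == 1) {
      w <- setNames(1, members)
    } else {
      w <- stacking_weights(loos[members])
    }
    lpd <- elpd_mat[, members, drop = FALSE]
    score <- sum(apply(lpd, 1, function(r) logsumexp(r + log(w + 1e-300))))
    list(family = fam, score = score, weights = w)
  })
  families <- tibble::tibble(
    family = vapply(fam_scores, `[[`, "", "family"),
    stacked_lpd = vapply(fam_scores, `[[`, 0, "score"))

  tab$stack_weight_within_family <- NA_real_
  for (fs in fam_scores) {
    tab$stack_weight_within_family[match(names(fs$weights), tab$model)] <-
      unname(fs$weights)
  }
  tab$stack_weight_all <- if (nrow(tab) >= 2) {
    unname(stacking_weights(loos)[tab$model])
  } else 1

  # pairwise elpd differences vs the overall best model
  best_overall <- tab$model[which.min(tab$looic)]
  diffs <- elpd_mat - elpd_mat[, best_overall]
  tab$elpd_diff <- colSums(diffs)[tab$model]
  tab$se_elpd_diff <- vapply(tab$model, function(m) {
    sqrt(n_obs * var(diffs[, m]))
  }, 0)
  tab$non_decisive <- abs(tab$elpd_diff) < 2 * tab$se_elpd_diff

  tie <- FALSE
  selected_family <- NA_character_
  selected_model <- NA_character_
  if (nrow(families) > 0) {
    ordered <- families[order(-families$stacked_lpd), ]
    if (nrow(ordered) > 1 &&
        abs(ordered$stacked_lpd[1] - ordered$stacked_lpd[2]) < 1e-8) {
      tie <- TRUE
    } else {
      selected_family <- ordered$family[1]
      members <- tab[tab$family == selected_family, ]
      selected_model <- members$model[which.min(members$looic)]
    }
  }
  tab <- dplyr::arrange(tab, .data$looic)
  structure(list(table = tab, families = families,
                 selected_family = selected_family,
                 selected_model = selected_model, tie = tie,
                 n_obs = n_obs, loos = loos),
            class = "rl_comparison")
}

#' @export
print.rl_comparison <- function(x, ...) {
  cat("Model comparison (PSIS-LOO, lower looic is better)\n")
  print(x$table[, c("model", "family", "elpd_loo", "se_elpd_loo", "looic",
                    "stack_weight_within_family", "non_decisive")])
  if (x$tie) {
    cat("Family contest: tie between families (no winner declared)\n")
  } else if (!is.na(x$selected_family)) {
    cat(sprintf("Selected family: %s; selected model: %s\n",
                x$selected_family, x$selected_model))
  }
  invisible(x)
}

#' @export
tidy.rl_comparison <- function(x, ...) x$table

#' @export
glance.rl_comparison <- function(x, ...) {
  tibble::tibble(selected_family = x$selected_family,
                 selected_model = x$selected_model, tie = x$tie,
                 n_models = nrow(x$table), n_obs = x$n_obs)
}
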