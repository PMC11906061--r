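# ELPD-based model comparison from a pointwise log-likelihood matrix
# (S posterior draws x n subjects).

check_loglik_matrix <- function(ll, min_draws = 1L) {
  if (inherits(ll, "sine_ph_bayes")) ll <- pointwise_loglik_matrix(ll)
  ll <- as.matrix(ll)
  if (length(ll) == 0) abort_validation("Empty log-likelihood matrix.")
  if (!all(is.finite(ll))) {
    abort_validation("All log-likelihood entries must be finite.")
  }
  if (nrow(ll) < min_draws) {
    abort_validation(sprintf("Need at least %d posterior draws.", min_draws))
  }
  ll
}

#' Pointwise log-likelihood matrix of a Bayesian fit
#'
#' Evaluates the per-subject censored log density
#' `delta_i log h(t_i | x_i) - H(t_i | x_i)` at every posterior draw,
#' giving the draws-by-subjects matrix that feeds [waic()] and [looic()].
#'
#' @param fit A `sine_ph_bayes` object fitted to data.
#' @param data Optional survival data frame; defaults to the data stored in
#'   the fit.
#' @return An `S x n` matrix.
#' @export
pointwise_loglik_matrix <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "sine_ph_bayes"))
  data <- data %||% fit$data
  if (is.null(data)) abort_validation("The fit has no data attached.")
  data <- as_survival_data(data)
  X <- survival_covariate_matrix(data)
  dm <- dim(fit$draws)
  S <- dm[1] * dm[2]
  flat <- matrix(fit$draws, nrow = S, ncol = dm[3])
  colnames(flat) <- fit$params
  has_shape <- family_has_shape(fit$family)
  bn <- fit$beta_names
  out <- matrix(NA_real_, S, nrow(data))
  for (s in seq_len(S)) {
    out[s, ] <- ph_pointwise_core(
      fit$family, flat[s, "lambda"], if (has_shape) flat[s, "alpha"],
      unname(flat[s, bn]), data$time, data$event, X
    )
  }
  out
}

#' Log pointwise predictive density (lppd)
#'
#' `sum_i log( (1/S) sum_s exp(ll[s, i]) )`, computed with log-sum-exp
#' stabilisation.  This is the in-sample estimate of the expected log
#' predictive density that WAIC penalises.
#'
#' @param ll An `S x n` pointwise log-likelihood matrix (or a
#'   `sine_ph_bayes` fit, from which it is extracted).
#' @return A single number.
#' @examples
#' lppd(matrix(log(c(0.5, 0.25)), ncol = 1)) # log 0.375
#' @export
lppd <- function(ll) {
  ll <- check_loglik_matrix(ll)
  S <- nrow(ll)
  sum(apply(ll, 2, logsumexp) - log(S))
}

#' Effective number of parameters (p_WAIC)
#'
#' The mean-difference form
#' `2 sum_i ( log E_s[p(y_i | Psi_s)] - E_s[log p(y_i | Psi_s)] )`,
#' nonnegative by Jensen's inequality.  The variance-based alternative
#' (`method = "variance"`) is available but not the default.
#'
#' @inheritParams lppd
#' @param method `"mean_diff"` (default) or `"variance"`.
#' @return A single nonnegative number.
#' @export
p_waic <- function(ll, method = c("mean_diff", "variance")) {
  method <- match.arg(method)
  ll <- check_loglik_matrix(ll, min_draws = 2L)
  S <- nrow(ll)
  if (method == "mean_diff") {
    # each Jensen gap is >= 0; clamp roundoff so identical draws give 0
    2 * sum(pmax(apply(ll, 2, logsumexp) - log(S) - colMeans(ll), 0))
  } else {
    sum(apply(ll, 2, stats::var))
  }
}

#' Watanabe-Akaike information criterion
#'
#' `WAIC = -2 (lppd - p_WAIC)`; lower is better.
#'
#' @inheritParams p_waic
#' @return A single number.
#' @export
waic <- function(ll, method = c("mean_diff", "variance")) {
  ll <- check_loglik_matrix(ll, min_draws = 2L)
  -2 * (lppd(ll) - p_waic(ll, method))
}

# Zhang-Stephens empirical-Bayes fit of the generalised Pareto shape to
# tail exceedances; returns the shape estimate k (with the usual weak
# prior regularisation) and scale sigma.
gpd_fit <- function(z) {
  z <- sort(z)
  n <- length(z)
  if (n < 5) return(list(k = NA_real_, sigma = NA_real_))
  prior_bk <- 3
  m <- 30 + floor(sqrt(n))
  jj <- seq_len(m)
  zstar <- z[max(1, floor(n / 4 + 0.5))]
  theta <- 1 / z[n] + (1 - sqrt(m / (jj - 0.5))) / prior_bk / zstar
  kfun <- function(b) -mean(log1p(-b * z))
  l_theta <- vapply(theta, function(b) {
    k <- kfun(b)
    # admissible whenever b and k share a sign (negative b = heavy tail)
    if (!is.finite(k) || b / k <= 0) return(-Inf)
    n * (log(b / k) + k - 1)
  }, numeric(1))
  w <- exp(l_theta - logsumexp(l_theta))
  theta_hat <- sum(theta * w)
  k <- mean(log1p(-theta_hat * z))
  sigma <- -k / theta_hat
  # weakly informative prior pulling k toward 0.5
  k <- k * n / (n + 10) + 0.5 * 10 / (n + 10)
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

# Pareto-smooth a vector of log importance weights when the fitted tail
# index exceeds `threshold`; returns list(lw, khat, smoothed).
psis_smooth <- function(lw, threshold = 0.7) {
  S <- length(lw)
  tail_len <- ceiling(min(0.2 * S, 3 * sqrt(S)))
  khat <- NA_real_
  smoothed <- FALSE
  if (tail_len >= 5) {
    ord <- order(lw)
    tail_idx <- ord[(S - tail_len + 1):S]
    cutoff <- lw[ord[S - tail_len]]
    exceed <- exp(lw[tail_idx]) - exp(cutoff)
    fit <- gpd_fit(exceed)
    khat <- fit$k
    if (is.finite(khat) && khat > threshold && is.finite(fit$sigma) &&
        fit$sigma > 0) {
      pp <- (seq_len(tail_len) - 0.5) / tail_len
      repl <- log(exp(cutoff) + qgpd(pp, fit$k, fit$sigma))
      repl <- pmin(repl, max(lw))
      lw[tail_idx[order(lw[tail_idx])]] <- repl
      smoothed <- TRUE
    }
  }
  list(lw = lw, khat = khat, smoothed = smoothed)
}

#' Leave-one-out expected log predictive density and LOOIC
#'
#' Importance-sampling LOO from full-posterior draws: the predictive
#' density for held-out subject `i` is estimated by
#' `1 / ( (1/S) sum_s exp(-ll[s, i]) )` (weights proportional to the
#' inverse pointwise likelihood).  A generalised-Pareto tail diagnostic is
#' computed per observation; when the tail index exceeds `threshold`
#' (default 0.7) the tail weights are Pareto-smoothed before the estimate.
#' `looic = -2 * elpd_loo`; lower is better.
#'
#' @inheritParams lppd
#' @param threshold Pareto tail-index value above which smoothing is
#'   applied.
#' @return `elpd_loo()`: a number with attributes `pareto_k`
#'   (per-observation tail indices) and `smoothed` (logical flags);
#'   `looic()`: `-2 * elpd_loo` with the same attributes.
#' @export
elpd_loo <- function(ll, threshold = 0.7) {
  ll <- check_loglik_matrix(ll, min_draws = 2L)
  S <- nrow(ll)
  res <- apply(ll, 2, function(lli) {
    sm <- psis_smooth(-lli, threshold)        # log weights = -loglik
    lw <- sm$lw
    c(elpd = logsumexp(lw + lli) - logsumexp(lw),
      khat = sm$khat, smoothed = as.numeric(sm$smoothed))
  })
  out <- sum(res["elpd", ])
  attr(out, "pareto_k") <- unname(res["khat", ])
  attr(out, "smoothed") <- as.logical(res["smoothed", ])
  out
}

#' @rdname elpd_loo
#' @export
looic <- function(ll, threshold = 0.7) {
  e <- elpd_loo(ll, threshold)
  out <- -2 * as.numeric(e)
  attr(out, "pareto_k") <- attr(e, "pareto_k")
  attr(out, "smoothed") <- attr(e, "smoothed")
  out
}

#' All fit criteria for one model
#'
#' @inheritParams lppd
#' @return A one-row tibble: `lppd`, `p_waic`, `waic`, `elpd_loo`, `looic`,
#'   `n_high_pareto_k` (observations whose tail index exceeds 0.7).
#' @export
model_criteria <- function(ll) {
  ll <- check_loglik_matrix(ll, min_draws = 2L)
  e <- elpd_loo(ll)
  k <- attr(e, "pareto_k")
  tibble::tibble(
    lppd = lppd(ll), p_waic = p_waic(ll), waic = waic(ll),
    elpd_loo = as.numeric(e), looic = -2 * as.numeric(e),
    n_high_pareto_k = sum(is.finite(k) & k > 0.7)
  )
}

#' Rank competing models by WAIC or LOOIC
#'
#' Takes named fits (or pointwise log-likelihood matrices, or precomputed
#' [model_criteria()] rows) for models of the *same* data and returns them
#' sorted by the chosen criterion, with the difference from the best model.
#' The best-fitting model is the one with the lowest WAIC or LOOIC.
#'
#' @param ... Named models: `sine_ph_bayes` fits, `S x n` matrices, or
#'   one-row criteria tibbles.
#' @param criterion `"waic"` or `"looic"`.
#' @return A tibble sorted ascending by the criterion with a `delta`
#'   column.
#' @examples
#' a <- matrix(log(c(0.5, 0.25)), ncol = 1)
#' b <- matrix(log(c(0.6, 0.55)), ncol = 1)
#' compare_models(A = a, B = b)
#' @export
compare_models <- function(..., criterion = c("waic", "looic")) {
  criterion <- match.arg(criterion)
  models <- list(...)
  if (length(models) == 1 && is.list(models[[1]]) &&
      !is.data.frame(models[[1]]) && !is.matrix(models[[1]]) &&
      !inherits(models[[1]], "sine_ph_bayes")) {
    models <- models[[1]]
  }
  if (length(models) == 0) abort_validation("No models supplied.")
  nms <- names(models) %||% paste0("model", seq_along(models))
  nms[nms == ""] <- paste0("model", which(nms == ""))

  rows <- purrr::map(models, function(m) {
    if (is.data.frame(m)) {
      if (!all(c("waic", "looic") %in% names(m))) {
        abort_validation("Criteria tibbles need `waic` and `looic` columns.")
      }
      list(crit = m, n = attr(m, "n_obs"))
    } else {
      ll <- check_loglik_matrix(m, min_draws = 2L)
      list(crit = model_criteria(ll), n = ncol(ll))
    }
  })
  ns <- purrr::map(rows, "n")
  known <- purrr::compact(ns)
  if (length(known) > 1 && length(unique(unlist(known))) > 1) {
    abort_validation(
      "Models were evaluated on different numbers of subjects; not comparable."
    )
  }
  out <- dplyr::bind_rows(purrr::map(rows, "crit"))
  out <- dplyr::mutate(out, model = nms, .before = 1)
  out <- dplyr::arrange(out, .data[[criterion]])
  out <- dplyr::mutate(out, delta = .data[[criterion]] - .data[[criterion]][1])
  class(out) <- c("sinegph_comparison", class(out))
  out
}
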