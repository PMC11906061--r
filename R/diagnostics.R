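# convergence diagnostics: split R-hat, autocorrelation ESS, MCSE

split_chains <- function(x) {
  # x: iterations x chains matrix -> halved iterations x (2 * chains)
  x <- as.matrix(x)
  n <- nrow(x)
  half <- floor(n / 2)
  if (half < 2) return(x)
  cbind(x[seq_len(half), , drop = FALSE],
        x[(n - half + 1):n, , drop = FALSE])
}

as_draws_mat <- function(samples, parameter = NULL) {
  if (inherits(samples, "sine_ph_bayes")) {
    if (is.null(parameter)) {
      abort_domain("Give `parameter` when passing a fit object.")
    }
    return(as.matrix(draws_matrix(samples, parameter)))
  }
  x <- as.matrix(samples)
  if (ncol(x) == 1) {
    rlang::warn("Single chain: diagnostics computed on its split halves.")
  }
  x
}

#' Split-chain potential scale reduction factor (R-hat)
#'
#' Each chain is split in half and the classic between/within variance
#' ratio is computed on the split chains, so non-stationarity within a
#' chain inflates the diagnostic too.  Values near 1 indicate convergence;
#' fits should satisfy `rhat <= 1.01`.
#'
#' @param samples A `sine_ph_bayes` fit or an iterations-by-chains numeric
#'   matrix (a single chain is split in half, with a warning).
#' @param parameter Parameter name (required for fit objects).
#' @return A single number (>= 1 up to estimator noise); `Inf` when chains
#'   with zero within-variance disagree, 1 for all-constant chains.
#' @examples
#' x <- matrix(rnorm(4000), 1000, 4)
#' rhat(x)
#' @export
rhat <- function(samples, parameter = NULL) {
  x <- split_chains(as_draws_mat(samples, parameter))
  m <- ncol(x)
  n <- nrow(x)
  w <- mean(apply(x, 2, stats::var))
  b <- n * stats::var(colMeans(x))
  if (!is.finite(w) || w == 0) {
    return(if (is.finite(b) && b > 0) Inf else 1)
  }
  var_plus <- (n - 1) / n * w + b / n
  sqrt(var_plus / w)
}

#' Effective sample size of MCMC draws
#'
#' Autocorrelation-based effective draw count on split chains, following
#' the combined-chain estimator: per-chain autocovariances are averaged,
#' converted to correlations against the pooled variance, and summed using
#' Geyer's initial monotone positive-pair sequence.  The Monte Carlo
#' standard error of the posterior mean is `sd / sqrt(ess)`.
#'
#' @inheritParams rhat
#' @return A single number; 0 for a zero-variance (constant) chain.
#' @examples
#' x <- matrix(rnorm(4000), 1000, 4)
#' ess(x) # close to 4000
#' @export
ess <- function(samples, parameter = NULL) {
  x <- split_chains(as_draws_mat(samples, parameter))
  m <- ncol(x)
  n <- nrow(x)
  if (n < 3) return(NA_real_)
  w <- mean(apply(x, 2, stats::var))
  if (!is.finite(w) || w == 0) return(0)
  b <- n * stats::var(colMeans(x))
  var_plus <- (n - 1) / n * w + b / n

  max_lag <- n - 1
  acov <- vapply(seq_len(m), function(j) {
    a <- stats::acf(x[, j], lag.max = max_lag, type = "covariance",
                    plot = FALSE, demean = TRUE)$acf[, 1, 1]
    a * (n - 1) / n
  }, numeric(max_lag + 1))
  mean_acov <- rowMeans(acov)
  rho <- 1 - (w - mean_acov) / var_plus
  rho[1] <- 1

  # Geyer: sum consecutive pairs while positive, enforce monotone decrease
  tau <- 0
  prev_pair <- Inf
  s <- 1
  while (s + 1 <= length(rho)) {
    pair <- rho[s] + rho[s + 1]
    if (pair < 0) break
    pair <- min(pair, prev_pair)
    prev_pair <- pair
    tau <- tau + pair
    s <- s + 2
  }
  tau <- max(2 * tau - 1, 1 / (log10(n * m) + 1))
  min(m * n / tau, m * n * log10(m * n))
}

#' Monte Carlo standard error of the posterior mean
#'
#' @inheritParams rhat
#' @return `sd(draws) / sqrt(ess)`.
#' @export
mcse <- function(samples, parameter = NULL) {
  x <- as_draws_mat(samples, parameter)
  e <- ess(x)
  if (!is.finite(e) || e <= 0) return(NA_real_)
  stats::sd(as.vector(x)) / sqrt(e)
}

#' Summarise a posterior fit
#'
#' Per-parameter posterior mean, Monte Carlo standard error, standard
#' deviation, 2.5%/50%/97.5% quantiles, effective sample size and split
#' R-hat — the usual fit-summary table layout for parametric PH models.
#'
#' @param fit A `sine_ph_bayes` object.
#' @return A tibble with columns `term`, `estimate`, `mcse`, `sd`, `q2.5`,
#'   `median`, `q97.5`, `ess`, `rhat`.
#' @export
summarize_posterior <- function(fit) {
  stopifnot(inherits(fit, "sine_ph_bayes"))
  purrr::map_dfr(fit$params, function(p) {
    x <- draws_matrix(fit, p)
    v <- as.vector(x)
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    tibble::tibble(
      term = p, estimate = mean(v),
      mcse = mcse(as.matrix(x)), sd = stats::sd(v),
      q2.5 = q[1], median = q[2], q97.5 = q[3],
      ess = ess(as.matrix(x)), rhat = rhat(as.matrix(x))
    )
  })
}

#' Tidy a Bayesian fit
#'
#' @param x A `sine_ph_bayes` object.
#' @param ... Unused.
#' @return The [summarize_posterior()] tibble.
#' @method tidy sine_ph_bayes
#' @export
tidy.sine_ph_bayes <- function(x, ...) summarize_posterior(x)

#' One-row summary of a Bayesian fit
#'
#' @param x A `sine_ph_bayes` object.
#' @param ... Unused.
#' @return A one-row tibble (`n`, `chains`, `draws`, `max_rhat`, `min_ess`,
#'   `divergences`).
#' @method glance sine_ph_bayes
#' @export
glance.sine_ph_bayes <- function(x, ...) {
  s <- summarize_posterior(x)
  tibble::tibble(
    n = x$n, chains = dim(x$draws)[2],
    draws = dim(x$draws)[1] * dim(x$draws)[2],
    max_rhat = max(s$rhat), min_ess = min(s$ess),
    divergences = sum(x$divergences)
  )
}
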