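#' Sine-G proportional-hazards model
#'
#' Combines a Sine-G baseline distribution with a vector of regression
#' coefficients `beta` (no intercept: the baseline hazard plays that role
#' and an intercept would destroy identifiability).  Under the model the
#' hazard for a subject with covariates `x` is
#' `h(t | x) = h0(t) * exp(x' beta)`, so the survival function is
#' `S0(t)^(exp(x' beta))` and the cumulative hazard `H0(t) * exp(x' beta)`.
#'
#' @param dist A [sine_dist()] baseline distribution.
#' @param beta Named numeric vector of regression coefficients (may be
#'   empty for an intercept-free i.i.d. model).
#' @return An object of class `sine_ph`.
#' @examples
#' m <- sine_ph(sine_dist("sw", 0.34, 0.95), beta = c(treat = -0.06))
#' ph_hazard(m, t = 1, x = c(treat = 1))
#' @export
sine_ph <- function(dist, beta = numeric(0)) {
  check_dist(dist)
  if (!is.numeric(beta) || anyNA(beta) || any(!is.finite(beta))) {
    abort_domain("`beta` must be a finite numeric vector.")
  }
  structure(list(dist = dist, beta = beta), class = "sine_ph")
}

#' @export
print.sine_ph <- function(x, ...) {
  cat(sprintf(
    "<sine_ph> baseline %s; beta = [%s]\n", format(x$dist),
    paste(sprintf("%s=%.4g", names(x$beta) %||% seq_along(x$beta), x$beta),
          collapse = ", ")
  ))
  invisible(x)
}

check_ph <- function(model) {
  if (!inherits(model, "sine_ph")) {
    abort_domain("`model` must be a <sine_ph> object; see sine_ph().")
  }
  model
}

linear_predictor <- function(model, x) {
  beta <- model$beta
  if (length(beta) == 0) return(0)
  if (is.matrix(x)) {
    if (ncol(x) != length(beta)) {
      abort_domain(sprintf(
        "Covariate matrix has %d column(s) but the model has %d coefficient(s).",
        ncol(x), length(beta)
      ))
    }
    as.vector(x %*% beta)
  } else {
    if (length(x) != length(beta)) {
      abort_domain(sprintf(
        "Covariate vector has length %d but the model has %d coefficient(s).",
        length(x), length(beta)
      ))
    }
    sum(x * beta)
  }
}

#' Proportional-hazards functions
#'
#' Hazard, survival and cumulative-hazard functions of a [sine_ph()] model
#' for a subject with covariate vector `x`.  Survival is computed as
#' `exp(-H0(t) * exp(x' beta))`, i.e. through the log-scale baseline
#' survival, so extreme linear predictors do not lose precision.
#'
#' @param model A [sine_ph()] model.
#' @param t Vector of times.
#' @param x Covariate vector of the same length as `model$beta` (or a matrix
#'   with one row per time point).
#' @return Numeric vector.
#' @export
ph_hazard <- function(model, t, x = numeric(0)) {
  check_ph(model)
  exp(sine_hrf(model$dist, t, log = TRUE) + linear_predictor(model, x))
}

#' @rdname ph_hazard
#' @export
ph_survival <- function(model, t, x = numeric(0)) {
  check_ph(model)
  exp(-sine_chrf(model$dist, t) * exp(linear_predictor(model, x)))
}

#' @rdname ph_hazard
#' @export
ph_chrf <- function(model, t, x = numeric(0)) {
  check_ph(model)
  sine_chrf(model$dist, t) * exp(linear_predictor(model, x))
}

# fast unvalidated core used by estimation: pointwise log density of the
# right-censored PH model, delta*log h(t|x) - H(t|x)
ph_pointwise_core <- function(family, lambda, alpha, beta, t, delta, X) {
  eta <- if (length(beta) > 0) as.vector(X %*% beta) else rep(0, length(t))
  lh0 <- sine_loghrf_core(family, t, lambda, alpha)
  H0 <- sine_chrf_core(family, t, lambda, alpha)
  delta * (lh0 + eta) - H0 * exp(eta)
}

#' Right-censored log-likelihood of a Sine-G PH model
#'
#' The censored-data log-likelihood
#' `sum_i delta_i (log h0(t_i) + x_i' beta) - sum_i H0(t_i) exp(x_i' beta)`,
#' i.e. the log of `prod_i f(t_i|x_i)^delta_i S(t_i|x_i)^(1-delta_i)`.
#' `ph_pointwise_loglik()` returns the per-subject contributions
#' `delta_i log h(t_i|x_i) - H(t_i|x_i)`, which sum to the total and feed
#' the WAIC/LOOIC machinery.
#'
#' @param model A [sine_ph()] model.
#' @param data A survival data frame (validated via [as_survival_data()]).
#' @param time,event,covariates Column mapping passed to
#'   [as_survival_data()].
#' @return `ph_loglik()`: a single number; `ph_pointwise_loglik()`: a
#'   numeric vector of length `nrow(data)`.
#' @examples
#' m <- sine_ph(sine_dist("se", 1), beta = c(trt = 0.5))
#' df <- data.frame(time = c(1, 2), event = c(1, 0), trt = c(0, 1))
#' ph_loglik(m, df)
#' @export
ph_loglik <- function(model, data, time = "time", event = "event",
                      covariates = NULL) {
  sum(ph_pointwise_loglik(model, data, time, event, covariates))
}

#' @rdname ph_loglik
#' @export
ph_pointwise_loglik <- function(model, data, time = "time", event = "event",
                                covariates = NULL) {
  check_ph(model)
  data <- as_survival_data(data, time, event, covariates)
  X <- survival_covariate_matrix(data)
  if (ncol(X) != length(model$beta)) {
    abort_domain(sprintf(
      "Data has %d covariate(s) but the model has %d coefficient(s).",
      ncol(X), length(model$beta)
    ))
  }
  out <- ph_pointwise_core(
    model$dist$family, model$dist$scale, model$dist$shape, model$beta,
    data$time, data$event, X
  )
  bad <- which(!is.finite(out))
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Non-finite log-likelihood contribution for subject(s): %s.",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  out
}
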