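# Internal closed-form math for the five baseline families.
#
# Everything is parameterised as (lambda = scale, alpha = shape) and works on
# the log scale where the proportional-hazards likelihood needs it.  The
# survival fraction 1 - G is always computed directly from its own closed
# form (never as 1 - cdf) so that the sine-transform survival function keeps
# full precision when G is close to 1.

sinegph_families <- c(
  "exponential", "weibull", "lomax", "exponentiated_exponential", "gompertz"
)

# short codes used in the literature for the sine-transformed families
sinegph_family_codes <- c(
  se = "exponential", sw = "weibull", sl = "lomax",
  see = "exponentiated_exponential", sg = "gompertz"
)

match_family <- function(family) {
  if (!is.character(family) || length(family) != 1L || is.na(family)) {
    abort_domain("`family` must be a single family name.")
  }
  fam <- tolower(family)
  if (fam %in% names(sinegph_family_codes)) {
    return(unname(sinegph_family_codes[[fam]]))
  }
  hit <- pmatch(fam, sinegph_families)
  if (is.na(hit)) {
    abort_domain(sprintf(
      "Unknown family '%s'. Use one of: %s (or codes %s).",
      family,
      paste(sinegph_families, collapse = ", "),
      paste(names(sinegph_family_codes), collapse = ", ")
    ))
  }
  sinegph_families[hit]
}

family_has_shape <- function(family) family != "exponential"

# G(t); 0 for t < 0 by convention
base_cdf <- function(family, t, lambda, alpha = NULL) {
  tt <- pmax(t, 0)
  switch(family,
    exponential = -expm1(-lambda * tt),
    weibull = -expm1(-(lambda * tt)^alpha),
    lomax = -expm1(-alpha * log1p(lambda * tt)),
    exponentiated_exponential = exp(alpha * log(-expm1(-lambda * tt))),
    gompertz = -expm1(-alpha * expm1(lambda * tt))
  )
}

# log(1 - G(t)), exact closed forms; 0 for t <= 0
base_logsf <- function(family, t, lambda, alpha = NULL) {
  tt <- pmax(t, 0)
  switch(family,
    exponential = -lambda * tt,
    weibull = -(lambda * tt)^alpha,
    lomax = -alpha * log1p(lambda * tt),
    exponentiated_exponential = log(-expm1(alpha * log(-expm1(-lambda * tt)))),
    gompertz = -alpha * expm1(lambda * tt)
  )
}

# log g(t); -Inf for t < 0 (density 0 off the support)
base_logpdf <- function(family, t, lambda, alpha = NULL) {
  tt <- pmax(t, 0)
  out <- switch(family,
    exponential = log(lambda) - lambda * tt,
    weibull = log(lambda) + log(alpha) + (alpha - 1) * log(lambda * tt) -
      (lambda * tt)^alpha,
    lomax = log(alpha) + log(lambda) - (alpha + 1) * log1p(lambda * tt),
    exponentiated_exponential = log(alpha) + log(lambda) - lambda * tt +
      (alpha - 1) * log(-expm1(-lambda * tt)),
    gompertz = log(lambda) + log(alpha) + lambda * tt - alpha * expm1(lambda * tt)
  )
  out[t < 0] <- -Inf
  out
}

# G^{-1}(p), closed form per family, for p in [0, 1)
base_quantile <- function(family, p, lambda, alpha = NULL) {
  switch(family,
    exponential = -log1p(-p) / lambda,
    weibull = (-log1p(-p))^(1 / alpha) / lambda,
    lomax = expm1(-log1p(-p) / alpha) / lambda,
    exponentiated_exponential = -log1p(-exp(log(p) / alpha)) / lambda,
    gompertz = log1p(-log1p(-p) / alpha) / lambda
  )
}

# --- sine transform layer -------------------------------------------------
# With Gbar = 1 - G:
#   F_sin = sin((pi/2) G) = cos((pi/2) Gbar)
#   S_sin = 1 - F_sin     = 2 sin^2(pi Gbar / 4)
#   f_sin = (pi/2) g cos((pi/2) G) = (pi/2) g sin((pi/2) Gbar)
#   h_sin = f_sin / S_sin = (pi/2) g cot(pi Gbar / 4)    [half-angle identity]
# so log S_sin = log 2 + 2 log sin(pi Gbar / 4), which stays accurate in the
# right tail where 1 - sin(.) would cancel catastrophically.

sine_logsf_core <- function(family, t, lambda, alpha = NULL) {
  gbar <- exp(base_logsf(family, t, lambda, alpha))
  out <- log(2) + 2 * log(sin(pi * gbar / 4))
  out[t <= 0] <- 0
  out
}

sine_logpdf_core <- function(family, t, lambda, alpha = NULL) {
  gbar <- exp(base_logsf(family, t, lambda, alpha))
  out <- log(pi / 2) + base_logpdf(family, t, lambda, alpha) +
    log(sin(pi * gbar / 2))
  out[t < 0] <- -Inf
  out
}

sine_loghrf_core <- function(family, t, lambda, alpha = NULL) {
  gbar <- exp(base_logsf(family, t, lambda, alpha))
  log(pi / 2) + base_logpdf(family, t, lambda, alpha) +
    log(cos(pi * gbar / 4)) - log(sin(pi * gbar / 4))
}

sine_chrf_core <- function(family, t, lambda, alpha = NULL) {
  -sine_logsf_core(family, t, lambda, alpha)
}

# F_sin^{-1}(u) = G^{-1}((2/pi) asin(u))
sine_quantile_core <- function(family, u, lambda, alpha = NULL) {
  base_quantile(family, 2 / pi * asin(u), lambda, alpha)
}

# H_sin^{-1}(v) = G^{-1}((2/pi) asin(1 - e^{-v}))
sine_chrf_inverse_core <- function(family, v, lambda, alpha = NULL) {
  base_quantile(family, 2 / pi * asin(-expm1(-v)), lambda, alpha)
}
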