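# shared validation helpers and error classes

abort_domain <- function(message, ...) {
  rlang::abort(message, class = "sinegph_domain_error", ...)
}

abort_validation <- function(message, ...) {
  rlang::abort(message, class = "sinegph_validation_error", ...)
}

check_positive_scalar <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    abort_domain(sprintf("`%s` must be a single positive finite number.", name))
  }
  invisible(x)
}

check_prob <- function(p, name = "p") {
  if (!is.numeric(p) || anyNA(p) || any(p < 0) || any(p >= 1)) {
    abort_domain(sprintf("`%s` must lie in [0, 1).", name))
  }
  invisible(p)
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
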