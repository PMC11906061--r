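#' Validate a right-censored survival data frame
#'
#' Checks and standardises the `(t_i, delta_i, x_i)` triplets used throughout
#' the package: an observed time column (nonnegative), an event indicator
#' column (`1` = event observed, `0` = right-censored) and zero or more
#' numeric covariate columns.  The returned tibble has the time and event
#' columns first, followed by the covariates, and carries the covariate
#' names as the `"covariates"` attribute.
#'
#' @param data A data frame.
#' @param time,event Names of the time and event-indicator columns.
#' @param covariates Character vector of covariate column names; by default
#'   every remaining column is a covariate.
#' @return A validated tibble with columns `time`, `event`, then covariates.
#' @examples
#' df <- data.frame(time = c(1, 2, 3), event = c(1, 0, 1), trt = c(0, 1, 1))
#' as_survival_data(df)
#' @export
as_survival_data <- function(data, time = "time", event = "event",
                             covariates = NULL) {
  if (!is.data.frame(data)) {
    abort_validation("`data` must be a data frame.")
  }
  missing_cols <- setdiff(c(time, event, covariates), names(data))
  if (length(missing_cols) > 0) {
    abort_validation(sprintf(
      "Column(s) not found in `data`: %s.",
      paste(missing_cols, collapse = ", ")
    ))
  }
  covariates <- covariates %||% setdiff(names(data), c(time, event))

  tvec <- data[[time]]
  dvec <- data[[event]]
  if (!is.numeric(tvec)) abort_validation("The time column must be numeric.")
  bad <- which(is.na(tvec) | !is.finite(tvec) | tvec < 0)
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Times must be finite and nonnegative; offending row(s): %s.",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  bad <- which(is.na(dvec) | !(dvec %in% c(0, 1)))
  if (length(bad) > 0) {
    abort_validation(sprintf(
      "Event indicators must be 0 (censored) or 1 (event); offending row(s): %s.",
      paste(utils::head(bad, 5), collapse = ", ")
    ))
  }
  for (cv in covariates) {
    xv <- data[[cv]]
    if (!is.numeric(xv)) {
      abort_validation(sprintf("Covariate column '%s' must be numeric.", cv))
    }
    bad <- which(is.na(xv) | !is.finite(xv))
    if (length(bad) > 0) {
      abort_validation(sprintf(
        "Covariate '%s' has missing/non-finite value(s) at row(s): %s.",
        cv, paste(utils::head(bad, 5), collapse = ", ")
      ))
    }
  }

  out <- tibble::tibble(time = as.numeric(tvec), event = as.integer(dvec))
  for (cv in covariates) out[[cv]] <- as.numeric(data[[cv]])
  attr(out, "covariates") <- covariates
  out
}

survival_covariate_matrix <- function(data) {
  covariates <- attr(data, "covariates") %||%
    setdiff(names(data), c("time", "event"))
  if (length(covariates) == 0) {
    matrix(numeric(0), nrow = nrow(data), ncol = 0)
  } else {
    as.matrix(data[covariates])
  }
}
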