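#' Read a right-censored survival table
#'
#' Reads a delimited text file with a header (comma by default, tab
#' accepted) into a validated survival tibble.  Event coding is fixed at
#' `1` = event, `0` = right-censored; files using other codes must be
#' remapped via `event_codes`.
#'
#' @param path File path.
#' @param time,event Column names holding the observed time and the event
#'   indicator.
#' @param covariates Covariate column names; default: all remaining
#'   columns.
#' @param delim Field delimiter; `NULL` guesses from the first line
#'   (comma or tab).
#' @param event_codes Optional length-2 vector `c(censored, event)` mapping
#'   nonstandard codes to 0/1.
#' @return A validated survival tibble (see [as_survival_data()]).
#' @export
read_survival_table <- function(path, time = "time", event = "event",
                                covariates = NULL, delim = NULL,
                                event_codes = NULL) {
  if (!file.exists(path)) {
    abort_validation(sprintf("File not found: %s", path))
  }
  if (is.null(delim)) {
    first <- readLines(path, n = 1)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(event_codes)) {
    if (!event %in% names(raw)) {
      abort_validation(sprintf("Column '%s' not found in %s.", event, path))
    }
    raw[[event]] <- match(raw[[event]], event_codes) - 1L
  }
  as_survival_data(raw, time = time, event = event, covariates = covariates)
}

#' @rdname read_survival_table
#' @param data A survival data frame to write.
#' @export
write_survival_table <- function(data, path) {
  data <- as_survival_data(data)
  readr::write_csv(data, path, progress = FALSE)
  invisible(path)
}

#' Scaled total-time-on-test (TTT) transform
#'
#' With order statistics `t(1) <= ... <= t(n)` the r-th TTT coordinate is
#' `[sum_{i<=r} t(i) + (n - r) t(r)] / sum_i t(i)` plotted against `r/n`.
#' Curvature diagnoses the hazard shape: concave above the diagonal for an
#' increasing hazard, convex below it for a decreasing hazard, and an
#' S shape for bathtub / unimodal hazards.  The transform is defined for
#' complete samples; by default all observed times enter regardless of
#' censoring status (set `events_only = TRUE` together with an event vector
#' to restrict to events).
#'
#' @param times Vector of nonnegative observed times, `n >= 2`, not all
#'   zero.
#' @param event Optional event indicator vector (only used when
#'   `events_only = TRUE`).
#' @param events_only Restrict to event times.
#' @return A tibble of class `ttt_statistic` with columns `p` (= r/n) and
#'   `ttt`; the last row is (1, 1).
#' @examples
#' ttt_statistic(c(1, 2, 3))
#' @export
ttt_statistic <- function(times, event = NULL, events_only = FALSE) {
  if (events_only) {
    if (is.null(event)) {
      abort_validation("`events_only = TRUE` needs an `event` vector.")
    }
    times <- times[event == 1]
  }
  if (!is.numeric(times) || anyNA(times) || any(times < 0)) {
    abort_validation("`times` must be nonnegative with no missing values.")
  }
  n <- length(times)
  if (n < 2) abort_validation("Need at least two observations.")
  total <- sum(times)
  if (total <= 0) abort_validation("All times are zero; TTT is undefined.")
  ts <- sort(times)
  r <- seq_len(n)
  out <- tibble::tibble(
    p = r / n,
    ttt = (cumsum(ts) + (n - r) * ts) / total
  )
  class(out) <- c("ttt_statistic", class(out))
  out
}
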