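#' Coerce an object to a single-channel numeric series
#'
#' Most functions in tsnets operate on a single channel. Inputs may be a bare
#' numeric vector, or a data frame / tibble holding one channel per column
#' (the shape written by [read_timeseries()] and [generate_signal()]). For
#' data frames the channel is resolved by name, or, when only one non-time
#' numeric column exists, taken implicitly.
#'
#' @param x numeric vector or data frame.
#' @param channel optional column name selecting the channel of a data frame.
#' @return numeric vector of the channel values.
#' @keywords internal
#' @noRd
ts_values <- function(x, channel = NULL) {
  if (is.data.frame(x)) {
    cols <- names(x)[vapply(x, is.numeric, logical(1))]
    cols <- setdiff(cols, "time")
    if (!is.null(channel)) {
      if (!channel %in% names(x)) {
        stop("channel '", channel, "' not found in input", call. = FALSE)
      }
      v <- x[[channel]]
    } else if (length(cols) == 1L) {
      v <- x[[cols]]
    } else {
      stop("input has ", length(cols),
           " candidate channels; name one with `channel`", call. = FALSE)
    }
  } else {
    v <- x
  }
  v <- as.numeric(v)
  if (length(v) < 2L) stop("time series must have at least 2 samples", call. = FALSE)
  if (anyNA(v)) stop("time series contains missing values", call. = FALSE)
  v
}

# Resolve explicit sample times: user-supplied vector wins, then a `time`
# column, then the implicit regular grid 1..n.
ts_times <- function(x, times = NULL, n = NULL) {
  if (is.null(times) && is.data.frame(x) && "time" %in% names(x)) {
    times <- x[["time"]]
  }
  if (is.null(times)) times <- seq_len(n)
  times <- as.numeric(times)
  if (!is.null(n) && length(times) != n) {
    stop("`times` must match the series length (", n, ")", call. = FALSE)
  }
  if (anyDuplicated(times)) stop("duplicate time stamps", call. = FALSE)
  if (is.unsorted(times, strictly = TRUE)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  times
}
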