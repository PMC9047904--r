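#' Threshold-crossing encoder configuration
#'
#' `n_thresh` voltage thresholds are spaced uniformly over the interior of
#' the signal range (the `n_thresh` interior points of an equipartition of
#' `[lo, hi]`), so a single monotone sweep of the full range crosses each
#' threshold exactly once. The range is taken from pooled training traces
#' (fixed at test time) to avoid leakage; a degenerate (constant) range is an
#' error instructing the caller to supply a training-set range.
#'
#' @param n_thresh number of thresholds (the encoder emits `2 * n_thresh`
#'   channels: rising then falling).
#' @param range length-2 numeric range, or `NULL` to derive it from `traces`.
#' @param traces numeric vector/matrix/list of training traces pooled for the
#'   range.
#' @return object of class `encoder_config`: `n_thresh`, `thresholds`.
#' @export
encoder_config <- function(n_thresh = 50, range = NULL, traces = NULL) {
  if (is.null(range)) {
    if (is.null(traces)) stop("supply `range` or `traces`")
    v <- unlist(traces, use.names = FALSE)
    range <- base::range(v, na.rm = TRUE)
  }
  if (!is.numeric(range) || length(range) != 2 || !all(is.finite(range)) ||
      diff(range) <= 0)
    stop("degenerate signal range; supply a training-set range with spread")
  th <- seq(range[1], range[2], length.out = n_thresh + 2L)[2:(n_thresh + 1L)]
  structure(list(n_thresh = as.integer(n_thresh), thresholds = th,
                 range = range),
            class = "encoder_config")
}

#' Encode an analog trace as threshold-crossing spike events
#'
#' For every consecutive sample pair `(x_t, x_{t+1})`, rising channel `i`
#' (channels `1..n_thresh`) emits an event at the later sample iff
#' `x_t <= th_i < x_{t+1}`; falling channel `i + n_thresh` emits iff
#' `x_t >= th_i > x_{t+1}`. A constant trace yields no events.
#'
#' @param trace numeric analog trace (finite).
#' @param cfg an [encoder_config()].
#' @param times optional vector of sample times, s (defaults to the sample
#'   index starting at 0 with unit step `1/fs`).
#' @param fs sampling rate used when `times` is absent.
#' @return object of class `event_stream`: `events`, a list of `2 * n_thresh`
#'   sorted time vectors, plus `n_thresh`, `thresholds`.
#' @export
encode <- function(trace, cfg, times = NULL, fs = 1000) {
  stopifnot(inherits(cfg, "encoder_config"))
  if (!all(is.finite(trace))) stop("trace must be finite")
  if (is.null(times)) times <- (seq_along(trace) - 1L) / fs
  n <- length(trace)
  ev <- vector("list", 2L * cfg$n_thresh)
  if (n >= 2) {
    x0 <- trace[-n]; x1 <- trace[-1L]; t1 <- times[-1L]
    for (i in seq_len(cfg$n_thresh)) {
      th <- cfg$thresholds[i]
      ev[[i]] <- t1[x0 <= th & th < x1]
      ev[[i + cfg$n_thresh]] <- t1[x0 >= th & th > x1]
    }
  } else {
    ev[] <- list(numeric(0))
  }
  structure(list(events = ev, n_thresh = cfg$n_thresh,
                 thresholds = cfg$thresholds),
            class = "event_stream")
}

#' Total number of events in a stream
#'
#' Sparsity diagnostic: the event count summed over all channels.
#'
#' @param stream an `event_stream`.
#' @return integer count.
#' @export
total_event_count <- function(stream) {
  sum(vapply(stream$events, length, 1L))
}
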