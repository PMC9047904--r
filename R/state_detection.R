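#' Cumulative instantaneous firing rate and UP intervals
#'
#' Per electrode, the instantaneous firing rate (IFR) is the spike count in a
#' sliding window of `window` s (10 ms), stepped by `step` s (1 ms), divided
#' by the window length (Hz). The cumulative profile sums the IFR over all
#' electrodes; its global mean over the session serves as the UP/DOWN
#' threshold, and UP intervals are the maximal runs where the cumulative IFR
#' is strictly above threshold. A window starting at time t covers
#' `[t, t + window)`; the interval reported for a run of windows i..j is
#' `[t_i, t_j + window)`.
#'
#' @param raster a `spike_raster` (see [detect_spikes()]).
#' @param window sliding-window width, s.
#' @param step window step, s.
#' @return object of class `state_trace`: `t` (window start times), `cum_ifr`
#'   (Hz), `threshold`, `up_intervals` (data.frame start/end), `window`,
#'   `step`.
#' @export
compute_ifr <- function(raster, window = 0.010, step = 0.001) {
  span <- raster$span
  if (diff(span) <= 0) stop("recording span must be positive")
  n_steps <- max(1L, floor((diff(span) - window) / step) + 1L)
  t0 <- span[1]
  w_in_steps <- max(1L, round(window / step))
  # count spikes per `step` bin, pooled over electrodes, then a forward
  # rolling sum of `window/step` bins gives the pooled window counts
  n_bins <- n_steps + w_in_steps - 1L
  all_t <- unlist(raster$times, use.names = FALSE)
  counts <- numeric(n_bins)
  if (length(all_t) > 0) {
    b <- floor((all_t - t0) / step) + 1L
    b <- b[b >= 1L & b <= n_bins]
    if (length(b) > 0) {
      tb <- tabulate(b, nbins = n_bins)
      counts <- as.numeric(tb)
    }
  }
  win_counts <- cumsum(counts)
  win_counts <- win_counts[w_in_steps:n_bins] -
    c(0, win_counts[seq_len(n_bins - w_in_steps)])
  cum_ifr <- win_counts / window
  thr <- mean(cum_ifr)
  up <- cum_ifr > thr
  t_starts <- t0 + (seq_len(n_steps) - 1L) * step
  d <- diff(c(FALSE, up, FALSE))
  i0 <- which(d == 1L); i1 <- which(d == -1L) - 1L
  up_intervals <- data.frame(start = t_starts[i0],
                             end = t_starts[i1] + window)
  # window coverage can make neighbouring runs overlap in time; merge them
  if (nrow(up_intervals) > 1) {
    keep <- integer(0); cur <- 1L
    for (r in 2:nrow(up_intervals)) {
      if (up_intervals$start[r] <= up_intervals$end[cur]) {
        up_intervals$end[cur] <- max(up_intervals$end[cur], up_intervals$end[r])
      } else {
        keep <- c(keep, cur); cur <- r
      }
    }
    up_intervals <- up_intervals[c(keep, cur), , drop = FALSE]
    rownames(up_intervals) <- NULL
  }
  structure(list(t = t_starts, cum_ifr = cum_ifr, threshold = thr,
                 up_intervals = up_intervals, window = window, step = step,
                 span = span),
            class = "state_trace")
}

#' Label stimuli as delivered during UP or DOWN states
#'
#' A stimulus is labeled UP if any UP interval of the trace intersects the
#' half-open investigation window `[onset - pre_window, onset)`; otherwise
#' DOWN. Stimuli closer than `pre_window` to the recording start are labeled
#' from the truncated window (with a warning).
#'
#' @param trace a `state_trace` from [compute_ifr()].
#' @param stim stimulus table with an `onset` column, s.
#' @param pre_window investigation window before each stimulus, s.
#' @return data.frame: `onset`, `state` ("UP"/"DOWN").
#' @export
label_stimuli <- function(trace, stim, pre_window = 0.050) {
  on <- stim$onset
  if (any(on < trace$span[1] + pre_window))
    warning("some stimuli are within pre_window of the recording start; labeled from truncated windows")
  up <- trace$up_intervals
  state <- vapply(on, function(o) {
    w0 <- max(trace$span[1], o - pre_window)
    hit <- nrow(up) > 0 && any(up$start < o & up$end > w0)
    if (hit) "UP" else "DOWN"
  }, character(1))
  data.frame(onset = on, state = state, stringsAsFactors = FALSE)
}
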