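#' Mean LFP trace of one cortical layer
#'
#' Arithmetic mean across all member channels of the layer; averaging
#' suppresses channel noise before feature extraction. The classifier path
#' uses the layer-IV mean.
#'
#' @param sig a `band_signal` with `band == "LFP"`.
#' @param layer layer label ("II", "III", "IV", "Va", "Vb", "VI").
#' @return numeric trace (microvolt) at `sig$fs`.
#' @export
layer_mean_lfp <- function(sig, layer) {
  idx <- sig$channels$index[sig$channels$layer == layer]
  if (length(idx) == 0) stop(sprintf("unknown or empty layer '%s'", layer))
  if (length(idx) == 1) return(sig$samples[idx, ])
  colMeans(sig$samples[idx, , drop = FALSE])
}

#' Response onset latency (ROL)
#'
#' The first instant within 20 ms after stimulus onset at which the absolute
#' first derivative of the trace exceeds
#' `thr = mean(bas') + 3 * sd(bas')`, where `bas'` is the derivative over a
#' baseline window preceding the stimulus (nominally 10 s; automatically
#' truncated to the available pre-stimulus span). The derivative is computed
#' on a boxcar-smoothed copy of the trace (`smooth_ms`, default 2 ms) so that
#' broadband noise does not dominate the baseline statistics; `smooth_ms = 0`
#' disables smoothing.
#'
#' @param trace LFP trace, microvolt.
#' @param fs sampling rate of `trace`, Hz.
#' @param onset stimulus onset, s from trace start.
#' @param baseline_window baseline span before onset used for the threshold, s.
#' @param search_ms search span after onset, ms.
#' @param smooth_ms boxcar width for the derivative, ms.
#' @return latency in ms, or `NA` when no crossing occurs within the search
#'   span.
#' @export
response_onset_latency <- function(trace, fs, onset, baseline_window = 10,
                                   search_ms = 20, smooth_ms = 2) {
  rol_from_deriv(trace_derivative(trace, fs, smooth_ms), fs, onset,
                 baseline_window, search_ms)
}

# smoothed first derivative of a trace, microvolt per ms
trace_derivative <- function(trace, fs, smooth_ms = 2) {
  x <- trace
  if (smooth_ms > 0) {
    k <- max(1L, round(smooth_ms / 1000 * fs))
    if (k > 1) {
      sm <- as.numeric(stats::filter(x, rep(1 / k, k), sides = 2))
      sm[is.na(sm)] <- trace[is.na(sm)]
      x <- sm
    }
  }
  c(0, diff(x)) * fs / 1000
}

# ROL from a precomputed derivative (one smoothing pass per layer trace)
rol_from_deriv <- function(dx, fs, onset, baseline_window, search_ms = 20) {
  i_on <- round(onset * fs) + 1L
  bw <- min(baseline_window, onset)
  i_b0 <- max(1L, i_on - round(bw * fs))
  if (i_b0 >= i_on - 2L) stop("not enough pre-stimulus baseline for ROL")
  bas <- dx[i_b0:(i_on - 1L)]
  thr <- mean(bas) + 3 * sd(bas)
  i_end <- min(length(dx), i_on + round(search_ms / 1000 * fs))
  if (i_on + 1L > i_end) return(NA_real_)
  seg <- abs(dx[(i_on + 1L):i_end])
  hit <- which(seg > thr)
  if (length(hit) == 0) return(NA_real_)
  hit[1L] / fs * 1000
}

#' Response peak and response peak amplitude (RPA)
#'
#' The response peak (RP) is the extremal (most negative, for the default
#' negative-going response) value within 50 ms after the onset-latency
#' instant. The RPA is taken as the onset-to-peak voltage drop
#' `|trace(ROL) - RP|` -- the reading of the onset/peak combination that is
#' positive and monotone in response size.
#'
#' @param trace,fs,onset as in [response_onset_latency()].
#' @param rol_ms onset latency, ms (from [response_onset_latency()]).
#' @param window_ms search span after the onset instant, ms.
#' @param polarity `"neg"` (default) or `"pos"`, the expected main-peak sign.
#' @return list with `rp` (microvolt), `rpa` (microvolt), `peak_ms` (peak
#'   time relative to stimulus onset, ms); all `NA` if `rol_ms` is missing.
#' @export
response_peak_amplitude <- function(trace, fs, onset, rol_ms, window_ms = 50,
                                    polarity = c("neg", "pos")) {
  polarity <- match.arg(polarity)
  if (is.na(rol_ms)) return(list(rp = NA_real_, rpa = NA_real_, peak_ms = NA_real_))
  i_rol <- round((onset + rol_ms / 1000) * fs) + 1L
  i_end <- min(length(trace), i_rol + round(window_ms / 1000 * fs))
  seg <- trace[i_rol:i_end]
  k <- if (polarity == "neg") which.min(seg) else which.max(seg)
  rp <- seg[k]
  list(rp = rp, rpa = abs(trace[i_rol] - rp),
       peak_ms = rol_ms + (k - 1L) / fs * 1000)
}

#' Positive rebound (PR)
#'
#' Maximum positive voltage within 100 ms following the main response peak;
#' absent (`NA`) when the trace stays non-positive there.
#'
#' @param trace,fs,onset as in [response_onset_latency()].
#' @param peak_ms main-peak time relative to onset, ms.
#' @param window_ms search span after the peak, ms.
#' @return rebound amplitude in microvolt, or `NA` when absent.
#' @export
positive_rebound <- function(trace, fs, onset, peak_ms, window_ms = 100) {
  if (is.na(peak_ms)) return(NA_real_)
  i_pk <- round((onset + peak_ms / 1000) * fs) + 1L
  i0 <- i_pk + 1L
  i1 <- min(length(trace), i_pk + round(window_ms / 1000 * fs))
  if (i0 > i1) return(NA_real_)
  m <- max(trace[i0:i1])
  if (m <= 0) NA_real_ else m
}

#' Time-normalized LFP (tLFP)
#'
#' `tLFP = AUC / RD`. The response duration RD runs from the onset instant
#' until the trace first returns, after the main peak, to its value at the
#' onset instant (capped at `cap_ms`); AUC is the integral of
#' `|trace - trace(ROL)|` over that span.
#'
#' @param trace,fs,onset as in [response_onset_latency()].
#' @param rol_ms onset latency, ms.
#' @param peak_ms main-peak time, ms.
#' @param cap_ms cap on the response duration, ms.
#' @param polarity main-peak sign, as in [response_peak_amplitude()].
#' @return list with `tlfp` (microvolt), `rd_ms`, `auc` (microvolt * s) and
#'   `capped` (logical).
#' @export
time_normalized_lfp <- function(trace, fs, onset, rol_ms, peak_ms,
                                cap_ms = 300, polarity = c("neg", "pos")) {
  polarity <- match.arg(polarity)
  if (is.na(rol_ms) || is.na(peak_ms))
    return(list(tlfp = NA_real_, rd_ms = NA_real_, auc = NA_real_, capped = NA))
  i_rol <- round((onset + rol_ms / 1000) * fs) + 1L
  i_pk <- round((onset + peak_ms / 1000) * fs) + 1L
  v0 <- trace[i_rol]
  i_cap <- min(length(trace), i_rol + round(cap_ms / 1000 * fs))
  seg_after <- if (i_pk + 1L <= i_cap) trace[(i_pk + 1L):i_cap] else numeric(0)
  back <- if (polarity == "neg") which(seg_after >= v0) else which(seg_after <= v0)
  capped <- length(back) == 0
  i_ret <- if (capped) i_cap else i_pk + back[1L]
  rd_s <- (i_ret - i_rol) / fs
  if (rd_s <= 0)
    return(list(tlfp = 0, rd_ms = 0, auc = 0, capped = capped))
  auc <- sum(abs(trace[i_rol:i_ret] - v0)) / fs
  list(tlfp = auc / rd_s, rd_ms = rd_s * 1000, auc = auc, capped = capped)
}

#' Evoked MUA features for one stimulus
#'
#' The evoked MUA starts at `t1`, the first (layer-pooled) spike after the
#' stimulus onset, provided it falls within the response window (100 ms);
#' spikes following `t1` with inter-spike gaps below 20 ms extend the event
#' to its last spike `t2`. Latency is `t1 - onset`, duration `T = t2 - t1`,
#' rate `n_spikes / T` (missing for zero-duration, single-spike events).
#'
#' @param times sorted spike times of one channel or layer pool, s.
#' @param onset stimulus onset, s.
#' @param window response window after onset, s.
#' @param gap maximal inter-spike interval inside the evoked event, s.
#' @return list `latency_ms`, `duration_ms`, `rate_hz` (all `NA` when no
#'   spike falls in the window).
#' @export
mua_features <- function(times, onset, window = 0.100, gap = 0.020) {
  i1 <- which(times > onset & times <= onset + window)
  if (length(i1) == 0)
    return(list(latency_ms = NA_real_, duration_ms = NA_real_,
                rate_hz = NA_real_))
  i1 <- i1[1L]
  t1 <- times[i1]
  i2 <- i1
  while (i2 < length(times) && times[i2 + 1L] - times[i2] < gap) i2 <- i2 + 1L
  dur <- times[i2] - t1
  n_sp <- i2 - i1 + 1L
  list(latency_ms = (t1 - onset) * 1000,
       duration_ms = dur * 1000,
       rate_hz = if (dur > 0) n_sp / dur else NA_real_)
}

#' Per-trial, per-layer feature table
#'
#' Runs the LFP features (ROL, RPA, PR, tLFP) on each layer-mean LFP trace
#' and the MUA features (latency, duration, rate) on layer-pooled spike
#' events, for every stimulus.
#'
#' @param lfp a `band_signal` (LFP band; the feature path uses 2500 Hz).
#' @param raster a `spike_raster`.
#' @param stim stimulus table with `onset` and `amp_class`.
#' @param states optional vector of "UP"/"DOWN" per stimulus (from
#'   [label_stimuli()]).
#' @param baseline_window ROL baseline span, s (truncated to the available
#'   pre-stimulus span).
#' @param smooth_ms derivative smoothing for ROL, ms.
#' @return list of two data.frames, `lfp` (trial, layer, ROL, RPA, PR, tLFP,
#'   state, amp_class) and `mua` (trial, layer, latency, duration, rate,
#'   state, amp_class).
#' @export
extract_features <- function(lfp, raster, stim, states = NULL,
                             baseline_window = 10, smooth_ms = 2) {
  layers <- unique(lfp$channels$layer)
  if (is.null(states)) states <- rep(NA_character_, nrow(stim))
  pooled <- lapply(layers, function(l)
    sort(unlist(raster$times[raster$channels$index[raster$channels$layer == l]],
                use.names = FALSE)))
  names(pooled) <- layers
  lfp_rows <- list(); mua_rows <- list()
  for (l in layers) {
    tr <- layer_mean_lfp(lfp, l)
    dx <- trace_derivative(tr, lfp$fs, smooth_ms)
    times_l <- pooled[[l]]
    for (k in seq_len(nrow(stim))) {
      on <- stim$onset[k]
      bw <- min(baseline_window, on - 1 / lfp$fs)
      rol <- rol_from_deriv(dx, lfp$fs, on, baseline_window = bw)
      pk <- response_peak_amplitude(tr, lfp$fs, on, rol)
      pr <- positive_rebound(tr, lfp$fs, on, pk$peak_ms)
      tl <- time_normalized_lfp(tr, lfp$fs, on, rol, pk$peak_ms)
      lfp_rows[[length(lfp_rows) + 1L]] <- data.frame(
        trial = k, layer = l, ROL = rol, RPA = pk$rpa, PR = pr,
        tLFP = tl$tlfp, state = states[k], amp_class = stim$amp_class[k],
        stringsAsFactors = FALSE)
      mf <- mua_features(times_l, on)
      mua_rows[[length(mua_rows) + 1L]] <- data.frame(
        trial = k, layer = l, latency = mf$latency_ms,
        duration = mf$duration_ms, rate = mf$rate_hz,
        state = states[k], amp_class = stim$amp_class[k],
        stringsAsFactors = FALSE)
    }
  }
  list(lfp = do.call(rbind, lfp_rows), mua = do.call(rbind, mua_rows))
}
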