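#' Split a recording into LFP or spike band
#'
#' Zero-phase (forward-backward) elliptic filtering per channel. The LFP band
#' (0.1--300 Hz) is realized as a cascade of an order-2 elliptic highpass at
#' 0.1 Hz and an order-4 elliptic lowpass at 300 Hz -- a single bandpass
#' design with a normalized low edge of 2e-5 is numerically ill-conditioned.
#' The spike band (300--3000 Hz) is a single order-4 elliptic bandpass.
#' Passband ripple 0.01 dB, stopband attenuation 40 dB (zero-phase filtering squares the ripple; 0.01 dB keeps repeated filtering of in-band signals within 1% RMS).
#'
#' @param rec a `whisk_recording` (see [generate_recording()]), or any list
#'   with `samples` (channels x time), `fs`, `channels`.
#' @param band `"LFP"` or `"SPIKE"`.
#' @param downsample_to optional target rate, Hz, for the LFP branch
#'   (2500 for the feature path, 1000 for the classifier path). Must divide
#'   `fs`. The signal is already band-limited to 300 Hz, so decimation is a
#'   plain subsampling.
#' @return object of class `band_signal`: `samples`, `fs`, `band`, `channels`.
#' @export
bandpass <- function(rec, band = c("LFP", "SPIKE"), downsample_to = NULL) {
  band <- match.arg(band)
  fs <- rec$fs
  upper <- if (band == "LFP") 300 else 3000
  if (fs <= 2 * upper)
    stop(sprintf("sampling rate %g Hz violates the Nyquist bound for the %s band (needs fs > %g Hz)",
                 fs, band, 2 * upper))
  if (band == "LFP") {
    hp <- signal::ellip(2, 0.01, 40, 0.1 / (fs / 2), type = "high")
    lp <- signal::ellip(4, 0.01, 40, 300 / (fs / 2), type = "low")
    filt <- function(x) signal::filtfilt(lp, signal::filtfilt(hp, x))
  } else {
    bp <- signal::ellip(4, 0.01, 40, c(300, 3000) / (fs / 2), type = "pass")
    filt <- function(x) signal::filtfilt(bp, x)
  }
  out <- rec$samples
  for (i in seq_len(nrow(out))) out[i, ] <- filt(rec$samples[i, ])
  fs_out <- fs
  if (!is.null(downsample_to)) {
    if (band != "LFP") stop("downsampling is defined for the LFP branch only")
    dec <- fs / downsample_to
    if (abs(dec - round(dec)) > 1e-9)
      stop("downsample_to must divide fs")
    out <- out[, seq(1L, ncol(out), by = round(dec)), drop = FALSE]
    fs_out <- downsample_to
  }
  structure(list(samples = out, fs = fs_out, band = band,
                 channels = rec$channels),
            class = "band_signal")
}

#' Detect spikes by amplitude thresholding
#'
#' Per channel, the background-noise standard deviation is estimated robustly
#' as `sigma_n = median(|x|) / 0.6745` (the plain SD over the whole trace
#' inflates the threshold when firing is dense; `sigma_method = "sd"` restores
#' it). The threshold is `Thr = 3 * sigma_n`. A spike is registered at the
#' first sample where `|x|` (or `-x` for `polarity = "neg"`) exceeds `Thr`,
#' and further crossings within `dead_time` are absorbed into the same event.
#'
#' @param sig a `band_signal` with `band == "SPIKE"`.
#' @param polarity `"both"` (threshold on `|x|`, default) or `"neg"`.
#' @param dead_time refractory period of the detector, s.
#' @param sigma_method `"mad"` (robust, default) or `"sd"`.
#' @return object of class `spike_raster`: `times` (list of sorted spike-time
#'   vectors, s, one per channel), `sigma` and `threshold` (microvolt, per
#'   channel), `channels`, `span` (c(0, duration)).
#' @export
detect_spikes <- function(sig, polarity = c("both", "neg"), dead_time = 0.001,
                          sigma_method = c("mad", "sd")) {
  polarity <- match.arg(polarity)
  sigma_method <- match.arg(sigma_method)
  if (!identical(sig$band, "SPIKE"))
    stop("detect_spikes expects the SPIKE band")
  n_ch <- nrow(sig$samples)
  sigma <- numeric(n_ch); times <- vector("list", n_ch)
  dead_n <- max(1L, round(dead_time * sig$fs))
  for (i in seq_len(n_ch)) {
    x <- sig$samples[i, ]
    s <- if (sigma_method == "mad") median(abs(x)) / 0.6745 else sd(x)
    sigma[i] <- s
    thr <- 3 * s
    a <- if (polarity == "both") abs(x) else -x
    if (thr <= 0) { times[[i]] <- numeric(0); next }
    over <- a > thr
    # upward crossings: first sample of each excursion above threshold
    cross <- which(over & !c(FALSE, over[-length(over)]))
    keep <- integer(0)
    last <- -Inf
    for (k in cross) {
      if (k - last >= dead_n) { keep <- c(keep, k); last <- k }
    }
    times[[i]] <- (keep - 1L) / sig$fs
  }
  structure(list(times = times, sigma = sigma, threshold = 3 * sigma,
                 channels = sig$channels,
                 span = c(0, ncol(sig$samples) / sig$fs)),
            class = "spike_raster")
}

#' Group spikes into multi-unit activity (MUA) events
#'
#' A MUA event is a maximal run of spikes in which consecutive spikes are
#' strictly less than `gap` (20 ms) apart. With `scope = "layer"` the spike
#' times of all channels in a layer are pooled (merged and sorted) before
#' grouping.
#'
#' @param raster a `spike_raster`.
#' @param scope `"channel"` or `"layer"`.
#' @param gap maximal allowed inter-spike interval inside an event, s
#'   (exclusive bound: a gap of exactly `gap` splits events).
#' @return data.frame with columns `group` (channel index or layer label),
#'   `t1`, `t2` (s), `n_spikes`.
#' @export
group_mua <- function(raster, scope = c("channel", "layer"), gap = 0.020) {
  scope <- match.arg(scope)
  pooled <- if (scope == "channel") {
    stats::setNames(raster$times, as.character(seq_along(raster$times)))
  } else {
    lays <- unique(raster$channels$layer)
    stats::setNames(lapply(lays, function(l) {
      sort(unlist(raster$times[raster$channels$index[raster$channels$layer == l]],
                  use.names = FALSE))
    }), lays)
  }
  rows <- lapply(names(pooled), function(g) {
    t <- pooled[[g]]
    if (length(t) == 0) return(NULL)
    brk <- c(0L, which(diff(t) >= gap), length(t))
    data.frame(group = g,
               t1 = t[brk[-length(brk)] + 1L],
               t2 = t[brk[-1L]],
               n_spikes = diff(brk),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(group = character(0), t1 = numeric(0), t2 = numeric(0),
                      n_spikes = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
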