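# Shared fixtures, generated once per test session and cached.
.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixtures)) assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# small session: 8 trials/class, used by unit tests
fix_small <- function() fixture("small", function() {
  cfg <- synth_config(seed = 42, n_trials = c(large = 8, medium = 8, small = 8))
  g <- generate_recording(cfg)
  spk <- bandpass(g$recording, "SPIKE")
  raster <- detect_spikes(spk)
  lfp <- bandpass(g$recording, "LFP", downsample_to = 2500)
  list(cfg = cfg, g = g, raster = raster, lfp = lfp)
})

# trial dataset derived from the small session
fix_small_dataset <- function() fixture("small_ds", function() {
  f <- fix_small()
  build_trial_dataset(f$g$recording, f$g$stimuli,
                      states = f$g$truth$truth_state)
})

# full-size session (61/63/61 trials) driving the end-to-end checks
fix_default <- function() fixture("default", function() {
  cfg <- synth_config(seed = 1)
  g <- generate_recording(cfg)
  lfp <- bandpass(g$recording, "LFP", downsample_to = 2500)
  ds <- build_trial_dataset(g$recording, g$stimuli, states = g$truth$truth_state)
  spk <- bandpass(g$recording, "SPIKE")
  raster <- detect_spikes(spk)
  trace <- compute_ifr(raster)
  det_states <- label_stimuli(trace, g$stimuli)$state
  feats <- extract_features(lfp, raster, g$stimuli, states = det_states,
                            baseline_window = 1)
  list(cfg = cfg, stimuli = g$stimuli, truth = g$truth, ds = ds,
       feats = feats, det_states = det_states)
})

# independent brute-force oracles ------------------------------------------

# spike detection: plain per-sample scan with dead time
oracle_detect <- function(x, fs, dead_time = 0.001) {
  s <- median(abs(x)) / 0.6745
  thr <- 3 * s
  if (thr <= 0) return(numeric(0))
  dead_n <- max(1L, round(dead_time * fs))
  out <- integer(0)
  last <- -Inf
  above_prev <- FALSE
  for (i in seq_along(x)) {
    above <- abs(x[i]) > thr
    if (above && !above_prev && (i - last) >= dead_n) {
      out <- c(out, i); last <- i
    }
    above_prev <- above
  }
  (out - 1L) / fs
}

# threshold-crossing encoding: per-threshold scan over sample pairs
oracle_encode <- function(trace, thresholds, times) {
  n <- length(trace)
  rising <- lapply(thresholds, function(th) {
    hits <- which(trace[-n] <= th & th < trace[-1L])
    times[hits + 1L]
  })
  falling <- lapply(thresholds, function(th) {
    hits <- which(trace[-n] >= th & th > trace[-1L])
    times[hits + 1L]
  })
  c(rising, falling)
}

# sliding-window spike counts (IFR), computed naively per window
oracle_ifr <- function(times_list, span, window = 0.010, step = 0.001) {
  n_steps <- max(1L, floor((diff(span) - window) / step) + 1L)
  starts <- span[1] + (seq_len(n_steps) - 1L) * step
  all_t <- unlist(times_list, use.names = FALSE)
  vapply(starts, function(t0)
    sum(all_t >= t0 & all_t < t0 + window) / window, 1.0)
}

# permutation p-value for a difference-of-mean-ranks statistic (KW oracle)
oracle_kw_perm <- function(groups, n_perm = 2000, seed = 1) {
  x <- unlist(groups); gl <- rep(seq_along(groups), lengths(groups))
  stat <- function(g) {
    r <- rank(x)
    rb <- tapply(r, g, mean)
    sum(lengths(groups) * (rb - mean(r))^2)
  }
  obs <- stat(gl)
  with_seed_test(seed, {
    ref <- replicate(n_perm, stat(sample(gl)))
    mean(ref >= obs - 1e-12)
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}
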