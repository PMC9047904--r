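#' Build the per-trial classification dataset from a recording
#'
#' Runs the standard preprocessing once (LFP band at 1 kHz for the
#' classifier path, spike band + threshold detection for MUA) and slices
#' trial windows on a stimulus-relative clock (onset at 0).
#'
#' @param rec a `whisk_recording`.
#' @param stim stimulus table (`onset`, `amp_class`).
#' @param states optional per-stimulus "UP"/"DOWN" vector.
#' @param pre,post window span before/after onset, s.
#' @param lfp_fs classifier-path LFP rate, Hz.
#' @return object of class `whisk_trials`: `lfp_layers` (list layer ->
#'   trials x samples matrix), `t_lfp` (times relative to onset),
#'   `onset_index`, `fs_lfp`, `mua_trials` (list of per-channel spike-time
#'   lists, relative to onset), `labels` (factor), `states`, `n_channels`.
#' @export
build_trial_dataset <- function(rec, stim, states = NULL, pre = 1, post = 0.1,
                                lfp_fs = 1000) {
  lfp <- bandpass(rec, "LFP", downsample_to = lfp_fs)
  spk <- bandpass(rec, "SPIKE")
  raster <- detect_spikes(spk)
  layers <- unique(rec$channels$layer)
  n_tr <- nrow(stim)
  n_win <- round((pre + post) * lfp_fs) + 1L
  t_lfp <- seq(-pre, post, by = 1 / lfp_fs)
  lfp_layers <- lapply(layers, function(l) {
    tr <- layer_mean_lfp(lfp, l)
    out <- matrix(NA_real_, n_tr, n_win)
    for (k in seq_len(n_tr)) {
      i0 <- round((stim$onset[k] - pre) * lfp_fs) + 1L
      out[k, ] <- tr[i0:(i0 + n_win - 1L)]
    }
    out
  })
  names(lfp_layers) <- layers
  mua_trials <- lapply(seq_len(n_tr), function(k) {
    lapply(raster$times, function(ts) {
      w <- ts[ts >= stim$onset[k] - pre & ts <= stim$onset[k] + post]
      w - stim$onset[k]
    })
  })
  structure(list(
    lfp_layers = lfp_layers, t_lfp = t_lfp,
    onset_index = round(pre * lfp_fs) + 1L, fs_lfp = lfp_fs,
    mua_trials = mua_trials,
    labels = factor(stim$amp_class, levels = c("large", "medium", "small")),
    states = states, n_channels = length(raster$times)),
    class = "whisk_trials")
}

# stratified train/validation/test split of trial indices
split_trials <- function(labels, test_frac = 0.2, val_frac = 0.2, seed = 1L,
                         stratified = TRUE) {
  with_seed(seed, {
    n <- length(labels)
    for (attempt in 1:20) {
      if (stratified) {
        test <- unlist(lapply(levels(labels), function(l) {
          i <- which(labels == l)
          sample(i, max(1L, round(test_frac * length(i))))
        }))
      } else {
        test <- sample(n, max(1L, round(test_frac * n)))
      }
      rest <- setdiff(seq_len(n), test)
      if (stratified) {
        val <- unlist(lapply(levels(labels), function(l) {
          i <- intersect(which(labels == l), rest)
          sample(i, max(1L, round(val_frac * length(i))))
        }))
      } else {
        val <- sample(rest, max(1L, round(val_frac * length(rest))))
      }
      train <- setdiff(rest, val)
      ok <- all(vapply(list(train, val, test), function(ix)
        all(levels(labels) %in% labels[ix]), TRUE))
      if (ok || !stratified) break
    }
    list(train = train, val = val, test = sort(test))
  })
}

#' Liquid-state-machine classifier specification
#'
#' Grid search over the input/excitatory/inhibitory weight-scale factors and
#' the SVM regularization parameter C on the validation split; the liquid is
#' rebuilt per evaluation run (wiring resampled along with the split), the
#' readout is a linear support vector machine on the filtered excitatory
#' state at 45 ms post onset.
#'
#' @param signal `"lfp"` (threshold-encoded layer mean) or `"mua"` (direct
#'   electrode spike trains).
#' @param layer LFP source layer.
#' @param hardware apply [apply_hardware_constraints()] to the liquid.
#' @param n_thresh encoder thresholds (LFP path).
#' @param grid named list of vectors `input`, `e`, `i`, `C`.
#' @param lsm_args overrides forwarded to [lsm_config()].
#' @return classifier object for [run_protocol()].
#' @export
classifier_lsm <- function(signal = c("mua", "lfp"), layer = "IV",
                           hardware = FALSE, n_thresh = 50L,
                           grid = list(input = c(0.5, 1, 2), e = c(0.5, 1, 2),
                                       i = c(0.5, 1, 2), C = c(0.1, 1, 10)),
                           lsm_args = list()) {
  signal <- match.arg(signal)
  name <- paste0("lsm-", signal, if (hardware) "-hw" else "")
  fit_predict <- function(dataset, idx_train, idx_val, idx_test, seed) {
    cfg <- do.call(lsm_config, c(list(signal = signal), lsm_args))
    if (signal == "lfp") {
      cfg$n_channels <- 2L * n_thresh
      win <- dataset$lfp_layers[[layer]]
      if (is.null(win)) stop(sprintf("layer %s missing from the dataset", layer))
      enc_cfg <- encoder_config(n_thresh,
                                traces = win[c(idx_train, idx_val), , drop = FALSE])
      trial_inputs <- lapply(seq_len(nrow(win)), function(k)
        encode(win[k, ], enc_cfg, times = dataset$t_lfp)$events)
    } else {
      cfg$n_channels <- dataset$n_channels
      trial_inputs <- dataset$mua_trials
    }
    base_net <- build_network(cfg, seed = seed)
    if (hardware)
      base_net <- apply_hardware_constraints(base_net, seed = seed + 1L)
    best <- list(acc = -Inf)
    combos <- expand.grid(input = grid$input, e = grid$e, i = grid$i)
    for (q in seq_len(nrow(combos))) {
      net <- scale_network(base_net, as.list(combos[q, ]))
      states <- lsm_trial_states(net, trial_inputs, seed = seed * 1000L + q)
      for (C in grid$C) {
        sv <- e1071::svm(x = states[idx_train, , drop = FALSE],
                         y = dataset$labels[idx_train],
                         kernel = "linear", cost = C, scale = FALSE)
        acc <- mean(predict(sv, states[idx_val, , drop = FALSE]) ==
                      dataset$labels[idx_val])
        if (acc > best$acc)
          best <- list(acc = acc, sv = sv, states = states,
                       combo = combos[q, ], C = C)
      }
    }
    list(pred = predict(best$sv, best$states[idx_test, , drop = FALSE]),
         info = list(combo = best$combo, C = best$C, val_acc = best$acc))
  }
  structure(list(name = name, fit_predict = fit_predict), class = "whisk_classifier")
}

# bin spike events into a T x n_channels 0/1 matrix over [0, window) s
bin_events <- function(events, window = 0.050, dt = 0.001) {
  Tn <- round(window / dt)
  m <- matrix(0, Tn, length(events))
  for (c_i in seq_along(events)) {
    ts <- events[[c_i]]
    ts <- ts[ts >= 0 & ts < window]
    if (length(ts) > 0) m[cbind(pmin(Tn, floor(ts / dt) + 1L), c_i)] <- 1
  }
  m
}

#' BPTT-trained spiking-network classifier specification
#'
#' Trains the recurrent LIF network of [train_bptt()] on threshold-encoded
#' LFP events (or direct MUA spikes) within the 50 ms window after onset.
#' The learning rate and L1 coefficient are grid-searched on validation.
#'
#' @param signal `"lfp"` or `"mua"`.
#' @param layer LFP source layer.
#' @param n_thresh encoder thresholds (LFP path).
#' @param n_rec recurrent population size.
#' @param epochs training epochs per grid point.
#' @param grid named list `lr`, `l1`.
#' @return classifier object for [run_protocol()].
#' @export
classifier_snn_bptt <- function(signal = c("mua", "lfp"), layer = "IV",
                                n_thresh = 50L, n_rec = 125L, epochs = 60L,
                                grid = list(lr = c(0.02, 0.05), l1 = 1e-5)) {
  signal <- match.arg(signal)
  fit_predict <- function(dataset, idx_train, idx_val, idx_test, seed) {
    if (signal == "lfp") {
      win <- dataset$lfp_layers[[layer]]
      enc_cfg <- encoder_config(n_thresh,
                                traces = win[c(idx_train, idx_val), , drop = FALSE])
      inputs <- lapply(seq_len(nrow(win)), function(k)
        bin_events(encode(win[k, ], enc_cfg, times = dataset$t_lfp)$events))
    } else {
      inputs <- lapply(dataset$mua_trials, bin_events)
    }
    best <- list(acc = -Inf)
    for (lr in grid$lr) for (l1 in grid$l1) {
      cfg <- bptt_config(n_in = ncol(inputs[[1]]), n_rec = n_rec,
                         epochs = epochs, lr = lr, l1 = l1)
      fit <- train_bptt(inputs[idx_train], dataset$labels[idx_train], cfg,
                        seed = seed,
                        val_inputs = inputs[idx_val],
                        val_labels = dataset$labels[idx_val])
      va <- mean(predict_bptt(fit$net, inputs[idx_val])$class ==
                   as.integer(dataset$labels[idx_val]))
      if (va > best$acc) best <- list(acc = va, fit = fit)
    }
    cls <- predict_bptt(best$fit$net, inputs[idx_test])$class
    list(pred = factor(levels(dataset$labels)[cls],
                       levels = levels(dataset$labels)),
         info = list(val_acc = best$acc))
  }
  structure(list(name = paste0("snn-bp-", signal), fit_predict = fit_predict),
            class = "whisk_classifier")
}

#' Conventional baseline classifier specifications
#'
#' `classifier_ff()`: feed-forward network on the 50-sample LFP window.
#' `classifier_lstm()`: sequential LSTM on the same window.
#' `classifier_hcrf()`: random forest on hand-crafted LFP features.
#' `classifier_rf_mua()`: random forest on exponentially filtered MUA
#' counts.
#'
#' @param layer LFP source layer (LFP-based baselines).
#' @param epochs training epochs where applicable.
#' @return classifier object for [run_protocol()].
#' @export
classifier_ff <- function(layer = "IV", epochs = 50L) {
  fit_predict <- function(dataset, idx_train, idx_val, idx_test, seed) {
    x <- t(apply(dataset$lfp_layers[[layer]], 1, make_ff_inputs,
                 onset_index = dataset$onset_index, fs = dataset$fs_lfp))
    m <- train_ff(x[idx_train, ], dataset$labels[idx_train],
                  x[idx_val, ], dataset$labels[idx_val], seed = seed,
                  epochs = epochs)
    list(pred = predict_ff(m, x[idx_test, , drop = FALSE]),
         info = list(val_acc = m$val_acc))
  }
  structure(list(name = "ff", fit_predict = fit_predict), class = "whisk_classifier")
}

#' @rdname classifier_ff
#' @export
classifier_lstm <- function(layer = "IV", epochs = 250L) {
  fit_predict <- function(dataset, idx_train, idx_val, idx_test, seed) {
    x <- t(apply(dataset$lfp_layers[[layer]], 1, make_ff_inputs,
                 onset_index = dataset$onset_index, fs = dataset$fs_lfp))
    m <- train_lstm(x[idx_train, ], dataset$labels[idx_train],
                    x[idx_val, ], dataset$labels[idx_val], seed = seed,
                    epochs = epochs)
    list(pred = predict_lstm(m, x[idx_test, , drop = FALSE]),
         info = list(val_acc = m$val_acc))
  }
  structure(list(name = "lstm", fit_predict = fit_predict), class = "whisk_classifier")
}

#' @rdname classifier_ff
#' @export
classifier_hcrf <- function(layer = "IV") {
  fit_predict <- function(dataset, idx_train, idx_val, idx_test, seed) {
    x <- hc_feature_matrix(dataset$lfp_layers[[layer]], dataset$fs_lfp,
                           dataset$onset_index)
    m <- train_rf(x[idx_train, ], dataset$labels[idx_train],
                  x[idx_val, ], dataset$labels[idx_val], seed = seed)
    list(pred = predict(m$model, x[idx_test, , drop = FALSE]),
         info = list(val_acc = m$val_acc, best = m$best))
  }
  structure(list(name = "hc-rf", fit_predict = fit_predict), class = "whisk_classifier")
}

#' @rdname classifier_ff
#' @export
classifier_rf_mua <- function() {
  fit_predict <- function(dataset, idx_train, idx_val, idx_test, seed) {
    x <- mua_filter_features(dataset$mua_trials)
    m <- train_rf(x[idx_train, ], dataset$labels[idx_train],
                  x[idx_val, ], dataset$labels[idx_val], seed = seed)
    list(pred = predict(m$model, x[idx_test, , drop = FALSE]),
         info = list(val_acc = m$val_acc, best = m$best))
  }
  structure(list(name = "rf-mua", fit_predict = fit_predict), class = "whisk_classifier")
}

#' Repeated-split evaluation protocol
#'
#' For each of `n_runs` evaluations: draw an independent stratified
#' train/validation/test split (80/20 with a 20%-of-training validation
#' part), let the classifier grid-search its hyperparameters on validation,
#' evaluate once on the untouched test split, and report the mean and
#' standard deviation of the per-run test accuracies.
#'
#' @param dataset a `whisk_trials` dataset.
#' @param classifier a classifier object (e.g. [classifier_lsm()]).
#' @param n_runs number of independent evaluations.
#' @param test_frac,val_frac split fractions.
#' @param seed master seed; run k derives its split seed and classifier seed
#'   from it.
#' @param stratified stratify splits by class (a plain random split can
#'   leave a class absent at this dataset scale).
#' @return object of class `whisk_protocol`: `table` (one summary row:
#'   classifier, condition, mean_acc, sd_acc, n_runs), `runs` (per run:
#'   `acc`, `pred`, `idx_test`).
#' @export
run_protocol <- function(dataset, classifier, n_runs = 20L, test_frac = 0.2,
                         val_frac = 0.2, seed = 1L, stratified = TRUE) {
  runs <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    sp <- split_trials(dataset$labels, test_frac, val_frac,
                       seed = seed * 131L + r, stratified = stratified)
    res <- classifier$fit_predict(dataset, sp$train, sp$val, sp$test,
                                  seed = seed * 977L + r)
    acc <- 100 * mean(res$pred == dataset$labels[sp$test])
    runs[[r]] <- list(acc = acc, pred = res$pred, idx_test = sp$test,
                      info = res$info)
  }
  accs <- vapply(runs, `[[`, 1.0, "acc")
  structure(list(
    table = data.frame(classifier = classifier$name, condition = "all",
                       mean_acc = mean(accs), sd_acc = sd(accs),
                       n_runs = n_runs, stringsAsFactors = FALSE),
    runs = runs),
    class = "whisk_protocol")
}

#' State-conditioned accuracy breakdown
#'
#' Training uses the combined data (inside [run_protocol()]); here the
#' per-run test predictions are split into UP-only and DOWN-only subsets and
#' scored separately. A state absent from every test split yields a row with
#' `n_trials = 0` and missing accuracy.
#'
#' @param protocol a `whisk_protocol` from [run_protocol()].
#' @param dataset the dataset it was run on.
#' @param states per-trial "UP"/"DOWN" vector (defaults to
#'   `dataset$states`).
#' @return data.frame with one row per state: condition, mean_acc, sd_acc,
#'   n_runs, mean_n_trials.
#' @export
state_conditioned_eval <- function(protocol, dataset, states = NULL) {
  states <- states %||% dataset$states
  if (is.null(states)) stop("no state labels available")
  rows <- lapply(c("UP", "DOWN"), function(st) {
    per_run <- vapply(protocol$runs, function(r) {
      i <- r$idx_test[states[r$idx_test] == st]
      if (length(i) == 0) return(c(NA_real_, 0))
      keep <- states[r$idx_test] == st
      c(100 * mean(r$pred[keep] == dataset$labels[i]), length(i))
    }, numeric(2))
    acc <- per_run[1, ]
    data.frame(condition = paste0(st, "-test"),
               mean_acc = mean(acc, na.rm = TRUE),
               sd_acc = sd(acc, na.rm = TRUE),
               n_runs = sum(!is.na(acc)),
               mean_n_trials = mean(per_run[2, ]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Layer-conditioned evaluation of the LFP liquid
#'
#' Repeats the full LSM-LFP protocol with the encoder fed by each layer's
#' mean LFP in turn.
#'
#' @param dataset a `whisk_trials` dataset (all layers present).
#' @param n_runs,seed protocol parameters.
#' @param layers layers to evaluate (default: all in the dataset).
#' @param ... forwarded to [classifier_lsm()].
#' @return data.frame with one row per layer: condition `layer-<k>`,
#'   mean/sd accuracy.
#' @export
layer_conditioned_eval <- function(dataset, n_runs = 20L, seed = 1L,
                                   layers = names(dataset$lfp_layers), ...) {
  missing_l <- setdiff(layers, names(dataset$lfp_layers))
  if (length(missing_l) > 0)
    stop("layer(s) missing from the recording: ", paste(missing_l, collapse = ", "))
  rows <- lapply(layers, function(l) {
    pr <- run_protocol(dataset, classifier_lsm(signal = "lfp", layer = l, ...),
                       n_runs = n_runs, seed = seed)
    data.frame(condition = paste0("layer-", l),
               mean_acc = pr$table$mean_acc, sd_acc = pr$table$sd_acc,
               n_runs = n_runs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Peristimulus time histogram
#'
#' Trial-averaged binned spike counts aligned to stimulus onset (bin width
#' 4 ms by default).
#'
#' @param trials list of trials, each a list of per-channel (or per-neuron)
#'   spike-time vectors relative to onset, s.
#' @param bin bin width, s.
#' @param window time range relative to onset, s.
#' @return matrix channels x bins of mean spike counts per trial; bin edges
#'   as the `"edges"` attribute.
#' @export
psth <- function(trials, bin = 0.004, window = c(-0.1, 0.1)) {
  edges <- seq(window[1], window[2], by = bin)
  n_bins <- length(edges) - 1L
  if (length(trials) == 0) return(matrix(0, 0, n_bins))
  n_ch <- length(trials[[1]])
  acc <- matrix(0, n_ch, n_bins)
  for (tr in trials) {
    for (c_i in seq_len(n_ch)) {
      ts <- tr[[c_i]]
      ts <- ts[ts >= window[1] & ts < window[2]]
      if (length(ts) > 0) {
        b <- pmin(n_bins, floor((ts - window[1]) / bin) + 1L)
        acc[c_i, ] <- acc[c_i, ] + tabulate(b, nbins = n_bins)
      }
    }
  }
  out <- acc / length(trials)
  attr(out, "edges") <- edges
  out
}
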