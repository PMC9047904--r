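#' Feed-forward input vectors from an LFP trace
#'
#' The 50 consecutive 1 kHz samples starting at stimulus onset
#' (t_onset, t_onset + 1 ms, ..., t_onset + 49 ms).
#'
#' @param trace LFP trace sampled at `fs`.
#' @param onset_index sample index of the stimulus onset (1-based).
#' @param n_samples window length in samples.
#' @param fs sampling rate, Hz (must be 1000 for the canonical setup).
#' @return numeric vector of length `n_samples`.
#' @export
make_ff_inputs <- function(trace, onset_index, n_samples = 50L, fs = 1000) {
  i1 <- onset_index + n_samples - 1L
  if (onset_index < 1L || i1 > length(trace))
    stop("input window exceeds the recording")
  trace[onset_index:i1]
}

# Per-feature standardization learned on the training split only.
standardize_fit <- function(x) {
  mu <- colMeans(x)
  sdv <- apply(x, 2, sd)
  sdv[sdv == 0 | !is.finite(sdv)] <- 1   # degenerate features pass through as 0
  list(mean = mu, sd = sdv)
}

standardize_apply <- function(x, st) {
  sweep(sweep(x, 2, st$mean, "-"), 2, st$sd, "/")
}

# uniform init U(-k, k), k = 1/sqrt(fan_in)
init_unif <- function(nr, nc, fan_in) {
  k <- 1 / sqrt(fan_in)
  matrix(runif(nr * nc, -k, k), nr, nc)
}

#' Train the single-hidden-layer feed-forward baseline
#'
#' 80 hidden rectified-linear units on the standardized 50-sample LFP window,
#' softmax output, cross-entropy loss with L2 penalty (coefficient 0.001),
#' optimized with L-BFGS for `epochs` iterations. Early stopping keeps the
#' parameters of the iteration with the highest validation accuracy. Weights
#' start from U(-k, k) with `k = 1/sqrt(fan_in)`; biases at zero.
#'
#' @param x_train,y_train training inputs (n x 50) and factor labels.
#' @param x_val,y_val validation split used for early stopping.
#' @param seed integer seed.
#' @param hidden hidden units.
#' @param epochs L-BFGS iteration budget.
#' @param l2 L2 regularization coefficient.
#' @return model list with `predict(x)` usable via [predict_ff()].
#' @export
train_ff <- function(x_train, y_train, x_val, y_val, seed = 1L,
                     hidden = 80L, epochs = 50L, l2 = 0.001) {
  st <- standardize_fit(x_train)
  xt <- standardize_apply(x_train, st)
  xv <- standardize_apply(x_val, st)
  n_in <- ncol(xt); n_out <- nlevels(y_train)
  yt <- as.integer(y_train); yv <- as.integer(y_val)
  with_seed(seed, {
    W1 <- init_unif(n_in, hidden, n_in); b1 <- numeric(hidden)
    W2 <- init_unif(hidden, n_out, hidden); b2 <- numeric(n_out)
    pack <- function(W1, b1, W2, b2) c(W1, b1, W2, b2)
    unpack <- function(p) {
      i <- 0L
      W1 <- matrix(p[i + seq_len(n_in * hidden)], n_in); i <- i + n_in * hidden
      b1 <- p[i + seq_len(hidden)]; i <- i + hidden
      W2 <- matrix(p[i + seq_len(hidden * n_out)], hidden); i <- i + hidden * n_out
      b2 <- p[i + seq_len(n_out)]
      list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
    }
    forward <- function(x, par) {
      h <- pmax(sweep(x %*% par$W1, 2, par$b1, "+"), 0)
      logits <- sweep(h %*% par$W2, 2, par$b2, "+")
      p <- exp(logits - apply(logits, 1, max)); p <- p / rowSums(p)
      list(h = h, p = p)
    }
    best <- list(acc = -Inf, par = NULL)
    fn <- function(p) {
      par <- unpack(p)
      fw <- forward(xt, par)
      # early-stopping bookkeeping: track the best validation accuracy seen
      fv <- forward(xv, par)
      acc <- mean(max.col(fv$p) == yv)
      if (acc > best$acc) best <<- list(acc = acc, par = par)
      -mean(log(pmax(fw$p[cbind(seq_along(yt), yt)], 1e-12))) +
        l2 * (sum(par$W1^2) + sum(par$W2^2))
    }
    gr <- function(p) {
      par <- unpack(p)
      fw <- forward(xt, par)
      n <- nrow(xt)
      d2 <- fw$p; d2[cbind(seq_len(n), yt)] <- d2[cbind(seq_len(n), yt)] - 1
      d2 <- d2 / n
      gW2 <- t(fw$h) %*% d2 + 2 * l2 * par$W2
      gb2 <- colSums(d2)
      dh <- (d2 %*% t(par$W2)) * (fw$h > 0)
      gW1 <- t(xt) %*% dh + 2 * l2 * par$W1
      gb1 <- colSums(dh)
      pack(gW1, gb1, gW2, gb2)
    }
    res <- tryCatch(
      optim(pack(W1, b1, W2, b2), fn, gr, method = "L-BFGS-B",
            control = list(maxit = epochs)),
      error = function(e) stop("feed-forward training aborted: ", conditionMessage(e)))
    par <- best$par %||% unpack(res$par)
    list(par = par, standardize = st, levels = levels(y_train),
         val_acc = best$acc, forward = forward)
  })
}

#' Predict with a trained feed-forward baseline
#' @param model result of [train_ff()].
#' @param x input matrix (raw, unstandardized).
#' @return factor of predicted labels.
#' @export
predict_ff <- function(model, x) {
  xs <- standardize_apply(x, model$standardize)
  p <- model$forward(xs, model$par)$p
  factor(model$levels[max.col(p)], levels = model$levels)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# LSTM forward pass over a batch (rows of x = trials, columns = time steps).
# Gate order along the 4H axis: input, forget, cell candidate, output.
lstm_forward <- function(x, th, H, keep = FALSE) {
  nb <- nrow(x); Tn <- ncol(x)
  h <- matrix(0, nb, H); cc <- matrix(0, nb, H)
  S <- if (keep) vector("list", Tn) else NULL
  for (t in seq_len(Tn)) {
    a <- x[, t] %*% th$Wx + h %*% th$Wh
    a <- sweep(a, 2, th$b, "+")
    i <- sigmoid(a[, 1:H, drop = FALSE])
    f <- sigmoid(a[, H + 1:H, drop = FALSE])
    g <- tanh(a[, 2 * H + 1:H, drop = FALSE])
    o <- sigmoid(a[, 3 * H + 1:H, drop = FALSE])
    c_new <- f * cc + i * g
    h_new <- o * tanh(c_new)
    if (keep) S[[t]] <- list(i = i, f = f, g = g, o = o,
                             c_prev = cc, c = c_new, h_prev = h)
    cc <- c_new; h <- h_new
  }
  logits <- sweep(h %*% th$Wo, 2, th$bo, "+")
  p <- exp(logits - apply(logits, 1, max)); p <- p / rowSums(p)
  out <- list(p = p, h = h)
  if (keep) out$S <- S
  out
}

# gradients of the mean cross-entropy w.r.t. all LSTM parameters
lstm_backward <- function(x, y_int, th, fw, H) {
  nb <- nrow(x); Tn <- ncol(x)
  d <- fw$p; d[cbind(seq_len(nb), y_int)] <- d[cbind(seq_len(nb), y_int)] - 1
  d <- d / nb
  g <- list(Wx = 0 * th$Wx, Wh = 0 * th$Wh, b = 0 * th$b,
            Wo = t(fw$h) %*% d, bo = colSums(d))
  dh <- d %*% t(th$Wo); dc <- matrix(0, nb, H)
  for (t in rev(seq_len(Tn))) {
    s <- fw$S[[t]]
    tc <- tanh(s$c)
    do <- dh * tc * s$o * (1 - s$o)
    dc <- dc + dh * s$o * (1 - tc^2)
    di <- dc * s$g * s$i * (1 - s$i)
    df <- dc * s$c_prev * s$f * (1 - s$f)
    dg <- dc * s$i * (1 - s$g^2)
    da <- cbind(di, df, dg, do)
    g$Wx <- g$Wx + x[, t] %*% da
    g$Wh <- g$Wh + t(s$h_prev) %*% da
    g$b <- g$b + colSums(da)
    dh <- da %*% t(th$Wh)
    dc <- dc * s$f
  }
  g
}

#' Train the LSTM baseline
#'
#' A 64-unit LSTM receiving the standardized LFP window sequentially through
#' a single input neuron; softmax readout of the final hidden state. Trained
#' with minibatch stochastic gradient descent (learning rate 0.1, momentum
#' 0.9, batch size 32) with early stopping on validation accuracy.
#' Weights start from U(-k, k) with `k = 1/sqrt(fan_in)`, biases at zero.
#'
#' @param x_train,y_train training inputs (n x T) and labels.
#' @param x_val,y_val validation split.
#' @param seed integer seed.
#' @param units LSTM units.
#' @param epochs training epochs.
#' @param lr learning rate.
#' @param momentum momentum factor.
#' @param batch_size minibatch size.
#' @return model list usable via [predict_lstm()].
#' @export
train_lstm <- function(x_train, y_train, x_val, y_val, seed = 1L,
                       units = 64L, epochs = 250L, lr = 0.1,
                       momentum = 0.9, batch_size = 32L) {
  st <- standardize_fit(x_train)
  xt <- standardize_apply(x_train, st)
  xv <- standardize_apply(x_val, st)
  H <- units; Tn <- ncol(xt); n_out <- nlevels(y_train)
  yt <- as.integer(y_train); yv <- as.integer(y_val)
  with_seed(seed, {
    fan <- H + 1
    th <- list(Wx = matrix(runif(4 * H, -1 / sqrt(fan), 1 / sqrt(fan)), 1),
               Wh = init_unif(H, 4 * H, fan),
               b = numeric(4 * H),
               Wo = init_unif(H, n_out, H),
               bo = numeric(n_out))
    vel <- lapply(th, function(w) 0 * w)
    best <- list(acc = -Inf, th = th)
    n <- nrow(xt)
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ok <- TRUE
      for (b0 in seq(1, n, by = batch_size)) {
        idx <- ord[b0:min(n, b0 + batch_size - 1L)]
        fw <- lstm_forward(xt[idx, , drop = FALSE], th, H, keep = TRUE)
        if (!all(is.finite(fw$p))) { ok <- FALSE; break }
        g <- lstm_backward(xt[idx, , drop = FALSE], yt[idx], th, fw, H)
        for (m in names(th)) {
          vel[[m]] <- momentum * vel[[m]] - lr * g[[m]]
          th[[m]] <- th[[m]] + vel[[m]]
        }
      }
      if (!ok) {
        warning(sprintf("LSTM training diverged at epoch %d; keeping best parameters", ep))
        break
      }
      acc <- mean(max.col(lstm_forward(xv, th, H)$p) == yv)
      if (acc > best$acc) best <- list(acc = acc, th = th)
    }
    list(th = best$th, H = H, standardize = st, levels = levels(y_train),
         val_acc = best$acc)
  })
}

#' Predict with a trained LSTM baseline
#' @param model result of [train_lstm()].
#' @param x input matrix (raw).
#' @return factor of predicted labels.
#' @export
predict_lstm <- function(model, x) {
  xs <- standardize_apply(x, model$standardize)
  p <- lstm_forward(xs, model$th, model$H)$p
  factor(model$levels[max.col(p)], levels = model$levels)
}

#' Hand-crafted LFP feature matrix for the random-forest baseline
#'
#' Per trial: response peak amplitude, positive rebound, response onset
#' latency and time-normalized LFP (extracted from the trial's layer-mean
#' trace), plus the mean and standard deviation of the 50 ms post-onset
#' window. Missing features (no onset found, absent rebound) are encoded as
#' zero so the forest can split on them.
#'
#' @param windows matrix trials x samples of LFP traces.
#' @param fs sampling rate, Hz.
#' @param onset_index sample index of stimulus onset.
#' @param smooth_ms derivative smoothing for the onset latency, ms.
#' @return matrix trials x 6 with columns RPA, PR, ROL, tLFP, win_mean,
#'   win_sd.
#' @export
hc_feature_matrix <- function(windows, fs, onset_index, smooth_ms = 2) {
  onset_s <- (onset_index - 1L) / fs
  t(apply(windows, 1, function(tr) {
    rol <- response_onset_latency(tr, fs, onset_s,
                                  baseline_window = onset_s,
                                  smooth_ms = smooth_ms)
    pk <- response_peak_amplitude(tr, fs, onset_s, rol)
    pr <- positive_rebound(tr, fs, onset_s, pk$peak_ms)
    tl <- time_normalized_lfp(tr, fs, onset_s, rol, pk$peak_ms)
    win <- tr[onset_index:min(length(tr), onset_index + round(0.05 * fs) - 1L)]
    out <- c(RPA = pk$rpa, PR = pr, ROL = rol, tLFP = tl$tlfp,
             win_mean = mean(win), win_sd = sd(win))
    out[is.na(out)] <- 0
    out
  }))
}

#' Exponentially filtered spike-count features for the MUA random forest
#'
#' Per channel, the value at `t_read` (30 ms post onset) of the spike train
#' filtered with an exponential kernel (time constant 16 ms).
#'
#' @param mua_trials list of trials, each a list of per-channel spike-time
#'   vectors relative to onset, s.
#' @param tau filter time constant, s.
#' @param t_read readout instant relative to onset, s.
#' @return matrix trials x channels.
#' @export
mua_filter_features <- function(mua_trials, tau = 0.016, t_read = 0.030) {
  t(vapply(mua_trials, function(trial) {
    vapply(trial, function(ts) {
      ts <- ts[ts <= t_read]
      if (length(ts) == 0) 0 else sum(exp(-(t_read - ts) / tau))
    }, 1.0)
  }, numeric(length(mua_trials[[1]]))))
}

#' Train a random-forest baseline with a small hyperparameter grid
#'
#' 100 trees; the number of features per split (`mtry`) and the minimal node
#' size are grid-searched on the validation split (split criterion: Gini
#' impurity).
#'
#' @param x_train,y_train training features and labels.
#' @param x_val,y_val validation split for the grid.
#' @param seed integer seed.
#' @param n_trees forest size.
#' @param grid list with `mtry` (fractions of feature count or integers) and
#'   `nodesize`.
#' @return list `model` (randomForest), `best` (chosen grid point),
#'   `val_acc`.
#' @export
train_rf <- function(x_train, y_train, x_val, y_val, seed = 1L,
                     n_trees = 100L,
                     grid = list(mtry = NULL, nodesize = c(1L, 5L))) {
  p <- ncol(x_train)
  mtry_vals <- grid$mtry %||% unique(pmax(1L, round(c(sqrt(p), p / 3, p / 2))))
  best <- list(acc = -Inf)
  for (m in mtry_vals) for (ns in grid$nodesize) {
    fit <- with_seed(seed, randomForest::randomForest(
      x = x_train, y = y_train, ntree = n_trees, mtry = m, nodesize = ns))
    acc <- mean(predict(fit, x_val) == y_val)
    if (acc > best$acc) best <- list(acc = acc, model = fit,
                                     mtry = m, nodesize = ns)
  }
  list(model = best$model, best = list(mtry = best$mtry, nodesize = best$nodesize),
       val_acc = best$acc)
}
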