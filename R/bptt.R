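#' Surrogate gradient (pseudo-derivative) of the spike nonlinearity
#'
#' `gamma * max(0, 1 - |v|)` evaluated at the normalized membrane potential
#' `v = (V - b)/b`; the dampening factor defaults to 0.3. Replaces the
#' non-existent derivative of the hard threshold during backpropagation
#' through time.
#'
#' @param v normalized membrane potential (vectorized).
#' @param gamma dampening factor.
#' @return pseudo-derivative values.
#' @export
surrogate_grad <- function(v, gamma = 0.3) {
  gamma * pmax(0, 1 - abs(v))
}

# Soft spike nonlinearity used only for gradient validation: a continuous
# function whose derivative is exactly surrogate_grad(). Maps v <= -1 to 0
# and v >= 1 to gamma.
soft_spike <- function(v, gamma = 0.3) {
  z <- numeric(length(v))
  i <- v > -1 & v < 0
  z[i] <- gamma * (v[i] + v[i]^2 / 2) + gamma / 2
  j <- v >= 0 & v < 1
  z[j] <- gamma * (v[j] - v[j]^2 / 2) + gamma / 2
  z[v >= 1] <- gamma
  z
}

#' One discrete-time LIF update step
#'
#' `V <- alpha * V + (1 - alpha) * Rm * I`; outside the refractory period a
#' neuron whose potential exceeds the threshold `b` emits a spike
#' (`z = 1/dt`) and is reset by subtracting the threshold. During the
#' refractory period the potential is held and no spike is emitted.
#'
#' @param V membrane potentials, V (vector).
#' @param I input currents (in units such that `Rm * I` is in volts).
#' @param refr remaining refractory steps per neuron (integer vector).
#' @param tau_m membrane time constant, s.
#' @param dt time step, s.
#' @param Rm membrane resistance (1 by convention when `I` is pre-scaled).
#' @param b firing threshold, V.
#' @param t_ref refractory duration, s.
#' @return list `V`, `z` (0 or `1/dt`), `refr`.
#' @export
lif_step <- function(V, I, refr = integer(length(V)), tau_m = 0.020,
                     dt = 0.001, Rm = 1, b = 0.01, t_ref = 0.002) {
  alpha <- exp(-dt / tau_m)
  active <- refr <= 0L
  Vn <- ifelse(active, alpha * V + (1 - alpha) * Rm * I, V)
  z <- ifelse(active & Vn > b, 1 / dt, 0)
  fired <- z > 0
  Vn[fired] <- Vn[fired] - b
  refr_steps <- as.integer(round(t_ref / dt))
  refr_new <- pmax(0L, refr - 1L)
  refr_new[fired] <- refr_steps
  list(V = Vn, z = z, refr = refr_new)
}

#' Configuration of the BPTT-trained recurrent spiking network
#'
#' Structure is matched to the liquid: 80/20 excitatory/inhibitory split,
#' recurrent in-degree 2 excitatory + 1 inhibitory per neuron, each input
#' channel wired to 4 random excitatory neurons, static synapses with signs
#' fixed by the presynaptic type. Neurons follow the discrete 1 ms LIF map
#' with `tau_m` 20 ms, `Rm` 1 GOhm, threshold `b` 0.01 V (reset by
#' subtraction) and the surrogate gradient of [surrogate_grad()]. Readout: 3
#' leaky integrator units (time constant `tau_out`) with a softmax over
#' their values at the window end; loss is categorical cross-entropy plus an
#' L1 penalty on active weights. Training: stochastic gradient descent; the
#' learning rate is halved when validation accuracy stalls for more than 10
#' epochs; a sign-constrained Deep-Rewiring variant keeps the live-connection
#' count of each weight matrix at the liquid scheme's count, resampling
#' dormant slots uniformly.
#'
#' @param n_in number of input channels.
#' @param n_rec number of recurrent neurons.
#' @param n_out number of classes.
#' @param frac_exc excitatory fraction of the recurrent population.
#' @param dt time step, s.
#' @param tau_m membrane time constant, s.
#' @param b threshold, V.
#' @param gamma surrogate dampening factor.
#' @param t_ref refractory period, s.
#' @param tau_out readout integrator time constant, s.
#' @param epochs training epochs.
#' @param lr initial learning rate.
#' @param lr_patience epochs without improvement before the rate is halved.
#' @param l1 L1 regularization coefficient.
#' @param temperature rewiring noise temperature.
#' @param batch_size minibatch size.
#' @param rewire enable the rewiring of dormant connections.
#' @param w_in_scale,w_rec_scale,w_out_scale initialization scales, V.
#' @return object of class `bptt_config`.
#' @export
bptt_config <- function(n_in, n_rec, n_out = 3L, frac_exc = 0.8,
                        dt = 0.001, tau_m = 0.020, b = 0.01, gamma = 0.3,
                        t_ref = 0.002, tau_out = 0.020,
                        epochs = 500L, lr = 0.05, lr_patience = 10L,
                        l1 = 1e-5, temperature = 0, batch_size = 16L,
                        rewire = TRUE,
                        w_in_scale = 0.004, w_rec_scale = 0.004,
                        w_out_scale = 0.1) {
  structure(as.list(environment()), class = "bptt_config")
}

#' Initialize a BPTT network with liquid-matched sparse structure
#'
#' @param cfg a [bptt_config()].
#' @param seed integer seed.
#' @return object of class `bptt_net`: weight matrices `W_in`
#'   (n_in x n_rec), `W_rec` (n_rec x n_rec, zero diagonal), `W_out`
#'   (n_rec x n_out), `b_out`, sign matrices, live-count targets.
#' @export
bptt_init <- function(cfg, seed = 1L) {
  with_seed(seed, {
    n_rec <- cfg$n_rec; n_in <- cfg$n_in
    n_exc <- max(3L, round(cfg$frac_exc * n_rec))
    type <- rep(c(1, -1), c(n_exc, n_rec - n_exc))  # +1 exc, -1 inh
    sign_rec <- matrix(rep(type, times = n_rec), nrow = n_rec)  # row = pre
    W_rec <- matrix(0, n_rec, n_rec)
    for (j in seq_len(n_rec)) {
      pe <- sample(setdiff(which(type == 1), j), min(2L, n_exc - 1L))
      W_rec[pe, j] <- abs(rnorm(length(pe), 0, cfg$w_rec_scale))
      inh <- which(type == -1)
      if (length(inh) > 0) {
        pi <- sample(setdiff(inh, j), min(1L, length(setdiff(inh, j))))
        W_rec[pi, j] <- abs(rnorm(length(pi), 0, cfg$w_rec_scale))
      }
    }
    W_in <- matrix(0, n_in, n_rec)
    fan <- min(4L, n_exc)
    for (c_i in seq_len(n_in)) {
      tgt <- sample(seq_len(n_exc), fan)
      W_in[c_i, tgt] <- abs(rnorm(fan, 0, cfg$w_in_scale))
    }
    structure(list(
      cfg = cfg, type = type,
      W_in = W_in, W_rec = W_rec,
      sign_rec = sign_rec,
      W_out = matrix(rnorm(n_rec * cfg$n_out, 0, cfg$w_out_scale), n_rec),
      b_out = numeric(cfg$n_out),
      k_in = sum(W_in != 0), k_rec = sum(W_rec != 0)),
      class = "bptt_net")
  })
}

# Forward pass over one batch.
# inputs: list of T x n_in spike matrices (0/1). Returns loss pieces and,
# when `keep` is TRUE, the per-step state needed by the backward pass.
bptt_forward <- function(net, inputs, labels = NULL, soft = FALSE,
                         keep = FALSE) {
  cfg <- net$cfg
  nb <- length(inputs)
  Tn <- nrow(inputs[[1]])
  n_rec <- cfg$n_rec
  alpha <- exp(-cfg$dt / cfg$tau_m)
  kappa <- exp(-cfg$dt / cfg$tau_out)
  refr_steps <- if (soft) 0L else as.integer(round(cfg$t_ref / cfg$dt))
  Wr <- net$W_rec * net$sign_rec  # signed effective weights
  Wi <- net$W_in
  V <- matrix(0, nb, n_rec)
  z <- matrix(0, nb, n_rec)
  refr <- matrix(0L, nb, n_rec)
  y <- matrix(0, nb, cfg$n_out)
  X <- vapply(inputs, identity, matrix(0, Tn, cfg$n_in))  # T x n_in x nb
  if (keep) {
    Zs <- array(0, c(Tn + 1L, nb, n_rec))
    Vpre <- array(0, c(Tn, nb, n_rec))
    Act <- array(FALSE, c(Tn, nb, n_rec))
  }
  spike_count <- 0
  for (t in seq_len(Tn)) {
    xt <- t(matrix(X[t, , ], cfg$n_in, nb))
    I <- xt %*% Wi + z %*% Wr
    active <- refr <= 0L
    A <- alpha * V + (1 - alpha) * I
    A[!active] <- V[!active]
    v_norm <- (A - cfg$b) / cfg$b
    if (soft) {
      z_new <- soft_spike(v_norm, cfg$gamma)
      dim(z_new) <- dim(A)
    } else {
      z_new <- (A > cfg$b & active) * 1
    }
    if (keep) {
      Vpre[t, , ] <- A
      Act[t, , ] <- active
    }
    V <- A - cfg$b * z_new
    refr <- pmax(refr - 1L, 0L)
    if (!soft && refr_steps > 0L) refr[z_new > 0] <- refr_steps
    z <- z_new
    spike_count <- spike_count + sum(z_new > 0)
    if (keep) Zs[t + 1L, , ] <- z
    y <- kappa * y + z %*% net$W_out
  }
  logits <- sweep(y, 2, net$b_out, "+")
  p <- exp(logits - apply(logits, 1, max))
  p <- p / rowSums(p)
  loss <- NA_real_
  if (!is.null(labels)) {
    li <- as.integer(labels)
    loss <- -mean(log(pmax(p[cbind(seq_len(nb), li)], 1e-12))) +
      cfg$l1 * (sum(net$W_in) + sum(net$W_rec))
  }
  out <- list(probs = p, loss = loss, y = y,
              rate_hz = spike_count / (nb * n_rec * Tn * cfg$dt))
  if (keep) { out$Zs <- Zs; out$Vpre <- Vpre; out$Act <- Act; out$X <- X }
  out
}

# Backward pass (BPTT with the surrogate gradient). Returns gradients of the
# cross-entropy loss w.r.t. the magnitude parameters (W_in, W_rec) and the
# readout (W_out, b_out). The L1 term is handled in the update, not here.
bptt_backward <- function(net, fwd, labels) {
  cfg <- net$cfg
  nb <- dim(fwd$Zs)[2]; Tn <- dim(fwd$Zs)[1] - 1L
  n_rec <- cfg$n_rec
  alpha <- exp(-cfg$dt / cfg$tau_m)
  kappa <- exp(-cfg$dt / cfg$tau_out)
  Wr <- net$W_rec * net$sign_rec
  li <- as.integer(labels)
  gy <- fwd$probs
  gy[cbind(seq_len(nb), li)] <- gy[cbind(seq_len(nb), li)] - 1
  gy <- gy / nb
  gW_out <- matrix(0, n_rec, cfg$n_out)
  gb_out <- colSums(gy)
  gW_in <- matrix(0, cfg$n_in, n_rec)
  gW_rec <- matrix(0, n_rec, n_rec)
  gV <- matrix(0, nb, n_rec)
  gz_future <- matrix(0, nb, n_rec)   # dL/dz_t via I_{t+1}
  gy_t <- gy                          # dL/dy_t (readout integrator adjoint)
  for (t in rev(seq_len(Tn))) {
    z_t <- matrix(fwd$Zs[t + 1L, , ], nb, n_rec)
    z_prev <- matrix(fwd$Zs[t, , ], nb, n_rec)
    A <- matrix(fwd$Vpre[t, , ], nb, n_rec)
    act <- matrix(fwd$Act[t, , ], nb, n_rec)
    v_norm <- (A - cfg$b) / cfg$b
    psi <- surrogate_grad(v_norm, cfg$gamma) / cfg$b   # dz/dA
    psi[!act] <- 0
    gz <- gz_future + gy_t %*% t(net$W_out) - cfg$b * gV
    gW_out <- gW_out + t(z_t) %*% gy_t
    gA <- gV + gz * psi
    xt <- t(matrix(fwd$X[t, , ], cfg$n_in, nb))
    gI <- (1 - alpha) * gA
    gI[!act] <- 0
    gW_in <- gW_in + t(xt) %*% gI
    gW_rec <- gW_rec + t(z_prev) %*% gI
    gz_future <- gI %*% t(Wr)
    gV_prev <- alpha * gA
    gV_prev[!act] <- gA[!act]   # held potential passes through unchanged
    gV <- gV_prev
    gy_t <- kappa * gy_t
  }
  # chain to magnitude parameters: effective W_rec = sign * magnitude
  list(W_in = gW_in, W_rec = gW_rec * net$sign_rec,
       W_out = gW_out, b_out = gb_out)
}

#' Train the recurrent spiking network with surrogate-gradient BPTT
#'
#' Unrolls the network over the input window, applies minibatch stochastic
#' gradient descent on the cross-entropy loss with L1 regularization and
#' sign-constrained rewiring that keeps the live-connection count of the
#' input and recurrent matrices at their initial (liquid-scheme) values.
#' The learning rate is halved when the monitored accuracy (validation if
#' provided, else training) fails to improve for more than `lr_patience`
#' epochs. Divergence (non-finite loss) aborts and returns the last stable
#' parameters with a warning.
#'
#' @param inputs list of T x n_in binary spike matrices (one per trial).
#' @param labels factor of class labels, one per trial.
#' @param cfg a [bptt_config()].
#' @param seed integer seed (initialization, shuffling, rewiring noise).
#' @param val_inputs,val_labels optional validation set for the schedule and
#'   for parameter selection at the best validation accuracy.
#' @return list `net` (trained `bptt_net`), `log` (data.frame epoch, loss,
#'   train_acc, val_acc, lr), `best_epoch`.
#' @export
train_bptt <- function(inputs, labels, cfg, seed = 1L,
                       val_inputs = NULL, val_labels = NULL) {
  net <- bptt_init(cfg, seed)
  with_seed(seed + 1000L, {
    lr <- cfg$lr
    best_acc <- -Inf; best_net <- net; best_epoch <- 0L; stall <- 0L
    log <- NULL
    n <- length(inputs)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(n)
      ep_loss <- 0; n_batch <- 0L
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(n, b0 + cfg$batch_size - 1L)]
        fwd <- bptt_forward(net, inputs[idx], labels[idx], keep = TRUE)
        if (!is.finite(fwd$loss)) {
          warning(sprintf("training diverged at epoch %d; returning last stable parameters", ep))
          return(list(net = best_net, log = log, best_epoch = best_epoch))
        }
        g <- bptt_backward(net, fwd, labels[idx])
        net$W_out <- net$W_out - lr * g$W_out
        net$b_out <- net$b_out - lr * g$b_out
        for (m in c("W_in", "W_rec")) {
          W <- net[[m]]
          act <- W != 0
          noise <- if (cfg$temperature > 0)
            sqrt(2 * lr * cfg$temperature) * rnorm(sum(act)) else 0
          W[act] <- W[act] - lr * (g[[m]][act] + cfg$l1) + noise
          W[W < 0] <- 0          # crossed zero -> dormant
          net[[m]] <- W
        }
        if (cfg$rewire) net <- rewire_net(net)
        ep_loss <- ep_loss + fwd$loss; n_batch <- n_batch + 1L
      }
      tr <- bptt_forward(net, inputs, labels)
      train_acc <- mean(max.col(tr$probs) == as.integer(labels))
      val_acc <- NA_real_
      if (!is.null(val_inputs)) {
        va <- bptt_forward(net, val_inputs, val_labels)
        val_acc <- mean(max.col(va$probs) == as.integer(val_labels))
      }
      mon <- if (is.na(val_acc)) train_acc else val_acc
      if (mon > best_acc + 1e-12) {
        best_acc <- mon; best_net <- net; best_epoch <- ep; stall <- 0L
      } else stall <- stall + 1L
      if (stall > cfg$lr_patience) { lr <- lr / 2; stall <- 0L }
      log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / n_batch,
                                   train_acc = train_acc, val_acc = val_acc,
                                   lr = lr))
    }
    list(net = best_net, log = log, best_epoch = best_epoch)
  })
}

# Reactivate random dormant slots until the live-connection counts match the
# targets recorded at initialization. Reactivated weights start at a tiny
# magnitude; slots must respect the scheme (input rows may only target
# excitatory neurons; the recurrent diagonal stays empty).
rewire_net <- function(net) {
  eps <- 1e-6
  n_exc <- sum(net$type == 1)
  fix <- function(W, k_target, allowed) {
    deficit <- k_target - sum(W != 0)
    if (deficit > 0) {
      free <- which(W == 0 & allowed)
      if (length(free) > 0) {
        pick <- if (length(free) <= deficit) free else sample(free, deficit)
        W[pick] <- eps
      }
    }
    W
  }
  allow_in <- matrix(FALSE, nrow(net$W_in), ncol(net$W_in))
  allow_in[, seq_len(n_exc)] <- TRUE
  net$W_in <- fix(net$W_in, net$k_in, allow_in)
  allow_rec <- matrix(TRUE, nrow(net$W_rec), ncol(net$W_rec))
  diag(allow_rec) <- FALSE
  net$W_rec <- fix(net$W_rec, net$k_rec, allow_rec)
  net
}

#' Predict class labels with a trained BPTT network
#'
#' @param net a trained `bptt_net`.
#' @param inputs list of T x n_in spike matrices.
#' @return list `class` (integer class index), `probs` (matrix).
#' @export
predict_bptt <- function(net, inputs) {
  fwd <- bptt_forward(net, inputs)
  list(class = max.col(fwd$probs), probs = fwd$probs)
}
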