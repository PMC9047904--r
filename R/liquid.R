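#' Liquid state machine configuration
#'
#' Defaults follow the two network variants used in the study setup: the
#' LFP-input liquid (330 excitatory / 80 inhibitory neurons, input weights
#' U(250, 750) pA for the 100 threshold-encoding channels) and the MUA-input
#' liquid (100 excitatory / 25 inhibitory, input weights U(15, 45) pA for the
#' 27 electrode channels). Neuron parameters: resting potential 0 mV,
#' capacitance 30 pF, membrane time constant 30 ms, synaptic decay 3 ms
#' (excitatory) / 2 ms (inhibitory), refractory period 2 ms, threshold 15 mV,
#' reset 13.8 mV, constant input current 7 pA. Every neuron receives exactly
#' 2 excitatory and 1 inhibitory recurrent connections; weights are drawn
#' N(100, 70) pA for E-to-E, N(500, 350) for E-to-I, N(-400, 280) for
#' I-to-E/I-to-I, then sign-constrained to `[0, Inf)` / `(-Inf, 0]`; delays
#' are N(10, 20) ms clipped to [3, 200] ms. Each input channel projects to 4
#' random excitatory neurons through static synapses. Recurrent synapses
#' carry Tsodyks-Markram short-term plasticity with class-wise (U, tau_rec,
#' tau_fac) means EE (0.5, 1.1 s, 0.05 s), EI (0.05, 0.125 s, 1.2 s),
#' IE (0.25, 0.7 s, 0.02 s), II (0.32, 0.144 s, 0.06 s), jittered +-50%.
#' Membrane potentials are initialized uniformly over `[0, theta)` to
#' desynchronize the liquid (`v_init = -70` restores a fixed start value).
#' Per-neuron noise is a 100 Hz Poisson generator with weight N(2, 1) pA.
#'
#' @param signal `"mua"` or `"lfp"`; selects population size, input channel
#'   count and input weight range.
#' @param n_channels number of input channels (defaults: 27 for MUA, 100 for
#'   encoded LFP).
#' @param scales named list of multiplicative scale factors `input`, `e`,
#'   `i` applied to input/excitatory/inhibitory weights (the grid-searched
#'   hyperparameters).
#' @param readout_tau exponential readout filter time constant, s.
#' @param readout_time state readout instant relative to stimulus onset, s.
#' @param warmup pre-onset simulation span, s.
#' @param dt integration step, s.
#' @param v_init `"uniform"` or a numeric fixed initial potential, mV.
#' @param ... overrides for any other stored field (e.g. `N_E`, `noise_rate`).
#' @return object of class `lsm_config`.
#' @export
lsm_config <- function(signal = c("mua", "lfp"), n_channels = NULL,
                       scales = list(input = 1, e = 1, i = 1),
                       readout_tau = 0.005, readout_time = 0.045,
                       warmup = 1, dt = 1e-4, v_init = "uniform", ...) {
  signal <- match.arg(signal)
  cfg <- list(
    signal = signal,
    N_E = if (signal == "lfp") 330L else 100L,
    N_I = if (signal == "lfp") 80L else 25L,
    n_channels = n_channels %||% (if (signal == "lfp") 100L else 27L),
    in_deg_E = 2L, in_deg_I = 1L,
    w_EE = c(100, 70), w_EI = c(500, 350),
    w_IE = c(-400, 280), w_II = c(-400, 280),
    delay_ms = c(10, 20), delay_clip_ms = c(3, 200),
    input_fanout = 4L,
    input_w_range = if (signal == "lfp") c(250, 750) else c(15, 45),
    noise_w = c(2, 1), noise_rate = 100,
    stp = list(EE = c(0.5, 1100, 50), EI = c(0.05, 125, 1200),
               IE = c(0.25, 700, 20), II = c(0.32, 144, 60)),  # U, tau_rec ms, tau_fac ms
    stp_jitter = 0.5,
    neuron = list(V_rest = 0, C_m = 30, tau_m = 30, tau_syn_E = 3,
                  tau_syn_I = 2, t_ref = 2, theta = 15, V_reset = 13.8,
                  I_const = 7),
    scales = scales, readout_tau = readout_tau, readout_time = readout_time,
    warmup = warmup, dt = dt, v_init = v_init)
  dots <- list(...)
  cfg[names(dots)] <- dots
  class(cfg) <- "lsm_config"
  cfg
}

#' Build a liquid network
#'
#' Samples neuron assignments, recurrent connectivity (exactly 2 excitatory
#' and 1 inhibitory presynaptic partners per neuron), weights, delays,
#' short-term-plasticity parameters and input projections from the
#' distributions in the configuration. Deterministic under `seed`.
#'
#' @param cfg an [lsm_config()].
#' @param seed integer seed.
#' @return object of class `lsm_network` with elements `neurons`
#'   (data.frame: type, per-neuron LIF parameters), `synapses` (data.frame:
#'   pre, post, weight pA, delay_ms, stp, U, tau_rec_ms, tau_fac_ms),
#'   `input_map` (data.frame: channel, post, weight, delay_ms), `noise_w`,
#'   `cfg`.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "lsm_config"))
  n <- cfg$N_E + cfg$N_I
  if (cfg$N_E < cfg$in_deg_E + 1L || cfg$N_I < cfg$in_deg_I)
    stop("population too small for the configured in-degree")
  with_seed(seed, {
    type <- rep(c("E", "I"), c(cfg$N_E, cfg$N_I))
    exc_idx <- which(type == "E"); inh_idx <- which(type == "I")
    np <- cfg$neuron
    neurons <- data.frame(
      id = seq_len(n), type = type,
      C_m = np$C_m, tau_m = np$tau_m, theta = np$theta,
      V_reset = np$V_reset, V_rest = np$V_rest, t_ref = np$t_ref,
      I_const = np$I_const, stringsAsFactors = FALSE)

    pre <- integer(0); post <- integer(0); w <- numeric(0); cls <- character(0)
    for (j in seq_len(n)) {
      pe <- sample(setdiff(exc_idx, j), cfg$in_deg_E)
      pi <- sample(setdiff(inh_idx, j), cfg$in_deg_I)
      pre <- c(pre, pe, pi); post <- c(post, rep(j, cfg$in_deg_E + cfg$in_deg_I))
      cls_e <- if (type[j] == "E") "EE" else "EI"
      cls_i <- if (type[j] == "E") "IE" else "II"
      cls <- c(cls, rep(cls_e, cfg$in_deg_E), rep(cls_i, cfg$in_deg_I))
    }
    wpar <- list(EE = cfg$w_EE, EI = cfg$w_EI, IE = cfg$w_IE, II = cfg$w_II)
    w <- vapply(seq_along(cls), function(s)
      rnorm(1, wpar[[cls[s]]][1], wpar[[cls[s]]][2]), 1.0)
    exc_syn <- substr(cls, 1, 1) == "E"
    w[exc_syn] <- pmax(w[exc_syn], 0)
    w[!exc_syn] <- pmin(w[!exc_syn], 0)
    delay <- pmin(pmax(rnorm(length(w), cfg$delay_ms[1], cfg$delay_ms[2]),
                       cfg$delay_clip_ms[1]), cfg$delay_clip_ms[2])
    stp_mean <- t(vapply(cls, function(cl) cfg$stp[[cl]], numeric(3)))
    jit <- function(m) m * runif(length(m), 1 - cfg$stp_jitter, 1 + cfg$stp_jitter)
    U <- pmin(pmax(jit(stp_mean[, 1]), 1e-3), 1)
    synapses <- data.frame(
      pre = pre, post = post, class = cls, weight = w, delay_ms = delay,
      stp = TRUE, U = U, tau_rec_ms = pmax(jit(stp_mean[, 2]), 1),
      tau_fac_ms = pmax(jit(stp_mean[, 3]), 1), stringsAsFactors = FALSE)

    in_post <- integer(0); in_ch <- integer(0)
    for (c_i in seq_len(cfg$n_channels)) {
      tgt <- sample(exc_idx, cfg$input_fanout)
      in_post <- c(in_post, tgt); in_ch <- c(in_ch, rep(c_i, cfg$input_fanout))
    }
    input_map <- data.frame(
      channel = in_ch, post = in_post,
      weight = runif(length(in_post), cfg$input_w_range[1], cfg$input_w_range[2]),
      delay_ms = pmin(pmax(rnorm(length(in_post), cfg$delay_ms[1], cfg$delay_ms[2]),
                           cfg$delay_clip_ms[1]), cfg$delay_clip_ms[2]),
      stringsAsFactors = FALSE)

    structure(list(neurons = neurons, synapses = synapses,
                   input_map = input_map,
                   noise_w = rnorm(n, cfg$noise_w[1], cfg$noise_w[2]),
                   cfg = cfg, seed = seed),
              class = "lsm_network")
  })
}

#' Apply input/excitatory/inhibitory weight scale factors
#'
#' Multiplies input weights by `input`, excitatory recurrent weights by `e`
#' and inhibitory recurrent weights by `i`, re-imposing the sign constraints.
#'
#' @param net an `lsm_network`.
#' @param scales named list/vector with `input`, `e`, `i`.
#' @return the scaled network.
#' @export
scale_network <- function(net, scales) {
  s <- as.list(scales)
  exc <- substr(net$synapses$class, 1, 1) == "E"
  net$synapses$weight[exc] <- pmax(net$synapses$weight[exc] * s$e, 0)
  net$synapses$weight[!exc] <- pmin(net$synapses$weight[!exc] * s$i, 0)
  net$input_map$weight <- net$input_map$weight * s$input
  net
}

#' Simulate a liquid network
#'
#' Fixed-step integration (default 0.1 ms) of the LIF dynamics
#' `dV/dt = (V_rest - V)/tau_m + (I_syn + I_const + I_noise)/C_m` with
#' exponential synaptic currents, threshold/reset with a 2 ms refractory
#' period, Tsodyks-Markram depression/facilitation on recurrent synapses and
#' per-neuron Poisson noise. Input spikes are delivered through the static
#' input projections (delays rounded to the step grid).
#'
#' @param net an `lsm_network`.
#' @param input_spikes list of spike-time vectors (s), one per input channel
#'   (length must match `net$cfg$n_channels`).
#' @param t_start,t_end simulation span, s (input spike times share this
#'   clock; typically `t_start = -warmup`, onset at 0).
#' @param seed optional seed for the noise generator (the caller's RNG state
#'   is used when `NULL`).
#' @param record_all record inhibitory spikes too (default: excitatory only).
#' @return object of class `lsm_sim`: data.frame `spikes` (neuron, time),
#'   `stp_u_range`, `stp_R_range`, `span`, `n_neurons`, `n_exc`.
#' @export
simulate_lsm <- function(net, input_spikes, t_start, t_end, seed = NULL,
                         record_all = FALSE) {
  cfg <- net$cfg
  if (length(input_spikes) != cfg$n_channels)
    stop(sprintf("expected %d input channels, got %d", cfg$n_channels,
                 length(input_spikes)))
  dt <- cfg$dt
  nn <- net$neurons
  n <- nrow(nn)
  run <- function() {
    v0 <- if (identical(cfg$v_init, "uniform"))
      runif(n, 0, nn$theta) else rep(as.numeric(cfg$v_init), n)
    # expand input spikes through the projection map into arrival events
    im <- net$input_map
    ev_step <- integer(0); ev_post <- integer(0); ev_w <- numeric(0)
    for (c_i in seq_len(cfg$n_channels)) {
      ts <- input_spikes[[c_i]]
      ts <- ts[ts >= t_start & ts <= t_end]
      if (length(ts) == 0) next
      rows <- which(im$channel == c_i)
      base_step <- as.integer(round((ts - t_start) / dt))
      for (r in rows) {
        d <- max(1L, as.integer(round(im$delay_ms[r] / 1000 / dt)))
        ev_step <- c(ev_step, base_step + d)
        ev_post <- c(ev_post, rep(im$post[r] - 1L, length(ts)))
        ev_w <- c(ev_w, rep(im$weight[r], length(ts)))
      }
    }
    o <- order(ev_step)
    res <- lsm_simulate_cpp(
      is_exc = as.integer(nn$type == "E"),
      Cm = nn$C_m, tau_m = nn$tau_m, theta = nn$theta,
      Vreset = nn$V_reset, Vrest = nn$V_rest, tref = nn$t_ref,
      Iconst = nn$I_const,
      tau_synE = cfg$neuron$tau_syn_E, tau_synI = cfg$neuron$tau_syn_I,
      syn_pre = net$synapses$pre - 1L, syn_post = net$synapses$post - 1L,
      syn_w = net$synapses$weight,
      syn_delay_steps = pmax(1L, as.integer(round(net$synapses$delay_ms / 1000 / dt))),
      syn_stp = as.integer(net$synapses$stp),
      syn_U = net$synapses$U, syn_taurec = net$synapses$tau_rec_ms,
      syn_taufac = net$synapses$tau_fac_ms,
      ev_step = ev_step[o], ev_post = ev_post[o], ev_w = ev_w[o],
      noise_w = net$noise_w, noise_rate = cfg$noise_rate,
      V_init = v0, t_start = t_start, t_end = t_end, dt = dt,
      record_all = record_all)
    structure(list(spikes = data.frame(neuron = res$neuron, time = res$time),
                   stp_u_range = res$stp_u_range,
                   stp_R_range = res$stp_R_range,
                   span = c(t_start, t_end), n_neurons = n,
                   n_exc = sum(nn$type == "E")),
              class = "lsm_sim")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Mean population firing rate of a simulation
#'
#' Spike count divided by (number of neurons x simulated span). With the
#' default recording (excitatory spikes only) the rate refers to the
#' excitatory population.
#'
#' @param sim an `lsm_sim`.
#' @param population `"exc"` (default) or `"all"` (requires
#'   `record_all = TRUE` in [simulate_lsm()]).
#' @return rate in Hz.
#' @export
lsm_mean_rate <- function(sim, population = c("exc", "all")) {
  population <- match.arg(population)
  n <- if (population == "exc") sim$n_exc else sim$n_neurons
  nrow(sim$spikes) / (n * diff(sim$span))
}

#' Exponentially filtered liquid state at a readout instant
#'
#' Per excitatory neuron, the sum over its spikes of
#' `exp(-(t_read - t_spike)/tau)` for spikes at or before `t_read`.
#'
#' @param sim an `lsm_sim`.
#' @param readout_time readout instant on the simulation clock, s.
#' @param tau filter time constant, s.
#' @return numeric vector of length `n_exc` (zero for silent neurons).
#' @export
readout_state <- function(sim, readout_time, tau = 0.005) {
  if (readout_time < sim$span[1])
    stop("readout time precedes the simulated span")
  st <- numeric(sim$n_exc)
  sp <- sim$spikes[sim$spikes$time <= readout_time &
                     sim$spikes$neuron <= sim$n_exc, , drop = FALSE]
  if (nrow(sp) > 0) {
    contrib <- exp(-(readout_time - sp$time) / tau)
    acc <- rowsum(contrib, sp$neuron)
    st[as.integer(rownames(acc))] <- acc[, 1]
  }
  st
}

#' Liquid states for a set of trials
#'
#' Simulates the network once per trial on a trial-relative clock (stimulus
#' onset at 0, span `[-warmup, readout_time + margin]`) and reads out the
#' filtered excitatory state at `readout_time`.
#'
#' @param net an `lsm_network`.
#' @param trial_inputs list of trials; each trial is a list of per-channel
#'   spike-time vectors relative to its stimulus onset.
#' @param seed base seed; trial k uses `seed + k` for its noise stream.
#' @param margin extra simulated span after the readout, s.
#' @return matrix trials x excitatory neurons.
#' @export
lsm_trial_states <- function(net, trial_inputs, seed = 1L, margin = 0.005) {
  cfg <- net$cfg
  t0 <- -cfg$warmup; t1 <- cfg$readout_time + margin
  out <- matrix(0, nrow = length(trial_inputs), ncol = sum(net$neurons$type == "E"))
  for (k in seq_along(trial_inputs)) {
    sim <- simulate_lsm(net, trial_inputs[[k]], t0, t1, seed = seed + k)
    out[k, ] <- readout_state(sim, cfg$readout_time, cfg$readout_tau)
  }
  out
}

#' Neuromorphic hardware constraint profile
#'
#' Constraint set mirroring a mixed-signal neuromorphic processor: per-neuron
#' fan-in capped at `fan_in_max` unit connections, four synapse types
#' (excitatory/inhibitory x fast/slow) sharing one weight magnitude each,
#' no synaptic delays, and per-neuron parameter mismatch (Gaussian,
#' coefficient of variation `mismatch_cv`, clipped at `mismatch_clip`
#' standard deviations) on the membrane time constant, threshold, reset
#' potential and capacitance.
#'
#' @param fan_in_max maximal incoming unit connections per neuron.
#' @param mismatch_cv coefficient of variation of the parameter jitter.
#' @param mismatch_clip clip of the jitter factor, in standard deviations.
#' @return object of class `hardware_profile`.
#' @export
hardware_profile <- function(fan_in_max = 64L, mismatch_cv = 0.20,
                             mismatch_clip = 2) {
  structure(list(fan_in_max = as.integer(fan_in_max),
                 mismatch_cv = mismatch_cv, mismatch_clip = mismatch_clip,
                 jittered = c("tau_m", "theta", "V_reset", "C_m")),
            class = "hardware_profile")
}

#' Emulate hardware constraints on a liquid network
#'
#' Each synapse (recurrent and input) is assigned to one of at most four
#' types by sign and synaptic time constant; the shared per-type base
#' magnitude is the median absolute weight of that type. Every synapse is
#' replaced by `round(|w| / base)` parallel unit connections of the base
#' magnitude (synapses rounding to zero are dropped), truncated in input
#' order so that no neuron's incoming unit count exceeds the fan-in limit.
#' All delays are set to zero (delivered at the next integration step),
#' short-term plasticity is disabled (static synapses), and the per-neuron
#' parameters in the profile are jittered multiplicatively (mean 1, sd
#' `mismatch_cv`, clipped to `1 +- mismatch_clip * mismatch_cv`).
#'
#' @param net an `lsm_network`.
#' @param profile a [hardware_profile()].
#' @param seed seed for the mismatch draw.
#' @return the constrained `lsm_network` (field `hardware = TRUE`).
#' @export
apply_hardware_constraints <- function(net, profile = hardware_profile(),
                                       seed = 1L) {
  with_seed(seed, {
    syn <- net$synapses
    im <- net$input_map
    tau_of <- function(wv) ifelse(wv >= 0, net$cfg$neuron$tau_syn_E,
                                  net$cfg$neuron$tau_syn_I)
    all_w <- c(syn$weight, im$weight)
    typ <- paste0(ifelse(all_w >= 0, "E", "I"), "_", tau_of(all_w))
    base <- tapply(abs(all_w), typ, median)
    if (any(base == 0)) stop("a synapse type has zero base magnitude")
    units <- as.integer(round(abs(all_w) / base[typ]))
    qw <- sign(all_w) * units * base[typ]

    n_syn <- nrow(syn)
    syn$weight <- qw[seq_len(n_syn)]
    syn$units <- units[seq_len(n_syn)]
    im$weight <- qw[n_syn + seq_len(nrow(im))]
    im$units <- units[n_syn + seq_len(nrow(im))]
    syn <- syn[syn$units > 0, , drop = FALSE]
    im <- im[im$units > 0, , drop = FALSE]

    # fan-in truncation over all incoming connections, in input order
    inc <- rbind(data.frame(kind = rep("syn", nrow(syn)),
                            row = seq_len(nrow(syn)),
                            post = syn$post, units = syn$units),
                 data.frame(kind = rep("in", nrow(im)),
                            row = seq_len(nrow(im)),
                            post = im$post, units = im$units))
    inc <- inc[order(inc$post), , drop = FALSE]
    for (p in unique(inc$post)) {
      rows <- which(inc$post == p)
      used <- 0L
      for (r in rows) {
        allow <- max(0L, profile$fan_in_max - used)
        take <- min(inc$units[r], allow)
        inc$units[r] <- take
        used <- used + take
      }
    }
    for (r in seq_len(nrow(inc))) {
      if (inc$kind[r] == "syn") {
        k <- inc$row[r]
        syn$weight[k] <- sign(syn$weight[k]) *
          inc$units[r] * abs(syn$weight[k] / max(syn$units[k], 1L))
        syn$units[k] <- inc$units[r]
      } else {
        k <- inc$row[r]
        im$weight[k] <- sign(im$weight[k]) *
          inc$units[r] * abs(im$weight[k] / max(im$units[k], 1L))
        im$units[k] <- inc$units[r]
      }
    }
    syn <- syn[syn$units > 0, , drop = FALSE]
    im <- im[im$units > 0, , drop = FALSE]
    syn$delay_ms <- rep(0, nrow(syn)); im$delay_ms <- rep(0, nrow(im))
    syn$stp <- rep(FALSE, nrow(syn))

    jf <- function(n) pmin(pmax(rnorm(n, 1, profile$mismatch_cv),
                                1 - profile$mismatch_clip * profile$mismatch_cv),
                           1 + profile$mismatch_clip * profile$mismatch_cv)
    nn <- net$neurons
    for (p in profile$jittered) nn[[p]] <- nn[[p]] * jf(nrow(nn))

    net$neurons <- nn
    net$synapses <- syn
    net$input_map <- im
    net$hardware <- TRUE
    net
  })
}
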