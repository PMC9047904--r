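quiet_net <- function(seed = 1) {
  # isolated population: no recurrent synapses, no input, no noise
  net <- build_network(lsm_config("mua", v_init = 0, noise_rate = 0,
                                  n_channels = 1L), seed = seed)
  net$synapses <- net$synapses[0, , drop = FALSE]
  net$input_map <- net$input_map[0, , drop = FALSE]
  net$noise_w[] <- 0
  net
}

test_that("network construction honors in-degree, sign, delay and size contracts", {
  cfg <- lsm_config("mua")
  net <- build_network(cfg, seed = 3)
  expect_equal(nrow(net$neurons), 125L)
  expect_equal(nrow(net$synapses), 125L * 3L)  # in-degree 2E + 1I each
  ind <- table(net$synapses$post)
  expect_true(all(ind == 3))
  pre_type <- net$neurons$type[net$synapses$pre]
  expect_true(all(net$synapses$weight[pre_type == "E"] >= 0))
  expect_true(all(net$synapses$weight[pre_type == "I"] <= 0))
  expect_true(all(net$synapses$delay_ms >= 3 & net$synapses$delay_ms <= 200))
  expect_true(all(table(net$input_map$channel) == 4))
  expect_true(all(net$neurons$type[net$input_map$post] == "E"))
  # LFP variant sizes
  cfg2 <- lsm_config("lfp")
  expect_equal(cfg2$N_E + cfg2$N_I, 410L)
  expect_equal(cfg2$n_channels, 100L)
  # determinism
  expect_identical(build_network(cfg, seed = 3)$synapses, net$synapses)
  expect_error(build_network(lsm_config("mua", N_E = 2L), seed = 1), "in-degree")
})

test_that("an unconnected neuron settles at the closed-form steady state without firing", {
  net <- quiet_net()
  sim <- simulate_lsm(net, list(numeric(0)), 0, 0.5, seed = 1)
  expect_equal(nrow(sim$spikes), 0L)
  # V_inf = V_rest + (tau_m / C_m) * I_const = 0 + 1 GOhm * 7 pA = 7 mV
  v_final <- attr(sim, "V_final")
  sim2 <- whiskdecode:::lsm_simulate_cpp(
    is_exc = rep(1L, 1), Cm = 30, tau_m = 30, theta = 15, Vreset = 13.8,
    Vrest = 0, tref = 2, Iconst = 7, tau_synE = 3, tau_synI = 2,
    syn_pre = integer(0), syn_post = integer(0), syn_w = numeric(0),
    syn_delay_steps = integer(0), syn_stp = integer(0), syn_U = numeric(0),
    syn_taurec = numeric(0), syn_taufac = numeric(0),
    ev_step = integer(0), ev_post = integer(0), ev_w = numeric(0),
    noise_w = 0, noise_rate = 0, V_init = 0, t_start = 0, t_end = 1,
    dt = 1e-4, record_all = TRUE)
  expect_lt(abs(sim2$V_final - 7), 0.01)
  expect_length(sim2$neuron, 0)
})

test_that("one strong input spike fires the target exactly once, then refractoriness holds", {
  # weight chosen so the PSC crosses threshold once near its peak and the
  # residual current after the refractory hold is subthreshold
  net <- quiet_net()
  net$input_map <- data.frame(channel = 1L, post = 1L, weight = 130,
                              delay_ms = 3, stp = FALSE)
  sim <- simulate_lsm(net, list(c(0.1)), 0, 0.3, seed = 1, record_all = TRUE)
  sp1 <- sim$spikes[sim$spikes$neuron == 1, ]
  expect_equal(nrow(sp1), 1L)
  expect_lt(abs(sp1$time - 0.106), 0.004)
  # refractoriness across the population under strong drive
  netf <- quiet_net()
  netf$input_map <- data.frame(channel = 1L,
                               post = which(netf$neurons$type == "E")[1:10],
                               weight = 5000, delay_ms = 3, stp = FALSE)
  drive <- list(seq(0.05, 0.45, by = 0.001))
  simf <- simulate_lsm(netf, drive, 0, 0.5, seed = 2, record_all = TRUE)
  isi_ok <- tapply(simf$spikes$time, simf$spikes$neuron, function(ts) {
    length(ts) < 2 || min(diff(sort(ts))) >= 0.002 - 1e-9
  })
  expect_true(all(isi_ok))
})

test_that("readout state equals the brute-force kernel sum and its edge values", {
  f <- fix_small()
  net <- build_network(lsm_config("mua"), seed = 4)
  ds_trial <- list(lapply(1:27, function(i) sort(runif(20, -1, 0.05))))
  sim <- simulate_lsm(net, ds_trial[[1]], -1, 0.05, seed = 3)
  st <- readout_state(sim, 0.045, tau = 0.005)
  expect_length(st, sim$n_exc)
  brute <- vapply(seq_len(sim$n_exc), function(j) {
    ts <- sim$spikes$time[sim$spikes$neuron == j & sim$spikes$time <= 0.045]
    sum(exp(-(0.045 - ts) / 0.005))
  }, 1.0)
  expect_equal(st, brute, tolerance = 1e-12)
  expect_true(all(st >= 0))
  expect_error(readout_state(sim, -2), "precedes")
  # kernel arithmetic: spike at readout counts 1, 5 ms earlier counts e^-1
  fake <- structure(list(spikes = data.frame(neuron = c(1L, 2L),
                                             time = c(0.045, 0.040)),
                         span = c(0, 0.05), n_neurons = 3, n_exc = 3),
                    class = "lsm_sim")
  st2 <- readout_state(fake, 0.045, tau = 0.005)
  expect_equal(st2, c(1, exp(-1), 0))
})

test_that("short-term plasticity states stay inside [0, 1] under strong drive", {
  f <- fix_small()
  net <- scale_network(build_network(lsm_config("mua"), seed = 5),
                       list(input = 8, e = 3, i = 1))
  u_lo <- Inf; u_hi <- -Inf; r_lo <- Inf; r_hi <- -Inf
  for (k in 1:5) {
    sim <- simulate_lsm(net, fix_small_dataset()$mua_trials[[k]], -1, 0.05,
                        seed = 10 + k)
    if (!is.na(sim$stp_u_range[1])) {
      u_lo <- min(u_lo, sim$stp_u_range[1]); u_hi <- max(u_hi, sim$stp_u_range[2])
      r_lo <- min(r_lo, sim$stp_R_range[1]); r_hi <- max(r_hi, sim$stp_R_range[2])
    }
  }
  expect_gte(u_lo, 0); expect_lte(u_hi, 1)
  expect_gte(r_lo, 0); expect_lte(r_hi, 1)
})

test_that("a repeatedly firing synapse depresses and recovers within bounds", {
  # one input-driven neuron with a single depressing outgoing synapse
  net <- quiet_net()
  net$input_map <- data.frame(channel = 1L, post = 1L, weight = 5000,
                              delay_ms = 3, stp = FALSE)
  net$synapses <- data.frame(pre = 1L, post = 2L, class = "EE", weight = 100,
                             delay_ms = 3, stp = TRUE, U = 0.5,
                             tau_rec_ms = 800, tau_fac_ms = 50,
                             stringsAsFactors = FALSE)
  drive <- list(seq(0.05, 0.95, by = 0.010))  # 100 Hz for ~1 s
  sim <- simulate_lsm(net, drive, 0, 1, seed = 1, record_all = TRUE)
  expect_gt(sum(sim$spikes$neuron == 1), 50)
  expect_gte(sim$stp_R_range[1], 0)
  expect_lte(sim$stp_R_range[2], 1)
  expect_lt(sim$stp_R_range[1], 0.8)   # depression engaged
  expect_gte(sim$stp_u_range[1], 0)
  expect_lte(sim$stp_u_range[2], 1)
})

test_that("Dale signs survive scaling and hardware quantization", {
  net <- build_network(lsm_config("mua"), seed = 6)
  for (s in list(list(input = 0.5, e = 2, i = 3), list(input = 4, e = 0.1, i = 0.1))) {
    sc <- scale_network(net, s)
    pre_type <- sc$neurons$type[sc$synapses$pre]
    expect_true(all(sc$synapses$weight[pre_type == "E"] >= 0))
    expect_true(all(sc$synapses$weight[pre_type == "I"] <= 0))
    hw <- apply_hardware_constraints(sc, seed = 7)
    pre_type_hw <- hw$neurons$type[hw$synapses$pre]
    expect_true(all(hw$synapses$weight[pre_type_hw == "E"] >= 0))
    expect_true(all(hw$synapses$weight[pre_type_hw == "I"] <= 0))
  }
})

test_that("hardware transform enforces fan-in, zero delays, shared magnitudes and jitter clips", {
  net <- build_network(lsm_config("mua"), seed = 8)
  hw <- apply_hardware_constraints(net, hardware_profile(), seed = 9)
  fan_in <- rep(0L, nrow(hw$neurons))
  for (d in list(hw$synapses, hw$input_map)) {
    agg <- tapply(d$units, d$post, sum)
    fan_in[as.integer(names(agg))] <- fan_in[as.integer(names(agg))] + agg
  }
  expect_lte(max(fan_in), 64L)
  expect_true(all(hw$synapses$delay_ms == 0))
  expect_true(all(hw$input_map$delay_ms == 0))
  expect_false(any(hw$synapses$stp))
  mags <- abs(c(hw$synapses$weight / hw$synapses$units,
                hw$input_map$weight / hw$input_map$units))
  expect_lte(length(unique(round(mags, 9))), 4L)
  # weight exactly at base magnitude -> one unit connection
  base <- unique(round(mags, 9))
  expect_true(all(hw$synapses$units >= 1))
  # mismatch: tau_m jitter sd 20% of 30 ms, clipped at 2 sd -> [18, 42]
  expect_true(all(hw$neurons$tau_m >= 18 - 1e-9 & hw$neurons$tau_m <= 42 + 1e-9))
  expect_gt(sd(hw$neurons$tau_m), 0)
})
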