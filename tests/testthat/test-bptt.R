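test_that("LIF decay factor, fixed point and reset follow the discrete map", {
  # alpha for tau 20 ms, dt 1 ms
  expect_equal(exp(-0.001 / 0.020), 0.951229, tolerance = 1e-6)
  # subthreshold constant drive converges to Rm*I without spiking
  V <- 0; refr <- 0L
  for (i in 1:2000) {
    st <- lif_step(V, 0.008, refr, Rm = 1, b = 0.01)
    V <- st$V; refr <- st$refr
    expect_equal(st$z, 0)
  }
  expect_lt(abs(V - 0.008), 1e-9)
  # reset by subtraction: V just above threshold
  st <- lif_step(0.0108 / exp(-0.05), 0, 0L, b = 0.01)  # engineered to land over b
  if (st$z > 0) expect_equal(st$V, exp(-0.05) * 0.0108 / exp(-0.05) - 0.01)
  # vectorized form conserves V - b exactly on spike
  stv <- lif_step(c(0.012, 0.005), c(0, 0), c(0L, 0L))
  expect_equal(stv$z[2], 0)
  if (stv$z[1] > 0) expect_equal(stv$V[1], 0.012 * exp(-0.001 / 0.020) - 0.01)
})

test_that("surrogate gradient evaluates the dampened triangular pseudo-derivative", {
  expect_equal(surrogate_grad(0), 0.3)
  expect_equal(surrogate_grad(0.5), 0.15)
  expect_equal(surrogate_grad(c(-1, 1, 2, -3)), c(0, 0, 0, 0))
  expect_equal(surrogate_grad(0, gamma = 0.5), 0.5)
  # soft spike nonlinearity has the surrogate as its exact derivative
  v <- seq(-1.5, 1.5, by = 0.01)
  h <- whiskdecode:::soft_spike(v)
  num <- diff(h) / 0.01
  mid <- (v[-1] + v[-length(v)]) / 2
  expect_lt(max(abs(num - surrogate_grad(mid))), 1e-3)
})

test_that("BPTT gradients match central finite differences on a 3-neuron network", {
  cfg <- bptt_config(n_in = 2, n_rec = 3, epochs = 1, t_ref = 0, frac_exc = 1)
  net <- bptt_init(cfg, seed = 3)
  with_seed_test(4, {
    inputs <- list(matrix(rbinom(30 * 2, 1, 0.4), 30, 2),
                   matrix(rbinom(30 * 2, 1, 0.3), 30, 2))
  })
  labels <- factor(c("a", "b", "c"))[c(1, 2)]
  ce_loss <- function(nn) {
    whiskdecode:::bptt_forward(nn, inputs, labels, soft = TRUE)$loss -
      cfg$l1 * (sum(nn$W_in) + sum(nn$W_rec))
  }
  fwd <- whiskdecode:::bptt_forward(net, inputs, labels, soft = TRUE, keep = TRUE)
  g <- whiskdecode:::bptt_backward(net, fwd, labels)
  eps <- 1e-6
  for (m in c("W_in", "W_rec", "W_out")) {
    idx <- if (m == "W_out") seq_along(net[[m]]) else which(net[[m]] != 0)
    for (k in idx) {
      np <- net; np[[m]][k] <- np[[m]][k] + eps
      nm <- net; nm[[m]][k] <- nm[[m]][k] - eps
      fd <- (ce_loss(np) - ce_loss(nm)) / (2 * eps)
      an <- g[[m]][k]
      if (abs(fd) > 1e-7 || abs(an) > 1e-7)
        expect_lt(abs(fd - an) / max(abs(fd), abs(an)), 1e-3)
    }
  }
})

test_that("zero dampening blocks all spike-mediated gradient flow", {
  cfg <- bptt_config(n_in = 2, n_rec = 4, epochs = 1, gamma = 0)
  net <- bptt_init(cfg, seed = 5)
  with_seed_test(6, {
    inputs <- list(matrix(rbinom(40 * 2, 1, 0.5), 40, 2))
  })
  labels <- factor("a", levels = c("a", "b"))
  fwd <- whiskdecode:::bptt_forward(net, inputs, labels, keep = TRUE)
  g <- whiskdecode:::bptt_backward(net, fwd, labels)
  expect_true(all(g$W_in == 0))
  expect_true(all(g$W_rec == 0))
})

test_that("a linearly separable toy task trains to 100% within 50 epochs", {
  with_seed_test(1, {
    mk <- function(ch) { m <- matrix(0, 50, 2); m[sample(50, 12), ch] <- 1; m }
    ins <- c(lapply(1:10, function(i) mk(1)), lapply(1:10, function(i) mk(2)))
  })
  labs <- factor(rep(c("A", "B"), each = 10))
  cfg <- bptt_config(n_in = 2, n_rec = 10, n_out = 2, epochs = 50, lr = 0.5,
                     l1 = 1e-6, batch_size = 5)
  fit <- train_bptt(ins, labs, cfg, seed = 2)
  acc <- mean(predict_bptt(fit$net, ins)$class == as.integer(labs))
  expect_equal(acc, 1)
})

test_that("rewiring keeps the live-connection count at the scheme target", {
  with_seed_test(7, {
    ins <- lapply(1:12, function(i) matrix(rbinom(50 * 3, 1, 0.3), 50, 3))
  })
  labs <- factor(rep(c("A", "B", "C"), each = 4))
  cfg <- bptt_config(n_in = 3, n_rec = 12, n_out = 3, epochs = 15, lr = 0.3,
                     l1 = 1e-3, temperature = 1e-6, batch_size = 4)
  fit <- train_bptt(ins, labs, cfg, seed = 8)
  expect_equal(sum(fit$net$W_in != 0), fit$net$k_in)
  expect_equal(sum(fit$net$W_rec != 0), fit$net$k_rec)
  expect_true(all(fit$net$W_in >= 0))
  expect_true(all(fit$net$W_rec >= 0))  # magnitudes; signs live in sign_rec
  expect_true(all(diag(fit$net$W_rec) == 0))
})

test_that("training on shuffled labels stays near chance on held-out data", {
  with_seed_test(9, {
    ins <- lapply(1:30, function(i) matrix(rbinom(50 * 4, 1, 0.3), 50, 4))
    labs <- factor(sample(rep(c("A", "B", "C"), each = 10)))
  })
  cfg <- bptt_config(n_in = 4, n_rec = 12, n_out = 3, epochs = 25, lr = 0.2,
                     batch_size = 8)
  fit <- train_bptt(ins[1:21], labs[1:21], cfg, seed = 10)
  val <- mean(predict_bptt(fit$net, ins[22:30])$class == as.integer(labs[22:30]))
  expect_lt(val, 0.85)  # random inputs + random labels cannot generalize
})
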