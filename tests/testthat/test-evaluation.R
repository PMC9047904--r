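stub_classifier <- function(kind = c("perfect", "random", "state_artifact"),
                            states = NULL) {
  kind <- match.arg(kind)
  fit_predict <- function(dataset, idx_train, idx_val, idx_test, seed) {
    pred <- switch(kind,
      perfect = dataset$labels[idx_test],
      random = with_seed_test(seed, factor(sample(levels(dataset$labels),
                                             length(idx_test), TRUE),
                                      levels = levels(dataset$labels))),
      state_artifact = {
        # correct during UP, random during DOWN: a planted state confound
        p <- dataset$labels[idx_test]
        dn <- states[idx_test] == "DOWN"
        p[dn] <- with_seed_test(seed, factor(sample(levels(dataset$labels),
                                               sum(dn), TRUE),
                                        levels = levels(dataset$labels)))
        p
      })
    list(pred = pred, info = NULL)
  }
  structure(list(name = kind, fit_predict = fit_predict),
            class = "whisk_classifier")
}

test_that("the protocol reports exact accuracies for stub classifiers", {
  ds <- fix_small_dataset()
  pr <- run_protocol(ds, stub_classifier("perfect"), n_runs = 4, seed = 2)
  expect_equal(pr$table$mean_acc, 100)
  expect_equal(pr$table$sd_acc, 0)
  pr2 <- run_protocol(ds, stub_classifier("random"), n_runs = 12, seed = 3)
  n_test <- length(pr2$runs[[1]]$idx_test)
  se <- 100 * sqrt(1 / 3 * 2 / 3 / (n_test * 12))
  expect_lt(abs(pr2$table$mean_acc - 100 / 3), 4 * se)
  # determinism under the master seed
  pr3 <- run_protocol(ds, stub_classifier("random"), n_runs = 12, seed = 3)
  expect_identical(pr2$table, pr3$table)
})

test_that("splits are stratified, disjoint and leak-free", {
  ds <- fix_small_dataset()
  for (r in 1:5) {
    sp <- whiskdecode:::split_trials(ds$labels, seed = r)
    expect_length(intersect(sp$train, sp$test), 0)
    expect_length(intersect(sp$val, sp$test), 0)
    expect_length(intersect(sp$train, sp$val), 0)
    expect_setequal(c(sp$train, sp$val, sp$test), seq_along(ds$labels))
    for (ix in list(sp$train, sp$val, sp$test))
      expect_true(all(levels(ds$labels) %in% ds$labels[ix]))
  }
})

test_that("state-conditioned scoring separates UP and DOWN test subsets", {
  ds <- fix_small_dataset()
  states <- ds$states
  pr <- run_protocol(ds, stub_classifier("perfect"), n_runs = 3, seed = 4)
  rows <- state_conditioned_eval(pr, ds)
  expect_equal(rows$condition, c("UP-test", "DOWN-test"))
  expect_true(all(rows$mean_acc[rows$n_runs > 0] == 100))
  # a state-correlated artifact produces a detectable UP/DOWN gap
  pra <- run_protocol(ds, stub_classifier("state_artifact", states = states),
                      n_runs = 6, seed = 5)
  ra <- state_conditioned_eval(pra, ds)
  up <- ra$mean_acc[ra$condition == "UP-test"]
  dn <- ra$mean_acc[ra$condition == "DOWN-test"]
  expect_gt(up - dn, 20)
})

test_that("PSTH bins, conservation and degenerate input behave", {
  # single spike per trial at onset + 10 ms falls in the [8, 12) ms bin
  trials <- lapply(1:7, function(i) list(c(0.010)))
  m <- psth(trials, bin = 0.004, window = c(0, 0.04))
  expect_equal(dim(m), c(1L, 10L))
  expect_equal(m[1, 3], 1)     # bin [0.008, 0.012)
  expect_equal(sum(m), 1)
  # conservation: total mass equals mean spike count per trial
  set.seed(6)
  trials2 <- lapply(1:20, function(i)
    list(runif(sample(0:6, 1), 0, 0.04), runif(3, 0, 0.04)))
  m2 <- psth(trials2, bin = 0.004, window = c(0, 0.04))
  expect_equal(sum(m2), mean(vapply(trials2, function(tr) sum(lengths(tr)), 1.0)),
               tolerance = 1e-12)
  expect_equal(dim(psth(list(), bin = 0.004)), c(0L, 50L))
})

test_that("layer-conditioned evaluation demands known layers", {
  ds <- fix_small_dataset()
  expect_error(layer_conditioned_eval(ds, layers = c("IV", "VII")), "missing")
})

test_that("the MUA liquid pipeline beats chance on a small session", {
  ds <- fix_small_dataset()
  cl <- classifier_lsm("mua", grid = list(input = 1, e = 1, i = 1, C = c(0.1, 1)))
  pr <- run_protocol(ds, cl, n_runs = 2, seed = 11)
  expect_gte(pr$table$mean_acc, 100 / 3)
  expect_true(all(vapply(pr$runs, function(r)
    all(r$pred %in% levels(ds$labels)), TRUE)))
})

test_that("the BPTT classifier runs end to end on a small session", {
  ds <- fix_small_dataset()
  cl <- classifier_snn_bptt("mua", n_rec = 30L, epochs = 8L,
                            grid = list(lr = 0.1, l1 = 1e-5))
  pr <- run_protocol(ds, cl, n_runs = 1, seed = 12)
  expect_true(pr$table$mean_acc >= 0 && pr$table$mean_acc <= 100)
})
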