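# The engine's physics: Poisson input statistics, exact equivalence with the
# scalar reference integrator, refractoriness, silencing, reproducibility.

walkoff_connectome <- function(seed = 1L, ...) {
  sc <- synth_connectome(walkoff_motif_spec(...), seed = seed)
  signed_connectome(sc$neurons, sc$edges)
}

test_that("poisson_train edge cases and counting statistics", {
  expect_length(poisson_train(0, 0, 1), 0)
  expect_length(poisson_train(100, 0.3, 0.3), 0)
  expect_error(poisson_train(-5, 0, 1), ">= 0")
  tr <- poisson_train(150, 0.25, 0.75, seed = 3)
  expect_true(all(tr >= 0.25 & tr < 0.75))
  expect_identical(tr, poisson_train(150, 0.25, 0.75, seed = 3))

  # counting oracle: mean count over many trials within 3 standard errors
  rate <- 150; n_rep <- 1000
  counts <- vapply(seq_len(n_rep),
                   function(s) length(poisson_train(rate, 0, 1, seed = s)),
                   numeric(1))
  se <- sqrt(rate / n_rep)
  expect_lt(abs(mean(counts) - rate), 3 * se)
})

test_that("network with no external input is silent", {
  con <- walkoff_connectome()
  ras <- simulate_network(con, lif_params(), stim_protocol(n_trials = 3))
  expect_equal(nrow(ras$spikes), 0)
  expect_true(all(firing_rates(ras) == 0))
})

test_that("engine matches the scalar Euler reference exactly on small motifs", {
  p <- lif_params()
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- sample(2:5, 1)
    nts <- sample(c("ACh", "GABA", "Glu"), n, replace = TRUE)
    nn <- data.frame(id = seq_len(n), label = paste0("n", seq_len(n)),
                     hemisphere = "left", nt = nts, class_tag = "other")
    n_e <- sample(1:(n * (n - 1)), 1)
    pairs <- expand.grid(pre = seq_len(n), post = seq_len(n))
    pairs <- pairs[sample(nrow(pairs), n_e), ]
    ee <- data.frame(pre = pairs$pre, post = pairs$post,
                     count = sample(1:40, n_e, replace = TRUE))
    con <- signed_connectome(nn, ee)
    targets <- sample(seq_len(n), sample(1:2, 1))
    proto <- stim_protocol(list(stim_epoch(targets, sample(c(80, 150, 250), 1),
                                           0, 0.2)),
                           duration = 0.2, n_trials = 2, seed = s)
    ras <- simulate_network(con, p, proto)

    ids <- con$neurons$id
    n_steps <- as.integer(round(0.2 * 1000 / p$dt))
    oe <- data.frame(pre = match(con$edges$pre, ids),
                     post = match(con$edges$post, ids),
                     w = con$edges$sign * con$edges$count * p$w_unit)
    for (trial in 1:2) {
      ev <- flyhalt:::external_events(proto, p, ids, trial)
      ref <- oracle_lif(n, oe, ev, n_steps, p)
      got <- ras$spikes[ras$spikes$trial == trial, ]
      expect_identical(ids[ref$neuron], got$id)
      expect_identical(ref$t, got$t)
    }
  }
})

test_that("no inter-spike interval violates the refractory period", {
  con <- walkoff_connectome()
  proto <- stim_protocol(list(stim_epoch(c(1, 2), 400, 0, 1, strength = 60)),
                         n_trials = 5, seed = 11)
  ras <- simulate_network(con, lif_params(), proto)
  sp <- ras$spikes
  expect_gt(nrow(sp), 100)
  for (tr in unique(sp$trial)) {
    for (id in unique(sp$id[sp$trial == tr])) {
      isi <- diff(sp$t[sp$trial == tr & sp$id == id])
      expect_true(all(isi * 1000 >= ras$params$t_refract - 1e-9))
    }
  }
})

test_that("single-neuron rate is non-decreasing in stimulation rate", {
  nn <- data.frame(id = 1, label = "solo", hemisphere = "left",
                   nt = "ACh", class_tag = "other")
  con <- signed_connectome(nn, data.frame(pre = integer(0),
                                          post = integer(0),
                                          count = integer(0)))
  rates <- vapply(c(20, 80, 200), function(rt) {
    pr <- stim_protocol(list(stim_epoch(1, rt, 0, 1)), n_trials = 20,
                        seed = 5)
    firing_rates(simulate_network(con, lif_params(), pr))[["1"]]
  }, numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("inhibitory co-stimulation lowers the target's rate", {
  con <- walkoff_connectome()
  p <- lif_params()
  walk_only <- stim_protocol(list(stim_epoch(1, 150, 0, 1)),
                             n_trials = 10, seed = 2)
  co <- stim_protocol(list(stim_epoch(1, 150, 0, 1),
                           stim_epoch(2, 150, 0, 1)),
                      n_trials = 10, seed = 2)
  r_walk <- firing_rates(simulate_network(con, p, walk_only))[["3"]]
  r_co <- firing_rates(simulate_network(con, p, co))[["3"]]
  expect_lt(r_co, r_walk)
})

test_that("protocol-level silencing equals structural silencing, bit for bit", {
  con <- walkoff_connectome()
  p <- lif_params()
  proto_sil <- stim_protocol(list(stim_epoch(1, 150, 0, 1),
                                  stim_epoch(2, 150, 0, 1)),
                             silenced = 2, n_trials = 4, seed = 9)
  proto_plain <- stim_protocol(list(stim_epoch(1, 150, 0, 1),
                                    stim_epoch(2, 150, 0, 1)),
                               n_trials = 4, seed = 9)
  a <- simulate_network(con, p, proto_sil)
  b <- simulate_network(silence_neurons(con, 2), p, proto_plain)
  expect_identical(a$spikes, b$spikes)
})

test_that("identical protocol and seed give bit-identical rasters", {
  con <- walkoff_connectome()
  pr <- stim_protocol(list(stim_epoch(1, 120, 0.2, 0.8)), n_trials = 3,
                      seed = 77)
  a <- simulate_network(con, lif_params(), pr)
  b <- simulate_network(con, lif_params(), pr)
  expect_identical(a$spikes, b$spikes)
})

test_that("exponential kernel preserves silence and delivers comparable drive", {
  con <- walkoff_connectome()
  p_exp <- lif_params(kernel = "exp")
  expect_equal(nrow(simulate_network(con, p_exp,
                                     stim_protocol(n_trials = 2))$spikes), 0)
  pr <- stim_protocol(list(stim_epoch(1, 150, 0, 1)), n_trials = 10, seed = 4)
  r_exp <- firing_rates(simulate_network(con, p_exp, pr))[["1"]]
  r_delta <- firing_rates(simulate_network(con, lif_params(), pr))[["1"]]
  expect_gt(r_exp, 0)
  expect_lt(abs(r_exp - r_delta) / r_delta, 0.5)
})

test_that("firing_rates: scalar mode, windows, and integral-preserving smoothing", {
  # hand-built raster: 10 spikes in 1 s, 1 trial -> 10 Hz
  ras <- structure(list(spikes = data.frame(trial = 1, id = 1,
                                            t = seq(0.05, 0.95, length.out = 10)),
                        ids = c(1, 2), n_trials = 1, duration = 1,
                        params = lif_params()),
                   class = "spike_raster")
  r <- firing_rates(ras)
  expect_equal(unname(r[c("1", "2")]), c(10, 0))
  expect_error(firing_rates(ras, window = c(0.5, 0.5)), "empty")

  # interior bump: Gaussian smoothing preserves the time-integral within 1%
  set.seed(1)
  bump <- data.frame(trial = 1, id = 1, t = runif(200, 0.45, 0.55))
  ras2 <- structure(list(spikes = bump, ids = 1, n_trials = 1, duration = 1,
                         params = lif_params()),
                    class = "spike_raster")
  tr <- firing_rates(ras2, bin = 5, smooth_sigma = 25)
  un <- firing_rates(ras2, bin = 5)
  int_sm <- sum(tr$rate[1, ]) * 0.005
  int_un <- sum(un$rate[1, ]) * 0.005
  expect_lt(abs(int_sm - int_un) / int_un, 0.01)
})

test_that("top_responders ranks by rate with ascending-id tie-break", {
  r <- c(`7` = 5, `3` = 5, `10` = 20, `1` = 0, `4` = 12)
  expect_equal(top_responders(r, 100), c(10L, 4L, 3L, 7L, 1L))
  expect_equal(top_responders(r, 2), c(10L, 4L))
  # constructed ground truth: the most-driven neuron ranks first
  con <- walkoff_connectome()
  pr <- stim_protocol(list(stim_epoch(1, 150, 0, 1)), n_trials = 5, seed = 3)
  rr <- firing_rates(simulate_network(con, lif_params(), pr))
  expect_equal(top_responders(rr, 1), 1L)
})

test_that("rate_sweep grids, consistency and inhibition-release difference map", {
  con <- walkoff_connectome()
  p <- lif_params()
  ax1 <- list(targets = 1, rates = c(50, 150))
  ax2 <- list(targets = 2, rates = c(0, 100))
  sw <- rate_sweep(con, p, ax1, ax2, readout = 3, silenced = 2,
                   n_trials = 10, seed = 6)
  expect_equal(dim(sw$intact), c(2, 2))
  expect_true(all(sw$difference >= 0))  # releasing the only inhibitor
  # zero column of axis 2 equals a single-axis run (matched streams)
  single <- rate_sweep(con, p, ax1, list(targets = 2, rates = 0),
                       readout = 3, n_trials = 10, seed = 6)
  expect_equal(sw$intact[, "0"], single$intact[, "0"])
  # silenced set empty -> no difference grid
  expect_null(single$difference)
  expect_error(rate_sweep(con, p, ax1, ax2, readout = 2, silenced = 2,
                          n_trials = 2), "silenced")
})
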