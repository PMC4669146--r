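# closed-form LIF firing rate under constant excitatory conductance g
lif_rate <- function(g, np) {
  vinf <- (np$v_rest + g * np$e_e) / (1 + g)
  if (vinf <= np$v_thresh) return(0)
  tau <- np$tau_m / (1 + g)
  t_isi <- tau * log((vinf - np$v_reset) / (vinf - np$v_thresh))
  1000 / (t_isi + np$t_ref)
}

zero_w <- function(n_vis, n_hid) {
  weight_state(matrix(0, n_vis, n_hid), matrix(0, n_hid, n_vis), "nonneg")
}

test_that("a quiescent network stays quiescent", {
  cfg <- network_config(4, 2)
  s <- simulate_trial(cfg, neuron_params(), zero_w(4, 2))
  expect_equal(nrow(s), 0L)
})

test_that("constant-drive firing matches the closed-form f-I curve", {
  np <- neuron_params(adapt_b = 0)
  cfg <- network_config(1, 1, n_inh_vis = 0, n_inh_hid = 0,
                        trial_duration = 2000)
  for (g in c(0.4, 0.6, 1, 2)) {
    s <- simulate_trial(cfg, np, zero_w(1, 1), const_drive = g)
    sim_rate <- sum(s$population == "visible") / 2
    expect_lt(abs(sim_rate - lif_rate(g, np)) / lif_rate(g, np), 0.02)
  }
  # subthreshold drive is silent
  s0 <- simulate_trial(cfg, np, zero_w(1, 1), const_drive = 0.2)
  expect_equal(nrow(s0), 0L)
  # rate never exceeds 1 / refractory period
  s_hi <- simulate_trial(cfg, np, zero_w(1, 1), const_drive = 50)
  expect_lte(sum(s_hi$population == "visible") / 2, 1000 / np$t_ref)
})

test_that("spike-frequency adaptation stretches inter-spike intervals", {
  cfg <- network_config(1, 1, n_inh_vis = 0, n_inh_hid = 0,
                        trial_duration = 300)
  s <- simulate_trial(cfg, neuron_params(adapt_b = 0.1), zero_w(1, 1),
                      const_drive = 0.6)
  isi <- diff(s$time_ms[s$population == "visible"])
  expect_gt(length(isi), 5)
  expect_true(all(diff(isi) >= -1e-9))
})

test_that("every simulated neuron respects the refractory period", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  toy <- make_toy_network(128, 16, "nonneg", seed = 3, w_max = 0.1)
  np <- neuron_params(adapt_b = 0.05)
  cfg <- network_config(128, 16)
  for (seed in 1:5) {
    inp <- poisson_encode(prep$stimulus[[seed]], seed = seed)
    s <- simulate_trial(cfg, np, toy$weights, inp)
    gaps <- dplyr::summarise(
      dplyr::group_by(s, .data$population, .data$neuron),
      min_gap = if (dplyr::n() > 1) min(diff(.data$time_ms)) else Inf)
    expect_true(all(gaps$min_gap >= np$t_ref - 1e-9))
  }
})

test_that("without feedback there is no reverberation after input ends", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  toy <- make_toy_network(128, 16, "nonneg", seed = 3, w_max = 0.1)
  np <- neuron_params(adapt_b = 0.05)
  cfg <- network_config(128, 16)
  w_noq <- weight_state(toy$weights$W, matrix(0, 16, 128), "nonneg")
  for (seed in 1:5) {
    inp <- poisson_encode(prep$stimulus[[seed + 4]], seed = seed)
    s <- simulate_trial(cfg, np, w_noq, inp)
    vt <- s$time_ms[s$population == "visible"]
    # input window + membrane time constant + delay
    limit <- attr(inp, "duration") + np$tau_m + cfg$synaptic_delay
    expect_lt(max(c(vt, 0)), limit)
  }
})

test_that("halving the timestep moves ensemble spike counts by at most 5%", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  toy <- make_toy_network(128, 16, "nonneg", seed = 3, w_max = 0.1)
  np <- neuron_params(adapt_b = 0.05)
  tot <- function(dt) {
    cfg <- network_config(128, 16, dt = dt)
    out <- c(visible = 0, hidden = 0, inh_visible = 0, inh_hidden = 0)
    for (seed in 1:10) {
      inp <- poisson_encode(prep$stimulus[[(seed %% 16) + 1]], seed = seed)
      s <- simulate_trial(cfg, np, toy$weights, inp)
      out <- out + table(factor(s$population, names(out)))
    }
    out
  }
  t1 <- tot(0.1); t2 <- tot(0.05)
  expect_true(all(abs(t1 - t2) / pmax(t1, 1) <= 0.05))
})

test_that("scaling feedforward weights up never loses hidden spikes", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  toy <- make_toy_network(128, 16, "nonneg", seed = 3, w_max = 0.1)
  np <- neuron_params(adapt_b = 0.05)
  cfg <- network_config(128, 16)
  for (seed in 1:4) {
    inp <- poisson_encode(prep$stimulus[[seed * 3]], seed = seed)
    counts <- vapply(c(0.5, 1, 2, 4), function(sc) {
      w <- weight_state(toy$weights$W * sc, toy$weights$Q, "nonneg")
      sum(simulate_trial(cfg, np, w, inp)$population == "hidden")
    }, numeric(1))
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("the simulator is deterministic and validates its inputs", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  toy <- make_toy_network(128, 16, "nonneg", seed = 3, w_max = 0.1)
  cfg <- network_config(128, 16)
  inp <- poisson_encode(prep$stimulus[[1]], seed = 9)
  a <- simulate_trial(cfg, neuron_params(), toy$weights, inp)
  b <- simulate_trial(cfg, neuron_params(), toy$weights, inp)
  expect_identical(a, b)

  bad <- toy$weights; bad$W[1, 1] <- NaN
  expect_error(simulate_trial(cfg, neuron_params(), bad, inp), "finite")
  expect_error(simulate_trial(network_config(128, 16, dt = 3),
                              neuron_params(), toy$weights, inp),
               "refractory")
})

test_that("bout counting follows the worked example and marks empty bouts", {
  rec <- delta_record(c(2), c(1), c(1), t1 = 3, t2 = 12, t3 = 18)
  rec$time_ms[rec$population == "visible" &
                rec$time_ms == 3] <- c(2, 4)  # split the early spikes
  cb <- count_bouts(rec, boundary = 10)
  expect_equal(cb$x, 2); expect_equal(cb$y, 1); expect_equal(cb$xhat, 1)
  expect_equal(cb$dt1, 9); expect_equal(cb$dt2, 6)

  # schematic three-bout trial: x = 5, y = 3, xhat = 2
  rec2 <- delta_record(5, 3, 2, t1 = 4, t2 = 20, t3 = 40)
  cb2 <- count_bouts(rec2, boundary = 10)
  expect_equal(c(sum(cb2$x), sum(cb2$y), sum(cb2$xhat)), c(5, 3, 2))

  # no hidden spikes: separations undefined
  rec3 <- delta_record(2, 0, 1, t1 = 3, t2 = 12, t3 = 18)
  cb3 <- count_bouts(rec3, boundary = 10)
  expect_equal(cb3$y, 0)
  expect_true(is.na(cb3$dt1) && is.na(cb3$dt2))
})
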