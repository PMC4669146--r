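small_cfg <- function(...) {
  dots <- list(...)
  base <- list(n_presentations = 30, master_seed = 5, eval_every = Inf)
  base[names(dots)] <- dots
  do.call(bars_study_config, base)
}

test_that("weight initialization honours mode, symmetry and seeding", {
  cfg_sym <- small_cfg(init = "symmetric",
                       plasticity = plasticity_params(eta = 2e-4, zeta = 1e-4))
  w <- initialize_weights(cfg_sym, 128)
  expect_equal(symmetry_correlation(w$W, w$Q), 1)
  expect_equal(w$Q, 0.5 * t(w$W))

  cfg_ind <- small_cfg(init = "independent")
  w2 <- initialize_weights(cfg_ind, 128)
  expect_lt(abs(symmetry_correlation(w2$W, w2$Q)), 0.1)
  expect_true(min(w2$W) >= 0)
  expect_identical(w2, initialize_weights(cfg_ind, 128))
})

test_that("zero learning rates leave weights untouched; nonzero rates act", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  cfg0 <- small_cfg(plasticity = plasticity_params(eta = 0))
  net0 <- train_network(prep, cfg0)
  expect_identical(net0$weights$W, initialize_weights(cfg0, 128)$W)
  expect_identical(net0$weights$Q, initialize_weights(cfg0, 128)$Q)

  cfg1 <- small_cfg(n_presentations = 10)
  net1 <- train_network(prep, cfg1)
  expect_false(identical(net1$weights$W, initialize_weights(cfg1, 128)$W))
})

test_that("checkpoint round-trip continues bit-identically", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  cfg <- small_cfg(n_presentations = 40)
  full <- train_network(prep, cfg)

  cfg20 <- small_cfg(n_presentations = 20)
  half <- train_network(prep, cfg20)
  dir <- withr::local_tempdir()
  save_checkpoint(half, dir)
  resumed <- train_network(prep, cfg, state = load_checkpoint(dir))
  expect_identical(resumed$weights$W, full$weights$W)
  expect_identical(resumed$weights$Q, full$weights$Q)
  expect_identical(resumed$homeostasis$A, full$homeostasis$A)
  expect_identical(resumed$homeostasis$Phi, full$homeostasis$Phi)
})

test_that("evaluation is reproducible and respects the boost path", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  cfg <- small_cfg(n_presentations = 60)
  net <- train_network(prep, cfg)
  ev1 <- evaluate_network(net$weights, net$homeostasis, net$network, cfg,
                          net$test_stimuli)
  ev2 <- evaluate_network(net$weights, net$homeostasis, net$network, cfg,
                          net$test_stimuli)
  expect_identical(ev1$summary, ev2$summary)

  ev_b1 <- evaluate_network(net$weights, net$homeostasis, net$network, cfg,
                            net$test_stimuli, scale_boost = 1)
  expect_identical(ev_b1$summary, ev1$summary)
  expect_error(evaluate_network(net$weights, net$homeostasis, net$network,
                                cfg, list()), "empty")
})

test_that("symmetric-init training maintains the tied-weight relation", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  cfg <- small_cfg(mode = "signed_additive", init = "symmetric",
                   n_presentations = 25,
                   plasticity = plasticity_params(eta = 2e-4,
                                                  w_min = -Inf, w_max = Inf))
  net <- train_network(prep, cfg)
  expect_lt(max(abs(net$weights$Q - t(net$weights$W))), 1e-10)
  expect_equal(symmetry_correlation(net$weights), 1, tolerance = 1e-9)
})

test_that("the runaway-excitation guard trips on pathological weights", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  cfg <- small_cfg(n_presentations = 150, runaway_factor = 1.01,
                   plasticity = plasticity_params(eta = 5e-3, w_max = 5))
  expect_error(train_network(prep, cfg), "runaway")
})

test_that("tidiers summarise a trained network", {
  prep <- prepare_stimuli(make_bars_dataset(8))
  cfg <- small_cfg(n_presentations = 20, eval_every = 10)
  net <- train_network(prep, cfg)
  td <- tidy(net)
  expect_equal(nrow(td), 128 * 16)
  expect_named(td, c("visible", "hidden", "feedforward", "feedback"))
  expect_equal(matrix(td$feedforward, 128, 16), unname(net$weights$W))
  gl <- glance(net)
  expect_equal(gl$presentations, 20)
  expect_s3_class(autoplot(net), "ggplot")
  rf <- receptive_fields(net$weights$W)
  expect_s3_class(autoplot(rf), "ggplot")
  expect_s3_class(plot_spike_raster(random_record(4, 2, 30, 100, 1)), "ggplot")
})
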