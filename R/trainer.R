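#' Prepare raw stimuli for training
#'
#' Applies the stimulus pipeline to a tibble of raw images: subtract the
#' dataset mean (computed over the set unless supplied), flatten row-major,
#' optionally drop low-contrast patches, and split into ON/OFF rate vectors.
#'
#' @param raw Tibble with a `pixels` list-column of equal-size matrices,
#'   e.g. from [generate_synthetic_stimuli()] or [make_bars_dataset()].
#' @param dataset_mean Optional per-pixel mean vector (row-major); computed
#'   from `raw` when `NULL`.
#' @param contrast_threshold If non-`NULL`, drop stimuli failing
#'   [contrast_filter()] at this threshold.
#' @return `raw` with added list-column `stimulus` of [split_on_off()]
#'   objects (filtered rows removed); attribute `dataset_mean` records the
#'   mean used.
#' @export
prepare_stimuli <- function(raw, dataset_mean = NULL,
                            contrast_threshold = NULL) {
  if (nrow(raw) == 0L) abort("empty stimulus set")
  flat <- purrr::map(raw$pixels, ~ as.vector(t(.x)))
  dataset_mean <- dataset_mean %||% (Reduce(`+`, flat) / length(flat))
  signed <- purrr::map(raw$pixels, preprocess_stimulus, dataset_mean = dataset_mean)
  if (!is.null(contrast_threshold)) {
    keep <- purrr::map_lgl(signed, contrast_filter, threshold = contrast_threshold)
    raw <- raw[keep, ]
    signed <- signed[keep]
  }
  raw$stimulus <- purrr::map(signed, split_on_off)
  attr(raw, "dataset_mean") <- dataset_mean
  raw
}

#' Training configuration
#'
#' Binds together the network, neuron, plasticity, homeostasis and encoding
#' settings for a training run. The two modes mirror the two experimental
#' regimes: `"signed_additive"` lets weights take either sign and uses
#' additive synaptic offsets (digit-recognition-style), while
#' `"nonneg_multiplicative"` restricts weights to be non-negative (Dale's
#' law) and uses multiplicative scaling factors (natural-patch-style).
#'
#' @param n_hid Number of hidden units.
#' @param mode `"signed_additive"` or `"nonneg_multiplicative"`.
#' @param init Weight initialization: `"symmetric"` draws `W` and ties
#'   `Q = (zeta/eta) * t(W)`; `"independent"` draws both separately.
#' @param n_presentations Number of training presentations.
#' @param eval_every Evaluate (plasticity and homeostasis frozen) every this
#'   many presentations; `Inf` disables periodic evaluation.
#' @param test_set_size Number of frozen test stimuli (default 100).
#' @param master_seed Master seed; every stream (presentation order, weight
#'   init, per-trial and per-test-image Poisson encoding) is derived from it.
#' @param rho Target activation rate for homeostasis.
#' @param kappa,ema_decay Homeostasis rates, see [homeostasis_state()].
#' @param w_init_max Upper end of the uniform weight-init interval.
#' @param network Optional [network_config()]; when `NULL` one is built from
#'   the stimulus dimension and `n_hid` at training time.
#' @param neuron [neuron_params()].
#' @param neuron_hidden Optional [neuron_params()] for the hidden layer
#'   (defaults to `neuron`); hidden units are often given weaker adaptation
#'   so that a matching stimulus evokes a short burst rather than a single
#'   marginal spike.
#' @param plasticity [plasticity_params()]; bounds are forced to match the
#'   mode (`w_min = 0` in non-negative mode, `-w_max` in signed mode).
#' @param encoding [encoding_params()].
#' @param runaway_factor Abort if a trial's total spike count exceeds this
#'   multiple of the median over the first 100 trials (runaway-excitation
#'   guard).
#' @return A list of class `mstdp_train_config`.
#' @export
train_config <- function(n_hid,
                         mode = c("nonneg_multiplicative", "signed_additive"),
                         init = c("independent", "symmetric"),
                         n_presentations = 2000, eval_every = 500,
                         test_set_size = 100, master_seed = 1L,
                         rho = 0.0625, kappa = NULL, ema_decay = 0.01,
                         w_init_max = 0.02, network = NULL,
                         neuron = neuron_params(), neuron_hidden = NULL,
                         plasticity = plasticity_params(),
                         encoding = encoding_params(),
                         runaway_factor = 20) {
  mode <- arg_match(mode)
  init <- arg_match(init)
  plasticity$w_min <- if (mode == "signed_additive") -plasticity$w_max else 0
  structure(list(n_hid = as.integer(n_hid), mode = mode, init = init,
                 n_presentations = n_presentations, eval_every = eval_every,
                 test_set_size = test_set_size,
                 master_seed = as.integer(master_seed), rho = rho,
                 kappa = kappa, ema_decay = ema_decay,
                 w_init_max = w_init_max, network = network, neuron = neuron,
                 neuron_hidden = neuron_hidden, plasticity = plasticity, encoding = encoding,
                 runaway_factor = runaway_factor),
            class = "mstdp_train_config")
}

weight_mode <- function(config) {
  if (config$mode == "signed_additive") "signed" else "nonneg"
}

#' Reference configuration for the bars experiment
#'
#' The package's standard desk-scale experiment: an 8x8 single-bar ensemble
#' (16 stimuli, 128 visible neurons after ON/OFF doubling) learned by 16
#' hidden units in non-negative / multiplicative-scaling mode with
#' independent weight initialization. All rates and conductances are the
#' values at which the network shows the three-bout trial structure with
#' sparse hidden activity; see the package vignette for how each was chosen.
#'
#' @param n_presentations Number of presentations (default 5000).
#' @param master_seed Master seed.
#' @param eval_every Evaluation cadence (default 500).
#' @param ... Overrides passed on to [train_config()].
#' @return A [train_config()] object; pair it with
#'   `prepare_stimuli(make_bars_dataset(8))`.
#' @export
bars_study_config <- function(n_presentations = 5000, master_seed = 1L,
                              eval_every = 500, ...) {
  args <- list(
    n_hid = 16, mode = "nonneg_multiplicative", init = "independent",
    n_presentations = n_presentations, eval_every = eval_every,
    test_set_size = 16, master_seed = master_seed,
    rho = 1 / 16, kappa = 0.05, ema_decay = 0.01, w_init_max = 0.05,
    network = network_config(n_vis = 128, n_hid = 16),
    neuron = neuron_params(adapt_b = 0.05),
    plasticity = plasticity_params(eta = 2e-4, w_max = 0.5))
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(train_config, args)
}

#' Initialize network weights
#'
#' Weights are drawn uniformly from `[0, w_init_max]` — small enough that
#' initial hidden firing is rare but nonzero. Symmetric initialization ties
#' `Q = (zeta/eta) * t(W)`; independent initialization draws `Q` separately
#' (its symmetry correlation with `W` then starts near zero and is expected
#' to rise under mirrored STDP).
#'
#' @param config [train_config()].
#' @param n_vis Number of visible neurons (after ON/OFF doubling).
#' @return An [weight_state()] object.
#' @export
initialize_weights <- function(config, n_vis) {
  ratio <- if (config$plasticity$eta > 0) {
    config$plasticity$zeta / config$plasticity$eta
  } else 1
  withr::with_seed(substream(config$master_seed, 11L), {
    W <- matrix(runif(n_vis * config$n_hid, 0, config$w_init_max),
                n_vis, config$n_hid)
    Q <- if (config$init == "symmetric") ratio * t(W) else {
      matrix(runif(n_vis * config$n_hid, 0, config$w_init_max),
             config$n_hid, n_vis)
    }
    weight_state(W, Q, weight_mode(config))
  })
}

resolve_network <- function(config, n_vis) {
  config$network %||% network_config(n_vis = n_vis, n_hid = config$n_hid)
}

new_homeostasis <- function(config) {
  homeostasis_state(
    config$n_hid,
    mode = if (config$mode == "signed_additive") "additive" else "multiplicative",
    rho = config$rho, kappa = config$kappa, ema_decay = config$ema_decay)
}

encode_seed <- function(master, trial) substream(master, 100000L + trial)
test_seed <- function(master, image) substream(master, 900000L + image)

#' Train the spiking autoencoder
#'
#' Runs sequential stimulus presentations. Each presentation Poisson-encodes
#' one training stimulus, simulates a trial with the homeostasis-adjusted
#' effective weights, applies the mirrored-STDP update (accumulated over the
#' trial, applied once, then clipped), and finally updates the homeostatic
#' state. Every `eval_every` presentations plasticity and homeostasis are
#' frozen and the network is evaluated on the same fixed test stimuli.
#'
#' @param dataset Prepared stimulus tibble from [prepare_stimuli()].
#' @param config [train_config()].
#' @param state Optional checkpoint state (list with `weights`,
#'   `homeostasis`, `presentation`) to resume from, e.g. a loaded
#'   checkpoint; seeds being derived from the master seed and presentation
#'   index, a resumed run reproduces an uninterrupted one exactly.
#' @return An object of class `mstdp_net`: list with `weights`,
#'   `homeostasis`, `history` (evaluation metrics tibble), `config`,
#'   `test_stimuli`, `dataset_mean`.
#' @export
train_network <- function(dataset, config, state = NULL) {
  if (nrow(dataset) == 0L) abort("empty dataset")
  if (is.null(dataset$stimulus)) abort("run `prepare_stimuli()` first")
  n_vis <- length(dataset$stimulus[[1]]$rates)
  net_cfg <- resolve_network(config, n_vis)
  stopifnot(net_cfg$n_vis == n_vis)

  order_all <- withr::with_seed(substream(config$master_seed, 21L),
    sample.int(nrow(dataset), config$n_presentations, replace = TRUE))
  test_idx <- withr::with_seed(substream(config$master_seed, 31L),
    sample.int(nrow(dataset), min(config$test_set_size, nrow(dataset))))
  test_stimuli <- dataset$stimulus[test_idx]

  weights <- state$weights %||% initialize_weights(config, n_vis)
  hstate <- state$homeostasis %||% new_homeostasis(config)
  start <- (state$presentation %||% 0L) + 1L
  history <- state$history %||% NULL
  warmup_totals <- state$warmup_totals %||% numeric(0)
  ceiling_total <- state$ceiling_total %||% Inf
  fired_accum <- rep(0, config$n_hid)
  trials_accum <- 0

  for (t_i in seq(start, config$n_presentations)) {
    stim <- dataset$stimulus[[order_all[t_i]]]
    input <- poisson_encode(stim, config$encoding,
                            seed = encode_seed(config$master_seed, t_i))
    w_eff <- weight_state(effective_weights(weights$W, hstate), weights$Q,
                          weight_mode(config))
    spikes <- simulate_trial(net_cfg, config$neuron, w_eff, input,
                             np_hid = config$neuron_hidden)

    total <- nrow(spikes)
    if (length(warmup_totals) < 100L) {
      warmup_totals <- c(warmup_totals, total)
      if (length(warmup_totals) == 100L) {
        ceiling_total <- config$runaway_factor *
          max(stats::median(warmup_totals), 1)
      }
    } else if (total > ceiling_total) {
      abort(sprintf(paste0("runaway excitation at presentation %d: %d spikes ",
                           "exceeds guard ceiling %.0f"),
                    t_i, total, ceiling_total))
    }

    upd <- mstdp_trial_update(spikes, n_vis, config$n_hid, config$plasticity)
    weights <- apply_weight_update(weights, upd, config$plasticity)

    fired <- count_bouts(spikes)$y > 0
    hstate <- update_activity(hstate, fired)
    hstate <- update_scaling(hstate)
    fired_accum <- fired_accum + fired
    trials_accum <- trials_accum + 1

    if (is.finite(config$eval_every) && t_i %% config$eval_every == 0L) {
      ev <- evaluate_network(weights, hstate, net_cfg, config, test_stimuli)
      A_window <- fired_accum / trials_accum
      summ <- dplyr::mutate(
        ev$summary, presentation = t_i,
        sparsity_loss_train = sparsity_loss(A_window, hstate$rho),
        mean_activation_train = mean(A_window), .before = 1)
      history <- dplyr::bind_rows(history, summ)
      fired_accum[] <- 0
      trials_accum <- 0
    }
  }

  structure(list(weights = weights, homeostasis = hstate,
                 history = history %||% tibble(), config = config,
                 network = net_cfg, test_stimuli = test_stimuli,
                 dataset_mean = attr(dataset, "dataset_mean"),
                 presentation = config$n_presentations,
                 warmup_totals = warmup_totals,
                 ceiling_total = ceiling_total),
            class = "mstdp_net")
}

#' Evaluate the network with plasticity disabled
#'
#' Presents frozen test stimuli (each with its own fixed encoding seed, so
#' the test inputs are identical across evaluations), records hidden spike
#' counts `z`, computes the feedback excitation `t(Q) %*% z`, and summarises
#' reconstruction loss, sparsity loss, symmetry correlation and mean
#' activation. Plasticity and homeostasis are both frozen.
#'
#' @param weights [weight_state()] (raw weights).
#' @param hstate [homeostasis_state()].
#' @param net_cfg [network_config()].
#' @param config [train_config()] (for encoding, neuron and master seed).
#' @param test_stimuli List of `mstdp_stimulus` objects.
#' @param scale_boost Multiplier applied to the scaling factors `Phi_j`
#'   during this evaluation only (multiplicative mode; e.g. 1.5 probes
#'   reconstruction with excitability raised by 50%). Ignored in additive
#'   mode.
#' @return List with `per_stimulus` (tibble: `stimulus`, list-columns `nu`,
#'   `z`, `feedback`, and `hidden_spikes`) and `summary` (one-row tibble).
#' @export
evaluate_network <- function(weights, hstate, net_cfg, config, test_stimuli,
                             scale_boost = 1) {
  if (length(test_stimuli) == 0L) abort("empty test set")
  W_eff <- effective_weights(weights$W, hstate, boost = scale_boost)
  w_eff <- weight_state(W_eff, weights$Q, weight_mode(config))
  rows <- purrr::imap(test_stimuli, function(stim, k) {
    input <- poisson_encode(stim, config$encoding,
                            seed = test_seed(config$master_seed, k))
    spikes <- simulate_trial(net_cfg, config$neuron, w_eff, input,
                             np_hid = config$neuron_hidden)
    z <- tabulate(spikes$neuron[spikes$population == "hidden"], config$n_hid)
    list(nu = stim$rates, z = z,
         feedback = as.vector(t(weights$Q) %*% z))
  })
  per_stimulus <- tibble(
    stimulus = seq_along(rows),
    nu = purrr::map(rows, "nu"), z = purrr::map(rows, "z"),
    feedback = purrr::map(rows, "feedback"),
    hidden_spikes = purrr::map_int(rows, ~ sum(.x$z)))
  A_test <- Reduce(`+`, purrr::map(rows, ~ as.numeric(.x$z > 0))) / length(rows)
  rec <- reconstruction_loss(per_stimulus$nu, per_stimulus$feedback)
  summary <- tibble(
    reconstruction_loss = as.numeric(rec),
    mean_input_correlation = 1 - as.numeric(rec),
    sparsity_loss = sparsity_loss(A_test, hstate$rho),
    symmetry_correlation = symmetry_correlation(weights$W, weights$Q),
    mean_activation = mean(A_test),
    n_degenerate = attr(rec, "n_degenerate"))
  list(per_stimulus = per_stimulus, summary = summary, A_test = A_test)
}
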