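#' Neuron parameters for the conductance-based LIF model
#'
#' Leaky integrate-and-fire neurons with exponential synaptic conductances
#' and (for excitatory cells) spike-frequency adaptation modelled as a
#' potassium-like conductance incremented at each spike. Conductances are
#' dimensionless, relative to the leak. Defaults follow the widely used
#' Vogels-Abbott family of cortical network models.
#'
#' @param tau_m Membrane time constant (ms).
#' @param v_rest,v_thresh,v_reset Resting, threshold and reset potentials (mV).
#' @param t_ref Absolute refractory period (ms).
#' @param tau_e,tau_i Excitatory / inhibitory synaptic conductance time
#'   constants (ms).
#' @param e_e,e_i Excitatory / inhibitory reversal potentials (mV); the
#'   adaptation conductance reverses at `e_i`.
#' @param adapt_b Adaptation conductance increment per spike (0 disables).
#' @param tau_adapt Adaptation decay time constant (ms).
#' @return A list of class `mstdp_neuron`.
#' @export
neuron_params <- function(tau_m = 20, v_rest = -70, v_thresh = -54,
                          v_reset = -60, t_ref = 2, tau_e = 5, tau_i = 10,
                          e_e = 0, e_i = -80, adapt_b = 0.02,
                          tau_adapt = 100) {
  if (v_thresh <= v_rest) abort("`v_thresh` must exceed `v_rest`")
  if (any(c(tau_m, t_ref, tau_e, tau_i, tau_adapt) <= 0)) {
    abort("all time constants must be > 0")
  }
  structure(list(tau_m = tau_m, v_rest = v_rest, v_thresh = v_thresh,
                 v_reset = v_reset, t_ref = t_ref, tau_e = tau_e,
                 tau_i = tau_i, e_e = e_e, e_i = e_i, adapt_b = adapt_b,
                 tau_adapt = tau_adapt),
            class = "mstdp_neuron")
}

np_vector <- function(np) {
  c(np$tau_m, np$v_rest, np$v_thresh, np$v_reset, np$t_ref,
    np$tau_e, np$tau_i, np$e_e, np$e_i, np$adapt_b, np$tau_adapt)
}

#' Network architecture and simulation configuration
#'
#' Visible and hidden excitatory layers are reciprocally all-to-all
#' connected (feedforward `W`, feedback `Q`); each layer additionally has a
#' pool of inhibitory LIF neurons (no adaptation) connected all-to-all with
#' the layer's excitatory cells at fixed, uniform weights that never change
#' during learning.
#'
#' @param n_vis,n_hid Excitatory population sizes.
#' @param n_inh_vis,n_inh_hid Inhibitory pool sizes (default: a quarter of
#'   the layer, at least 4).
#' @param synaptic_delay Synaptic transmission delay (ms), default 2.
#' @param trial_duration Trial length (ms), default 65.
#' @param dt Integration timestep (ms).
#' @param w_ext Excitatory conductance increment per external input spike.
#' @param w_vis_to_inh,w_hid_to_inh E-to-I conductance weights.
#' @param w_inh_to_vis,w_inh_to_hid I-to-E conductance weights.
#' @return A list of class `mstdp_network`.
#' @export
network_config <- function(n_vis, n_hid,
                           n_inh_vis = max(4L, round(n_vis / 4)),
                           n_inh_hid = max(4L, round(n_hid / 4)),
                           synaptic_delay = 2, trial_duration = 65,
                           dt = 0.1, w_ext = 1,
                           w_vis_to_inh = 0.03, w_inh_to_vis = 0.02,
                           w_hid_to_inh = 0.5, w_inh_to_hid = 0.8) {
  if (synaptic_delay < 0) abort("`synaptic_delay` must be >= 0")
  if (trial_duration <= 0) abort("`trial_duration` must be > 0")
  structure(list(n_vis = as.integer(n_vis), n_hid = as.integer(n_hid),
                 n_inh_vis = as.integer(n_inh_vis),
                 n_inh_hid = as.integer(n_inh_hid),
                 synaptic_delay = synaptic_delay,
                 trial_duration = trial_duration, dt = dt, w_ext = w_ext,
                 w_vis_to_inh = w_vis_to_inh, w_inh_to_vis = w_inh_to_vis,
                 w_hid_to_inh = w_hid_to_inh, w_inh_to_hid = w_inh_to_hid),
            class = "mstdp_network")
}

#' Weight state of the two-layer network
#'
#' @param W Feedforward matrix, `n_vis x n_hid` (visible to hidden).
#' @param Q Feedback matrix, `n_hid x n_vis` (hidden to visible).
#' @param mode `"signed"` (entries may be negative; a negative weight is
#'   delivered as an inhibitory conductance of equal magnitude) or
#'   `"nonneg"` (all entries must be >= 0).
#' @return A list of class `mstdp_weights`.
#' @export
weight_state <- function(W, Q, mode = c("signed", "nonneg")) {
  mode <- arg_match(mode)
  if (nrow(Q) != ncol(W) || ncol(Q) != nrow(W)) {
    abort("`Q` must be the transpose shape of `W`")
  }
  if (mode == "nonneg" && (min(W) < 0 || min(Q) < 0)) {
    abort("negative weights in non-negative mode")
  }
  structure(list(W = W, Q = Q, mode = mode), class = "mstdp_weights")
}

#' @export
print.mstdp_weights <- function(x, ...) {
  cat(sprintf("<mstdp_weights> %d visible x %d hidden (%s mode), |W| in [%.3g, %.3g]\n",
              nrow(x$W), ncol(x$W), x$mode, min(x$W), max(x$W)))
  invisible(x)
}

#' Simulate one stimulus presentation of the full network
#'
#' Integrates the four populations (visible E, hidden E, and the two
#' inhibitory pools) over one trial with exponential-Euler conductance LIF
#' dynamics. Every delivered spike arrives one synaptic delay after
#' emission. The dynamics contain no noise, so the result is fully
#' determined by the input spikes and weights.
#'
#' @param config [network_config()].
#' @param np [neuron_params()] for the excitatory populations; inhibitory
#'   neurons use the same parameters without adaptation and a 10 ms membrane
#'   time constant.
#' @param weights [weight_state()]; pass homeostasis-adjusted effective
#'   weights (see [effective_weights()]).
#' @param input_spikes Tibble with `neuron`, `time_ms` — external input to
#'   visible neurons, e.g. from [poisson_encode()].
#' @param const_drive Optional numeric vector (length `n_vis`) of constant
#'   excitatory conductance applied to visible neurons throughout the trial;
#'   used for controlled f-I measurements.
#' @param np_hid Optional [neuron_params()] override for the hidden
#'   excitatory population (defaults to `np`); populations having their own
#'   parameter sets mirrors how this model family is usually specified.
#' @param np_inh Optional [neuron_params()] override for inhibitory pools.
#' @return Spike tibble with columns `population` (factor: visible, hidden,
#'   inh_visible, inh_hidden), `neuron`, `time_ms`, carrying attributes
#'   `n_vis`, `n_hid`, `trial_duration`, `stimulus_end`.
#' @export
simulate_trial <- function(config, np, weights, input_spikes = NULL,
                           const_drive = NULL, np_hid = NULL, np_inh = NULL) {
  if (config$dt > np$t_ref) {
    abort("timestep exceeds the refractory period; reduce `dt`")
  }
  if (!all(is.finite(weights$W)) || !all(is.finite(weights$Q))) {
    abort("non-finite weights")
  }
  stopifnot(nrow(weights$W) == config$n_vis, ncol(weights$W) == config$n_hid)
  np_hid <- np_hid %||% np
  np_inh <- np_inh %||% neuron_params(tau_m = 10, adapt_b = 0)
  ext_t <- numeric(0); ext_id <- integer(0)
  if (!is.null(input_spikes) && nrow(input_spikes) > 0L) {
    if (max(input_spikes$neuron) > config$n_vis) {
      abort("input spikes target a neuron beyond `n_vis`")
    }
    ext_t <- input_spikes$time_ms
    ext_id <- as.integer(input_spikes$neuron)
  }
  res <- lif_trial_cpp(
    config$dt, config$trial_duration, config$synaptic_delay,
    np_vector(np), np_vector(np_hid), np_vector(np_inh),
    pmax(weights$W, 0), pmax(-weights$W, 0),
    pmax(weights$Q, 0), pmax(-weights$Q, 0),
    config$w_vis_to_inh, config$w_inh_to_vis,
    config$w_hid_to_inh, config$w_inh_to_hid,
    config$n_inh_vis, config$n_inh_hid,
    ext_t, ext_id, config$w_ext,
    const_drive %||% numeric(0))
  pops <- c("visible", "hidden", "inh_visible", "inh_hidden")
  spk <- purrr::map2_dfr(res, pops, function(p, nm) {
    tibble(population = nm, neuron = as.integer(p$neuron),
           time_ms = as.numeric(p$time_ms))
  })
  spk$population <- factor(spk$population, levels = pops)
  spk <- dplyr::arrange(spk, .data$population, .data$neuron, .data$time_ms)
  attr(spk, "n_vis") <- config$n_vis
  attr(spk, "n_hid") <- config$n_hid
  attr(spk, "trial_duration") <- config$trial_duration
  if (!is.null(attr(input_spikes, "duration"))) {
    attr(spk, "stimulus_end") <- attr(input_spikes, "duration")
  }
  spk
}

#' Bout decomposition of a trial's spike record
#'
#' Splits visible activity at a boundary into the initial bout `x` (external
#' drive) and the late, feedback-driven reconstruction bout `xhat`, counts
#' hidden spikes `y`, and measures the mean bout separations: `dt1` from
#' early visible to hidden spikes and `dt2` from hidden to late visible
#' spikes. Empty bouts yield `NA` separations.
#'
#' @param spikes Spike tibble from [simulate_trial()].
#' @param boundary Time (ms) separating initial from late visible activity;
#'   defaults to the end of the external input window recorded on `spikes`.
#' @param n_vis,n_hid Population sizes (taken from attributes if present).
#' @return A list of class `mstdp_counts`: count vectors `x`, `y`, `xhat`
#'   and scalars `dt1`, `dt2`, `boundary`.
#' @export
count_bouts <- function(spikes, boundary = NULL, n_vis = NULL, n_hid = NULL) {
  n_vis <- n_vis %||% attr(spikes, "n_vis")
  n_hid <- n_hid %||% attr(spikes, "n_hid")
  boundary <- boundary %||% attr(spikes, "stimulus_end")
  if (is.null(boundary)) abort("no `boundary` given and none recorded on `spikes`")
  vis <- spikes[spikes$population == "visible", ]
  hid <- spikes[spikes$population == "hidden", ]
  early <- vis[vis$time_ms < boundary, ]
  late <- vis[vis$time_ms >= boundary, ]
  x <- tabulate(early$neuron, n_vis)
  xhat <- tabulate(late$neuron, n_vis)
  y <- tabulate(hid$neuron, n_hid)
  dt1 <- if (nrow(hid) && nrow(early)) mean(hid$time_ms) - mean(early$time_ms) else NA_real_
  dt2 <- if (nrow(hid) && nrow(late)) mean(late$time_ms) - mean(hid$time_ms) else NA_real_
  structure(list(x = x, y = y, xhat = xhat, dt1 = dt1, dt2 = dt2,
                 boundary = boundary),
            class = "mstdp_counts")
}

#' @export
print.mstdp_counts <- function(x, ...) {
  cat(sprintf("<mstdp_counts> sum(x)=%d sum(y)=%d sum(xhat)=%d dt1=%.2f dt2=%.2f\n",
              sum(x$x), sum(x$y), sum(x$xhat), x$dt1, x$dt2))
  invisible(x)
}
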