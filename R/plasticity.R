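#' Plasticity parameters for the mirrored STDP rule
#'
#' Additive, all-to-all pair-based STDP with exponential kernels. `tau_plus`
#' governs the potentiation branch and `tau_minus` the depression branch in
#' both the feedforward (STDP) and feedback (anti-Hebbian STDP) rules;
#' biological values are tens of milliseconds.
#'
#' @param eta Feedforward learning rate (> 0).
#' @param zeta Feedback learning rate; defaults to `eta` (the maintained
#'   weight symmetry is then `Q = t(W)`).
#' @param tau_plus,tau_minus Potentiation / depression timescales (ms).
#' @param w_min,w_max Weight bounds applied after each trial update. Use
#'   `w_min = 0` for the non-negative (Dale-respecting) mode and
#'   `w_min = -w_max` for the signed mode.
#' @return A list of class `mstdp_plasticity`.
#' @export
plasticity_params <- function(eta = 2e-4, zeta = eta,
                              tau_plus = 20, tau_minus = 20,
                              w_min = 0, w_max = 0.5) {
  if (eta < 0 || zeta < 0) abort("learning rates must be >= 0")
  if (tau_plus <= 0 || tau_minus <= 0) abort("STDP timescales must be > 0")
  if (w_min > w_max) abort("`w_min` must be <= `w_max`")
  structure(list(eta = eta, zeta = zeta, tau_plus = tau_plus,
                 tau_minus = tau_minus, w_min = w_min, w_max = w_max),
            class = "mstdp_plasticity")
}

#' All-pairs additive STDP sum for one synapse
#'
#' Sums the exponential STDP kernel over every (pre, post) spike pair:
#' a post spike after a pre spike potentiates by `exp(-|dt|/tau_plus)`;
#' a post spike at or before a pre spike depresses by `exp(-|dt|/tau_minus)`
#' (simultaneous spikes count as depression). Returns the change divided by
#' the learning rate.
#'
#' @param pre_spikes,post_spikes Numeric vectors of spike times (ms).
#' @param params [plasticity_params()].
#' @return Scalar pair sum (multiply by `eta` for the weight change).
#' @export
stdp_pair_sum <- function(pre_spikes, post_spikes, params = plasticity_params()) {
  if (length(pre_spikes) == 0L || length(post_spikes) == 0L) return(0)
  dt <- outer(post_spikes, pre_spikes, `-`)  # t_post - t_pre
  sum(ifelse(dt > 0, exp(-dt / params$tau_plus), -exp(dt / params$tau_minus)))
}

#' All-pairs anti-Hebbian STDP sum for one synapse
#'
#' The temporally reversed rule used at feedback synapses: pre before post
#' depresses, post at or before pre potentiates. `tau_plus` stays with the
#' potentiation branch, mirroring [stdp_pair_sum()].
#'
#' @inheritParams stdp_pair_sum
#' @return Scalar pair sum (multiply by `zeta` for the weight change).
#' @export
astdp_pair_sum <- function(pre_spikes, post_spikes, params = plasticity_params()) {
  if (length(pre_spikes) == 0L || length(post_spikes) == 0L) return(0)
  dt <- outer(post_spikes, pre_spikes, `-`)
  sum(ifelse(dt <= 0, exp(dt / params$tau_plus), -exp(-dt / params$tau_minus)))
}

# Shared mirrored kernel in terms of visible (k) and hidden (l) spike times:
# potentiation when the hidden spike is later. Written so that
# stdp_pair_sum(vis, hid) == astdp_pair_sum(hid, vis) == this.
mstdp_pair_matrix <- function(vis_times, hid_times, params) {
  dt <- outer(hid_times, vis_times, `-`)  # t_hidden - t_visible
  ifelse(dt > 0, exp(-dt / params$tau_plus), -exp(dt / params$tau_minus))
}

#' Mirrored-STDP weight update for one completed trial
#'
#' Applies the combined rule in which feedforward synapses follow STDP and
#' feedback synapses follow anti-Hebbian STDP. Because visible neurons are
#' pre-synaptic for feedforward connections but post-synaptic for feedback
#' ones, both rules reduce to one kernel over (visible, hidden) spike pairs,
#' and the two updates are exactly proportional:
#' `dW[i, j] / eta == dQ[j, i] / zeta` for every pair.
#'
#' @param trial_spikes Spike tibble from [simulate_trial()] (or any tibble
#'   with columns `population`, `neuron`, `time_ms`); only `visible` and
#'   `hidden` rows are used.
#' @param n_vis,n_hid Population sizes; taken from the spike record's
#'   attributes when omitted.
#' @param params [plasticity_params()].
#' @return List with matrices `dW` (n_vis x n_hid) and `dQ` (n_hid x n_vis).
#'   Bounds are not applied here; see [apply_weight_update()].
#' @export
mstdp_trial_update <- function(trial_spikes, n_vis = NULL, n_hid = NULL,
                               params = plasticity_params()) {
  n_vis <- n_vis %||% attr(trial_spikes, "n_vis")
  n_hid <- n_hid %||% attr(trial_spikes, "n_hid")
  if (is.null(n_vis) || is.null(n_hid)) {
    abort("supply `n_vis` and `n_hid` (or a spike record carrying them)")
  }
  vis <- trial_spikes[trial_spikes$population == "visible", ]
  hid <- trial_spikes[trial_spikes$population == "hidden", ]
  dW <- matrix(0, n_vis, n_hid)
  if (nrow(vis) > 0L && nrow(hid) > 0L) {
    K <- mstdp_pair_matrix(vis$time_ms, hid$time_ms, params)  # hid x vis pairs
    by_vis <- rowsum(t(K), group = vis$neuron)                # vis-neuron x hid-spike
    by_both <- t(rowsum(t(by_vis), group = hid$neuron))       # vis-neuron x hid-neuron
    dW[as.integer(rownames(by_both)), as.integer(colnames(by_both))] <- by_both
  }
  list(dW = params$eta * dW, dQ = params$zeta * t(dW))
}

#' Apply a trial update to a weight state, with clipping
#'
#' @param weights An `mstdp_weights` object (see [weight_state()]).
#' @param update List with `dW`, `dQ` from [mstdp_trial_update()].
#' @param params [plasticity_params()]; supplies the clip bounds.
#' @return The updated `mstdp_weights`.
#' @export
apply_weight_update <- function(weights, update, params) {
  weights$W <- pmin(pmax(weights$W + update$dW, params$w_min), params$w_max)
  weights$Q <- pmin(pmax(weights$Q + update$dQ, params$w_min), params$w_max)
  weights
}

#' Effective-rule prediction from bout counts
#'
#' When trial activity falls into three bouts (initial visible, hidden, late
#' visible) the all-pairs mirrored-STDP sum is approximated by replacing each
#' pairwise time difference with the mean bout separation, giving
#' `dW[i, j] = eta * (beta * x[i] - gamma * xhat[i]) * y[j]` with
#' `beta = exp(-dt1 / tau_plus)` and `gamma = exp(-dt2 / tau_minus)`.
#'
#' @param counts Bout counts from [count_bouts()] (fields `x`, `y`, `xhat`,
#'   `dt1`, `dt2`), or any list with those fields.
#' @param params [plasticity_params()].
#' @return Matrix `n_vis x n_hid` of predicted weight changes.
#' @export
effective_rule_prediction <- function(counts, params = plasticity_params()) {
  x <- counts$x; y <- counts$y; xhat <- counts$xhat
  if (!is.finite(counts$dt1) && any(x > 0) && any(y > 0)) {
    abort("dt1 undefined with nonzero early counts")
  }
  if (!is.finite(counts$dt2) && any(xhat > 0) && any(y > 0)) {
    abort("dt2 undefined with nonzero late counts")
  }
  beta <- if (is.finite(counts$dt1)) exp(-counts$dt1 / params$tau_plus) else 0
  gamma <- if (is.finite(counts$dt2)) exp(-counts$dt2 / params$tau_minus) else 0
  params$eta * outer(beta * x - gamma * xhat, y)
}

#' Scaled autoencoder learning rule (rate-based oracle)
#'
#' The approximate gradient-descent rule the spiking network should follow
#' under weak feedback with scaling `alpha < 1`:
#' `dW[i, j] = (x[i] - xhat[i] / alpha) * y[j]`. A perfect scaled
#' reconstruction `xhat = alpha * x` is a fixed point. This is an analysis
#' oracle; training itself uses [mstdp_trial_update()].
#'
#' @param x,y,xhat Spike-count vectors for initial visible, hidden, and late
#'   visible (reconstruction) activity.
#' @param alpha Feedback scaling factor (> 0).
#' @return Matrix `length(x) x length(y)`.
#' @export
scaled_autoencoder_rule <- function(x, y, xhat, alpha) {
  if (alpha <= 0) abort("`alpha` must be > 0")
  if (length(xhat) != length(x)) abort("`x` and `xhat` lengths differ")
  outer(x - xhat / alpha, y)
}
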