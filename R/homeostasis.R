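#' Synaptic-scaling homeostasis state
#'
#' Each hidden unit tracks a running average `A_j` of the fraction of trials
#' in which it fired at least one spike, and nudges its responsiveness
#' toward a target lifetime activation rate `rho`: additively through a
#' synaptic offset `phi_j` added to every incoming weight (akin to a bias
#' term; suits signed weights), or multiplicatively through a scaling factor
#' `Phi_j` (suits non-negative weights, where scaling up reliably increases
#' net excitation).
#'
#' @param n_hid Number of hidden units.
#' @param mode `"additive"` or `"multiplicative"`.
#' @param rho Target activation rate, in (0, 1).
#' @param kappa Homeostatic learning rate for the per-trial update
#'   `phi_j <- phi_j + kappa * (rho - A_j)` (same for `Phi_j`).
#' @param ema_decay Per-trial weight of the running-average update
#'   (default 0.01, an effective window of roughly 100 trials).
#' @param A0 Initial activity average (defaults to `rho`).
#' @return A list of class `mstdp_homeostasis` with fields `mode`, `rho`,
#'   `kappa`, `ema_decay`, `A`, and `phi` or `Phi`.
#' @export
homeostasis_state <- function(n_hid, mode = c("additive", "multiplicative"),
                              rho = 0.05, kappa = NULL, ema_decay = 0.01,
                              A0 = rho) {
  mode <- arg_match(mode)
  if (rho <= 0 || rho >= 1) abort("`rho` must lie in (0, 1)")
  if (ema_decay <= 0 || ema_decay >= 1) abort("`ema_decay` must lie in (0, 1)")
  kappa <- kappa %||% if (mode == "additive") 0.01 else 0.5
  st <- list(mode = mode, rho = rho, kappa = kappa, ema_decay = ema_decay,
             A = rep(A0, n_hid))
  if (mode == "additive") st$phi <- rep(0, n_hid) else st$Phi <- rep(1, n_hid)
  structure(st, class = "mstdp_homeostasis")
}

#' Update the running activation averages
#'
#' @param state An `mstdp_homeostasis` object.
#' @param fired Logical (or 0/1) vector: did each hidden unit fire at least
#'   one spike this trial?
#' @return The updated state.
#' @export
update_activity <- function(state, fired) {
  stopifnot(length(fired) == length(state$A))
  d <- state$ema_decay
  state$A <- (1 - d) * state$A + d * as.numeric(fired)
  state
}

#' Apply the per-trial homeostatic scaling update
#'
#' Moves each unit's offset (or factor) by `kappa * (rho - A_j)`: units
#' firing above target become less excitable, silent units more so.
#' Multiplicative factors are floored at zero.
#'
#' @param state An `mstdp_homeostasis` object (call after
#'   [update_activity()]).
#' @return The updated state.
#' @export
update_scaling <- function(state) {
  delta <- state$kappa * (state$rho - state$A)
  if (state$mode == "additive") {
    state$phi <- state$phi + delta
  } else {
    state$Phi <- pmax(state$Phi + delta, 0)
  }
  state
}

#' Homeostasis-adjusted effective feedforward weights
#'
#' Scaling acts only on the feedforward excitation of hidden units; raw
#' weights (used by plasticity) are untouched, and feedback onto visible
#' units is not scaled.
#'
#' @param W Raw feedforward matrix (`n_vis x n_hid`).
#' @param state An `mstdp_homeostasis` object.
#' @param boost Optional extra multiplier on `Phi` (evaluation only), e.g.
#'   1.5 to probe reconstruction with raised excitability.
#' @return The effective weight matrix, same shape as `W`.
#' @export
effective_weights <- function(W, state, boost = 1) {
  if (state$mode == "additive") {
    sweep(W, 2, state$phi, `+`)
  } else {
    if (min(W) < 0) abort("multiplicative scaling requires non-negative weights")
    sweep(W, 2, pmax(state$Phi * boost, 0), `*`)
  }
}
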