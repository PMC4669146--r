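#' Deterministic bars stimulus set
#'
#' Enumerates all `2 * grid` single-bar images (each a horizontal or
#' vertical unit-intensity bar on a zero background), optionally followed by
#' seeded two-bar superpositions. Bars are the canonical desk-scale toy set
#' here: each stimulus is reconstructable from a sparse hidden code, which
#' exercises the same learning dynamics as full image datasets.
#'
#' @param grid Side length (>= 4).
#' @param seed Seed for the optional two-bar draws.
#' @param n_two_bar Number of extra two-bar superpositions (default 0).
#' @return Tibble with `stimulus_id`, `kind`, `label`, `pixels`
#'   (list-column), and `bars` (list of contributing bar indices).
#' @export
make_bars_dataset <- function(grid = 8, seed = 1L, n_two_bar = 0L) {
  if (grid < 4) abort("`grid` must be >= 4")
  single <- tibble(
    stimulus_id = seq_len(2L * grid), kind = "bars",
    label = c(paste0("h", seq_len(grid)), paste0("v", seq_len(grid))),
    pixels = lapply(seq_len(2L * grid), function(i) bar_image(grid, i)),
    bars = as.list(seq_len(2L * grid)))
  if (n_two_bar > 0L) {
    extra <- withr::with_seed(seed, {
      pairs <- replicate(n_two_bar, sort(sample.int(2L * grid, 2L)),
                         simplify = FALSE)
      tibble(
        stimulus_id = 2L * grid + seq_len(n_two_bar), kind = "bars",
        label = purrr::map_chr(pairs, ~ paste0("pair_", paste(.x, collapse = "_"))),
        pixels = purrr::map(pairs, ~ pmin(bar_image(grid, .x[1]) +
                                            bar_image(grid, .x[2]), 1)),
        bars = pairs)
    })
    single <- dplyr::bind_rows(single, extra)
  }
  single
}

#' Frozen Poisson spike records for plasticity oracle tests
#'
#' Generates reproducible per-neuron homogeneous Poisson spike trains with a
#' content checksum, for regression-style testing of pair-based plasticity.
#'
#' @param n_neurons Number of neurons.
#' @param rate Firing rate (spikes/s).
#' @param duration Record length (ms).
#' @param seed Integer seed.
#' @return List of class `mstdp_spike_records`: `times` (list of sorted
#'   spike-time vectors), `rate`, `duration`, `seed`, `checksum`.
#' @export
make_frozen_spike_records <- function(n_neurons, rate, duration, seed = 1L) {
  times <- withr::with_seed(seed, {
    lapply(seq_len(n_neurons), function(i) {
      n <- rpois(1, rate / 1000 * duration)
      sort(runif(n, 0, duration))
    })
  })
  all_t <- unlist(times)
  checksum <- sum(round(all_t * 1e6)) %% 2147483647
  structure(list(times = times, rate = rate, duration = duration,
                 seed = seed, checksum = checksum),
            class = "mstdp_spike_records")
}

#' Small reproducible network state for unit tests
#'
#' @param n_vis,n_hid Sizes (visible kept small, <= 128).
#' @param mode `"signed"` or `"nonneg"`.
#' @param seed Integer seed.
#' @param w_max Upper end of the uniform init interval.
#' @param rho Homeostasis target for the bundled state.
#' @return List with `weights` ([weight_state()]) and `homeostasis`
#'   ([homeostasis_state()]).
#' @export
make_toy_network <- function(n_vis = 32, n_hid = 8,
                             mode = c("nonneg", "signed"), seed = 1L,
                             w_max = 0.02, rho = 0.1) {
  mode <- arg_match(mode)
  if (n_vis > 128) abort("toy networks are capped at 128 visible neurons")
  weights <- withr::with_seed(seed, {
    W <- matrix(runif(n_vis * n_hid, 0, w_max), n_vis, n_hid)
    Q <- matrix(runif(n_vis * n_hid, 0, w_max), n_hid, n_vis)
    weight_state(W, Q, mode)
  })
  hmode <- if (mode == "signed") "additive" else "multiplicative"
  list(weights = weights,
       homeostasis = homeostasis_state(n_hid, hmode, rho = rho))
}
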