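# Shared builders and an independent brute-force STDP oracle.

# Literal double-loop over all spike pairs; deliberately structured unlike
# the vectorized implementation so the two can cross-check each other.
brute_stdp <- function(pre, post, tau_plus, tau_minus, anti = FALSE) {
  total <- 0
  for (tk in pre) {
    for (tl in post) {
      pot <- if (anti) tl <= tk else tl > tk
      total <- total + if (pot) {
        exp(-abs(tl - tk) / tau_plus)
      } else {
        -exp(-abs(tl - tk) / tau_minus)
      }
    }
  }
  total
}

# brute-force trial update over a spike tibble
brute_trial_update <- function(spikes, n_vis, n_hid, params) {
  dW <- matrix(0, n_vis, n_hid)
  vis <- spikes[spikes$population == "visible", ]
  hid <- spikes[spikes$population == "hidden", ]
  for (i in seq_len(n_vis)) {
    for (j in seq_len(n_hid)) {
      dW[i, j] <- brute_stdp(vis$time_ms[vis$neuron == i],
                             hid$time_ms[hid$neuron == j],
                             params$tau_plus, params$tau_minus)
    }
  }
  list(dW = params$eta * dW, dQ = params$zeta * t(dW))
}

# random Poisson spike record over visible + hidden populations
random_record <- function(n_vis, n_hid, duration, rate, seed) {
  withr::with_seed(seed, {
    rows <- purrr::map_dfr(
      list(list(pop = "visible", n = n_vis), list(pop = "hidden", n = n_hid)),
      function(p) {
        counts <- rpois(p$n, rate / 1000 * duration)
        tibble::tibble(population = p$pop,
                       neuron = rep(seq_len(p$n), counts),
                       time_ms = sort(runif(sum(counts), 0, duration)))
      })
    rows$population <- factor(rows$population,
                              levels = c("visible", "hidden",
                                         "inh_visible", "inh_hidden"))
    attr(rows, "n_vis") <- n_vis
    attr(rows, "n_hid") <- n_hid
    rows
  })
}

# three-bout delta record: every visible neuron spikes x[i] times at t1,
# hidden y[j] times at t2, visible again xhat[i] times at t3
delta_record <- function(x, y, xhat, t1, t2, t3, jitter = 0, seed = NULL) {
  mk <- function(counts, t0) {
    tibble::tibble(neuron = rep(seq_along(counts), counts),
                   time_ms = rep(t0, sum(counts)))
  }
  vis <- rbind(mk(x, t1), mk(xhat, t3))
  hid <- mk(y, t2)
  if (jitter > 0) {
    withr::with_seed(seed %||% 1L, {
      vis$time_ms <- pmax(vis$time_ms + rnorm(nrow(vis), 0, jitter), 0)
      hid$time_ms <- pmax(hid$time_ms + rnorm(nrow(hid), 0, jitter), 0)
    })
  }
  tag <- function(df, pop) {
    tibble::tibble(population = rep(pop, nrow(df)),
                   neuron = df$neuron, time_ms = df$time_ms)
  }
  out <- rbind(tag(vis, "visible"), tag(hid, "hidden"))
  out$population <- factor(out$population,
                           levels = c("visible", "hidden",
                                      "inh_visible", "inh_hidden"))
  attr(out, "n_vis") <- length(x)
  attr(out, "n_hid") <- length(y)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# One shared end-to-end bars run, trained lazily and reused across
# acceptance checks (training, symmetrization, boost).
.bars_cache <- new.env(parent = emptyenv())

bars_reference_run <- function() {
  if (is.null(.bars_cache$net)) {
    prep <- prepare_stimuli(make_bars_dataset(8))
    cfg <- bars_study_config(n_presentations = 5000, master_seed = 1,
                             eval_every = 100)
    .bars_cache$prep <- prep
    .bars_cache$cfg <- cfg
    .bars_cache$net <- train_network(prep, cfg)
  }
  list(net = .bars_cache$net, cfg = .bars_cache$cfg, prep = .bars_cache$prep)
}
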