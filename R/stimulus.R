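#' Mean-subtract and flatten a raw stimulus
#'
#' Subtracts a dataset mean from raw pixel intensities and flattens the
#' result row-major, producing the signed drive that is subsequently split
#' into ON/OFF channels. Mean subtraction leaves values that can be either
#' positive or negative, representing pixels above or below their average.
#'
#' @param pixels Numeric matrix (height x width) or vector of raw pixel
#'   intensities.
#' @param dataset_mean Numeric vector of per-pixel means (row-major, same
#'   length as `pixels`), or a single number applied to every pixel.
#' @return Numeric vector of signed, mean-subtracted values (row-major).
#' @examples
#' preprocess_stimulus(matrix(c(1, 0, 0, 1), 2, 2), dataset_mean = 0.5)
#' @export
preprocess_stimulus <- function(pixels, dataset_mean) {
  v <- if (is.matrix(pixels)) as.vector(t(pixels)) else as.numeric(pixels)
  if (!all(is.finite(v))) abort("`pixels` must be finite")
  if (length(dataset_mean) == 1L) dataset_mean <- rep(dataset_mean, length(v))
  if (length(dataset_mean) != length(v)) {
    abort(sprintf("`dataset_mean` has length %d but the stimulus has %d pixels",
                  length(dataset_mean), length(v)))
  }
  v - as.numeric(dataset_mean)
}

#' Split a signed stimulus into non-negative ON/OFF rate channels
#'
#' Biological firing rates cannot be negative; the ON/OFF-cell strategy uses
#' twice as many visible neurons as pixels, with the first half carrying
#' `max(0, v)` and the second half `max(0, -v)`. The split is lossless:
#' ON minus OFF recovers the signed vector exactly.
#'
#' @param signed Numeric vector of signed pixel values.
#' @return An object of class `mstdp_stimulus`: a list with `rates`
#'   (length `2 * length(signed)`), and integer index vectors `on`, `off`.
#' @examples
#' split_on_off(c(-1, 2, 0))
#' @export
split_on_off <- function(signed) {
  signed <- as.numeric(signed)
  if (!all(is.finite(signed))) abort("`signed` must be finite")
  p <- length(signed)
  structure(
    list(rates = c(pmax(signed, 0), pmax(-signed, 0)),
         on = seq_len(p), off = p + seq_len(p)),
    class = "mstdp_stimulus")
}

#' @export
print.mstdp_stimulus <- function(x, ...) {
  cat(sprintf("<mstdp_stimulus> %d pixels (%d ON/OFF rates), L1 = %.3g\n",
              length(x$on), length(x$rates), sum(x$rates)))
  invisible(x)
}

#' Recover the signed stimulus from its ON/OFF representation
#'
#' @param stim An `mstdp_stimulus`.
#' @return Numeric vector, `rates[on] - rates[off]`.
#' @export
on_off_to_signed <- function(stim) {
  stopifnot(inherits(stim, "mstdp_stimulus"))
  stim$rates[stim$on] - stim$rates[stim$off]
}

#' High-contrast filter for preprocessed patches
#'
#' Training on low-contrast patches produces no hidden activity and hence no
#' learning, so patches are kept only when the mean of the ON/OFF rate vector
#' (equivalently, the mean absolute signed value) reaches a threshold.
#'
#' @param signed_patch Numeric vector of mean-subtracted pixel values.
#' @param threshold Non-negative contrast threshold; default 0.06.
#' @return `TRUE` if the patch passes (mean absolute value at or above the
#'   threshold), else `FALSE`.
#' @export
contrast_filter <- function(signed_patch, threshold = 0.06) {
  if (length(signed_patch) == 0L) abort("empty patch")
  if (threshold < 0) abort("`threshold` must be >= 0")
  mean(abs(signed_patch)) >= threshold
}

#' Encoding parameters for Poisson input spike generation
#'
#' @param rate_scale Spikes/second fired by a visible neuron per unit of
#'   ON/OFF rate value. The default gives a unit-intensity pixel roughly 10
#'   spikes during the default 10 ms input window.
#' @param stimulus_duration Duration (ms) of the external input window at
#'   the start of each trial.
#' @return A list of class `mstdp_encoding`.
#' @export
encoding_params <- function(rate_scale = 1000, stimulus_duration = 10) {
  if (rate_scale <= 0) abort("`rate_scale` must be > 0")
  if (stimulus_duration <= 0) abort("`stimulus_duration` must be > 0")
  structure(list(rate_scale = rate_scale,
                 stimulus_duration = stimulus_duration),
            class = "mstdp_encoding")
}

#' Encode a stimulus as Poisson input spike trains
#'
#' Each visible neuron fires a homogeneous Poisson train over the input
#' window with rate equal to its ON/OFF value times `rate_scale`. The same
#' seed and stimulus always produce identical spikes.
#'
#' @param stim An `mstdp_stimulus` (or non-negative numeric rate vector).
#' @param params An [encoding_params()] object.
#' @param seed Integer seed for the spike draw.
#' @return Spike tibble with columns `neuron` (1-based visible index) and
#'   `time_ms`, sorted by time, with attribute `n_neurons`.
#' @export
poisson_encode <- function(stim, params = encoding_params(), seed = 1L) {
  rates <- if (inherits(stim, "mstdp_stimulus")) stim$rates else as.numeric(stim)
  if (any(rates < 0)) abort("stimulus rates must be non-negative")
  t_ms <- params$stimulus_duration
  lam <- rates * params$rate_scale / 1000 * t_ms  # expected counts
  spk <- withr::with_seed(seed, {
    counts <- rpois(length(lam), lam)
    neuron <- rep(seq_along(lam), counts)
    time_ms <- runif(sum(counts), 0, t_ms)
    tibble(neuron = neuron, time_ms = time_ms)
  })
  spk <- dplyr::arrange(spk, .data$time_ms, .data$neuron)
  attr(spk, "n_neurons") <- length(rates)
  attr(spk, "duration") <- t_ms
  spk
}

#' Generate synthetic stimulus images with known latent structure
#'
#' Provides download-free inputs in three flavours: `bars` (one horizontal or
#' vertical unit-intensity bar on a zero background — the canonical sparse
#' toy set), `blobs` (an isotropic Gaussian bump at a random centre), and
#' `strokes` (a short random line segment). Deterministic under `seed`.
#'
#' @param kind One of `"bars"`, `"blobs"`, `"strokes"`.
#' @param grid_size Image side length (>= 4).
#' @param count Number of stimuli to draw (with replacement for bars).
#' @param seed Integer seed.
#' @return Tibble with one row per stimulus: `stimulus_id`, `kind`, `label`,
#'   and list-column `pixels` (grid_size x grid_size matrices).
#' @export
generate_synthetic_stimuli <- function(kind = c("bars", "blobs", "strokes"),
                                       grid_size = 8, count = 16, seed = 1L) {
  kind <- arg_match(kind)
  if (grid_size < 4) abort("`grid_size` must be >= 4")
  if (count == 0L) {
    return(tibble(stimulus_id = integer(), kind = character(),
                  label = character(), pixels = list()))
  }
  g <- grid_size
  draw <- withr::with_seed(seed, switch(kind,
    bars = {
      idx <- sample.int(2L * g, count, replace = TRUE)
      list(label = ifelse(idx <= g, paste0("h", idx), paste0("v", idx - g)),
           pixels = lapply(idx, function(i) bar_image(g, i)))
    },
    blobs = {
      cx <- runif(count, 1, g); cy <- runif(count, 1, g)
      sd <- g / 6
      list(label = sprintf("blob_%.1f_%.1f", cx, cy),
           pixels = purrr::map2(cx, cy, function(x0, y0) {
             outer(seq_len(g), seq_len(g), function(r, c)
               exp(-((r - y0)^2 + (c - x0)^2) / (2 * sd^2)))
           }))
    },
    strokes = {
      x0 <- runif(count, 1, g); y0 <- runif(count, 1, g)
      ang <- runif(count, 0, pi); len <- runif(count, g / 3, g)
      list(label = sprintf("stroke_%.0f", seq_len(count)),
           pixels = purrr::pmap(list(x0, y0, ang, len), function(x0, y0, a, l) {
             m <- matrix(0, g, g)
             t_seq <- seq(-l / 2, l / 2, by = 0.25)
             xs <- pmin(pmax(round(x0 + t_seq * cos(a)), 1), g)
             ys <- pmin(pmax(round(y0 + t_seq * sin(a)), 1), g)
             m[cbind(ys, xs)] <- 1
             m
           }))
    }))
  tibble(stimulus_id = seq_len(count), kind = kind,
         label = draw$label, pixels = draw$pixels)
}

# Single-bar image: index 1..g are horizontal bars (rows), g+1..2g vertical.
bar_image <- function(g, index) {
  m <- matrix(0, g, g)
  if (index <= g) m[index, ] <- 1 else m[, index - g] <- 1
  m
}
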