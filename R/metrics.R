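# Pearson correlation that returns NA instead of erroring/warning on
# zero-variance input; callers decide the sentinel policy.
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  cor(a, b)
}

#' Reconstruction loss: one minus the mean input/feedback correlation
#'
#' For each test stimulus the network's feedback excitation `t(Q) %*% z`
#' (with `z` the hidden spike counts) is compared with the input rate vector
#' `nu` by Pearson correlation; the loss is `1 - mean(corr)`, so 0 is a
#' perfect (up to positive scale) reconstruction and 2 a perfectly inverted
#' one. Stimulus pairs where either vector is constant have undefined
#' correlation and contribute 0 (neutral) to the average; their number is
#' returned as an attribute `n_degenerate`.
#'
#' @param inputs List of input rate vectors `nu` (one per test stimulus).
#' @param feedback List of feedback excitation vectors `t(Q) %*% z`.
#' @return Scalar loss in `[0, 2]`.
#' @export
reconstruction_loss <- function(inputs, feedback) {
  if (length(inputs) != length(feedback)) abort("list lengths differ")
  cors <- purrr::map2_dbl(inputs, feedback, function(nu, fb) {
    if (length(nu) != length(fb)) abort("dimension mismatch in a stimulus pair")
    safe_cor(as.numeric(nu), as.numeric(fb))
  })
  n_deg <- sum(is.na(cors))
  cors[is.na(cors)] <- 0
  structure(1 - mean(cors), n_degenerate = n_deg)
}

#' Sparsity loss: squared deviation of activations from target
#'
#' `sum((A - rho)^2) / rho^2` over hidden units, where `A_j` is the fraction
#' of test stimuli for which unit `j` fired at least one spike.
#'
#' @param A Numeric vector of activation fractions in `[0, 1]`.
#' @param rho Target activation rate (> 0).
#' @return Non-negative scalar.
#' @export
sparsity_loss <- function(A, rho) {
  if (rho <= 0) abort("`rho` must be > 0")
  if (any(A < 0 | A > 1)) abort("`A` entries must lie in [0, 1]")
  sum((A - rho)^2) / rho^2
}

#' Pearson correlation between feedback and transposed feedforward weights
#'
#' Measures how symmetric ("tied") the two weight matrices are:
#' `cor(vec(W), vec(t(Q)))`, 1 when `Q` is a positive multiple of `t(W)`.
#'
#' @param W Feedforward matrix (`n_vis x n_hid`).
#' @param Q Feedback matrix (`n_hid x n_vis`), or an `mstdp_weights` object
#'   in place of both arguments.
#' @return Scalar in `[-1, 1]`, or `NA` if either matrix is constant.
#' @export
symmetry_correlation <- function(W, Q = NULL) {
  if (inherits(W, "mstdp_weights")) { Q <- W$Q; W <- W$W }
  if (!all(dim(Q) == rev(dim(W)))) abort("incompatible shapes")
  safe_cor(as.vector(W), as.vector(t(Q)))
}

#' Pairwise correlations between hidden units
#'
#' Either between the incoming-weight vectors of each pair of hidden units
#' (`source = "weights"`, pass `W`) or between their spike-count vectors
#' across stimulus presentations (`source = "spike_counts"`, pass an
#' `n_stimuli x n_hid` count matrix). Pairs involving a constant vector are
#' skipped; the skipped count is reported.
#'
#' @param data Matrix with hidden units in columns.
#' @param source `"weights"` or `"spike_counts"` (label only; both paths
#'   correlate columns).
#' @return Tibble with `unit_a`, `unit_b`, `correlation`, carrying an
#'   attribute `n_skipped`.
#' @export
hidden_correlations <- function(data, source = c("weights", "spike_counts")) {
  source <- arg_match(source)
  n <- ncol(data)
  if (n < 2L) abort("need at least 2 hidden units")
  pairs <- utils::combn(n, 2)
  vals <- apply(pairs, 2, function(p) safe_cor(data[, p[1]], data[, p[2]]))
  out <- tibble(unit_a = pairs[1, ], unit_b = pairs[2, ],
                correlation = vals, source = source)
  n_skipped <- sum(is.na(vals))
  out <- out[!is.na(out$correlation), ]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Render hidden-unit receptive fields as ON-minus-OFF images
#'
#' For each hidden unit, weights from OFF visible neurons are subtracted
#' from weights from ON visible neurons and the result reshaped to the
#' stimulus grid; optionally each unit is normalized by its largest absolute
#' value (all-zero units are left as zeros).
#'
#' @param W Feedforward matrix (`2 * n_pixels x n_hid`).
#' @param on_half,off_half Integer index vectors of the ON and OFF rows of
#'   `W`; default the first and second halves.
#' @param grid Image side length; default `sqrt(n_pixels)`.
#' @param per_unit_normalize Normalize each unit by max |value|.
#' @return Tibble with columns `unit`, `row`, `col`, `value` (one row per
#'   unit-pixel), ready for [autoplot.mstdp_rf()]; class `mstdp_rf`.
#' @export
receptive_fields <- function(W, on_half = NULL, off_half = NULL, grid = NULL,
                             per_unit_normalize = TRUE) {
  n_visible <- nrow(W)
  if (n_visible %% 2L != 0L) abort("odd visible count; expected ON/OFF doubling")
  p <- n_visible / 2L
  on_half <- on_half %||% seq_len(p)
  off_half <- off_half %||% (p + seq_len(p))
  grid <- grid %||% as.integer(round(sqrt(p)))
  if (grid * grid != p) abort("`grid`^2 must equal the pixel count")
  fields <- W[on_half, , drop = FALSE] - W[off_half, , drop = FALSE]
  if (per_unit_normalize) {
    mx <- apply(abs(fields), 2, max)
    mx[mx == 0] <- 1  # all-zero units stay zero
    fields <- sweep(fields, 2, mx, `/`)
  }
  out <- purrr::map_dfr(seq_len(ncol(fields)), function(j) {
    img <- matrix(fields[, j], grid, grid, byrow = TRUE)  # row-major pixels
    tibble(unit = j, row = rep(seq_len(grid), each = grid),
           col = rep(seq_len(grid), grid), value = as.vector(t(img)))
  })
  class(out) <- c("mstdp_rf", class(out))
  attr(out, "grid") <- grid
  out
}

#' Fraction of bar stimuli recovered as dominant receptive-field structure
#'
#' Matches each hidden unit's ON-minus-OFF receptive field against every
#' single-bar template by Pearson correlation. A bar counts as recovered
#' when it is some unit's best-matching template with correlation above
#' `min_corr`.
#'
#' @param W Feedforward matrix (`2 * grid^2 x n_hid`).
#' @param grid Bar image side length.
#' @param min_corr Minimum template correlation for a match (default 0.4).
#' @return Scalar fraction in `[0, 1]` of the `2 * grid` bars recovered;
#'   attribute `matches` gives each unit's best bar and correlation.
#' @export
bar_recovery <- function(W, grid, min_corr = 0.4) {
  templates <- sapply(seq_len(2L * grid), function(i) as.vector(t(bar_image(grid, i))))
  p <- grid * grid
  fields <- W[seq_len(p), , drop = FALSE] - W[p + seq_len(p), , drop = FALSE]
  best <- purrr::map_dfr(seq_len(ncol(fields)), function(j) {
    cors <- apply(templates, 2, function(tp) safe_cor(fields[, j], tp))
    cors[is.na(cors)] <- -Inf
    tibble(unit = j, bar = which.max(cors), correlation = max(cors))
  })
  recovered <- unique(best$bar[best$correlation >= min_corr])
  structure(length(recovered) / (2 * grid), matches = best)
}
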