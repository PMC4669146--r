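# Plain-text persistence. Doubles are written with 17 significant digits,
# which round-trips IEEE doubles exactly, so a saved/loaded run continues
# bit-identically.

write_matrix_txt <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(m), ncol(m)), con)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.17g", r), collapse = " ")),
             con)
}

read_matrix_txt <- function(path) {
  lines <- readLines(path)
  dims <- as.integer(strsplit(lines[1], " ")[[1]])
  vals <- as.numeric(unlist(strsplit(lines[-1], " ")))
  matrix(vals, dims[1], dims[2], byrow = TRUE)
}

#' Save a trained network (or mid-run state) as plain text
#'
#' Writes `W.txt`, `Q.txt`, `homeostasis.txt`, `history.csv` and
#' `meta.json` into `dir`. Values are stored at full double precision so a
#' resumed run is bit-identical to an uninterrupted one.
#'
#' @param net An `mstdp_net` from [train_network()], or a compatible list
#'   with `weights`, `homeostasis`, `presentation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_checkpoint <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_txt(net$weights$W, file.path(dir, "W.txt"))
  write_matrix_txt(net$weights$Q, file.path(dir, "Q.txt"))
  h <- net$homeostasis
  scale_vec <- if (h$mode == "additive") h$phi else h$Phi
  hm <- rbind(h$A, scale_vec)
  write_matrix_txt(hm, file.path(dir, "homeostasis.txt"))
  meta <- list(weight_mode = net$weights$mode, homeo_mode = h$mode,
               rho = h$rho, kappa = h$kappa, ema_decay = h$ema_decay,
               presentation = net$presentation %||% 0L,
               ceiling_total = net$ceiling_total %||% Inf,
               warmup_totals = net$warmup_totals %||% numeric(0))
  writeLines(to_json_scalar(meta), file.path(dir, "meta.json"))
  if (!is.null(net$history) && nrow(net$history %||% tibble())) {
    utils::write.csv(net$history, file.path(dir, "history.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}

# minimal JSON writer for the flat metadata list (full-precision numbers)
to_json_scalar <- function(x) {
  fmt <- function(v) {
    if (is.character(v)) sprintf('"%s"', v)
    else if (length(v) > 1) sprintf("[%s]", paste(sprintf("%.17g", v), collapse = ","))
    else if (is.infinite(v)) sprintf('"%s"', as.character(v))
    else sprintf("%.17g", as.numeric(v))
  }
  paste0("{", paste(sprintf('"%s": %s', names(x),
                            vapply(x, fmt, character(1))), collapse = ", "), "}")
}

parse_json_flat <- function(path) {
  txt <- paste(readLines(path), collapse = " ")
  txt <- sub("^\\s*\\{", "", sub("\\}\\s*$", "", txt))
  parts <- strsplit(txt, ",(?=\\s*\")", perl = TRUE)[[1]]
  out <- list()
  for (p in parts) {
    kv <- strsplit(p, ":", fixed = TRUE)[[1]]
    key <- gsub('[" ]', "", kv[1])
    val <- trimws(paste(kv[-1], collapse = ":"))
    out[[key]] <- if (grepl('^"', val)) gsub('"', "", val)
    else if (grepl("^\\[", val)) as.numeric(strsplit(gsub("[][]", "", val), ",")[[1]])
    else as.numeric(val)
  }
  out
}

#' Load a checkpoint saved by [save_checkpoint()]
#'
#' @param dir Checkpoint directory.
#' @return List with `weights`, `homeostasis`, `presentation`, `history`
#'   (if present), suitable as the `state` argument of [train_network()].
#' @export
load_checkpoint <- function(dir) {
  meta <- parse_json_flat(file.path(dir, "meta.json"))
  W <- read_matrix_txt(file.path(dir, "W.txt"))
  Q <- read_matrix_txt(file.path(dir, "Q.txt"))
  hm <- read_matrix_txt(file.path(dir, "homeostasis.txt"))
  h <- homeostasis_state(ncol(hm), meta$homeo_mode, rho = meta$rho,
                         kappa = meta$kappa, ema_decay = meta$ema_decay)
  h$A <- hm[1, ]
  if (h$mode == "additive") h$phi <- hm[2, ] else h$Phi <- hm[2, ]
  hist_path <- file.path(dir, "history.csv")
  history <- if (file.exists(hist_path)) {
    as_tibble(utils::read.csv(hist_path))
  } else NULL
  ceiling_total <- meta$ceiling_total
  if (is.character(ceiling_total)) ceiling_total <- Inf
  list(weights = weight_state(W, Q, meta$weight_mode), homeostasis = h,
       presentation = as.integer(meta$presentation), history = history,
       warmup_totals = meta$warmup_totals %||% numeric(0),
       ceiling_total = ceiling_total)
}

#' Export a spike record as CSV events
#'
#' @param spikes Spike tibble from [simulate_trial()].
#' @param path Output CSV path (columns `population`, `neuron_id`,
#'   `time_ms`).
#' @return `path`, invisibly.
#' @export
write_spikes_csv <- function(spikes, path) {
  out <- data.frame(population = as.character(spikes$population),
                    neuron_id = spikes$neuron, time_ms = spikes$time_ms)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Save a prepared stimulus set as CSV
#'
#' One row per stimulus, rates in wide columns; a JSON sidecar records
#' provenance (grid, count, mean).
#'
#' @param dataset Prepared tibble from [prepare_stimuli()].
#' @param path Output CSV path; the sidecar is `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_stimuli_csv <- function(dataset, path) {
  rates <- do.call(rbind, purrr::map(dataset$stimulus, "rates"))
  df <- cbind(data.frame(stimulus_id = dataset$stimulus_id,
                         label = dataset$label),
              as.data.frame(rates))
  utils::write.csv(df, path, row.names = FALSE)
  meta <- list(count = nrow(df), n_rates = ncol(rates),
               dataset_mean = attr(dataset, "dataset_mean") %||% numeric(0))
  writeLines(to_json_scalar(meta), paste0(path, ".json"))
  invisible(path)
}
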