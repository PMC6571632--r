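#' Default run configuration
#'
#' The complete configuration of a simulation run, with every field at
#' its default: global constants, the initial cell-parameter table,
#' synaptic kinetics, plasticity parameters, input-population settings,
#' the lesion protocol and analysis settings. A configuration
#' round-trips losslessly through YAML.
#'
#' @return A nested named list of class `hs_config`.
#' @export
default_config <- function() {
  structure(list(
    constants = list(dt = 0.5, ReP = -80, refractory_ms = 1.5),
    cells = default_cell_table(),
    kinetics = default_kinetics(),
    plasticity = list(CaMT = -68, clog = 2.3026, decay_every = 2000L),
    inputs = list(ec_rate_peak = 13, dg_rate_peak = 9.5, ms_rate_peak = 40,
                  theta_freq = 8, ec2_phase = 0, ec3_phase = pi,
                  dg_phase = 0, ms_phase = pi),
    lesion = list(t_start = 500, t_end = 8200, order = "random",
                  n_deletions = NULL),
    engine = list(delay_boxes = 1L, record_every = 10L),
    analysis = list(final_window = 1000, bin_ms = 500, n_bins = 16L)
  ), class = "hs_config")
}

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    here <- c(path, key)
    if (!key %in% names(base))
      stop("unknown configuration key: ", paste(here, collapse = "$"),
           call. = FALSE)
    if (is.list(base[[key]]) && !is.data.frame(base[[key]])) {
      if (!is.list(override[[key]]))
        stop("configuration key ", paste(here, collapse = "$"),
             " must be a mapping", call. = FALSE)
      base[[key]] <- merge_config(base[[key]], override[[key]], here)
    } else if (is.data.frame(base[[key]])) {
      base[[key]] <- merge_cell_table(base[[key]], override[[key]], here)
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

merge_cell_table <- function(cells, override, path) {
  if (is.data.frame(override)) return(override)
  # per-cell overrides: list keyed by cell id, each a named list of fields
  for (id in names(override)) {
    row <- which(cells$id == id)
    if (!length(row))
      stop("unknown cell id in ", paste(path, collapse = "$"), ": ", id,
           call. = FALSE)
    for (field in names(override[[id]])) {
      if (!field %in% names(cells))
        stop("unknown cell field: ", field, call. = FALSE)
      cells[row, field] <- override[[id]][[field]]
    }
  }
  cells
}

#' Validate a run configuration
#'
#' Checks types and scientific constraints (positive time step,
#' refractory period a multiple of the time step, forgetting coefficient
#' not below 1, unblock threshold above rest, weights in range) and
#' returns the configuration invisibly.
#'
#' @param config An `hs_config`.
#' @export
validate_config <- function(config) {
  cons <- config$constants
  if (cons$dt <= 0) stop("constants$dt must be > 0", call. = FALSE)
  nref <- cons$refractory_ms / cons$dt
  if (abs(nref - round(nref)) > 1e-9)
    stop("constants$refractory_ms must be an integer multiple of dt",
         call. = FALSE)
  validate_cells(config$cells)
  if (any(config$cells$FQ < 1))
    stop("FQ must be >= 1 for every cell", call. = FALSE)
  if (config$plasticity$CaMT <= cons$ReP)
    stop("plasticity$CaMT must exceed the resting potential", call. = FALSE)
  with(config$kinetics, {
    if (any(c(ampa_rise, ampa_decay, nmda_rise, nmda_decay,
              gaba_rise, gaba_decay) <= 0))
      stop("synaptic time constants must be positive", call. = FALSE)
    if (nmda_frac < 0) stop("kinetics$nmda_frac must be >= 0", call. = FALSE)
  })
  inp <- config$inputs
  if (inp$theta_freq <= 0) stop("inputs$theta_freq must be > 0", call. = FALSE)
  if (any(c(inp$ec_rate_peak, inp$dg_rate_peak, inp$ms_rate_peak) < 0))
    stop("input peak rates must be >= 0", call. = FALSE)
  if (!config$lesion$order %in% c("random", "listed"))
    stop("lesion$order must be 'random' or 'listed'", call. = FALSE)
  invisible(config)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file, fills every omitted field with its default,
#' rejects unknown keys, and validates constraints. An empty file yields
#' the full default configuration. Cell-parameter overrides are given as
#' a mapping keyed by cell id, e.g. `cells: {P1: {LSW: 0.5}}`.
#'
#' @param path Path to a YAML file.
#' @return A validated `hs_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  cfg <- default_config()
  if (length(raw)) cfg <- merge_config(cfg, raw)
  class(cfg) <- "hs_config"
  validate_config(cfg)
  cfg
}

#' @rdname load_config
#' @param config An `hs_config` to write.
#' @export
save_config <- function(config, path) {
  out <- unclass(config)
  out$cells <- lapply(seq_len(nrow(config$cells)), function(i)
    as.list(config$cells[i, ]))
  names(out$cells) <- config$cells$id
  out$cells <- lapply(out$cells, function(x) x[names(x) != "id"])
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Build the network described by a configuration
#'
#' @param config An `hs_config`.
#' @return An `hs_network`.
#' @export
network_from_config <- function(config) {
  validate_config(config)
  inp <- config$inputs
  build_default_network(
    cells = config$cells,
    constants = global_constants(config$constants$dt, config$constants$ReP,
                                 config$constants$refractory_ms),
    plasticity = plasticity_params(
      CaMT = config$plasticity$CaMT, ReP = config$constants$ReP,
      clog = config$plasticity$clog,
      decay_every = config$plasticity$decay_every),
    kinetics = config$kinetics,
    inputs = default_input_params(
      ec_rate_peak = inp$ec_rate_peak, dg_rate_peak = inp$dg_rate_peak,
      ms_rate_peak = inp$ms_rate_peak, theta_freq = inp$theta_freq,
      ec2_phase = inp$ec2_phase, ec3_phase = inp$ec3_phase,
      dg_phase = inp$dg_phase, ms_phase = inp$ms_phase),
    delay = config$engine$delay_boxes
  )
}

# short content fingerprint (polynomial rolling hash over the
# serialized object) used to stamp output files so result sets can be
# matched to their configuration
config_hash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, version = 2))
  hash <- 0
  for (b in bytes) hash <- (hash * 31 + b) %% 2147483647
  sprintf("%08x", hash)
}

#' Write a simulation result to a directory
#'
#' Emits `spikes.csv` (cell_id, t_ms), `memory.csv`, `lesions.csv`,
#' and `summary.json` (per-cell counts and frequencies). Every file
#' carries a comment header naming the configuration hash and seed.
#'
#' @param result An `hs_sim_result`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_result <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(result$network)
  header <- sprintf("# config_hash: %s seed: %s", hash, result$seed)
  wr <- function(df, file) {
    path <- file.path(dir, file)
    writeLines(header, path)
    suppressWarnings(utils::write.table(
      df, path, sep = ",", row.names = FALSE, append = TRUE, quote = FALSE))
    path
  }
  wr(result$spikes, "spikes.csv")
  wr(result$memory, "memory.csv")
  wr(data.frame(t_ms = result$schedule$t_ms,
                conn_id = result$schedule$conn_id), "lesions.csv")
  s <- summarize_cells(result,
                       final_window = min(1000, result$duration))
  jsonlite::write_json(
    list(config_hash = hash, seed = result$seed,
         duration_ms = result$duration,
         cells = s[, c("cell_id", "spike_count", "rate_hz",
                       "freq_mean_hz", "final_freq_hz", "mean_memory")]),
    file.path(dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  invisible(dir)
}

#' Read a spikes.csv written by [write_result()]
#'
#' @param path Path to the CSV (comment header tolerated).
#' @return A data.frame with `cell_id` and `t_ms`.
#' @export
read_spikes_csv <- function(path) {
  utils::read.csv(path, comment.char = "#",
                  colClasses = c(cell_id = "character", t_ms = "numeric"))
}
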