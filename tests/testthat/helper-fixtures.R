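# Shared fixtures, built in code at test time.

# empty spike-train set for a population (used to silence inputs)
empty_trains <- function(n_cells = 0L) {
  structure(data.frame(cell = integer(0), t_ms = numeric(0)),
            duration = 0, class = c("hs_spike_trains", "data.frame"))
}

as_trains <- function(cell, t_ms, duration) {
  structure(data.frame(cell = cell, t_ms = t_ms), duration = duration,
            class = c("hs_spike_trains", "data.frame"))
}

# silence every input population of the default network
silent_inputs <- function(net) {
  out <- lapply(net$inputs, function(p) empty_trains())
  names(out) <- names(net$inputs)
  out
}

# Minimal one-cell network: a single pyramidal cell driven by a single
# "EC2" source cell on one distal apical compartment (AMPA only).
# A high threshold keeps the cell from ever firing, so register traces
# can be compared with direct superposition.
single_cell_network <- function(threshold = 0, weight_comp = 12L,
                                class = "AMPA") {
  cells <- data.frame(id = "P1", region = "CA1", type = "pyramidal",
                      LSW = 0.2, EPSPd = 4.5, IPSPd = -6,
                      threshold = threshold, FQ = 1)
  conns <- data.frame(source = "EC2", source_kind = "input", target = "P1",
                      comp = as.integer(weight_comp), class = class,
                      delay = 1L, lesionable = FALSE,
                      input_cell = NA_integer_, stringsAsFactors = FALSE)
  conns$weight <- hippsim:::comp_base_weight(conns$comp, cells$LSW)
  conns$conn_id <- "C001"
  conns$deleted <- FALSE
  structure(
    list(cells = cells, connections = conns,
         constants = global_constants(),
         plasticity = plasticity_params(),
         kinetics = default_kinetics(),
         inputs = list(EC2 = list(n_cells = 1L, rate_peak = 10,
                                  theta_freq = 8, phase = 0))),
    class = "hs_network"
  )
}

# Direct superposition oracle: expected head-box deviation sequence for
# spikes delivered through a one-box-delay connection, template added
# spike by spike exactly as the engine does.
conv_oracle <- function(spike_t_ms, template, n_cycles, dt = 0.5,
                        delay = 1L) {
  dev <- numeric(n_cycles)
  for (t in spike_t_ms) {
    arr <- floor(t / dt) + 1L + delay
    if (arr > n_cycles) next
    idx <- arr:min(arr + length(template) - 1L, n_cycles)
    dev[idx] <- dev[idx] + template[seq_along(idx)]
  }
  dev
}
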