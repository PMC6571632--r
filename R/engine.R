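# Internal engine layout: compartments of all cells are stacked into the
# rows of three potential matrices (E = AMPA, M = NMDA, I = GABA-A), one
# column per register box, used as a circular buffer with a shared head
# pointer. Row of compartment k of cell ci is (ci - 1) * 16 + k.

template_values <- function(kind, peak, rise, decay, dt) {
  build_template(kind, peak, rise, decay, dt = dt)$values
}

# one template set per cell (peaks depend on the cell's EPSPd / IPSPd)
build_cell_templates <- function(cells, kinetics, dt) {
  lapply(seq_len(nrow(cells)), function(i) {
    list(
      E = template_values("excitatory", cells$EPSPd[i],
                          kinetics$ampa_rise, kinetics$ampa_decay, dt),
      M = template_values("excitatory", kinetics$nmda_frac * cells$EPSPd[i],
                          kinetics$nmda_rise, kinetics$nmda_decay, dt),
      I = template_values("inhibitory", cells$IPSPd[i],
                          kinetics$gaba_rise, kinetics$gaba_decay, dt)
    )
  })
}

# deterministic sub-seed derivation (kept inside 32-bit integer range)
derive_seed <- function(seed, idx) {
  as.integer((as.numeric(seed) * 97 + idx * 1000003) %% 2147483647)
}

# balanced seeded assignment of population cells to synapse slots
assign_input_cells <- function(n_cells, slot_idx, seed) {
  if (length(slot_idx) == 0L || n_cells == 0L) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  out <- sample(rep_len(slot_idx, n_cells))
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  out
}

#' Run the microcircuit simulation
#'
#' Advances the whole network in 0.5 ms cycles. Each cycle: due lesions
#' are applied; input and intra-network spikes are written into the
#' shift registers as PSP time courses; accumulated local potentials and
#' weighted somatic drives are computed; the plasticity rule integrates
#' the NMDA register head into the charge accumulator at every
#' NMDA-bearing compartment whose local potential clears the
#' magnesium-unblock gate, refreshing the memory multipliers; cells
#' whose drive exceeds threshold fire, reset their registers and become
#' refractory; the registers advance one box. The
#' update is stage-synchronous: every cell sees the previous cycle's
#' spikes, so cell iteration order is irrelevant.
#'
#' @param network An `hs_network` from [build_default_network()].
#' @param duration Simulated time in ms (default 10000 = 20000 cycles).
#' @param seed Integer seed controlling input generation and the
#'   input-cell-to-synapse assignment. Runs are bit-identical for equal
#'   (network, duration, seed, schedule).
#' @param schedule Optional `hs_lesion_schedule`; `NULL` (control run)
#'   behaves identically to an empty schedule.
#' @param input_spikes Optional named list of `hs_spike_trains`, keyed by
#'   population id, replacing the generated trains (replay mode).
#' @param record_every Memory-trace decimation in cycles (default 10,
#'   i.e. one sample per 5 ms).
#' @param record_potentials If `TRUE`, also record per-compartment
#'   potentials and per-cell drives every cycle (intended for small
#'   fixtures only).
#' @return An object of class `hs_sim_result`: list with `spikes`
#'   (data.frame `cell_id`, `t_ms`), `memory` (data.frame `t_ms`,
#'   `cell_id`, `M_mult`, `memory_time`), `deletion` (data.frame `t_ms`,
#'   `n_deleted`), `schedule`, `network`, `seed`, `duration`, `dt`,
#'   `n_cycles`, `charge` (final per-compartment charge matrix) and,
#'   when requested, `S_trace` / `drive_trace`.
#' @export
run_simulation <- function(network, duration = 10000, seed = 1L,
                           schedule = NULL, input_spikes = NULL,
                           record_every = 10L,
                           record_potentials = FALSE) {
  stopifnot(inherits(network, "hs_network"))
  validate_network(network)
  cells <- network$cells
  conns <- network$connections
  cons <- network$constants
  pp <- network$plasticity
  dt <- cons$dt
  ReP <- cons$ReP
  n_cells <- nrow(cells)
  n_rows <- n_cells * N_COMP
  n_cycles <- as.integer(round(duration / dt))
  if (n_cycles < 1L) stop("duration must cover at least one cycle", call. = FALSE)
  if (is.null(schedule))
    schedule <- structure(data.frame(t_ms = numeric(0),
                                     conn_id = character(0)),
                          class = c("hs_lesion_schedule", "data.frame"))

  tpl <- build_cell_templates(cells, network$kinetics, dt)
  max_len <- max(vapply(tpl, function(x) max(lengths(x)), 1L))
  L <- 2L * max_len

  row_of <- function(target, comp) (match(target, cells$id) - 1L) * N_COMP + comp
  cell_of_row <- rep(seq_len(n_cells), each = N_COMP)

  # per-compartment base weights from the proximity gradient
  w_base <- as.numeric(vapply(seq_len(n_cells), function(ci)
    comp_base_weight(1:N_COMP, cells$LSW[ci]), numeric(N_COMP)))
  FQ_row <- rep(cells$FQ, each = N_COMP)
  thr <- cells$threshold

  # first cycle at which each connection is dead (Inf = never)
  les_cycle <- rep(Inf, nrow(conns))
  if (nrow(schedule)) {
    m <- match(schedule$conn_id, conns$conn_id)
    if (anyNA(m)) stop("lesion schedule names unknown connections", call. = FALSE)
    les_cycle[m] <- ceiling(schedule$t_ms / dt) + 1
  }

  conn_rows <- row_of(conns$target, conns$comp)
  conn_code <- match(conns$class, c("AMPA", "AMPA_NMDA", "GABA_A"))
  nmda_rows <- sort(unique(conn_rows[conns$class == "AMPA_NMDA"]))

  ## ---- input events -------------------------------------------------
  pop_ids <- intersect(names(network$inputs),
                       unique(conns$source[conns$source_kind == "input"]))
  ev_cycle <- integer(0); ev_row <- integer(0); ev_code <- integer(0)
  for (pi in seq_along(pop_ids)) {
    pid <- pop_ids[pi]
    pop <- network$inputs[[pid]]
    trains <- if (!is.null(input_spikes[[pid]])) input_spikes[[pid]] else
      generate_theta_population(pop, duration, derive_seed(seed, pi))
    slot <- which(conns$source == pid)
    if (all(!is.na(conns$input_cell[slot]))) {
      # fixed one-to-one mapping (medial septum T cells)
      cell2slot <- slot[match(seq_len(pop$n_cells), conns$input_cell[slot])]
    } else {
      # each source cell is funneled onto one synapse slot of the
      # population's target field by balanced seeded assignment
      cell2slot <- assign_input_cells(pop$n_cells, slot,
                                      derive_seed(seed, 100 + pi))
    }
    sl <- cell2slot[trains$cell]
    keep <- !is.na(sl)
    sl <- sl[keep]
    cyc <- as.integer(floor(trains$t_ms[keep] / dt)) + 1L + conns$delay[sl]
    keep2 <- cyc <= n_cycles & cyc < les_cycle[sl]
    ev_cycle <- c(ev_cycle, cyc[keep2])
    ev_row <- c(ev_row, conn_rows[sl[keep2]])
    ev_code <- c(ev_code, conn_code[sl[keep2]])
  }
  ord <- order(ev_cycle)
  ev_cycle <- ev_cycle[ord]; ev_row <- ev_row[ord]; ev_code <- ev_code[ord]
  ev_count <- tabulate(ev_cycle, nbins = n_cycles)
  ev_end <- cumsum(ev_count)
  ev_start <- ev_end - ev_count + 1L

  ## ---- outgoing intra-network connections per cell ------------------
  out_by_cell <- lapply(seq_len(n_cells), function(ci) {
    idx <- which(conns$source_kind == "cell" & conns$source == cells$id[ci])
    list(rows = conn_rows[idx], codes = conn_code[idx],
         delays = conns$delay[idx], les = les_cycle[idx])
  })
  max_delay <- max(c(conns$delay, 1L))

  ## ---- state --------------------------------------------------------
  E <- matrix(ReP, n_rows, L); M <- matrix(ReP, n_rows, L)
  I <- matrix(ReP, n_rows, L)
  h <- 1L
  C <- numeric(n_rows)
  M_mult <- rep(1, n_rows)
  w_eff <- w_base
  refrac <- integer(n_cells)
  pend_rows <- vector("list", n_cycles + max_delay + 1L)
  pend_codes <- vector("list", n_cycles + max_delay + 1L)

  spike_cell <- integer(0); spike_t <- numeric(0)
  pc_idx <- which(cells$type == "pyramidal")
  rec_cycles <- seq(record_every, n_cycles, by = record_every)
  mem_M <- matrix(NA_real_, length(rec_cycles), length(pc_idx))
  mem_T <- matrix(NA_real_, length(rec_cycles), length(pc_idx))
  rec_i <- 0L
  nmda_rows_of_pc <- lapply(pc_idx, function(ci)
    intersect(nmda_rows, ((ci - 1L) * N_COMP + 1L):(ci * N_COMP)))
  if (record_potentials) {
    S_trace <- matrix(NA_real_, n_rows, n_cycles)
    drive_trace <- matrix(NA_real_, n_cells, n_cycles)
  }

  tplE <- lapply(tpl, `[[`, "E"); tplM <- lapply(tpl, `[[`, "M")
  tplI <- lapply(tpl, `[[`, "I")
  pos_base <- 0:(max_len - 1L)

  for (i in seq_len(n_cycles)) {
    pos_full <- ((h - 1L + pos_base) %% L) + 1L

    ## deliver spikes scheduled for this cycle
    rows_i <- pend_rows[[i]]; codes_i <- pend_codes[[i]]
    if (ev_count[i] > 0L) {
      sel <- ev_start[i]:ev_end[i]
      rows_i <- c(rows_i, ev_row[sel]); codes_i <- c(codes_i, ev_code[sel])
    }
    if (length(rows_i)) {
      for (j in seq_along(rows_i)) {
        r <- rows_i[j]; ci <- cell_of_row[r]
        code <- codes_i[j]
        if (code == 3L) {
          tv <- tplI[[ci]]; pos <- pos_full[seq_along(tv)]
          I[r, pos] <- I[r, pos] + tv
        } else {
          tv <- tplE[[ci]]; pos <- pos_full[seq_along(tv)]
          E[r, pos] <- E[r, pos] + tv
          if (code == 2L) {
            tv <- tplM[[ci]]; pos <- pos_full[seq_along(tv)]
            M[r, pos] <- M[r, pos] + tv
          }
        }
      }
    }

    ## accumulated local potentials and somatic drives
    Mhead <- M[, h]
    S <- ReP + (E[, h] - ReP) + (Mhead - ReP) + (I[, h] - ReP)
    dev <- w_eff * (S - ReP)
    dim(dev) <- c(N_COMP, n_cells)
    drive <- ReP + .colSums(dev, N_COMP, n_cells)

    ## plasticity: every cycle, charge integrates the NMDA register head
    ## at compartments whose local potential clears the unblock gate;
    ## forgetting runs on its slow cadence
    changed <- integer(0)
    g <- nmda_rows[S[nmda_rows] > pp$CaMT]
    if (length(g)) {
      C[g] <- C[g] + expm1(10 * (Mhead[g] - ReP) / 1000)
      changed <- g
    }
    if (i %% pp$decay_every == 0L) {
      over <- which(C > FQ_row)
      if (length(over)) {
        C[over] <- pmax(C[over] - FQ_row[over], 0)
        changed <- c(changed, over)
      }
    }
    if (length(changed)) {
      changed <- unique(changed)
      M_mult[changed] <- 1 + log1p(C[changed]) / 6
      w_eff[changed] <- w_base[changed] * M_mult[changed]
    }

    ## spiking, register reset, refractoriness
    fired <- which(refrac == 0L & drive > thr)
    act <- refrac > 0L
    if (any(act)) refrac[act] <- refrac[act] - 1L
    if (length(fired)) {
      spike_cell <- c(spike_cell, fired)
      spike_t <- c(spike_t, rep(i * dt, length(fired)))
      refrac[fired] <- cons$refractory_cycles
      for (ci in fired) {
        rr <- ((ci - 1L) * N_COMP + 1L):(ci * N_COMP)
        E[rr, ] <- ReP; M[rr, ] <- ReP; I[rr, ] <- ReP
        og <- out_by_cell[[ci]]
        if (length(og$rows)) {
          arr <- i + og$delays
          ok <- which(arr < og$les & arr <= n_cycles)
          for (j in ok) {
            pend_rows[[arr[j]]] <- c(pend_rows[[arr[j]]], og$rows[j])
            pend_codes[[arr[j]]] <- c(pend_codes[[arr[j]]], og$codes[j])
          }
        }
      }
    }

    if (record_potentials) {
      S_trace[, i] <- S
      drive_trace[, i] <- drive
    }
    if (rec_i < length(rec_cycles) && i == rec_cycles[rec_i + 1L]) {
      rec_i <- rec_i + 1L
      for (p in seq_along(pc_idx)) {
        rr <- nmda_rows_of_pc[[p]]
        mem_M[rec_i, p] <- if (length(rr)) mean(M_mult[rr]) else 1
        mem_T[rec_i, p] <- if (length(rr))
          mean(log1p(C[rr]) / pp$clog) else 0
      }
    }

    ## advance all registers one box
    E[, h] <- ReP; M[, h] <- ReP; I[, h] <- ReP
    h <- (h %% L) + 1L
  }

  rec_t <- rec_cycles * dt
  memory <- data.frame(
    t_ms = rep(rec_t, length(pc_idx)),
    cell_id = rep(cells$id[pc_idx], each = length(rec_t)),
    M_mult = as.numeric(mem_M),
    memory_time = as.numeric(mem_T)
  )
  deletion <- data.frame(
    t_ms = rec_t,
    n_deleted = vapply(rec_t, function(t) sum(schedule$t_ms <= t), 0)
  )
  res <- structure(
    list(
      spikes = data.frame(cell_id = cells$id[spike_cell], t_ms = spike_t),
      memory = memory,
      deletion = deletion,
      schedule = schedule,
      network = network,
      seed = seed,
      duration = duration,
      dt = dt,
      n_cycles = n_cycles,
      charge = matrix(C, N_COMP, n_cells,
                      dimnames = list(NULL, cells$id))
    ),
    class = "hs_sim_result"
  )
  if (record_potentials) {
    res$S_trace <- S_trace
    res$drive_trace <- drive_trace
  }
  res
}

#' @export
print.hs_sim_result <- function(x, ...) {
  cat("<hs_sim_result> ", x$duration, " ms (", x$n_cycles, " cycles), seed ",
      x$seed, "\n", sep = "")
  cat("  spikes: ", nrow(x$spikes), " across ",
      length(unique(x$spikes$cell_id)), " cells\n", sep = "")
  cat("  deletions scheduled: ", nrow(x$schedule), "\n", sep = "")
  invisible(x)
}
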