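# Compartment layout shared by every cell: 16 compartments.
# 1 axon, 2 soma, 3:6 basal dendrites (proximal -> distal),
# 7:16 apical dendrites (proximal -> distal).
COMP_AXON <- 1L
COMP_SOMA <- 2L
COMP_BASAL <- 3:6
COMP_APICAL <- 7:16
COMP_APICAL_MED <- 7:11    # stratum lucidum / radiatum (mossy, Schaffer)
COMP_APICAL_DIST <- 12:15  # lacunosum-moleculare (entorhinal input)
COMP_APICAL_TUFT <- 16L    # distal tuft (O-LM inhibition)
N_COMP <- 16L

#' Initial cell parameters of the CA3-CA1 microcircuit
#'
#' The 14-cell inventory with its initial parameters: four pyramidal
#' cells, two basket cells and one O-LM cell per region. `LSW` (low
#' significant weight) is the weight of the most distal dendritic input;
#' `EPSPd` and `IPSPd` are the peak excitatory and inhibitory
#' postsynaptic-potential amplitudes of synapses onto the cell.
#'
#' @param pc_threshold,in_threshold Spike thresholds in mV for pyramidal
#'   cells and for interneurons (basket, O-LM).
#' @param FQ Default forgetting coefficient assigned to every cell; may
#'   be overridden per cell afterwards.
#' @return A data.frame with one row per cell: `id`, `region`, `type`,
#'   `LSW`, `EPSPd`, `IPSPd`, `threshold`, `FQ`.
#' @export
default_cell_table <- function(pc_threshold = -55, in_threshold = -55,
                               FQ = 1) {
  cells <- rbind(
    data.frame(id = paste0("P", 1:4), region = "CA1", type = "pyramidal",
               LSW = 0.2, EPSPd = 4.5, IPSPd = -6),
    data.frame(id = c("B1", "B2"), region = "CA1", type = "basket",
               LSW = 1, EPSPd = 4, IPSPd = c(-4.5, -5.5)),
    data.frame(id = "OLM1", region = "CA1", type = "olm",
               LSW = 0.6, EPSPd = 4, IPSPd = -4),
    data.frame(id = paste0("P", 5:8), region = "CA3", type = "pyramidal",
               LSW = 0.6, EPSPd = 4.5, IPSPd = -6),
    data.frame(id = c("B3", "B4"), region = "CA3", type = "basket",
               LSW = 1, EPSPd = 4, IPSPd = c(-4.5, -5.5)),
    data.frame(id = "OLM2", region = "CA3", type = "olm",
               LSW = 0.6, EPSPd = 4, IPSPd = -4)
  )
  cells$threshold <- ifelse(cells$type == "pyramidal",
                            pc_threshold, in_threshold)
  cells$FQ <- FQ
  rownames(cells) <- NULL
  cells
}

#' Proximity-dependent base synaptic weight
#'
#' Base weights fall off linearly with distance from the soma along a
#' dendritic branch: 1.0 at the most proximal dendritic compartment down
#' to the cell's `LSW` at the most distal. Somatic synapses carry weight
#' 1.
#'
#' @param k Compartment index (may be a vector).
#' @param LSW Low significant weight: the weight at the most distal
#'   compartment of the branch.
#' @param branch Compartment indices making up the branch, ordered
#'   proximal to distal. Defaults to the apical dendrite.
#' @return Base weight(s) in `[LSW, 1]`.
#' @export
#' @examples
#' weight_gradient(16, 0.2)           # most distal apical -> 0.2
#' weight_gradient(7, 0.2)            # most proximal apical -> 1
weight_gradient <- function(k, LSW, branch = COMP_APICAL) {
  if (any(LSW <= 0 | LSW > 1)) stop("`LSW` must lie in (0, 1]", call. = FALSE)
  if (!all(k %in% branch)) stop("`k` is not on the given branch", call. = FALSE)
  pos <- (match(k, branch) - 1) / (length(branch) - 1)
  1 - pos * (1 - LSW)
}

# Base weight for any compartment of a cell (soma = 1, axon = 0).
# `LSW` is recycled to the length of `k` so per-connection tables with a
# per-row LSW work too.
comp_base_weight <- function(k, LSW) {
  LSW <- rep_len(LSW, length(k))
  w <- numeric(length(k))
  w[k == COMP_AXON] <- 0
  w[k == COMP_SOMA] <- 1
  b <- k %in% COMP_BASAL
  w[b] <- weight_gradient(k[b], LSW[b], COMP_BASAL)
  a <- k %in% COMP_APICAL
  w[a] <- weight_gradient(k[a], LSW[a], COMP_APICAL)
  w
}

conn_row <- function(source, source_kind, target, comp, class, delay,
                     lesionable = FALSE, input_cell = NA_integer_) {
  data.frame(source = source, source_kind = source_kind, target = target,
             comp = as.integer(comp), class = class,
             delay = as.integer(delay), lesionable = lesionable,
             input_cell = as.integer(input_cell),
             stringsAsFactors = FALSE)
}

#' Build the default CA3-CA1 microcircuit
#'
#' Wires the 14-cell network: entorhinal layer-2 input to CA3 pyramidal
#' and basket cells (distal apical), dentate mossy fibers to CA3
#' pyramidal mid-dendrites (AMPA+NMDA), CA3 recurrent excitation,
#' Schaffer collaterals to CA1 pyramidal mid-dendrites (AMPA+NMDA),
#' entorhinal layer-3 input to CA1 pyramidal and basket cells,
#' medial-septum theta inhibition onto basket and O-LM somas, basket
#' perisomatic inhibition of local pyramidal cells and of the adjacent
#' basket cell, pyramidal excitation of local basket and O-LM cells, and
#' O-LM inhibition of the pyramidal distal tuft. Each pyramidal cell
#' carries 13 excitatory synapses (4 entorhinal distal, 5 mid-dendritic,
#' 4 recurrent), 104 in total across P1-P8.
#'
#' @param cells Cell table as from [default_cell_table()]; overrides may
#'   be applied by editing it before the call.
#' @param constants [global_constants()] object.
#' @param plasticity [plasticity_params()] object.
#' @param kinetics Named list of synaptic kinetics: rise/decay time
#'   constants (ms) for AMPA, NMDA and GABA-A templates and the NMDA
#'   peak as a fraction of `EPSPd`.
#' @param inputs Named list describing the input populations (sizes,
#'   peak rates in Hz, theta frequency and phases in radians).
#' @param delay Conduction delay for intra-network connections, in boxes.
#' @return A list of class `hs_network`: `cells`, `connections` (one row
#'   per synapse slot), `constants`, `plasticity`, `kinetics`, `inputs`.
#' @export
#' @examples
#' net <- build_default_network()
#' nrow(net$cells)  # 14
build_default_network <- function(cells = default_cell_table(),
                                  constants = global_constants(),
                                  plasticity = plasticity_params(),
                                  kinetics = default_kinetics(),
                                  inputs = default_input_params(),
                                  delay = 1L) {
  validate_cells(cells)
  pcs <- function(region) cells$id[cells$type == "pyramidal" & cells$region == region]
  bcs <- function(region) cells$id[cells$type == "basket" & cells$region == region]
  olm <- function(region) cells$id[cells$type == "olm" & cells$region == region]

  conns <- list()
  add <- function(x) conns[[length(conns) + 1L]] <<- x

  for (region in c("CA3", "CA1")) {
    ec <- if (region == "CA3") "EC2" else "EC3"
    for (p in pcs(region)) {
      # entorhinal input on the distal apical dendrites (AMPA)
      add(conn_row(ec, "input", p, COMP_APICAL_DIST, "AMPA", delay,
                   lesionable = (region == "CA3")))
      # mid-dendritic excitation: mossy fibers (CA3) / Schaffer (CA1),
      # AMPA+NMDA -> the memory-forming synapses
      if (region == "CA3") {
        add(conn_row("DG", "input", p, COMP_APICAL_MED, "AMPA_NMDA", delay,
                     lesionable = TRUE))
      } else {
        src <- rep(pcs("CA3"), length.out = length(COMP_APICAL_MED))
        add(conn_row(src, "cell", p, COMP_APICAL_MED, "AMPA_NMDA", delay))
      }
      # recurrent excitation from the other local pyramidal cells (basal)
      others <- setdiff(pcs(region), p)
      add(conn_row(rep(others, length.out = length(COMP_BASAL)), "cell",
                   p, COMP_BASAL, "AMPA", delay))
      # perisomatic inhibition from both local basket cells
      add(conn_row(bcs(region), "cell", p, COMP_SOMA, "GABA_A", delay))
      # dendrite-targeting inhibition from the local O-LM cell
      add(conn_row(olm(region), "cell", p, COMP_APICAL_TUFT, "GABA_A", delay))
    }
    for (b in bcs(region)) {
      add(conn_row(ec, "input", b, COMP_APICAL_DIST, "AMPA", delay,
                   lesionable = (region == "CA3")))
      add(conn_row(rep(pcs(region), length.out = 4L), "cell", b,
                   COMP_APICAL_MED[1:4], "AMPA", delay))
      add(conn_row(setdiff(bcs(region), b), "cell", b, COMP_BASAL[1],
                   "GABA_A", delay))
    }
    for (o in olm(region)) {
      add(conn_row(pcs(region), "cell", o, COMP_BASAL, "AMPA", delay))
    }
  }
  # medial-septum theta: one GABAergic train per basket / O-LM soma
  ms_targets <- c("B3", "B4", "OLM2", "B1", "B2", "OLM1")
  for (j in seq_along(ms_targets)) {
    add(conn_row("MS", "input", ms_targets[j], COMP_SOMA, "GABA_A", delay,
                 input_cell = j))
  }

  connections <- do.call(rbind, conns)
  connections$weight <- comp_base_weight(
    connections$comp, cells$LSW[match(connections$target, cells$id)])
  connections$conn_id <- sprintf("C%03d", seq_len(nrow(connections)))
  connections$deleted <- FALSE
  rownames(connections) <- NULL

  net <- structure(
    list(cells = cells, connections = connections, constants = constants,
         plasticity = plasticity, kinetics = kinetics, inputs = inputs),
    class = "hs_network"
  )
  validate_network(net)
  net
}

#' @rdname build_default_network
#' @export
default_kinetics <- function() {
  list(ampa_rise = 2, ampa_decay = 6,
       nmda_rise = 5, nmda_decay = 25, nmda_frac = 0.5,
       gaba_rise = 2, gaba_decay = 6)
}

validate_cells <- function(cells) {
  need <- c("id", "region", "type", "LSW", "EPSPd", "IPSPd",
            "threshold", "FQ")
  if (!all(need %in% names(cells)))
    stop("cell table is missing columns: ",
         paste(setdiff(need, names(cells)), collapse = ", "), call. = FALSE)
  if (anyDuplicated(cells$id)) stop("duplicate cell ids", call. = FALSE)
  if (any(cells$LSW <= 0 | cells$LSW > 1))
    stop("LSW must lie in (0, 1]", call. = FALSE)
  if (any(cells$FQ < 1))
    stop("forgetting coefficient FQ must be >= 1", call. = FALSE)
  invisible(cells)
}

validate_network <- function(net) {
  conns <- net$connections
  exc <- conns$class %in% c("AMPA", "AMPA_NMDA")
  bad <- exc & conns$comp %in% c(COMP_SOMA, COMP_AXON)
  if (any(bad))
    stop("excitatory synapses must land on dendritic compartments",
         call. = FALSE)
  if (any(conns$class == "GABA_A" & conns$comp == COMP_AXON))
    stop("no synapses on the axon segment", call. = FALSE)
  invisible(net)
}

#' Count excitatory synapse slots on the pyramidal cells
#'
#' The default circuit carries 104 excitatory synapses across the eight
#' pyramidal cells (13 each). Counted as distinct (cell, compartment)
#' excitatory slots.
#'
#' @param network An `hs_network`.
#' @return Integer count.
#' @export
count_pc_excitatory_synapses <- function(network) {
  pcs <- network$cells$id[network$cells$type == "pyramidal"]
  conns <- network$connections
  exc <- conns[conns$class %in% c("AMPA", "AMPA_NMDA") &
                 conns$target %in% pcs, c("target", "comp")]
  nrow(unique(exc))
}

#' Build a progressive synaptic-deletion schedule
#'
#' The pathology (Alzheimer's-type) protocol turns off one CA3 afferent
#' synapse after the other: entorhinal layer-2 synapses onto CA3
#' pyramidal cells and basket cells, and mossy-fiber synapses onto CA3
#' pyramidal cells. Deletions are uniformly spaced in time and
#' irreversible; CA1 connections are never deleted.
#'
#' @param network An `hs_network`.
#' @param n_deletions Number of synapses to delete; defaults to all
#'   lesionable synapses.
#' @param t_start,t_end First and last deletion times in ms.
#' @param order `"random"` (seeded permutation, the default) or
#'   `"listed"` (entorhinal-to-pyramidal first, then
#'   entorhinal-to-basket, then mossy).
#' @param seed Integer seed for the random order.
#' @return A data.frame of class `hs_lesion_schedule` with columns
#'   `t_ms` (non-decreasing) and `conn_id`.
#' @export
build_lesion_schedule <- function(network, n_deletions = NULL,
                                  t_start = 500, t_end = 8200,
                                  order = c("random", "listed"),
                                  seed = 1L) {
  order <- match.arg(order)
  conns <- network$connections
  lesionable <- conns[conns$lesionable, , drop = FALSE]
  pcs <- network$cells$id[network$cells$type == "pyramidal"]
  if (is.null(n_deletions)) n_deletions <- nrow(lesionable)
  if (n_deletions > nrow(lesionable))
    stop("n_deletions (", n_deletions, ") exceeds the ",
         nrow(lesionable), " lesionable connections", call. = FALSE)
  if (n_deletions == 0L)
    return(structure(data.frame(t_ms = numeric(0), conn_id = character(0)),
                     class = c("hs_lesion_schedule", "data.frame")))
  if (order == "listed") {
    grp <- ifelse(lesionable$source == "EC2" & lesionable$target %in% pcs, 1L,
                  ifelse(lesionable$source == "EC2", 2L, 3L))
    ids <- lesionable$conn_id[order(grp, lesionable$conn_id)]
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    set.seed(seed)
    ids <- sample(lesionable$conn_id)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }
  ids <- ids[seq_len(n_deletions)]
  t <- if (n_deletions == 1L) t_start else
    seq(t_start, t_end, length.out = n_deletions)
  structure(data.frame(t_ms = t, conn_id = ids, stringsAsFactors = FALSE),
            class = c("hs_lesion_schedule", "data.frame"))
}

#' Apply all lesions due at or before a given time
#'
#' Marks every connection whose scheduled deletion time is `<= t` as
#' deleted. Deleted connections inject no postsynaptic potentials and
#' accumulate no charge; deletion is irreversible.
#'
#' @param network An `hs_network`.
#' @param schedule An `hs_lesion_schedule`.
#' @param t Current simulation time in ms.
#' @return The network with updated `deleted` flags.
#' @export
apply_lesion <- function(network, schedule, t) {
  due <- schedule$conn_id[schedule$t_ms <= t]
  network$connections$deleted <- network$connections$deleted |
    network$connections$conn_id %in% due
  network
}
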