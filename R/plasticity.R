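#' Plasticity-rule parameters
#'
#' Parameters of the NMDA-gated long-term potentiation rule. Charge is
#' accumulated at a compartment only while its local potential exceeds
#' the magnesium-unblock threshold `CaMT`; accumulated charge decays in
#' quanta of the forgetting coefficient `FQ` on a slow cadence.
#'
#' @param CaMT NMDA magnesium-unblock threshold in mV (default -68).
#' @param ReP Resting potential in mV (default -80).
#' @param clog Decimal-log conversion constant, ln(10) to five
#'   significant figures (2.3026); used for the reported memory time.
#' @param FQ Forgetting coefficient, the decay quantum subtracted from
#'   the charge accumulator. Must be >= 1.
#' @param decay_every Cycles between forgetting steps. The decay is slow
#'   compared with the per-event rise; the default applies it once per
#'   simulated second (2000 cycles at 0.5 ms).
#' @return A list of class `hs_plasticity_params`.
#' @export
plasticity_params <- function(CaMT = -68, ReP = -80, clog = 2.3026,
                              FQ = 1, decay_every = 2000L) {
  if (CaMT <= ReP)
    stop("`CaMT` must exceed the resting potential `ReP`", call. = FALSE)
  if (any(FQ < 1))
    stop("forgetting coefficient `FQ` must be >= 1", call. = FALSE)
  if (decay_every < 1)
    stop("`decay_every` must be a positive cycle count", call. = FALSE)
  structure(list(CaMT = CaMT, ReP = ReP, clog = clog, FQ = FQ,
                 decay_every = as.integer(decay_every)),
            class = "hs_plasticity_params")
}

#' NMDA magnesium-unblock gate
#'
#' Charge may be accumulated at a compartment only in cycles where its
#' accumulated local potential strictly exceeds the unblock threshold.
#'
#' @param S_k Local compartment potential(s), mV.
#' @param CaMT Unblock threshold, mV.
#' @return Logical, `TRUE` where `S_k > CaMT` (strict).
#' @export
#' @examples
#' ltp_gate(-67, -68)  # TRUE
#' ltp_gate(-68, -68)  # FALSE (strict inequality)
ltp_gate <- function(S_k, CaMT = -68) S_k > CaMT

#' Update the charge accumulator of a compartment
#'
#' While gated, the charge grows by `exp(10 * delta) - 1`, where `delta`
#' is the depolarization of the NMDA register head above rest expressed
#' in volts (a 12 mV depolarization contributes `exp(0.12) - 1`). When a
#' forgetting step is due and the charge exceeds the forgetting
#' coefficient, one quantum `FQ` is subtracted. Charge never goes
#' negative.
#'
#' @param C Current charge accumulator value(s) (dimensionless, >= 0).
#' @param M_head Head-box value of the NMDA (M) register, mV.
#' @param gated Logical: result of [ltp_gate()] for this cycle.
#' @param params An [plasticity_params()] object.
#' @param decay_due Logical: whether this cycle is a forgetting step.
#' @return Updated charge value(s).
#' @export
update_charge <- function(C, M_head, gated, params = plasticity_params(),
                          decay_due = FALSE) {
  if (any(C < 0)) stop("charge accumulator must be >= 0", call. = FALSE)
  delta_volts <- (M_head - params$ReP) / 1000
  inc <- expm1(10 * delta_volts)
  C <- C + ifelse(gated, inc, 0)
  if (decay_due) {
    over <- C > params$FQ
    C[over] <- C[over] - params$FQ
  }
  pmax(C, 0)
}

#' Memory multiplier and memory time from the charge accumulator
#'
#' The memory multiplier applied to a synapse's base weight is
#' `1 + ln(C + 1) / 6`; it equals 1 at zero charge and grows
#' logarithmically. The reported "time of memory" metric is the decimal
#' logarithm of `C + 1`, i.e. `ln(C + 1) / clog`.
#'
#' @param C Charge accumulator value(s) (>= 0).
#' @param clog Decimal-log constant (2.3026).
#' @return A list with `M_mult` (weight multiplier, >= 1) and
#'   `memory_time`.
#' @export
#' @examples
#' memory_value(0)           # M_mult 1, memory_time 0
#' memory_value(exp(6) - 1)  # M_mult 2
memory_value <- function(C, clog = 2.3026) {
  if (any(C < 0)) stop("charge accumulator must be >= 0", call. = FALSE)
  list(M_mult = 1 + log1p(C) / 6, memory_time = log1p(C) / clog)
}

#' Effective synaptic weight under potentiation
#'
#' @param base_w Base weight(s) from the proximity gradient.
#' @param M_mult Memory multiplier(s), >= 1.
#' @return `base_w * M_mult`, never below `base_w`.
#' @export
effective_weight <- function(base_w, M_mult) {
  if (any(M_mult < 1)) stop("`M_mult` must be >= 1", call. = FALSE)
  base_w * M_mult
}

#' One plasticity cycle over a cell's compartments
#'
#' For each excitatory compartment with an arriving presynaptic spike
#' this cycle, evaluates the unblock gate on the local potential, updates
#' the charge accumulator from the NMDA register head, and refreshes the
#' memory multiplier. Compartments without arrivals only take scheduled
#' forgetting steps.
#'
#' @param S Numeric vector of compartment potentials, mV.
#' @param M_head Numeric vector of NMDA register head values, mV.
#' @param C Numeric vector of charge accumulators.
#' @param arrived Logical vector: excitatory presynaptic arrival this
#'   cycle at an NMDA-bearing compartment.
#' @param params An [plasticity_params()] object.
#' @param decay_due Logical: whether this cycle is a forgetting step.
#' @return A list with updated `C`, `M_mult`, `memory_time`.
#' @export
plasticity_step <- function(S, M_head, C, arrived,
                            params = plasticity_params(),
                            decay_due = FALSE) {
  gated <- arrived & ltp_gate(S, params$CaMT)
  C <- update_charge(C, M_head, gated, params, decay_due = decay_due)
  mv <- memory_value(C, params$clog)
  list(C = C, M_mult = mv$M_mult, memory_time = mv$memory_time)
}
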