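#' Global simulation constants
#'
#' Constants shared by every cell in the microcircuit: the cycle length,
#' the resting potential the shift registers are filled with, and the
#' absolute refractory period that follows an action potential.
#'
#' @param dt Cycle length in ms. Each register box covers one cycle.
#' @param ReP Resting potential in mV. Registers are initialised to, and
#'   decay back to, this value.
#' @param refractory_ms Absolute refractory period in ms. Must be an
#'   integer multiple of `dt`; the default 1.5 ms spans three cycles.
#' @return A list of class `hs_constants` with fields `dt`, `ReP`,
#'   `refractory_ms` and the derived `refractory_cycles`.
#' @export
#' @examples
#' global_constants()
global_constants <- function(dt = 0.5, ReP = -80, refractory_ms = 1.5) {
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("`dt` must be a single positive number (ms)", call. = FALSE)
  n_ref <- refractory_ms / dt
  if (abs(n_ref - round(n_ref)) > 1e-9)
    stop("`refractory_ms` must be an integer multiple of `dt`", call. = FALSE)
  structure(
    list(dt = dt, ReP = ReP, refractory_ms = refractory_ms,
         refractory_cycles = as.integer(round(n_ref))),
    class = "hs_constants"
  )
}

#' Create a shift register filled with the resting potential
#'
#' A shift register is the cell's buffer of future membrane contributions:
#' an ordered sequence of potential boxes, each covering one 0.5 ms cycle.
#' Box 1 (the head) is the current cycle. Advancing the register discards
#' the head and appends a fresh box at the resting potential.
#'
#' @param length Number of boxes (>= 1).
#' @param ReP Resting potential in mV used to fill the register.
#' @return An object of class `hs_register`: a list with `boxes`
#'   (numeric vector) and `ReP`.
#' @export
#' @examples
#' r <- make_register(10)
#' register_head(r)  # -80
make_register <- function(length, ReP = -80) {
  if (!is.numeric(length) || length(length) != 1L || length < 1 ||
      abs(length - round(length)) > 1e-9)
    stop("register `length` must be a positive integer box count", call. = FALSE)
  structure(list(boxes = rep(ReP, as.integer(length)), ReP = ReP),
            class = "hs_register")
}

#' @rdname make_register
#' @param register An `hs_register`.
#' @export
register_head <- function(register) register$boxes[[1L]]

#' @rdname make_register
#' @export
advance_register <- function(register) {
  register$boxes <- c(register$boxes[-1L], register$ReP)
  register
}

#' Build a discrete postsynaptic-potential template
#'
#' Synaptic events are written into a register as a stereotyped time
#' course: a discrete alpha-shaped (double-exponential) deviation from
#' rest, sampled at the cycle length and scaled so its extremum equals the
#' requested peak (the EPSPd / IPSPd amplitude of the target cell).
#'
#' @param kind `"excitatory"` or `"inhibitory"`.
#' @param peak Peak deviation in mV. Positive for excitatory, negative for
#'   inhibitory; a zero peak yields an all-zero template.
#' @param rise_tau,decay_tau Rise and decay time constants in ms; must be
#'   positive with `decay_tau > rise_tau`.
#' @param dt Sampling interval in ms.
#' @param support_tol Amplitudes below `support_tol * abs(peak)` beyond
#'   the peak are dropped, fixing the template support.
#' @return An object of class `hs_psp_template`: list with `kind`, `peak`,
#'   `values` (deviations from rest, mV, one per box) and `support`.
#' @export
#' @examples
#' tpl <- build_template("excitatory", peak = 4.5, rise_tau = 2, decay_tau = 6)
#' max(tpl$values)  # 4.5
build_template <- function(kind = c("excitatory", "inhibitory"), peak,
                           rise_tau, decay_tau, dt = 0.5,
                           support_tol = 0.01) {
  kind <- match.arg(kind)
  if (!is.numeric(peak) || length(peak) != 1L)
    stop("`peak` must be a single number (mV)", call. = FALSE)
  if (kind == "excitatory" && peak < 0)
    stop("excitatory template requires `peak` >= 0", call. = FALSE)
  if (kind == "inhibitory" && peak > 0)
    stop("inhibitory template requires `peak` <= 0", call. = FALSE)
  if (rise_tau <= 0 || decay_tau <= 0)
    stop("`rise_tau` and `decay_tau` must be positive (ms)", call. = FALSE)
  if (decay_tau <= rise_tau)
    stop("`decay_tau` must exceed `rise_tau`", call. = FALSE)

  if (peak == 0) {
    values <- 0
  } else {
    # double exponential, evaluated until it has decayed below tolerance
    t_peak <- rise_tau * decay_tau / (decay_tau - rise_tau) *
      log(decay_tau / rise_tau)
    t_end <- t_peak + decay_tau * log(1 / support_tol) + 5 * decay_tau
    tt <- seq(0, t_end, by = dt)
    shape <- exp(-tt / decay_tau) - exp(-tt / rise_tau)
    shape <- shape / max(shape)
    past_peak <- tt > t_peak
    keep <- !(past_peak & abs(shape) < support_tol)
    last <- max(which(keep))
    values <- peak * shape[seq_len(last)]
  }
  structure(list(kind = kind, peak = peak, rise_tau = rise_tau,
                 decay_tau = decay_tau, dt = dt, values = values,
                 support = length(values)),
            class = "hs_psp_template")
}

#' Inject a weighted PSP time course into a shift register
#'
#' Adds `weight * template` into the register starting `delay` boxes after
#' the head. Contributions from overlapping events are additive; a
#' template running past the end of the register is truncated with a
#' warning.
#'
#' @param register An `hs_register`.
#' @param template An `hs_psp_template`.
#' @param weight Non-negative scale factor.
#' @param delay Delay in whole boxes (>= 0) before the template onset.
#' @return The updated register.
#' @export
inject_psp <- function(register, template, weight = 1, delay = 0L) {
  stopifnot(inherits(register, "hs_register"),
            inherits(template, "hs_psp_template"))
  if (weight < 0) stop("`weight` must be >= 0", call. = FALSE)
  if (delay < 0) stop("`delay` must be >= 0 boxes", call. = FALSE)
  if (weight == 0) return(register)
  L <- length(register$boxes)
  idx <- seq_along(template$values) + as.integer(delay)
  if (max(idx) > L) {
    warning("PSP template truncated at register end", call. = FALSE)
    keep <- idx <= L
    idx <- idx[keep]
    vals <- template$values[keep]
  } else {
    vals <- template$values
  }
  register$boxes[idx] <- register$boxes[idx] + weight * vals
  register
}

#' Accumulated local potential of one compartment
#'
#' Each compartment carries three registers: E (AMPA), M (NMDA) and I
#' (GABA-A). Its accumulated local potential for the current cycle is the
#' resting potential plus the superposed head-box deviations of the three
#' registers.
#'
#' @param E,M,I `hs_register` objects for the AMPA, NMDA and GABA-A
#'   channels of the compartment.
#' @param ReP Resting potential in mV.
#' @return The local potential S_k in mV.
#' @export
compartment_potential <- function(E, M, I, ReP = -80) {
  ReP + (register_head(E) - ReP) + (register_head(M) - ReP) +
    (register_head(I) - ReP)
}

#' Somatic drive of a cell from its compartment potentials
#'
#' The cell's drive for the current cycle is the resting potential plus
#' the weighted sum of compartment deviations, with effective weights
#' (base weight times the LTP memory multiplier) largest at proximal
#' compartments.
#'
#' @param S Numeric vector of compartment potentials (mV).
#' @param w_eff Effective weights, same length as `S`.
#' @param ReP Resting potential in mV.
#' @return The somatic drive in mV.
#' @export
soma_drive <- function(S, w_eff, ReP = -80) {
  stopifnot(length(S) == length(w_eff))
  ReP + sum(w_eff * (S - ReP))
}

#' Threshold crossing with refractory gating
#'
#' A cell fires when its somatic drive strictly exceeds its threshold and
#' it is not refractory. On a spike, every register box of the cell is
#' reset to the resting potential and the cell is inhibited for the
#' refractory period (three cycles at the default 0.5 ms resolution).
#'
#' @param drive Somatic drive in mV.
#' @param threshold Spike threshold in mV.
#' @param refractory_cycles_left Whole cycles of refractoriness remaining.
#' @return `TRUE` if the cell fires this cycle.
#' @export
fires <- function(drive, threshold, refractory_cycles_left = 0L) {
  refractory_cycles_left <= 0L && drive > threshold
}
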