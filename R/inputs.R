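#' Default input-population parameters
#'
#' The circuit is driven by four input populations: entorhinal layer 2
#' (EC2, 100 cells, to CA3), entorhinal layer 3 (EC3, 100 cells, to CA1,
#' in antiphase with EC2), dentate-gyrus mossy drive (DG, relayed onto
#' CA3 mid-dendrites) and the medial-septum GABAergic theta cells
#' (MS, T1-T6). All fire as theta-modulated (8 Hz) inhomogeneous Poisson
#' processes.
#'
#' @param ec_rate_peak Peak firing rate of each entorhinal cell, Hz.
#' @param dg_rate_peak Peak rate of each dentate (mossy-drive) cell, Hz.
#' @param ms_rate_peak Peak rate of each medial-septum theta cell, Hz.
#' @param theta_freq Theta frequency, Hz.
#' @param ec2_phase,ec3_phase,dg_phase,ms_phase Theta phases in radians.
#'   EC2 and EC3 differ by pi (when one is strong the other is weak);
#'   the septal inhibition is strongest when EC2 is weak.
#' @return Named list of per-population parameter lists.
#' @export
default_input_params <- function(ec_rate_peak = 13, dg_rate_peak = 9.5,
                                 ms_rate_peak = 40, theta_freq = 8,
                                 ec2_phase = 0, ec3_phase = pi,
                                 dg_phase = 0, ms_phase = pi) {
  list(
    EC2 = list(n_cells = 100L, rate_peak = ec_rate_peak,
               theta_freq = theta_freq, phase = ec2_phase),
    EC3 = list(n_cells = 100L, rate_peak = ec_rate_peak,
               theta_freq = theta_freq, phase = ec3_phase),
    DG  = list(n_cells = 100L, rate_peak = dg_rate_peak,
               theta_freq = theta_freq, phase = dg_phase),
    MS  = list(n_cells = 6L, rate_peak = ms_rate_peak,
               theta_freq = theta_freq, phase = ms_phase)
  )
}

#' Generate a theta-modulated input spike-train population
#'
#' Each source cell fires as an inhomogeneous Poisson process with rate
#' `r(t) = rate_peak * max(0, cos(2 pi f t / 1000 + phase))` (t in ms),
#' sampled by thinning a homogeneous process at `rate_peak`. Given the
#' same parameters and seed the trains are identical.
#'
#' @param pop Parameter list with `n_cells`, `rate_peak` (Hz),
#'   `theta_freq` (Hz) and `phase` (radians), as one element of
#'   [default_input_params()].
#' @param duration Duration in ms (> 0; a zero duration yields no
#'   spikes).
#' @param seed Integer seed.
#' @return A data.frame of class `hs_spike_trains` with columns
#'   `cell` (integer source index) and `t_ms`, sorted by time within
#'   cell, plus attributes `duration` and `pop`.
#' @export
#' @examples
#' tr <- generate_theta_population(list(n_cells = 5, rate_peak = 20,
#'                                      theta_freq = 8, phase = 0),
#'                                 duration = 1000, seed = 1)
generate_theta_population <- function(pop, duration, seed) {
  stopifnot(is.list(pop), pop$theta_freq > 0, pop$rate_peak >= 0,
            pop$n_cells >= 0, duration >= 0)
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))

  out <- vector("list", pop$n_cells)
  for (i in seq_len(pop$n_cells)) {
    n_cand <- stats::rpois(1, pop$rate_peak * duration / 1000)
    if (n_cand == 0) { out[[i]] <- numeric(0); next }
    t_cand <- sort(stats::runif(n_cand, 0, duration))
    mod <- pmax(0, cos(2 * pi * pop$theta_freq * t_cand / 1000 + pop$phase))
    keep <- stats::runif(n_cand) < mod
    out[[i]] <- t_cand[keep]
  }
  spikes <- data.frame(
    cell = rep.int(seq_len(pop$n_cells), lengths(out)),
    t_ms = unlist(out, use.names = FALSE)
  )
  structure(spikes, duration = duration, pop = pop,
            class = c("hs_spike_trains", "data.frame"))
}

#' Generate the medial-septum theta trains
#'
#' Six GABAergic trains (T1-T6), theta-rhythmic at 8 Hz, delivered to
#' the basket and O-LM cell somas (three trains per region).
#'
#' @param duration Duration in ms.
#' @param phase Theta phase in radians; the default pi places septal
#'   inhibition in antiphase with the EC2 drive.
#' @param seed Integer seed.
#' @param rate_peak Peak rate per train, Hz.
#' @param theta_freq Theta frequency, Hz.
#' @param n_cells Number of trains.
#' @return An `hs_spike_trains` data.frame.
#' @export
generate_ms_theta <- function(duration, phase = pi, seed = 1L,
                              rate_peak = 40, theta_freq = 8,
                              n_cells = 6L) {
  generate_theta_population(
    list(n_cells = n_cells, rate_peak = rate_peak,
         theta_freq = theta_freq, phase = phase),
    duration = duration, seed = seed
  )
}

#' Binned population spike count of a spike-train set
#'
#' @param trains An `hs_spike_trains` data.frame.
#' @param bin_ms Bin width in ms.
#' @param duration Total duration in ms; defaults to the trains'
#'   recorded duration.
#' @return A data.frame with `t_ms` (bin centres) and `count`.
#' @export
bin_population_count <- function(trains, bin_ms = 5,
                                 duration = attr(trains, "duration")) {
  breaks <- seq(0, duration, by = bin_ms)
  if (breaks[length(breaks)] < duration) breaks <- c(breaks, duration)
  counts <- graphics::hist(trains$t_ms, breaks = breaks, plot = FALSE)$counts
  data.frame(t_ms = (breaks[-length(breaks)] + breaks[-1]) / 2,
             count = counts)
}

#' Dominant modulation frequency of a population spike count
#'
#' Estimates the frequency of the largest non-DC peak of the power
#' spectrum of the binned population count (FFT periodogram, mean
#' removed).
#'
#' @param trains An `hs_spike_trains` data.frame.
#' @param bin_ms Bin width in ms.
#' @param duration Duration in ms.
#' @return Frequency in Hz.
#' @export
population_peak_frequency <- function(trains, bin_ms = 5,
                                      duration = attr(trains, "duration")) {
  b <- bin_population_count(trains, bin_ms = bin_ms, duration = duration)
  x <- b$count - mean(b$count)
  if (all(x == 0)) stop("population count is constant; no spectral peak",
                        call. = FALSE)
  n <- length(x)
  pw <- Mod(stats::fft(x))[2:floor(n / 2)]^2
  freq_hz <- (seq_along(pw)) / (n * bin_ms / 1000)
  freq_hz[which.max(pw)]
}

#' Write / read input spike trains as two-column CSV
#'
#' Spike trains round-trip through a plain `cell,t_ms` CSV so that runs
#' can be replayed from file.
#'
#' @param trains An `hs_spike_trains` data.frame.
#' @param path File path.
#' @return `read_spike_trains` returns an `hs_spike_trains` data.frame.
#' @export
write_spike_trains <- function(trains, path) {
  utils::write.csv(trains[, c("cell", "t_ms")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spike_trains
#' @param duration Duration in ms to attach; defaults to the last spike
#'   time rounded up.
#' @export
read_spike_trains <- function(path, duration = NULL) {
  df <- utils::read.csv(path)
  stopifnot(all(c("cell", "t_ms") %in% names(df)))
  if (is.null(duration)) duration <- ceiling(max(df$t_ms, 0))
  structure(df[, c("cell", "t_ms")], duration = duration,
            class = c("hs_spike_trains", "data.frame"))
}
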