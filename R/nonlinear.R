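#' Time-delay embedding of a scalar series
#'
#' @param series Numeric vector.
#' @param m Embedding dimension (>= 1).
#' @param tau Delay in samples (>= 1).
#' @return A matrix with `length(series) - (m - 1) * tau` rows and `m`
#'   columns; row i is `(x[i], x[i + tau], ..., x[i + (m-1) tau])`.
#' @export
embed_delay <- function(series, m, tau) {
  stopifnot(m >= 1, tau >= 1)
  n <- length(series) - (m - 1) * tau
  if (n < 1) stop("series too short for this (m, tau)", call. = FALSE)
  X <- matrix(0, n, m)
  for (j in 0:(m - 1)) X[, j + 1] <- series[(1 + j * tau):(n + j * tau)]
  X
}

#' Embedding delay from the autocorrelation function
#'
#' The delay is the first lag at which the autocorrelation drops to or
#' below 1/e; if it never does within `max_lag`, the first local minimum
#' is used. Constant series are rejected.
#'
#' @param series Numeric vector (length >= 10, non-constant).
#' @param max_lag Largest lag inspected; default half the series length.
#' @return Integer delay >= 1 (samples).
#' @export
delay_from_autocorrelation <- function(series,
                                       max_lag = floor(length(series) / 2)) {
  if (length(series) < 10)
    stop("series too short for delay estimation (need >= 10)", call. = FALSE)
  if (stats::sd(series) == 0)
    stop("delay undefined for a constant series", call. = FALSE)
  ac <- stats::acf(series, lag.max = max_lag, plot = FALSE,
                   demean = TRUE)$acf[-1]
  hit <- which(ac <= exp(-1))
  if (length(hit)) return(as.integer(hit[1]))
  dac <- diff(ac)
  mins <- which(dac[-1] > 0 & dac[-length(dac)] < 0) + 1L
  if (length(mins)) return(as.integer(mins[1]))
  as.integer(max_lag)
}

# nearest neighbour of each embedded point, excluding a Theiler window
# of temporally close points; brute force on the full distance matrix
nearest_neighbors <- function(X, theiler = 0L) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  idx <- abs(outer(seq_len(n), seq_len(n), "-")) <= theiler
  D[idx] <- Inf
  list(nn = apply(D, 1, which.min), d = apply(D, 1, min))
}

#' Minimum embedding dimension by false nearest neighbors
#'
#' For each candidate dimension m, each embedded point's nearest
#' neighbor (outside a Theiler window) is tested: it is a false neighbor
#' if adding the (m+1)-th coordinate stretches the pair by more than
#' `Rtol` relative to its distance, or beyond `Atol` standard deviations
#' of the series. The smallest m whose false-neighbor fraction falls
#' below `frac_threshold` is returned; if none qualifies, `m_max` is
#' returned with attribute `plateau = FALSE` (typical of noise).
#'
#' @param series Numeric vector.
#' @param tau Delay in samples.
#' @param m_max Largest dimension tried.
#' @param Rtol Relative stretch tolerance (default 15).
#' @param Atol Absolute stretch tolerance in series SDs (default 2).
#' @param frac_threshold Acceptable false-neighbor fraction (default
#'   0.01).
#' @param theiler Theiler window in samples (default `tau`).
#' @return Integer dimension with attributes `fnn_fraction` (per m) and
#'   `plateau`.
#' @export
fnn_embedding_dimension <- function(series, tau, m_max = 10L, Rtol = 15,
                                    Atol = 2, frac_threshold = 0.01,
                                    theiler = tau) {
  n_min <- (m_max + 1L) * tau + 10L
  if (length(series) < n_min)
    stop("series too short for FNN (need >= ", n_min, " samples)",
         call. = FALSE)
  sd_x <- stats::sd(series)
  if (sd_x == 0) stop("FNN undefined for a constant series", call. = FALSE)
  fracs <- numeric(m_max)
  for (m in seq_len(m_max)) {
    n <- length(series) - m * tau  # points that still have an m+1 coordinate
    X <- embed_delay(series, m, tau)[seq_len(n), , drop = FALSE]
    nn <- nearest_neighbors(X, theiler = theiler)
    extra_i <- series[seq_len(n) + m * tau]
    stretch <- abs(extra_i - extra_i[nn$nn])
    d_new <- sqrt(nn$d^2 + stretch^2)
    false_nb <- ((stretch / pmax(nn$d, .Machine$double.eps) > Rtol) |
                   (d_new / sd_x > Atol)) &
      d_new > 1e-8 * sd_x   # numerically coincident pairs are true neighbors
    fracs[m] <- mean(false_nb)
    if (fracs[m] < frac_threshold) {
      return(structure(as.integer(m), fnn_fraction = fracs[seq_len(m)],
                       plateau = TRUE))
    }
  }
  structure(as.integer(m_max), fnn_fraction = fracs, plateau = FALSE)
}

#' Grassberger-Procaccia correlation dimension
#'
#' Embeds the series, forms the correlation sum C(r) (fraction of point
#' pairs closer than r, pairs within the Theiler window excluded) over a
#' logarithmic r grid spanning the small-distance tail of the pairwise
#' distance distribution, and returns the slope of log C(r) vs log r
#' fitted over the scaling region: grid points where C(r) lies between
#' 0.01 and 0.4, i.e. where the sum grows as a power law before
#' saturating at the attractor diameter.
#'
#' @param series Numeric vector.
#' @param m Embedding dimension.
#' @param tau Delay in samples.
#' @param r_grid Optional radius grid; computed from the distance
#'   distribution when `NULL`.
#' @param n_r Number of radii when the grid is computed.
#' @param theiler Theiler window in samples (default `tau`).
#' @return The slope estimate `D2` with attributes `r_grid`, `C_r` and
#'   `fit_index`.
#' @export
correlation_dimension <- function(series, m, tau, r_grid = NULL,
                                  n_r = 24L, theiler = tau) {
  X <- embed_delay(series, m, tau)
  n <- nrow(X)
  if (n < 100) stop("need >= 100 embedded points", call. = FALSE)
  D <- as.matrix(stats::dist(X))
  keep <- abs(outer(seq_len(n), seq_len(n), "-")) > theiler
  d <- D[keep & upper.tri(D)]
  if (length(d) && all(d == 0)) {
    # all embedded states coincide: a zero-dimensional (point) attractor
    return(structure(0, r_grid = numeric(0), C_r = numeric(0),
                     fit_index = integer(0)))
  }
  # drop numerically coincident pairs (exact recurrences of a sampled
  # periodic orbit): they form an atom at r = 0 that is not part of the
  # continuous scaling law
  d <- d[d > 1e-9 * stats::median(d)]
  if (length(d) < 100)
    stop("degenerate scaling region: too few distinct pair distances",
         call. = FALSE)
  if (is.null(r_grid)) {
    qs <- stats::quantile(d, c(0.01, 0.95))
    r_grid <- exp(seq(log(qs[1]), log(qs[2]), length.out = n_r))
  }
  C_r <- vapply(r_grid, function(r) mean(d < r), 0)
  ok <- which(C_r > 0)
  if (length(ok) < 6)
    stop("degenerate scaling region: correlation sum is flat", call. = FALSE)
  mid <- which(C_r >= 0.01 & C_r <= 0.4)
  if (length(mid) < 3) mid <- ok
  fit <- stats::lm(log(C_r[mid]) ~ log(r_grid[mid]))
  structure(unname(stats::coef(fit)[2]),
            r_grid = r_grid, C_r = C_r, fit_index = mid)
}

#' Shannon entropy of a series histogram
#'
#' `H = -sum p log2 p` over an equal-width histogram of the series
#' (default 16 bins spanning the observed range). The default analysis
#' signal in this package is a cell's ISI sequence.
#'
#' @param series Non-empty numeric vector.
#' @param n_bins Number of histogram bins.
#' @return Entropy in bits, in `[0, log2(n_bins)]`.
#' @export
shannon_entropy <- function(series, n_bins = 16L) {
  if (!length(series)) stop("series is empty", call. = FALSE)
  if (length(unique(series)) == 1L) return(0)
  breaks <- seq(min(series), max(series), length.out = n_bins + 1L)
  cnt <- graphics::hist(series, breaks = breaks, plot = FALSE,
                        include.lowest = TRUE)$counts
  p <- cnt[cnt > 0] / sum(cnt)
  -sum(p * log2(p))
}

#' Recurrence distance matrix of a delay-embedded series
#'
#' All pairwise Euclidean distances between points of the
#' three-dimensional (by default) delay embedding, as used for visual
#' recurrence analysis.
#'
#' @param series Numeric vector of length >= `(m - 1) * tau + 2`.
#' @param tau Delay in samples.
#' @param m Embedding dimension (default 3).
#' @return A symmetric, zero-diagonal matrix of distances.
#' @export
recurrence_matrix <- function(series, tau, m = 3L) {
  if (length(series) < (m - 1) * tau + 2)
    stop("series too short: need at least ", (m - 1) * tau + 2,
         " samples", call. = FALSE)
  as.matrix(stats::dist(embed_delay(series, m, tau)))
}

#' Full nonlinear analysis of one series
#'
#' Convenience wrapper running the whole pipeline: autocorrelation delay
#' selection, FNN embedding dimension, correlation dimension at that
#' dimension, Shannon entropy, and the 3-D recurrence matrix.
#'
#' @param series Numeric vector (typically an ISI sequence).
#' @param n_bins Histogram bins for the entropy.
#' @param m_max Largest embedding dimension tried.
#' @return A list of class `hs_nla` with `tau`, `embedding_dimension`,
#'   `correlation_dimension` (NA when the scaling region is degenerate),
#'   `entropy_bits` and `recurrence` (distance matrix).
#' @export
nonlinear_analysis <- function(series, n_bins = 16L, m_max = 8L) {
  tau <- delay_from_autocorrelation(series)
  m <- tryCatch(fnn_embedding_dimension(series, tau, m_max = m_max),
                error = function(e) structure(NA_integer_,
                                              message = conditionMessage(e)))
  d2 <- tryCatch(
    correlation_dimension(series, m = max(3L, min(m, m_max, na.rm = TRUE),
                                          na.rm = TRUE), tau = tau),
    error = function(e) NA_real_
  )
  rec <- tryCatch(recurrence_matrix(series, tau), error = function(e) NULL)
  structure(
    list(tau = tau, embedding_dimension = as.integer(m),
         correlation_dimension = as.numeric(d2),
         entropy_bits = shannon_entropy(series, n_bins),
         recurrence = rec),
    class = "hs_nla"
  )
}
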