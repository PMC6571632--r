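#' Per-cell spike-train summaries
#'
#' Computes, for every cell in the network: spike count, interspike
#' intervals (ISI), overall rate (count / duration), mean instantaneous
#' frequency (mean of 1/ISI; this is the default "mean frequency" since
#' its dispersion across a theta-modulated train far exceeds the overall
#' rate), final frequency over the terminal window, and mean memory
#' multiplier (pyramidal cells only).
#'
#' @param result An `hs_sim_result`.
#' @param final_window Width of the terminal window in ms (default
#'   1000).
#' @return A data.frame with one row per cell: `cell_id`, `spike_count`,
#'   `rate_hz`, `freq_mean_hz`, `freq_sd_hz`, `final_freq_hz`,
#'   `mean_memory`; the ISI vectors are attached as a list column `isi`.
#' @export
summarize_cells <- function(result, final_window = 1000) {
  stopifnot(inherits(result, "hs_sim_result"))
  if (final_window > result$duration)
    stop("`final_window` exceeds the run duration", call. = FALSE)
  ids <- result$network$cells$id
  dur_s <- result$duration / 1000
  t0 <- result$duration - final_window
  out <- lapply(ids, function(id) {
    st <- sort(result$spikes$t_ms[result$spikes$cell_id == id])
    isi <- diff(st)
    inst <- if (length(isi)) 1000 / isi else numeric(0)
    mem <- result$memory$M_mult[result$memory$cell_id == id]
    data.frame(
      cell_id = id,
      spike_count = length(st),
      rate_hz = length(st) / dur_s,
      freq_mean_hz = if (length(inst)) mean(inst) else 0,
      freq_sd_hz = if (length(inst) > 1) stats::sd(inst) else 0,
      final_freq_hz = sum(st > t0) / (final_window / 1000),
      mean_memory = if (length(mem)) mean(mem) else NA_real_
    )
  })
  df <- do.call(rbind, out)
  df$isi <- lapply(ids, function(id)
    diff(sort(result$spikes$t_ms[result$spikes$cell_id == id])))
  rownames(df) <- NULL
  df
}

#' Binned per-cell firing-rate series aligned with the deletion load
#'
#' @param result An `hs_sim_result`.
#' @param cell_ids Cells to include; defaults to all.
#' @param bin_ms Bin width in ms.
#' @return A data.frame `t_ms` (bin centres), `cell_id`, `rate_hz`,
#'   `spike_count`, `n_deleted` (cumulative deletions at the bin end).
#' @export
binned_rate_series <- function(result, cell_ids = NULL, bin_ms = 500) {
  stopifnot(inherits(result, "hs_sim_result"))
  if (is.null(cell_ids)) cell_ids <- result$network$cells$id
  breaks <- seq(0, result$duration, by = bin_ms)
  if (breaks[length(breaks)] < result$duration)
    breaks <- c(breaks, result$duration)
  mids <- (breaks[-length(breaks)] + breaks[-1]) / 2
  ends <- breaks[-1]
  n_del <- vapply(ends, function(t) sum(result$schedule$t_ms <= t), 0)
  out <- lapply(cell_ids, function(id) {
    st <- result$spikes$t_ms[result$spikes$cell_id == id]
    cnt <- graphics::hist(st, breaks = breaks, plot = FALSE)$counts
    data.frame(t_ms = mids, cell_id = id, spike_count = cnt,
               rate_hz = cnt / (diff(breaks) / 1000), n_deleted = n_del)
  })
  df <- do.call(rbind, out)
  rownames(df) <- NULL
  df
}

#' Correlation between a metric series and the synaptic-deletion load
#'
#' Pearson or Spearman correlation with a two-sided p-value, for
#' aligned, equal-length series such as a cell's binned firing rate (or
#' memory trace) against the cumulative number of deleted synapses.
#'
#' @param metric_series Numeric vector.
#' @param deletion_series Numeric vector, same length.
#' @param method `"pearson"` or `"spearman"`.
#' @return A list with `r` (coefficient in \[-1, 1\]) and `p`.
#' @export
deletion_correlation <- function(metric_series, deletion_series,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(metric_series) != length(deletion_series))
    stop("series must be aligned and of equal length", call. = FALSE)
  if (length(metric_series) < 3)
    stop("need at least 3 aligned observations", call. = FALSE)
  if (stats::sd(metric_series) == 0 || stats::sd(deletion_series) == 0)
    stop("correlation undefined for a zero-variance series", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(metric_series, deletion_series, method = method,
                    exact = FALSE)
  )
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Two-group comparison (Student's t or Mann-Whitney U)
#'
#' Compares two groups of values with a two-sided Student's t test or
#' Mann-Whitney (Wilcoxon rank-sum) test. When `test = "auto"` a
#' Shapiro-Wilk normality pre-check on both groups (alpha = 0.05)
#' selects the t test if neither rejects, otherwise the U test.
#' Degenerate input (both groups constant and equal) yields p = 1 with a
#' warning.
#'
#' @param a,b Numeric vectors.
#' @param test `"auto"`, `"t"` or `"mannwhitney"`.
#' @return A list with `test` (the test used), `statistic` and `p`.
#' @export
compare_groups <- function(a, b, test = c("auto", "t", "mannwhitney")) {
  test <- match.arg(test)
  if (length(a) < 1 || length(b) < 1)
    stop("both groups must be non-empty", call. = FALSE)
  degenerate <- stats::sd(c(a, b)) == 0
  if (degenerate) {
    warning("both groups are constant and equal; p = 1", call. = FALSE)
    return(list(test = if (test == "t") "t" else "mannwhitney",
                statistic = 0, p = 1))
  }
  if (test == "auto") {
    normal <- function(x) {
      if (length(x) < 3 || stats::sd(x) == 0) return(FALSE)
      stats::shapiro.test(x)$p.value > 0.05
    }
    test <- if (normal(a) && normal(b)) "t" else "mannwhitney"
  }
  if (test == "t") {
    ht <- stats::t.test(a, b)
    list(test = "t", statistic = unname(ht$statistic), p = ht$p.value)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    list(test = "mannwhitney", statistic = unname(ht$statistic),
         p = ht$p.value)
  }
}

#' Paired memory / deletion / spike series for two runs
#'
#' Aligns, on the shared recording time base, the cumulative deletion
#' load and the mean memory multiplier of selected pyramidal cells for a
#' control and a pathology run, plus a per-cell spike-count vs
#' mean-memory table across both runs.
#'
#' @param result_control,result_pathology `hs_sim_result` objects from
#'   runs sharing `duration` and `record_every`.
#' @param cell_ids Pyramidal cells to track (default P1 and P5).
#' @return A list with `series` (data.frame: `t_ms`, `model`, `cell_id`,
#'   `n_deleted`, `M_mult`) and `spikes_memory` (data.frame: `model`,
#'   `cell_id`, `spike_count`, `mean_memory`).
#' @export
memory_vs_deletion <- function(result_control, result_pathology,
                               cell_ids = c("P1", "P5")) {
  stopifnot(inherits(result_control, "hs_sim_result"),
            inherits(result_pathology, "hs_sim_result"))
  if (!isTRUE(all.equal(result_control$deletion$t_ms,
                        result_pathology$deletion$t_ms)))
    stop("the two runs do not share a time base", call. = FALSE)
  one <- function(res, label) {
    mem <- res$memory[res$memory$cell_id %in% cell_ids, ]
    mem$n_deleted <- res$deletion$n_deleted[
      match(mem$t_ms, res$deletion$t_ms)]
    data.frame(t_ms = mem$t_ms, model = label, cell_id = mem$cell_id,
               n_deleted = mem$n_deleted, M_mult = mem$M_mult)
  }
  series <- rbind(one(result_control, "control"),
                  one(result_pathology, "pathology"))
  sm <- function(res, label) {
    s <- summarize_cells(res)
    pcs <- s[!is.na(s$mean_memory), ]
    data.frame(model = label, cell_id = pcs$cell_id,
               spike_count = pcs$spike_count,
               mean_memory = pcs$mean_memory)
  }
  list(series = series,
       spikes_memory = rbind(sm(result_control, "control"),
                             sm(result_pathology, "pathology")))
}
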