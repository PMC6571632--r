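# summaries operate on a result object; build a small synthetic one
fake_result <- function(spikes, duration = 10000) {
  net <- build_default_network()
  structure(
    list(spikes = spikes, duration = duration, network = net,
         memory = data.frame(t_ms = numeric(0), cell_id = character(0),
                             M_mult = numeric(0), memory_time = numeric(0)),
         deletion = data.frame(t_ms = numeric(0), n_deleted = numeric(0)),
         schedule = data.frame(t_ms = numeric(0), conn_id = character(0)),
         seed = 1, dt = 0.5, n_cycles = duration / 0.5),
    class = "hs_sim_result")
}

test_that("per-cell summaries match hand-computed statistics", {
  res <- fake_result(data.frame(cell_id = rep("P1", 3),
                                t_ms = c(100, 200, 300)))
  s <- summarize_cells(res)
  p1 <- s[s$cell_id == "P1", ]
  expect_equal(p1$spike_count, 3)
  expect_equal(p1$rate_hz, 0.3)
  expect_equal(p1$isi[[1]], c(100, 100))
  expect_equal(p1$freq_mean_hz, 10)       # instantaneous 1/ISI in Hz
  expect_equal(p1$final_freq_hz, 0)       # all spikes in the first second

  # every other cell is empty: zero counts, empty ISI
  other <- s[s$cell_id != "P1", ]
  expect_true(all(other$spike_count == 0))
  expect_true(all(lengths(other$isi) == 0))
  expect_true(all(other$final_freq_hz == 0))

  expect_error(summarize_cells(res, final_window = 20000), "exceeds")
})

test_that("summaries conserve the total spike count on a real run", {
  net <- build_default_network()
  res <- run_simulation(net, duration = 1500, seed = 4)
  s <- summarize_cells(res, final_window = 500)
  expect_equal(sum(s$spike_count), nrow(res$spikes))
})

test_that("deletion correlations recover exact and null relationships", {
  del <- c(0, 1, 2, 3, 4, 5, 6, 7)
  r <- deletion_correlation(-del, del)
  expect_equal(r$r, -1, tolerance = 1e-12)
  r2 <- deletion_correlation(2 * del + 3, del)
  expect_equal(r2$r, 1, tolerance = 1e-12)

  set.seed(99)
  noise <- rnorm(40)
  r3 <- deletion_correlation(noise, seq_len(40))
  expect_lt(abs(r3$r), 0.4)
  expect_gt(r3$p, 0.05)

  expect_error(deletion_correlation(rep(1, 5), 1:5), "zero-variance")
  expect_error(deletion_correlation(1:4, 1:5), "equal length")
  expect_error(deletion_correlation(1:2, 1:2), "at least 3")

  # spearman agrees in sign and handles monotone nonlinearity
  r4 <- deletion_correlation(exp(del), del, method = "spearman")
  expect_equal(r4$r, 1, tolerance = 1e-12)
})

test_that("group comparisons separate healthy-sized from AD-sized counts", {
  # identical samples: U test is degenerate, p = 1
  expect_warning(out <- compare_groups(c(2, 2, 2), c(2, 2, 2)), "constant")
  expect_equal(out$p, 1)

  a <- c(72, 74, 135, 88)
  b <- c(18, 20, 38, 20)
  out_t <- compare_groups(a, b, test = "t")
  expect_lt(out_t$p, 0.05)
  # frozen from a direct Welch computation on these values:
  # t = (92.25 - 24) / sqrt(862.9167/4 + 88/4)
  expect_equal(out_t$statistic, 4.42651, tolerance = 1e-5)

  # power grows monotonically with separation
  ps <- vapply(c(0, 20, 60), function(shift)
    compare_groups(a, b - shift, test = "t")$p, 0)
  expect_true(all(diff(ps) < 0))

  # Mann-Whitney is invariant under monotone transforms of both samples
  u1 <- compare_groups(a, b, test = "mannwhitney")
  u2 <- compare_groups(log(a), log(b), test = "mannwhitney")
  expect_equal(u1$statistic, u2$statistic)
  expect_equal(u1$p, u2$p)

  # auto mode picks a valid test and returns a sane p-value
  out_auto <- compare_groups(a, b)
  expect_true(out_auto$test %in% c("t", "mannwhitney"))
  expect_lt(out_auto$p, 0.05)
})

test_that("memory/deletion pairing aligns runs on the shared time base", {
  net <- build_default_network()
  ctrl <- run_simulation(net, duration = 2000, seed = 6)
  # delete the mossy-fiber synapses (the CA3 memory-forming inputs) so
  # the memory contrast is unconfounded by basket-cell disinhibition
  conns <- net$connections
  mossy <- conns$conn_id[conns$source == "DG"]
  sched <- structure(
    data.frame(t_ms = seq(200, 1000, length.out = length(mossy)),
               conn_id = mossy),
    class = c("hs_lesion_schedule", "data.frame"))
  path <- run_simulation(net, duration = 2000, seed = 6, schedule = sched)

  mv <- memory_vs_deletion(ctrl, path)
  ctrl_series <- mv$series[mv$series$model == "control", ]
  expect_true(all(ctrl_series$n_deleted == 0))
  path_series <- mv$series[mv$series$model == "pathology", ]
  expect_true(all(diff(path_series$n_deleted[path_series$cell_id == "P5"]) >= 0))
  expect_setequal(unique(mv$series$cell_id), c("P1", "P5"))

  # deafferented CA3 accumulates less memory than the control run
  end_mem <- function(df, cell) {
    x <- df[df$cell_id == cell, ]
    x$M_mult[which.max(x$t_ms)]
  }
  expect_lte(end_mem(path_series, "P5"), end_mem(ctrl_series, "P5"))

  expect_equal(nrow(mv$spikes_memory), 16)  # 8 PCs x 2 models
  expect_true(all(mv$spikes_memory$mean_memory >= 1))
})
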