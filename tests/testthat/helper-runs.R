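# Seed-paired control / pathology runs at the default configuration,
# computed once and cached for the session (several test files reuse
# them; each 10 s run takes on the order of a second).

.run_cache <- new.env(parent = emptyenv())

paired_runs <- function(seeds = 1:10) {
  key <- paste0("seeds_", paste(seeds, collapse = "_"))
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  net <- build_default_network()
  runs <- lapply(seeds, function(s) {
    control <- run_simulation(net, duration = 10000, seed = s)
    sched <- build_lesion_schedule(net, seed = s)
    pathology <- run_simulation(net, duration = 10000, seed = s,
                                schedule = sched)
    list(seed = s, control = control, pathology = pathology)
  })
  .run_cache[[key]] <- runs
  runs
}

mean_pc_count <- function(result, ids) {
  mean(vapply(ids, function(i) sum(result$spikes$cell_id == i), 0))
}

CA1_PCS <- paste0("P", 1:4)
CA3_PCS <- paste0("P", 5:8)
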