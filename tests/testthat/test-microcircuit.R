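test_that("the default circuit carries the full cell inventory", {
  net <- build_default_network()
  cells <- net$cells
  expect_equal(nrow(cells), 14)
  inv <- table(cells$region, cells$type)
  expect_equal(inv["CA1", "pyramidal"], 4)
  expect_equal(inv["CA3", "pyramidal"], 4)
  expect_equal(inv["CA1", "basket"], 2)
  expect_equal(inv["CA3", "basket"], 2)
  expect_equal(inv["CA1", "olm"], 1)
  expect_equal(inv["CA3", "olm"], 1)
  # all synapses land on one of the 16 compartments
  expect_true(all(net$connections$comp %in% 1:16))
})

test_that("pyramidal cells carry 104 excitatory synapses (8 x 13)", {
  net <- build_default_network()
  expect_equal(count_pc_excitatory_synapses(net), 104)
  # 13 per pyramidal cell
  conns <- net$connections
  for (p in paste0("P", 1:8)) {
    exc <- conns[conns$class %in% c("AMPA", "AMPA_NMDA") & conns$target == p, ]
    expect_equal(nrow(unique(exc[, c("target", "comp")])), 13)
  }
})

test_that("excitatory and inhibitory synapses land on the correct strata", {
  net <- build_default_network()
  conns <- net$connections
  # entorhinal input on distal apical; mossy/Schaffer mid-dendritic with NMDA
  expect_true(all(conns$comp[conns$source %in% c("EC2", "EC3")] %in% 12:15))
  expect_true(all(conns$comp[conns$source == "DG"] %in% 7:11))
  expect_true(all(conns$class[conns$source == "DG"] == "AMPA_NMDA"))
  sch <- conns[conns$source %in% paste0("P", 5:8) &
                 conns$target %in% paste0("P", 1:4), ]
  expect_true(all(sch$class == "AMPA_NMDA"))
  expect_true(all(sch$comp %in% 7:11))
  # basket inhibition is perisomatic, septal input somatic
  expect_true(all(conns$comp[conns$source %in% c("B1", "B2", "B3", "B4") &
                               grepl("^P", conns$target)] == 2))
  expect_true(all(conns$class[conns$source == "MS"] == "GABA_A"))
})

test_that("base weights fall linearly from 1 at proximal to LSW at distal", {
  expect_equal(weight_gradient(16, 0.2), 0.2)
  expect_equal(weight_gradient(7, 0.2), 1)
  # midpoint of a branch with LSW 0.2 sits at 0.6
  expect_equal(weight_gradient(2, 0.2, branch = 1:3), 0.6)
  w <- weight_gradient(7:16, 0.2)
  expect_true(all(diff(w) < 0))
  expect_error(weight_gradient(2, 0.2), "branch")
  expect_error(weight_gradient(16, 0), "LSW")
})

test_that("cell-table overrides stay local to the overridden cell", {
  cells <- default_cell_table()
  cells$LSW[cells$id == "P1"] <- 0.5
  net <- build_default_network(cells = cells)
  ref <- build_default_network()
  changed <- net$connections$weight != ref$connections$weight
  expect_true(all(net$connections$target[changed] == "P1"))
  expect_true(any(changed))
})

test_that("lesion schedules space deletions uniformly over CA3 afferents", {
  net <- build_default_network()
  conns <- net$connections

  # lesionable = EC2->CA3 PC, EC2->CA3 BC, mossy->CA3 PC only
  les <- conns[conns$lesionable, ]
  expect_equal(nrow(les), 44)  # 16 + 8 + 20
  expect_true(all(les$source %in% c("EC2", "DG")))
  expect_true(all(les$target %in% c(paste0("P", 5:8), "B3", "B4")))

  expect_equal(nrow(build_lesion_schedule(net, n_deletions = 0)), 0)

  s4 <- build_lesion_schedule(net, n_deletions = 4, t_start = 1000,
                              t_end = 9000)
  expect_equal(s4$t_ms, c(1000, 3666.666667, 6333.333333, 9000),
               tolerance = 1e-9)

  sl <- build_lesion_schedule(net, order = "listed")
  grp <- ifelse(conns$source[match(sl$conn_id, conns$conn_id)] == "DG", 3,
                ifelse(grepl("^P", conns$target[match(sl$conn_id,
                                                      conns$conn_id)]), 1, 2))
  expect_true(all(diff(grp) >= 0))

  expect_error(build_lesion_schedule(net, n_deletions = 100), "44")
  expect_true(all(diff(build_lesion_schedule(net)$t_ms) >= 0))
})

test_that("lesions accumulate monotonically and irreversibly", {
  net <- build_default_network()
  sched <- build_lesion_schedule(net, n_deletions = 10, t_start = 100,
                                 t_end = 1000)
  expect_equal(sum(apply_lesion(net, sched, 50)$connections$deleted), 0)
  mid <- apply_lesion(net, sched, 500)
  expect_equal(sum(mid$connections$deleted), sum(sched$t_ms <= 500))
  # applying an earlier time afterwards cannot resurrect a synapse
  expect_equal(sum(apply_lesion(mid, sched, 50)$connections$deleted),
               sum(mid$connections$deleted))
  expect_equal(sum(apply_lesion(net, sched, 2000)$connections$deleted), 10)
})
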