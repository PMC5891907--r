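test_that("validate_model accepts the built models and returns no violations", {
  expect_length(validate_model(build_intracellular_model()), 0)
  io <- derive_io_tables()
  expect_length(validate_model(build_tissue_model(io$ros_by_damps, io$ccl2)), 0)
})

test_that("validate_model reports incomplete tables and inadmissible outputs", {
  m <- build_intracellular_model()
  # drop the (DAMPs=2, CD13=0) row of the TRIF table, bypassing the
  # totality-checking constructor
  broken <- m
  broken$rules$TRIF$levels <- broken$rules$TRIF$levels[-5]
  v <- validate_model(broken)
  expect_length(v, 1)
  expect_match(v, "incomplete table.*TRIF")

  bad_out <- m
  bad_out$rules$CCL2$levels[2] <- 3L  # CCL2 is a 3-level node
  v <- validate_model(bad_out)
  expect_length(v, 1)
  expect_match(v, "inadmissible output.*CCL2")
})

test_that("validate_model flags duplicate names, missing rules and rogue input rules", {
  nodes <- rbind(node_spec("x", 2), node_spec("x", 2))
  v <- validate_model(logical_model(nodes, list(
    rule_table("x", "x", 2L, 0:1))))
  expect_true(any(grepl("duplicate node name: 'x'", v)))

  m <- logical_model(rbind(node_spec("a", 2), node_spec("b", 2)),
                     list(rule_table("a", "b", 2L, c(0L, 1L))))
  expect_match(validate_model(m), "non-input node 'b' has no rule")

  m2 <- logical_model(node_spec("a", 2, role = "input"),
                      list(rule_table("a", "a", 2L, c(1L, 0L))))
  expect_match(validate_model(m2), "input node 'a' has a non-identity rule")
})

test_that("synchronous step evaluates rules on the current state with clamps dominant", {
  cell <- build_intracellular_model()
  zero <- model_state(cell, default = 0L)
  expect_identical(synchronous_step(cell, zero), zero)

  # from the quiescent state with DAMPs forced on, the direct DAMP targets
  # (CD13, MyD88) activate, and TRIF transiently hyperactivates because CD13
  # has not yet caught up (its brake reads as absent this step)
  nxt <- synchronous_step(cell, zero, clamps = c(DAMPs = 1L, M2 = 0L))
  expect_identical(nxt[["CD13"]], 1L)
  expect_identical(nxt[["MyD88"]], 1L)
  expect_identical(nxt[["DAMPs"]], 1L)
  expect_identical(nxt[["TRIF"]], 2L)
  downstream <- c("IRF3", "IFNb", "ROS", "pIRAK", "NFkB", "CCL2")
  expect_true(all(nxt[downstream] == 0L))
})

test_that("the inflamed tissue steady state is a fixed point of one step", {
  io <- derive_io_tables()
  tm <- build_tissue_model(io$ros_by_damps, io$ccl2)
  s <- model_state(tm, DAMPs = 2L, M1 = 2L, M2 = 0L, Injury = 1L,
                   ROS = 1L, CCL2 = 2L)
  expect_identical(synchronous_step(tm, s), s)
})

test_that("invalid states and unknown clamp nodes are rejected by name", {
  cell <- build_intracellular_model()
  zero <- model_state(cell, default = 0L)
  bad <- zero
  bad[["TRIF"]] <- 3L
  expect_error(synchronous_step(cell, bad), "TRIF")
  expect_error(synchronous_step(cell, zero[-1]), "DAMPs")
  expect_error(synchronous_step(cell, zero, clamps = c(TLR4 = 0L)), "TLR4")
  expect_error(synchronous_step(cell, zero, clamps = c(TRIF = 0L, TRIF = 1L)),
               "conflicting clamp")
})

test_that("run_to_attractor finds fixed points and cycles deterministically", {
  neg <- negation_model()
  res <- run_to_attractor(neg, c(a = 0L))
  expect_identical(res$attractor$kind, "cycle")
  expect_identical(nrow(res$attractor$states), 2L)

  # clamped intracellular model: same fixed point from arbitrary internal
  # initializations (feed-forward wiring)
  cell <- build_intracellular_model()
  expected <- intracellular_fixed_point(1L, 0L)
  for (seed in 1:5) {
    init <- random_state(cell, seed = seed)
    init[c("DAMPs", "M2")] <- c(1L, 0L)
    res <- run_to_attractor(cell, init, clamps = c(DAMPs = 1L, M2 = 0L))
    expect_identical(res$attractor$kind, "fixed_point")
    expect_identical(res$attractor$states[1, ], expected)
  }

  # identical calls yield identical trajectories
  io <- derive_io_tables()
  tm <- build_tissue_model(io$ros_by_damps, io$ccl2)
  s0 <- model_state(tm, DAMPs = 0L, M1 = 0L, M2 = 0L, Injury = 1L,
                    ROS = 0L, CCL2 = 0L)
  r1 <- run_to_attractor(tm, s0)
  r2 <- run_to_attractor(tm, s0)
  expect_identical(r1, r2)
})

test_that("injury alone ignites DAMPs and macrophage recruitment before resolving", {
  io <- derive_io_tables()
  tm <- build_tissue_model(io$ros_by_damps, io$ccl2)
  s0 <- model_state(tm, DAMPs = 0L, M1 = 0L, M2 = 0L, Injury = 1L,
                    ROS = 0L, CCL2 = 0L)
  res <- run_to_attractor(tm, s0)
  expect_identical(res$attractor$kind, "fixed_point")
  expect_true(all(res$attractor$states[1, ] == 0L))
  traj <- res$trajectory
  expect_gt(max(traj[, "DAMPs"]), 0L)
  expect_gt(max(traj[, "CCL2"]), 0L)
  expect_gt(max(traj[, "M1"]), 0L)
})

test_that("run_to_attractor errors when max_steps is too small to revisit", {
  cell <- build_intracellular_model()
  init <- model_state(cell, DAMPs = 2L, M2 = 0L, default = 0L)
  expect_error(run_to_attractor(cell, init, max_steps = 1L), "max_steps")
})

test_that("exhaustive enumeration partitions the space exactly", {
  cm <- constant_model(3L)
  rep <- enumerate_attractors(cm)
  expect_length(rep$attractors, 1)
  expect_identical(rep$basins$count, 8L)
  expect_identical(rep$basins$percent, "100.00%")

  neg <- negation_model()
  rep <- enumerate_attractors(neg)
  expect_length(rep$attractors, 1)
  expect_identical(rep$attractors[[1]]$kind, "cycle")
  expect_identical(rep$basins$count, 2L)

  expect_error(enumerate_attractors(cm, enumerate = character(0)),
               "empty enumeration space")
})

test_that("restricted enumeration fixes non-enumerated nodes at stated levels", {
  cell <- build_intracellular_model()
  internal <- cell$nodes$name[cell$nodes$role != "input"]
  rep <- enumerate_attractors(cell, enumerate = c("DAMPs", "M2"),
                              fixed = setNames(rep(0L, length(internal)), internal))
  expect_identical(rep$total, 6L)
  expect_length(rep$attractors, 6)
  expect_identical(unique(rep$basins$count), 1L)
  expect_identical(sum(rep$basins$count), rep$total)
})

test_that("percentages are truncated, not rounded", {
  expect_identical(format_percent_trunc(1, 6), "16.66%")
  expect_identical(format_percent_trunc(12, 216), "5.55%")
  expect_identical(format_percent_trunc(200, 216), "92.59%")
  expect_identical(format_percent_trunc(4, 216), "1.85%")
  expect_identical(format_percent_trunc(1, 4), "25.00%")
  expect_identical(format_percent_trunc(4, 6, digits = 0), "66%")
  expect_identical(format_percent_trunc(2, 6, digits = 0), "33%")
  expect_identical(percent_trunc(200, 216), 92.59)
  expect_identical(percent_trunc(4, 6, digits = 0), 66)
})

test_that("clamped nodes never change along any trajectory", {
  cell <- build_intracellular_model()
  for (seed in 1:10) {
    init <- random_state(cell, seed = seed)
    res <- run_to_attractor(cell, init, clamps = c(MyD88 = 0L, DAMPs = 2L))
    expect_true(all(res$trajectory[, "MyD88"] == 0L))
    expect_true(all(res$trajectory[, "DAMPs"] == 2L))
  }
})
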