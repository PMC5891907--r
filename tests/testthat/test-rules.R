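test_that("tissue-scale update rules encode resolution, persistence and overload", {
  # injury: resolved by M2, persists otherwise, never arises spontaneously
  cases <- list(list(1, 1, 0), list(1, 0, 1), list(0, 0, 0), list(0, 1, 0))
  for (c in cases) expect_identical(update_Injury(c[[1]], c[[2]]), as.integer(c[[3]]))

  # DAMPs: (injury, ros, m2, prev) -> level
  cases <- list(
    list(1, 1, 0, 0, 2),  # both sources, no M2: overwhelming
    list(1, 1, 0, 2, 2),
    list(0, 1, 0, 2, 2),  # single source but already-overwhelming load holds
    list(1, 0, 0, 2, 2),
    list(1, 0, 0, 0, 1),  # single source, no M2: medium
    list(0, 1, 0, 1, 1),
    list(0, 0, 1, 2, 0),  # no source: cleared regardless of M2 and history
    list(0, 0, 0, 1, 0),
    list(1, 0, 1, 0, 0),  # single source cleared by M2
    list(0, 1, 1, 2, 0),
    list(1, 1, 1, 2, 1)   # both sources with M2: partial resolution
  )
  for (c in cases) {
    expect_identical(update_DAMPs(c[[1]], c[[2]], c[[3]], c[[4]]),
                     as.integer(c[[5]]))
  }

  # M1 tracks CCL2 level for level
  for (l in 0:2) expect_identical(update_M1(l), l)

  # M2 only from a standard M1 population
  expect_identical(update_M2(0L), 0L)
  expect_identical(update_M2(1L), 1L)
  expect_identical(update_M2(2L), 0L)
})

test_that("intracellular update rules encode the two TLR4 arms", {
  # CD13 active at any DAMP level
  expect_identical(vapply(0:2, update_CD13, integer(1)), c(0L, 1L, 1L))

  # TRIF: inactive without DAMPs; hyperactive without CD13 or at high DAMPs
  expect_identical(update_TRIF(0, 1), 0L)
  expect_identical(update_TRIF(1, 1), 1L)
  expect_identical(update_TRIF(1, 0), 2L)
  expect_identical(update_TRIF(2, 1), 2L)
  expect_identical(update_TRIF(2, 0), 2L)

  # level-for-level propagation
  for (l in 0:2) expect_identical(propagate_level(l), l)

  # ROS only from hyperactivated interferon response
  expect_identical(vapply(0:2, update_ROS_cell, integer(1)), c(0L, 0L, 1L))

  # NF-kB: M2 silences a standard response, not an overwhelming one
  expect_identical(update_NFkB(1, 1), 0L)
  expect_identical(update_NFkB(0, 1), 0L)
  expect_identical(update_NFkB(2, 1), 2L)
  expect_identical(update_NFkB(1, 0), 1L)
})

test_that("the intracellular model has 11 nodes, acyclic wiring and the TRIF table", {
  cell <- build_intracellular_model()
  expect_identical(nrow(cell$nodes), 11L)
  expect_length(validate_model(cell), 0)
  expect_true(igraph::is_dag(model_graph(cell)))

  trif <- as.data.frame(cell$rules$TRIF)
  expect_identical(names(trif), c("DAMPs", "CD13", "TRIF"))
  expect_identical(trif$TRIF, c(0L, 0L, 2L, 1L, 2L, 2L))
})

test_that("exactly the six reference rows are intracellular fixed points", {
  cell <- build_intracellular_model()
  ref <- read.delim(system.file("extdata", "reference",
                                "intracellular_steady_states.tsv",
                                package = "tlr4net"),
                    comment.char = "#")
  for (i in seq_len(nrow(ref))) {
    fp <- intracellular_fixed_point(ref$DAMPs[i], ref$M2[i])
    row <- setNames(as.integer(ref[i, cell$nodes$name]), cell$nodes$name)
    expect_identical(fp, row)
    expect_identical(synchronous_step(cell, fp,
                                      clamps = c(DAMPs = row[["DAMPs"]],
                                                 M2 = row[["M2"]])),
                     fp)
  }
  # and no other state over the six input combinations is one
  rep <- intracellular_attractors(space = "inputs")
  expect_length(rep$attractors, 6)
})

test_that("tissue model builder validates its supplied input/output tables", {
  io <- derive_io_tables()
  tm <- build_tissue_model(io$ros_by_damps, io$ccl2)
  expect_identical(nrow(tm$nodes), 6L)

  # the three published fixed points
  fps <- list(c(0L, 0L, 0L, 0L, 0L, 0L),
              c(2L, 2L, 0L, 1L, 1L, 2L),
              c(2L, 2L, 0L, 0L, 1L, 2L))
  for (fp in fps) {
    s <- setNames(fp, tm$nodes$name)
    expect_identical(synchronous_step(tm, s), s)
  }

  # mis-keyed and mis-targeted tables are rejected
  expect_error(build_tissue_model(io$ccl2, io$ccl2), "ros_table")
  bad <- rule_table("ROS", "Injury", 2L, c(0L, 1L))
  expect_error(build_tissue_model(bad, io$ccl2), "ROS")
})
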