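test_that("intracellular fixed points match the signaling logic under clamps", {
  fp <- intracellular_fixed_point(1L, 0L)
  expect_identical(fp[c("ROS", "CCL2", "TRIF", "CD13", "IRF3", "IFNb",
                        "MyD88", "pIRAK", "NFkB")],
                   c(ROS = 0L, CCL2 = 1L, TRIF = 1L, CD13 = 1L, IRF3 = 1L,
                     IFNb = 1L, MyD88 = 1L, pIRAK = 1L, NFkB = 1L))

  fp <- intracellular_fixed_point(2L, 1L)
  expect_identical(fp[c("ROS", "CCL2", "TRIF", "CD13", "IRF3", "IFNb",
                        "MyD88", "pIRAK", "NFkB")],
                   c(ROS = 1L, CCL2 = 2L, TRIF = 2L, CD13 = 1L, IRF3 = 2L,
                     IFNb = 2L, MyD88 = 2L, pIRAK = 2L, NFkB = 2L))

  # losing CD13's endocytic brake hyperactivates the TRIF arm at medium DAMPs
  fp <- intracellular_fixed_point(1L, 0L, clamps = c(CD13 = 0L))
  expect_identical(fp[c("TRIF", "IRF3", "IFNb", "ROS")],
                   c(TRIF = 2L, IRF3 = 2L, IFNb = 2L, ROS = 1L))

  # independence of internal initialization (feed-forward wiring)
  cell <- build_intracellular_model()
  for (seed in 1:8) {
    init <- random_state(cell, seed = 100 + seed)
    fp <- intracellular_fixed_point(1L, 1L, model = cell,
                                    init = init[!names(init) %in% c("DAMPs", "M2")])
    expect_identical(fp, intracellular_fixed_point(1L, 1L))
  }
})

test_that("derived input/output tables match the reference and respond to knockouts", {
  io <- derive_io_tables()
  expect_false(is.null(io$ros_by_damps))
  expect_identical(io$ros_by_damps$levels, c(0L, 0L, 1L))
  expect_identical(io$ccl2$levels, c(0L, 0L, 1L, 0L, 2L, 2L))

  # MyD88 knockout abolishes CCL2 output over every input
  io_ko <- derive_io_tables(clamps = c(MyD88 = 0L))
  expect_true(all(io_ko$ccl2$levels == 0L))
  # ...but leaves the TRIF-arm ROS table intact
  expect_identical(io_ko$ros$levels, io$ros$levels)

  # CD13 knockout makes medium DAMPs ROS-genic (hyperactivated TRIF arm)
  io_cd13 <- derive_io_tables(clamps = c(CD13 = 0L))
  expect_identical(io_cd13$ros_by_damps$levels, c(0L, 1L, 1L))
})

test_that("the two-scale step is quiescent at zero and fixed at the inflamed state", {
  cell <- build_intracellular_model()
  zero <- c(DAMPs = 0L, M1 = 0L, M2 = 0L, Injury = 0L, ROS = 0L, CCL2 = 0L)
  res <- multiscale_step(zero)
  expect_identical(res$tissue, zero)

  inflamed <- c(DAMPs = 2L, M1 = 2L, M2 = 0L, Injury = 1L, ROS = 1L, CCL2 = 2L)
  res <- multiscale_step(inflamed)
  expect_identical(res$tissue, inflamed)

  # M2 presence extinguishes injury in one step
  s <- c(DAMPs = 1L, M1 = 1L, M2 = 1L, Injury = 1L, ROS = 0L, CCL2 = 0L)
  res <- multiscale_step(s)
  expect_identical(res$tissue[["Injury"]], 0L)

  # composition consistency: the merged intracellular part is itself a fixed
  # point under further intracellular iteration
  for (s0 in list(zero, inflamed, s)) {
    res <- multiscale_step(s0)
    held <- c(DAMPs = res$cell[["DAMPs"]], M2 = res$cell[["M2"]])
    expect_identical(synchronous_step(cell, res$cell, clamps = held), res$cell)
  }
})

test_that("tissue enumeration yields three fixed points whose basins partition 216", {
  rep <- tissue_attractors()
  expect_identical(rep$total, 216L)
  expect_length(rep$attractors, 3)
  expect_true(all(vapply(rep$attractors, function(a) a$kind, character(1)) ==
                    "fixed_point"))
  expect_identical(sum(rep$basins$count), 216L)
  expect_equal(sum(rep$basins$fraction), 1)
  df <- as.data.frame(rep)
  df <- df[order(-df$count), ]
  expect_identical(unname(as.matrix(df[, c("DAMPs", "M1", "M2", "Injury",
                                           "ROS", "CCL2")])),
                   rbind(c(0L, 0L, 0L, 0L, 0L, 0L),
                         c(2L, 2L, 0L, 1L, 1L, 2L),
                         c(2L, 2L, 0L, 0L, 1L, 2L)))
})

test_that("knockout panel reproduces the published resolution phenotypes", {
  kp <- knockout_panel()
  s <- kp$summary
  expect_identical(s$genotype, c("WT", "MyD88", "IRAK", "CCL2", "TRIF", "CD13"))
  expect_identical(s$resolved_pct[s$genotype %in% c("WT", "TRIF", "CD13")],
                   rep("100%", 3))
  expect_identical(s$resolved_pct[s$genotype %in% c("MyD88", "IRAK", "CCL2")],
                   rep("66%", 3))

  # the failing completions are exactly the M2-absent corners (0,0) and (2,0)
  for (g in c("MyD88", "IRAK", "CCL2")) {
    unres <- kp$details[kp$details$genotype == g &
                          kp$details$outcome == "unresolved", ]
    expect_equal(unres[order(unres$M1), c("M1", "M2")],
                 data.frame(M1 = c(0L, 2L), M2 = c(0L, 0L)),
                 ignore_attr = TRUE)
    expect_true(all(unres$terminal_DAMPs == 1L))
  }

  # TRIF knockout resolves from every completion
  expect_true(all(kp$details$outcome[kp$details$genotype == "TRIF"] ==
                    "resolved"))
  expect_error(knockout_panel("ATF3"), "unknown genotype")
})

test_that("subsetted panels and CD13-knockout trajectories reach resolution", {
  kp <- knockout_panel(c("WT", "CD13"))
  expect_identical(kp$summary$resolved_pct, c("100%", "100%"))
  expect_true(all(kp$details$outcome == "resolved"))
})
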