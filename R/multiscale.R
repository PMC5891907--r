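#' Two-scale coupling of the injury model
#'
#' The intracellular signaling network equilibrates much faster than tissue
#' composition changes, so the coupled model advances in two alternating
#' phases: (1) hold the tissue-provided inputs DAMPs and M2 fixed and iterate
#' the intracellular model to its fixed point; (2) substitute that fixed
#' point's ROS and CCL2 outputs into the tissue state and apply one
#' synchronous tissue step. Because the intracellular fixed point is a pure
#' function of (DAMPs, M2) and the clamps, phase (1) can be precomputed as a
#' pair of input/output transition tables, and the whole two-scale step is
#' then one synchronous step of the six-node tissue model whose ROS and CCL2
#' rules are those tables.
#'
#' @name multiscale
NULL

#' Intracellular fixed point for given tissue inputs
#'
#' Iterates the (possibly clamped) intracellular model with DAMPs and M2 held
#' until it no longer changes. With the inputs held the wiring is
#' feed-forward, so the fixed point exists, is unique, and is independent of
#' the internal initialization; internal nodes start at 0 by default.
#'
#' @param damps,m2 Input levels (DAMPs 0..2, M2 0..1).
#' @param clamps Optional named integer vector of clamped levels
#'   (knockout = 0), applied at every step including initialization.
#' @param model The intracellular model; defaults to
#'   [build_intracellular_model()].
#' @param init Optional named integer vector of initial internal levels.
#' @return Named integer state vector (the fixed point), in model node order.
#' @export
intracellular_fixed_point <- function(damps, m2, clamps = NULL,
                                      model = build_intracellular_model(),
                                      init = NULL) {
  start <- model_state(model, DAMPs = as.integer(damps), M2 = as.integer(m2),
                       default = 0L)
  if (!is.null(init)) start[names(init)] <- as.integer(init)
  check_state(model, start)
  res <- run_to_attractor(model, start, clamps = clamps,
                          max_steps = nrow(model$nodes) + 2L)
  if (res$attractor$kind != "fixed_point") {
    stop("intracellular model did not reach a fixed point")  # unreachable: feed-forward
  }
  stats::setNames(as.integer(res$attractor$states[1L, ]),
                  colnames(res$attractor$states))
}

#' Derive the intracellular input/output transition tables
#'
#' For each of the six (DAMPs, M2) input combinations, records the ROS and
#' CCL2 levels of the intracellular fixed point. Internally both tables are
#' keyed on (DAMPs, M2); when ROS turns out independent of M2 (true for the
#' unperturbed model) a collapsed table keyed on DAMPs alone is also provided
#' for display and for building the tissue model in its conventional form.
#'
#' @inheritParams intracellular_fixed_point
#' @return An object of class `io_tables`: list with `ros`, `ccl2`
#'   (rule tables keyed on DAMPs, M2), `ros_by_damps` (rule table keyed on
#'   DAMPs, or `NULL` if ROS depends on M2 under the given clamps), and
#'   `clamps`.
#' @export
derive_io_tables <- function(clamps = NULL, model = build_intracellular_model()) {
  cards <- c(3L, 2L)
  tuples <- rule_tuples(cards)
  ros <- integer(nrow(tuples))
  ccl2 <- integer(nrow(tuples))
  for (i in seq_len(nrow(tuples))) {
    fp <- intracellular_fixed_point(tuples[i, 1L], tuples[i, 2L],
                                    clamps = clamps, model = model)
    ros[i] <- fp[["ROS"]]
    ccl2[i] <- fp[["CCL2"]]
  }
  ros_tab <- rule_table("ROS", c("DAMPs", "M2"), cards, ros)
  ccl2_tab <- rule_table("CCL2", c("DAMPs", "M2"), cards, ccl2)
  by_damps <- matrix(ros, ncol = 2L, byrow = TRUE)  # rows = DAMPs level
  ros_collapsed <- NULL
  if (all(by_damps[, 1L] == by_damps[, 2L])) {
    ros_collapsed <- rule_table("ROS", "DAMPs", 3L, by_damps[, 1L])
  }
  structure(list(ros = ros_tab, ccl2 = ccl2_tab, ros_by_damps = ros_collapsed,
                 clamps = check_clamps(model, clamps)),
            class = "io_tables")
}

#' @export
print.io_tables <- function(x, ...) {
  cat("Intracellular input/output transition tables")
  if (length(x$clamps)) {
    cat(" (clamps: ", paste(names(x$clamps), x$clamps, sep = "=", collapse = ", "),
        ")", sep = "")
  }
  cat("\n\n")
  print(if (is.null(x$ros_by_damps)) x$ros else x$ros_by_damps)
  cat("\n")
  print(x$ccl2)
  invisible(x)
}

## Tissue model under a set of knockout clamps: ROS/CCL2 rules are the clamped
## IO tables, and clamps on nodes that also exist at the tissue scale (DAMPs,
## M2, ROS, CCL2) are carried over so a knockout holds at both scales.
tissue_model_under <- function(clamps = NULL,
                               cell_model = build_intracellular_model()) {
  io <- derive_io_tables(clamps, model = cell_model)
  tm <- build_tissue_model(io$ros, io$ccl2)
  tcl <- clamps[names(clamps) %in% tm$nodes$name]
  list(model = tm, io = io,
       clamps = if (length(tcl)) tcl else NULL)
}

#' One two-scale update step
#'
#' Computes the intracellular fixed point from the current tissue DAMPs and
#' M2, substitutes its ROS and CCL2 outputs, applies one synchronous tissue
#' step, and merges the result with the fixed point into a global state.
#'
#' @param tissue_state Named integer vector over the tissue nodes
#'   DAMPs, M1, M2, Injury, ROS, CCL2.
#' @param clamps Optional named integer vector of knockout clamps, applied at
#'   both scales.
#' @return List with `tissue` (the next tissue state) and `cell` (the
#'   intracellular fixed point, computed from the *current* DAMPs and M2, that
#'   produced it); together they form the global state at the next time step.
#' @export
multiscale_step <- function(tissue_state, clamps = NULL) {
  tu <- tissue_model_under(clamps)
  check_state(tu$model, tissue_state)
  cell <- intracellular_fixed_point(tissue_state[["DAMPs"]], tissue_state[["M2"]],
                                    clamps = clamps)
  nxt <- synchronous_step(tu$model, tissue_state, clamps = tu$clamps)
  list(tissue = nxt, cell = cell)
}

#' Exhaustive tissue-level attractor analysis
#'
#' Enumerates every tissue configuration (216 = 3 x 3 x 2 x 2 x 2 x 3 in the
#' unperturbed model; clamped nodes are fixed, shrinking the space) and runs
#' each to its attractor under the two-scale step.
#'
#' @inheritParams multiscale_step
#' @return A `basin_report` (see [enumerate_attractors()]).
#' @export
tissue_attractors <- function(clamps = NULL) {
  tu <- tissue_model_under(clamps)
  enumerate_attractors(tu$model, clamps = tu$clamps)
}

#' Intracellular attractor analysis
#'
#' Enumerates initial states of the intracellular model and reports the fixed
#' points with their basins. `space = "inputs"` enumerates the six
#' (DAMPs, M2) input combinations with internal nodes started at 0;
#' `space = "full"` enumerates every internal initialization as well. The
#' wiring is feed-forward given the inputs, so both spaces yield the same six
#' fixed points with equal basin shares; the report records which space was
#' used.
#'
#' @inheritParams intracellular_fixed_point
#' @param space `"inputs"` (default, 6 initializations) or `"full"`
#'   (52,488 initializations).
#' @return A `basin_report` with an extra `space` field.
#' @export
intracellular_attractors <- function(clamps = NULL, space = c("inputs", "full"),
                                     model = build_intracellular_model()) {
  space <- match.arg(space)
  rep <- if (space == "inputs") {
    fixed <- stats::setNames(rep(0L, sum(model$nodes$role != "input")),
                             model$nodes$name[model$nodes$role != "input"])
    fixed <- fixed[!names(fixed) %in% names(clamps)]
    enumerate_attractors(model, clamps = clamps,
                         enumerate = c("DAMPs", "M2"), fixed = fixed)
  } else {
    enumerate_attractors(model, clamps = clamps)
  }
  rep$space <- space
  rep
}
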