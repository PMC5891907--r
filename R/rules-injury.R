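#' Update rules of the sterile-injury model
#'
#' The model couples two scales. At the tissue scale, injury releases
#' danger-associated molecular patterns (DAMPs, levels 0/1/2 = low/medium/high)
#' that recruit pro-inflammatory M1 macrophages via the chemokine CCL2; M1
#' cells differentiate into pro-healing M2 macrophages, which resolve injury
#' and damp further DAMP release. Inside each macrophage, DAMPs trigger two
#' TLR4 signaling arms: the plasma-membrane MyD88-dependent arm
#' (MyD88 -> pIRAK -> NF-kB -> CCL2) and the endosomal MyD88-independent arm
#' (CD13-regulated, TRIF -> IRF3 -> IFN-beta -> ROS). High IFN-beta drives
#' reactive oxygen species (ROS) that feed back into tissue damage.
#'
#' Each `update_*` function gives one node's next level from the current
#' levels of its regulators; [build_intracellular_model()] and
#' [build_tissue_model()] tabulate them into extensional [rule_table()]s.
#'
#' @name injury-rules
NULL

#' @describeIn injury-rules Injury is resolved (set to 0) by pro-healing M2
#'   macrophages when present; otherwise it persists at its previous level.
#'   Injury never arises spontaneously.
#' @param injury_prev,m2,injury,ros,damps_prev,ccl2,m1,damps,cd13,x,ifnb,pirak
#'   Current integer levels of the named regulators.
#' @export
update_Injury <- function(injury_prev, m2) {
  if (m2 == 1L && injury_prev == 1L) 0L else as.integer(injury_prev)
}

#' @describeIn injury-rules DAMP release: none without a source (no injury and
#'   no ROS); a single source (injury XOR ROS) is cleared by M2, yields medium
#'   DAMPs without M2 — except that an already-overwhelming DAMP load (level 2)
#'   stays at 2; both sources give medium DAMPs with M2 and high DAMPs without.
#' @export
update_DAMPs <- function(injury, ros, m2, damps_prev) {
  single <- (injury == 1L) != (ros == 1L)
  if (injury == 0L && ros == 0L) {
    0L
  } else if (single && m2 == 1L) {
    0L
  } else if (single && m2 == 0L) {
    if (damps_prev == 2L) 2L else 1L
  } else if (m2 == 1L) {  # injury and ROS both present
    1L
  } else {
    2L
  }
}

#' @describeIn injury-rules M1 macrophage infiltration follows the CCL2 level
#'   (no recruitment without chemokine; more chemokine, more M1).
#' @export
update_M1 <- function(ccl2) as.integer(ccl2)

#' @describeIn injury-rules M2 macrophages differentiate from a standard M1
#'   population (M1 = 1); absent M1 gives no M2, and overwhelming M1
#'   infiltration (M1 = 2) overcomes M2.
#' @export
update_M2 <- function(m1) if (m1 == 1L) 1L else 0L

#' @describeIn injury-rules CD13 is phosphorylated/active whenever DAMPs are
#'   present at any level.
#' @export
update_CD13 <- function(damps) if (damps >= 1L) 1L else 0L

#' @describeIn injury-rules TRIF activation: none without DAMPs; standard
#'   activation at medium DAMPs with active CD13; hyperactivation at medium
#'   DAMPs when CD13 is absent (loss of its endocytic brake) and at high DAMPs
#'   regardless of CD13.
#' @export
update_TRIF <- function(damps, cd13) {
  if (damps == 0L) 0L
  else if (damps == 2L) 2L
  else if (cd13 == 1L) 1L
  else 2L
}

#' @describeIn injury-rules Level-for-level propagation along an unbranched
#'   signaling edge; instantiated for IRF3 <- TRIF, IFN-beta <- IRF3,
#'   MyD88 <- DAMPs, pIRAK <- MyD88 and CCL2 <- NF-kB.
#' @export
propagate_level <- function(x) as.integer(x)

#' @describeIn injury-rules Intracellular ROS production requires a
#'   hyperactivated interferon response (IFN-beta = 2); lower IFN-beta levels
#'   produce none.
#' @export
update_ROS_cell <- function(ifnb) if (ifnb == 2L) 1L else 0L

#' @describeIn injury-rules NF-kB follows pIRAK, except that M2 macrophages
#'   silence a standard response (pIRAK at 0 or 1); an overwhelming response
#'   (pIRAK = 2) escapes M2 damping.
#' @export
update_NFkB <- function(pirak, m2) {
  if (m2 == 1L && pirak <= 1L) 0L else as.integer(pirak)
}

## Node tables in the column order used throughout the reports.
intracellular_nodes <- function() {
  rbind(
    node_spec("DAMPs", 3, "intracellular", "input"),
    node_spec("M2",    2, "intracellular", "input"),
    node_spec("ROS",   2, "intracellular", "output"),
    node_spec("CCL2",  3, "intracellular", "output"),
    node_spec("TRIF",  3, "intracellular", "internal"),
    node_spec("CD13",  2, "intracellular", "internal"),
    node_spec("IRF3",  3, "intracellular", "internal"),
    node_spec("IFNb",  3, "intracellular", "internal"),
    node_spec("MyD88", 3, "intracellular", "internal"),
    node_spec("pIRAK", 3, "intracellular", "internal"),
    node_spec("NFkB",  3, "intracellular", "internal")
  )
}

tissue_nodes <- function() {
  rbind(
    node_spec("DAMPs",  3, "tissue", "internal"),
    node_spec("M1",     3, "tissue", "internal"),
    node_spec("M2",     2, "tissue", "internal"),
    node_spec("Injury", 2, "tissue", "internal"),
    node_spec("ROS",    2, "tissue", "internal"),
    node_spec("CCL2",   3, "tissue", "internal")
  )
}

#' Build the intracellular TLR4 signaling model
#'
#' Eleven nodes: the boundary inputs DAMPs (3 levels) and M2 (2 levels), held
#' constant during sub-model iteration; the MyD88-independent arm CD13, TRIF,
#' IRF3, IFN-beta terminating in the output ROS; and the MyD88-dependent arm
#' MyD88, pIRAK, NF-kB terminating in the output CCL2. With the inputs held,
#' the wiring is feed-forward (acyclic), so every input combination has a
#' unique fixed point reached within the depth of the network.
#'
#' @return A validated [logical_model()].
#' @export
build_intracellular_model <- function() {
  m <- logical_model(intracellular_nodes(), list(
    rule_from_function("CD13",  "DAMPs",             3L,        update_CD13),
    rule_from_function("TRIF",  c("DAMPs", "CD13"),  c(3L, 2L), update_TRIF),
    rule_from_function("IRF3",  "TRIF",              3L,        propagate_level),
    rule_from_function("IFNb",  "IRF3",              3L,        propagate_level),
    rule_from_function("ROS",   "IFNb",              3L,        update_ROS_cell),
    rule_from_function("MyD88", "DAMPs",             3L,        propagate_level),
    rule_from_function("pIRAK", "MyD88",             3L,        propagate_level),
    rule_from_function("NFkB",  c("pIRAK", "M2"),    c(3L, 2L), update_NFkB),
    rule_from_function("CCL2",  "NFkB",              3L,        propagate_level)
  ))
  stopifnot(length(validate_model(m)) == 0L)
  m
}

#' Build the tissue-scale model
#'
#' Six nodes: DAMPs, M1, M2, Injury, and the two intracellular outputs ROS and
#' CCL2 whose update rules are *supplied* as input/output transition tables
#' derived from the intracellular model's fixed points (see
#' [derive_io_tables()]). The ROS table may be keyed on DAMPs alone or on
#' (DAMPs, M2); the CCL2 table is keyed on (DAMPs, M2).
#'
#' @param ros_table A [rule_table()] with target `"ROS"` and inputs among
#'   `DAMPs`, `M2`.
#' @param ccl2_table A [rule_table()] with target `"CCL2"` and inputs among
#'   `DAMPs`, `M2`.
#' @return A validated [logical_model()]. Supplied tables that are non-total
#'   or mis-keyed are rejected.
#' @export
build_tissue_model <- function(ros_table, ccl2_table) {
  stopifnot(inherits(ros_table, "rule_table"), inherits(ccl2_table, "rule_table"))
  if (ros_table$target != "ROS" || !all(ros_table$inputs %in% c("DAMPs", "M2"))) {
    stop("ros_table must target ROS with inputs among DAMPs, M2")
  }
  if (ccl2_table$target != "CCL2" || !all(ccl2_table$inputs %in% c("DAMPs", "M2"))) {
    stop("ccl2_table must target CCL2 with inputs among DAMPs, M2")
  }
  m <- logical_model(tissue_nodes(), list(
    rule_from_function("DAMPs", c("Injury", "ROS", "M2", "DAMPs"),
                       c(2L, 2L, 2L, 3L), update_DAMPs),
    rule_from_function("M1", "CCL2", 3L, update_M1),
    rule_from_function("M2", "M1", 3L, update_M2),
    rule_from_function("Injury", c("Injury", "M2"), c(2L, 2L), update_Injury),
    ros_table,
    ccl2_table
  ))
  issues <- validate_model(m)
  if (length(issues)) stop("invalid tissue model: ", paste(issues, collapse = "; "))
  m
}
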