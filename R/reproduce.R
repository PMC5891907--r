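#' One-command reproduction of the model's result tables
#'
#' Each `reproduce_*` function recomputes one of the model's result tables —
#' the TRIF transition table, the intracellular steady states with their
#' basins, the derived ROS/CCL2 input/output tables, the tissue steady states
#' with their basins, and the knockout panel — and compares it cell-by-cell
#' against reference values bundled under `inst/extdata/reference/`. Level
#' cells must match exactly; percent cells are compared after the package's
#' truncation formatting. Expected values live only in the bundled data files,
#' never in comparison code.
#'
#' @name reproduce
NULL

read_reference <- function(file) {
  path <- system.file("extdata", "reference", file, package = "tlr4net",
                      mustWork = TRUE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    check.names = FALSE, colClasses = "character")
}

new_table_artifact <- function(id, computed, expected) {
  rownames(computed) <- NULL
  rownames(expected) <- NULL
  cc <- vapply(computed, as.character, character(nrow(computed)))
  ee <- vapply(expected, as.character, character(nrow(expected)))
  if (nrow(computed) == 1L) { cc <- t(cc); ee <- t(ee) }
  if (!identical(names(computed), names(expected)) ||
      nrow(computed) != nrow(expected)) {
    return(structure(list(id = id, computed = computed, expected = expected,
                          matches = NULL, pass = FALSE,
                          note = "table shape differs from reference"),
                     class = "table_artifact"))
  }
  matches <- cc == ee
  structure(list(id = id, computed = computed, expected = expected,
                 matches = matches, pass = all(matches), note = NULL),
            class = "table_artifact")
}

#' @export
print.table_artifact <- function(x, ...) {
  cat(sprintf("Table artifact '%s': %s\n", x$id,
              if (x$pass) "all cells match reference" else "MISMATCH"))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  if (!x$pass && !is.null(x$matches)) {
    bad <- which(!x$matches, arr.ind = TRUE)
    for (i in seq_len(nrow(bad))) {
      cat(sprintf("  row %d, column '%s': computed %s, expected %s\n",
                  bad[i, 1], colnames(x$matches)[bad[i, 2]],
                  x$computed[bad[i, 1], bad[i, 2]],
                  x$expected[bad[i, 1], bad[i, 2]]))
    }
  }
  invisible(x)
}

#' @describeIn reproduce The TRIF transition table (DAMPs, CD13 -> TRIF),
#'   including hyperactivation (level 2) at medium DAMPs with CD13 absent.
#' @export
reproduce_trif_rule <- function() {
  model <- build_intracellular_model()
  computed <- as.data.frame(model$rules[["TRIF"]])
  new_table_artifact("trif_rule", computed, read_reference("trif_rule.tsv"))
}

#' @describeIn reproduce The six intracellular steady states over the six
#'   (DAMPs, M2) input combinations, each with an equal 16.66% basin.
#' @export
reproduce_intracellular_states <- function() {
  rep <- intracellular_attractors(space = "inputs")
  df <- as.data.frame(rep)
  df <- df[order(df$DAMPs, df$M2), ]
  computed <- df[, c("DAMPs", "M2", "ROS", "CCL2", "TRIF", "CD13", "IRF3",
                     "IFNb", "MyD88", "pIRAK", "NFkB")]
  computed$basin <- df$percent
  new_table_artifact("intracellular_steady_states", computed,
                     read_reference("intracellular_steady_states.tsv"))
}

#' @describeIn reproduce The derived input/output transition tables: ROS as a
#'   function of DAMPs (M2-independent in the unperturbed model) and CCL2 as a
#'   function of (DAMPs, M2). Returns a list of two artifacts.
#' @export
reproduce_io_tables <- function() {
  io <- derive_io_tables()
  if (is.null(io$ros_by_damps)) {
    stop("unperturbed ROS output unexpectedly depends on M2")
  }
  list(
    ros = new_table_artifact("ros_io", as.data.frame(io$ros_by_damps),
                             read_reference("ros_io.tsv")),
    ccl2 = new_table_artifact("ccl2_io", as.data.frame(io$ccl2),
                              read_reference("ccl2_io.tsv"))
  )
}

#' @describeIn reproduce The three tissue steady states over all 216
#'   configurations with basins 92.59%, 5.55% and 1.85%, ordered by basin
#'   size.
#' @export
reproduce_tissue_states <- function() {
  rep <- tissue_attractors()
  df <- as.data.frame(rep)
  df <- df[order(-df$count), ]
  computed <- df[, c("DAMPs", "M1", "M2", "Injury", "ROS", "CCL2")]
  computed$basin <- df$percent
  new_table_artifact("tissue_steady_states", computed,
                     read_reference("tissue_steady_states.tsv"))
}

#' @describeIn reproduce The knockout panel's resolved/unresolved percentages
#'   for all six genotypes.
#' @export
reproduce_knockout_panel <- function() {
  kp <- knockout_panel()
  computed <- kp$summary[, c("genotype", "resolved_pct", "unresolved_pct")]
  new_table_artifact("knockout_panel", computed,
                     read_reference("knockout_panel.tsv"))
}

#' Reproduce every result table
#'
#' Runs all `reproduce_*` comparisons and, optionally, writes each computed
#' table as TSV plus a verdict summary (TSV and JSON) to `outdir`.
#'
#' @param outdir Optional output directory (created if needed).
#' @return List with `artifacts` (named list of `table_artifact`s), `verdicts`
#'   (data frame: artifact id, cells compared, mismatches, pass), and `pass`
#'   (scalar: all artifacts pass).
#' @export
reproduce_all <- function(outdir = NULL) {
  io <- reproduce_io_tables()
  artifacts <- list(
    trif_rule = reproduce_trif_rule(),
    intracellular_steady_states = reproduce_intracellular_states(),
    ros_io = io$ros,
    ccl2_io = io$ccl2,
    tissue_steady_states = reproduce_tissue_states(),
    knockout_panel = reproduce_knockout_panel()
  )
  verdicts <- do.call(rbind, lapply(artifacts, function(a) {
    data.frame(id = a$id,
               cells = if (is.null(a$matches)) NA_integer_ else length(a$matches),
               mismatches = if (is.null(a$matches)) NA_integer_ else sum(!a$matches),
               pass = a$pass,
               stringsAsFactors = FALSE)
  }))
  rownames(verdicts) <- NULL
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (a in artifacts) {
      write_report_tsv(a$computed, file.path(outdir, paste0(a$id, ".tsv")))
    }
    write_report_tsv(verdicts, file.path(outdir, "verdicts.tsv"))
    write_report_json(verdicts, file.path(outdir, "verdicts.json"))
  }
  list(artifacts = artifacts, verdicts = verdicts, pass = all(verdicts$pass))
}
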