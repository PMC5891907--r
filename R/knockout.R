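#' In-silico knockout panel
#'
#' Reproduces the model-validation experiment: for each genotype, the knocked
#' out node is clamped to 0 at both scales for all steps (including
#' initialization), the clamped intracellular fixed point provides the ROS and
#' CCL2 levels of the starting tissue context, and the tissue model is run to
#' its attractor. Genotype contexts (which node is clamped, the starting DAMP
#' level, and the M1/M2 levels where the underlying in-vivo studies determined
#' them) are read from the bundled reference table; where M1 and M2 were not
#' determined, all six (M1, M2) completions are enumerated. Injury is present
#' (level 1) at the start — the panel asks whether an existing injury
#' resolves.
#'
#' A trajectory counts as *resolved* when it reaches the all-zero tissue fixed
#' point (DAMPs low, no residual inflammation) and *unresolved* when its fixed
#' point retains DAMPs at level 1 or 2.
#'
#' @param genotypes Character vector of genotypes to run; any of `"WT"`,
#'   `"MyD88"`, `"IRAK"`, `"CCL2"`, `"TRIF"`, `"CD13"` (default: all six).
#'   The IRAK knockout clamps the pIRAK node, the model's only IRAK species.
#' @return An object of class `knockout_report`: list with `summary` (one row
#'   per genotype: completions run, resolved/unresolved counts, fractions and
#'   integer-truncated percent strings) and `details` (one row per completion
#'   with its (M1, M2) levels and terminal state).
#' @export
knockout_panel <- function(genotypes = NULL) {
  ctx <- knockout_contexts()
  if (is.null(genotypes)) genotypes <- ctx$genotype
  unknown <- setdiff(genotypes, ctx$genotype)
  if (length(unknown)) {
    stop("unknown genotype(s): ", paste(unknown, collapse = ", "))
  }
  cell_model <- build_intracellular_model()
  summary_rows <- list()
  detail_rows <- list()
  for (g in genotypes) {
    row <- ctx[ctx$genotype == g, ]
    clamps <- if (is.na(row$clamp_node)) NULL else stats::setNames(0L, row$clamp_node)
    tu <- tissue_model_under(clamps, cell_model = cell_model)
    completions <- if (is.na(row$m1) || is.na(row$m2)) {
      expand.grid(m1 = 0:2, m2 = 0:1)  # M1 varies fastest, then M2
    } else {
      data.frame(m1 = row$m1, m2 = row$m2)
    }
    resolved <- logical(nrow(completions))
    for (i in seq_len(nrow(completions))) {
      m1 <- completions$m1[i]
      m2 <- completions$m2[i]
      cell <- intracellular_fixed_point(row$damps, m2, clamps = clamps,
                                        model = cell_model)
      start <- model_state(tu$model, DAMPs = row$damps, M1 = m1, M2 = m2,
                           Injury = 1L, ROS = cell[["ROS"]],
                           CCL2 = cell[["CCL2"]])
      res <- run_to_attractor(tu$model, start, clamps = tu$clamps,
                              max_steps = 300L)
      stopifnot(res$attractor$kind == "fixed_point")
      fp <- res$attractor$states[1L, ]
      resolved[i] <- all(fp == 0L)
      detail_rows[[length(detail_rows) + 1L]] <- data.frame(
        genotype = g, M1 = m1, M2 = m2,
        steps = nrow(res$trajectory) - 1L,
        terminal_DAMPs = fp[["DAMPs"]],
        outcome = if (resolved[i]) "resolved" else "unresolved",
        stringsAsFactors = FALSE
      )
    }
    n <- length(resolved)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      genotype = g,
      clamp_node = row$clamp_node,
      n_completions = n,
      resolved = sum(resolved),
      unresolved = sum(!resolved),
      resolved_pct = format_percent_trunc(sum(resolved), n, digits = 0L),
      unresolved_pct = format_percent_trunc(sum(!resolved), n, digits = 0L),
      stringsAsFactors = FALSE
    )
  }
  structure(list(summary = do.call(rbind, summary_rows),
                 details = do.call(rbind, detail_rows)),
            class = "knockout_report")
}

#' @export
print.knockout_report <- function(x, ...) {
  cat("In-silico knockout panel (resolved = all-zero tissue fixed point)\n")
  print(x$summary, row.names = FALSE)
  unres <- x$details[x$details$outcome == "unresolved", , drop = FALSE]
  if (nrow(unres)) {
    cat("\nNon-resolving completions:\n")
    print(unres[, c("genotype", "M1", "M2", "terminal_DAMPs")], row.names = FALSE)
  }
  invisible(x)
}

## Genotype contexts transcribed from the reference validation table:
## clamped node, starting DAMP level, and (M1, M2) where determined (NA =
## enumerate all completions).
knockout_contexts <- function() {
  path <- system.file("extdata", "reference", "knockout_contexts.tsv",
                      package = "tlr4net", mustWork = TRUE)
  ctx <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                           na.strings = "NA")
  ctx$damps <- as.integer(ctx$damps)
  ctx$m1 <- as.integer(ctx$m1)
  ctx$m2 <- as.integer(ctx$m2)
  ctx$clamp_node[!nzchar(ctx$clamp_node) | ctx$clamp_node == "none"] <- NA_character_
  ctx
}
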