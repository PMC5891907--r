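#' Model files and report writers
#'
#' Models are exchanged in a small JSON dialect with three top-level keys:
#' `nodes` (objects with `name`, `cardinality`, `scale`, `role`), `rules`
#' (objects with `target`, `inputs`, and `table` as a list of
#' `[input-tuple, output]` pairs), and `clamps` (objects with `node`,
#' `level`). The writer emits a canonical form — nodes in model order, rules
#' in node order, table rows in mixed-radix tuple order — so write/read/write
#' round-trips are byte-identical. The reader rejects non-total or duplicated
#' tables and unknown node references, reporting every violation with its
#' location.
#'
#' @name model-files
NULL

#' Write a model to a JSON file
#'
#' @param model A [logical_model()].
#' @param path Output file path.
#' @param clamps Optional named integer vector of clamps to record in the
#'   file.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path, clamps = NULL) {
  clamps <- check_clamps(model, clamps)
  nodes <- lapply(seq_len(nrow(model$nodes)), function(i) {
    list(name = model$nodes$name[i],
         cardinality = model$nodes$cardinality[i],
         scale = model$nodes$scale[i],
         role = model$nodes$role[i])
  })
  rule_order <- intersect(model$nodes$name, names(model$rules))
  rules <- lapply(rule_order, function(tgt) {
    r <- model$rules[[tgt]]
    tuples <- rule_tuples(r$input_cards)
    list(target = tgt,
         inputs = I(r$inputs),
         table = lapply(seq_len(nrow(tuples)), function(k) {
           list(I(unname(tuples[k, ])), r$levels[k])
         }))
  })
  clamp_list <- lapply(names(clamps), function(n) list(node = n, level = clamps[[n]]))
  js <- jsonlite::toJSON(list(nodes = nodes, rules = rules, clamps = clamp_list),
                         auto_unbox = TRUE, pretty = 2, digits = NA)
  writeLines(js, path)
  invisible(path)
}

#' Read a model from a JSON file
#'
#' @param path Path to a model file in the package's JSON dialect.
#' @return List with `model` (a validated [logical_model()]) and `clamps`
#'   (named integer vector, possibly empty). Malformed files are rejected with
#'   a diagnostic listing every violation found.
#' @export
read_model <- function(path) {
  js <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                 error = function(e) stop("malformed JSON in '", path, "': ",
                                          conditionMessage(e)))
  probs <- character(0)
  for (key in c("nodes", "rules", "clamps")) {
    if (is.null(js[[key]])) probs <- c(probs, sprintf("missing top-level key '%s'", key))
  }
  if (length(probs)) stop("invalid model file '", path, "': ",
                          paste(probs, collapse = "; "))

  nodes <- do.call(rbind, lapply(seq_along(js$nodes), function(i) {
    n <- js$nodes[[i]]
    for (f in c("name", "cardinality", "scale", "role")) {
      if (is.null(n[[f]])) {
        probs <<- c(probs, sprintf("nodes[%d]: missing field '%s'", i, f))
        return(NULL)
      }
    }
    node_spec(n$name, n$cardinality, n$scale, n$role)
  }))
  if (length(probs)) stop("invalid model file '", path, "': ",
                          paste(probs, collapse = "; "))
  dup <- unique(nodes$name[duplicated(nodes$name)])
  if (length(dup)) {
    stop("invalid model file '", path, "': duplicate node name '",
         paste(dup, collapse = "', '"), "'")
  }
  cards <- stats::setNames(nodes$cardinality, nodes$name)

  rules <- list()
  for (i in seq_along(js$rules)) {
    r <- js$rules[[i]]
    loc <- sprintf("rules[%d]", i)
    tgt <- r$target
    inputs <- as.character(unlist(r$inputs))
    if (is.null(tgt) || !tgt %in% nodes$name) {
      probs <- c(probs, sprintf("%s: unknown or missing target '%s'", loc, tgt))
      next
    }
    unknown <- setdiff(inputs, nodes$name)
    if (length(unknown)) {
      probs <- c(probs, sprintf("%s (%s): unknown input '%s'", loc, tgt, unknown))
      next
    }
    in_cards <- unname(cards[inputs])
    n_tuples <- prod(in_cards)
    levels <- rep(NA_integer_, n_tuples)
    for (k in seq_along(r$table)) {
      entry <- r$table[[k]]
      tuple <- as.integer(unlist(entry[[1]]))
      out <- as.integer(entry[[2]])
      if (length(tuple) != length(inputs) ||
          any(tuple < 0L | tuple >= in_cards)) {
        probs <- c(probs, sprintf("%s (%s) table[%d]: invalid input tuple", loc, tgt, k))
        next
      }
      idx <- mixed_radix_index(tuple, in_cards)
      if (!is.na(levels[idx])) {
        probs <- c(probs, sprintf("%s (%s) table[%d]: duplicate tuple (%s)",
                                  loc, tgt, k, paste(tuple, collapse = ",")))
        next
      }
      levels[idx] <- out
    }
    miss <- which(is.na(levels))
    if (length(miss)) {
      ex <- paste(mixed_radix_tuple(miss[1], in_cards), collapse = ",")
      probs <- c(probs, sprintf("%s (%s): incomplete table, %d missing tuple(s), e.g. (%s)",
                                loc, tgt, length(miss), ex))
      next
    }
    rules[[length(rules) + 1L]] <- rule_table(tgt, inputs, in_cards, levels)
  }
  if (length(probs)) stop("invalid model file '", path, "': ",
                          paste(probs, collapse = "; "))

  model <- logical_model(nodes, rules)
  issues <- validate_model(model)
  if (length(issues)) stop("invalid model file '", path, "': ",
                           paste(issues, collapse = "; "))

  clamps <- integer(0)
  if (length(js$clamps)) {
    clamps <- stats::setNames(
      vapply(js$clamps, function(c) as.integer(c$level), integer(1)),
      vapply(js$clamps, function(c) as.character(c$node), character(1)))
    clamps <- check_clamps(model, clamps)
  }
  list(model = model, clamps = clamps)
}

#' Load a bundled or on-disk model
#'
#' @param name_or_path Either a bundled model name — `"intracellular"` (the
#'   11-node TLR4 signaling model) or `"tissue"` (the 6-node tissue model with
#'   the unperturbed input/output tables) — or a path to a model JSON file.
#' @return A validated [logical_model()].
#' @export
load_model <- function(name_or_path) {
  path <- if (name_or_path %in% c("intracellular", "tissue")) {
    system.file("extdata", "models", paste0(name_or_path, ".json"),
                package = "tlr4net", mustWork = TRUE)
  } else {
    name_or_path
  }
  if (!file.exists(path)) stop("no such model file: '", path, "'")
  read_model(path)$model
}

#' Basin report as a data frame
#'
#' One row per fixed-point attractor: the state's levels in model node order,
#' then `count`, `fraction`, and the truncated `percent` string. Reports
#' containing cycle attractors are not tabulated this way.
#'
#' @param x A `basin_report`.
#' @param row.names,optional,... Passed over from the generic; unused.
#' @return A `data.frame`.
#' @export
as.data.frame.basin_report <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (any(vapply(x$attractors, function(a) a$kind, character(1)) != "fixed_point")) {
    stop("basin report contains cycle attractors; rows would not be level states")
  }
  states <- do.call(rbind, lapply(x$attractors, function(a) a$states[1L, ]))
  df <- as.data.frame(states)
  df$count <- x$basins$count
  df$fraction <- x$basins$fraction
  df$percent <- x$basins$percent
  df
}

#' Write a report table as TSV
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a report object as JSON
#'
#' @param x A list or data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
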