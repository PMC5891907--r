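#' Multi-valued logical networks
#'
#' A logical model is a set of named nodes, each taking integer levels
#' `0 ... cardinality - 1`, together with one extensional update rule per
#' non-input node. Rules are stored as full truth tables (a total mapping from
#' input-level tuples to an output level), which makes totality and
#' admissibility mechanically checkable and avoids any ambiguity about rule
#' precedence. Nodes without a rule ("input" nodes) hold their value under the
#' synchronous step, so a sub-model's boundary conditions stay constant while
#' it is iterated to its fixed point.
#'
#' @name tlr4net-model
NULL

#' Define a model node
#'
#' @param name Node name (unique within a model).
#' @param cardinality Number of discrete levels; admissible levels are
#'   `0 ... cardinality - 1`. At least 2.
#' @param scale Tag for the scale the node lives on, e.g. `"tissue"` or
#'   `"intracellular"`.
#' @param role One of `"input"` (held constant, no rule required),
#'   `"internal"`, or `"output"`.
#' @return A one-row `data.frame` with columns `name`, `cardinality`, `scale`,
#'   `role`; rows of several calls are combined with `rbind()` to form the
#'   node table of [logical_model()].
#' @export
node_spec <- function(name, cardinality, scale = "tissue", role = "internal") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  cardinality <- as.integer(cardinality)
  stopifnot(length(cardinality) == 1L, !is.na(cardinality))
  role <- match.arg(role, c("input", "internal", "output"))
  data.frame(name = name, cardinality = cardinality, scale = scale,
             role = role, stringsAsFactors = FALSE)
}

## Mixed-radix tuple indexing. The FIRST input is the most significant digit
## (odometer order: the last input varies fastest), matching the row order in
## which transition tables are conventionally printed.
mixed_radix_index <- function(levels, cards) {
  i <- 0L
  for (k in seq_along(cards)) i <- i * cards[[k]] + levels[[k]]
  i + 1L
}

mixed_radix_tuple <- function(index, cards) {
  i <- index - 1L
  out <- integer(length(cards))
  for (k in rev(seq_along(cards))) {
    out[[k]] <- i %% cards[[k]]
    i <- i %/% cards[[k]]
  }
  out
}

## All input tuples of a rule, as a matrix with one row per tuple, in
## mixed-radix order.
rule_tuples <- function(cards) {
  n <- prod(cards)
  m <- matrix(0L, nrow = n, ncol = length(cards))
  for (i in seq_len(n)) m[i, ] <- mixed_radix_tuple(i, cards)
  m
}

#' Create an extensional update rule
#'
#' @param target Name of the node this rule updates.
#' @param inputs Character vector of input node names (order matters: it fixes
#'   the tuple indexing of `levels`).
#' @param input_cards Integer vector of input cardinalities, parallel to
#'   `inputs`.
#' @param levels Integer vector of output levels, one per input tuple, in
#'   mixed-radix order (first input most significant, last input varying
#'   fastest).
#' @return An object of class `rule_table`.
#' @seealso [rule_from_function()] to tabulate a rule given as an R function.
#' @export
rule_table <- function(target, inputs, input_cards, levels) {
  stopifnot(is.character(target), length(target) == 1L,
            is.character(inputs), length(inputs) >= 1L,
            length(input_cards) == length(inputs))
  input_cards <- as.integer(input_cards)
  levels <- as.integer(levels)
  if (length(levels) != prod(input_cards)) {
    stop(sprintf("rule for '%s' is not total: %d entries for %d input tuples",
                 target, length(levels), prod(input_cards)))
  }
  structure(list(target = target, inputs = inputs,
                 input_cards = input_cards, levels = levels),
            class = "rule_table")
}

#' Tabulate an update rule from a function
#'
#' Enumerates every input tuple and records `fn`'s output, yielding the
#' extensional [rule_table()].
#'
#' @inheritParams rule_table
#' @param fn Function of as many scalar integer arguments as there are inputs,
#'   returning the target's next level.
#' @return A `rule_table`.
#' @export
rule_from_function <- function(target, inputs, input_cards, fn) {
  input_cards <- as.integer(input_cards)
  tuples <- rule_tuples(input_cards)
  levels <- vapply(seq_len(nrow(tuples)), function(i) {
    as.integer(do.call(fn, as.list(tuples[i, ])))
  }, integer(1))
  rule_table(target, inputs, input_cards, levels)
}

#' Evaluate a rule on one input tuple
#'
#' @param rule A [rule_table()].
#' @param levels Integer vector of input levels, parallel to `rule$inputs`.
#' @return The output level.
#' @export
rule_output <- function(rule, levels) {
  stopifnot(inherits(rule, "rule_table"), length(levels) == length(rule$inputs))
  rule$levels[[mixed_radix_index(as.integer(levels), rule$input_cards)]]
}

#' @export
print.rule_table <- function(x, ...) {
  cat(sprintf("Rule table: %s <- (%s)\n", x$target,
              paste(x$inputs, collapse = ", ")))
  tup <- rule_tuples(x$input_cards)
  df <- as.data.frame(tup)
  names(df) <- x$inputs
  df[[x$target]] <- x$levels
  print(df, row.names = FALSE)
  invisible(x)
}

#' Rule table as a data frame
#'
#' One row per input tuple (mixed-radix order), input columns named after the
#' input nodes and the output column after the target.
#'
#' @param x A `rule_table`.
#' @param row.names,optional,... Passed over from the generic; unused.
#' @return A `data.frame`.
#' @export
as.data.frame.rule_table <- function(x, row.names = NULL, optional = FALSE, ...) {
  df <- as.data.frame(rule_tuples(x$input_cards))
  names(df) <- x$inputs
  df[[x$target]] <- x$levels
  df
}

#' Assemble a logical model
#'
#' @param nodes A `data.frame` of node specifications (see [node_spec()]),
#'   one row per node; row order fixes state and enumeration order.
#' @param rules List of [rule_table()] objects, at most one per node. Nodes
#'   without a rule hold their value (input nodes).
#' @return An object of class `logical_model` with fields `nodes` (the node
#'   table) and `rules` (named by target).
#' @export
logical_model <- function(nodes, rules = list()) {
  stopifnot(is.data.frame(nodes),
            all(c("name", "cardinality", "scale", "role") %in% names(nodes)))
  nodes <- data.frame(name = as.character(nodes$name),
                      cardinality = as.integer(nodes$cardinality),
                      scale = as.character(nodes$scale),
                      role = as.character(nodes$role),
                      stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  stopifnot(all(vapply(rules, inherits, logical(1), "rule_table")))
  names(rules) <- vapply(rules, `[[`, character(1), "target")
  ## canonical rule order (node-table order) so structurally equal models
  ## compare identical and model files are written deterministically
  rules <- rules[order(match(names(rules), nodes$name))]
  structure(list(nodes = nodes, rules = rules), class = "logical_model")
}

model_cards <- function(model) {
  stats::setNames(model$nodes$cardinality, model$nodes$name)
}

#' @export
print.logical_model <- function(x, ...) {
  cat(sprintf("Logical model: %d nodes, %d rules, state space %s\n",
              nrow(x$nodes), length(x$rules),
              format(prod(as.double(x$nodes$cardinality)), big.mark = ",")))
  ndf <- x$nodes
  ndf$rule <- ifelse(ndf$name %in% names(x$rules),
                     vapply(ndf$name, function(n) {
                       if (is.null(x$rules[[n]])) "(hold)"
                       else paste(x$rules[[n]]$inputs, collapse = ",")
                     }, character(1)),
                     "(hold)")
  print(ndf, row.names = FALSE)
  invisible(x)
}

#' Validate a logical model
#'
#' Checks structural invariants and returns diagnostics rather than throwing:
#' unique node names, cardinalities at least 2, rules targeting known nodes
#' with known inputs, total truth tables of the right length, admissible output
#' levels, a rule (or input role) for every node, and hold-or-absent rules for
#' input nodes.
#'
#' @param model A [logical_model()].
#' @return Character vector of human-readable violations; `character(0)` if
#'   the model is valid.
#' @export
validate_model <- function(model) {
  v <- character(0)
  nm <- model$nodes$name
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    v <- c(v, sprintf("duplicate node name: '%s'", dup))
  }
  bad_card <- nm[model$nodes$cardinality < 2L]
  if (length(bad_card)) {
    v <- c(v, sprintf("node '%s' has cardinality < 2", bad_card))
  }
  cards <- model_cards(model)
  for (rule in model$rules) {
    tgt <- rule$target
    if (!tgt %in% nm) {
      v <- c(v, sprintf("rule targets unknown node '%s'", tgt))
      next
    }
    unknown <- setdiff(rule$inputs, nm)
    if (length(unknown)) {
      v <- c(v, sprintf("rule for '%s' uses unknown input '%s'", tgt, unknown))
      next
    }
    declared <- cards[rule$inputs]
    if (!identical(unname(declared), rule$input_cards)) {
      v <- c(v, sprintf("rule for '%s': input cardinalities disagree with node table", tgt))
    }
    if (length(rule$levels) != prod(rule$input_cards)) {
      v <- c(v, sprintf("incomplete table for '%s': %d of %d tuples defined",
                        tgt, length(rule$levels), prod(rule$input_cards)))
    }
    bad <- rule$levels < 0L | rule$levels >= cards[[tgt]]
    if (any(bad)) {
      v <- c(v, sprintf("inadmissible output for '%s': level %d outside 0..%d",
                        tgt, rule$levels[bad][1], cards[[tgt]] - 1L))
    }
  }
  for (i in seq_len(nrow(model$nodes))) {
    n <- model$nodes$name[i]
    role <- model$nodes$role[i]
    has_rule <- n %in% names(model$rules)
    if (role == "input" && has_rule) {
      r <- model$rules[[n]]
      is_hold <- identical(r$inputs, n) &&
        identical(r$levels, seq_len(cards[[n]]) - 1L)
      if (!is_hold) {
        v <- c(v, sprintf("input node '%s' has a non-identity rule", n))
      }
    }
    if (role != "input" && !has_rule) {
      v <- c(v, sprintf("non-input node '%s' has no rule", n))
    }
  }
  v
}

#' Wiring diagram of a model
#'
#' @param model A [logical_model()].
#' @return An [igraph::graph] with one vertex per node and one directed edge
#'   per rule dependency (input -> target).
#' @export
model_graph <- function(model) {
  edges <- do.call(rbind, lapply(model$rules, function(r) {
    cbind(r$inputs, r$target)
  }))
  g <- igraph::make_empty_graph(directed = TRUE) +
    igraph::vertices(model$nodes$name)
  if (!is.null(edges)) g <- g + igraph::edges(t(edges))
  g
}

#' Build a state vector for a model
#'
#' @param model A [logical_model()].
#' @param ... Named integer levels, one per model node (or a subset when
#'   `default` is given).
#' @param default If non-`NULL`, level assigned to every node not named in
#'   `...`.
#' @return Named integer vector in model node order.
#' @export
model_state <- function(model, ..., default = NULL) {
  given <- c(...)
  nm <- model$nodes$name
  if (is.null(default)) {
    missing <- setdiff(nm, names(given))
    if (length(missing)) {
      stop("state misses node(s): ", paste(missing, collapse = ", "))
    }
    st <- stats::setNames(as.integer(given[nm]), nm)
  } else {
    st <- stats::setNames(rep(as.integer(default), length(nm)), nm)
    st[names(given)] <- as.integer(given)
  }
  check_state(model, st)
  st
}

check_state <- function(model, state) {
  nm <- model$nodes$name
  missing <- setdiff(nm, names(state))
  if (length(missing)) {
    stop("state misses node(s): ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(names(state), nm)
  if (length(extra)) {
    stop("state names unknown node(s): ", paste(extra, collapse = ", "))
  }
  cards <- model_cards(model)
  bad <- names(state)[state < 0L | state >= cards[names(state)]]
  if (length(bad)) {
    stop("inadmissible level for node(s): ", paste(bad, collapse = ", "))
  }
  invisible(state)
}

check_clamps <- function(model, clamps) {
  if (is.null(clamps) || length(clamps) == 0L) return(integer(0))
  clamps <- stats::setNames(as.integer(clamps), names(clamps))
  if (is.null(names(clamps)) || any(!nzchar(names(clamps)))) {
    stop("clamps must be a named integer vector (node = level)")
  }
  if (anyDuplicated(names(clamps))) {
    stop("conflicting clamp specifications for node(s): ",
         paste(unique(names(clamps)[duplicated(names(clamps))]), collapse = ", "))
  }
  unknown <- setdiff(names(clamps), model$nodes$name)
  if (length(unknown)) {
    stop("clamp names unknown node(s): ", paste(unknown, collapse = ", "))
  }
  cards <- model_cards(model)
  bad <- names(clamps)[clamps < 0L | clamps >= cards[names(clamps)]]
  if (length(bad)) {
    stop("inadmissible clamp level for node(s): ", paste(bad, collapse = ", "))
  }
  clamps
}
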