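# Tiny fixture models built in code.

# One binary node that negates itself: the smallest forced oscillation.
negation_model <- function() {
  logical_model(
    node_spec("a", 2, role = "internal"),
    list(rule_table("a", "a", 2L, c(1L, 0L)))
  )
}

# Every rule constant zero: a single global fixed point.
constant_model <- function(n = 3L) {
  nodes <- do.call(rbind, lapply(seq_len(n), function(i) {
    node_spec(sprintf("c%d", i), 2, role = "internal")
  }))
  rules <- lapply(nodes$name, function(nm) {
    rule_table(nm, nm, 2L, c(0L, 0L))
  })
  logical_model(nodes, rules)
}

# Single-node (asynchronous) update of node `i`, computed from the rule
# tables directly -- an independent route from the compiled synchronous step.
async_update_node <- function(model, state, node) {
  r <- model$rules[[node]]
  out <- state
  if (!is.null(r)) out[[node]] <- rule_output(r, state[r$inputs])
  out
}

# Full state space of a model as a matrix (one row per state).
all_states <- function(model) {
  cards <- model$nodes$cardinality
  grid <- do.call(expand.grid, rev(lapply(cards, function(c) 0:(c - 1L))))
  m <- as.matrix(grid[, rev(seq_along(cards)), drop = FALSE])
  colnames(m) <- model$nodes$name
  storage.mode(m) <- "integer"
  m
}
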