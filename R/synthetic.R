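#' Seeded random logical networks
#'
#' The engine is exercised against randomly generated multistate logical
#' networks whose rule tables carry no biological meaning: they exist to
#' property-test the simulator (basin counts partition the state space, fixed
#' points coincide with states invariant under every single-node update,
#' determinism) independently of the hand-built injury model. All randomness
#' is drawn inside [withr::with_seed()], so generation is reproducible from
#' the config's seed and never touches the caller's RNG state.
#'
#' @name synthetic-models
NULL

#' Configuration for the random model generator
#'
#' @param n_nodes Number of nodes (>= 1).
#' @param cardinalities Integer vector of admissible node cardinalities to
#'   sample from (each >= 2).
#' @param max_inputs Maximum number of inputs per rule (>= 1, at most
#'   `n_nodes`).
#' @param input_fraction Expected fraction of rule-less hold (input) nodes.
#' @param seed Integer seed; identical seed and config give identical models.
#' @return An object of class `generator_config`.
#' @export
generator_config <- function(n_nodes, cardinalities = c(2L, 3L),
                             max_inputs = 2L, input_fraction = 0, seed = 1L) {
  n_nodes <- as.integer(n_nodes)
  cardinalities <- as.integer(cardinalities)
  max_inputs <- as.integer(max_inputs)
  stopifnot(n_nodes >= 1L, all(cardinalities >= 2L), max_inputs >= 1L,
            max_inputs <= n_nodes, input_fraction >= 0, input_fraction <= 1)
  structure(list(n_nodes = n_nodes, cardinalities = cardinalities,
                 max_inputs = max_inputs, input_fraction = input_fraction,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a random logical model
#'
#' Node cardinalities are sampled uniformly from `config$cardinalities`; each
#' non-input node receives a rule over 1 to `config$max_inputs` distinct
#' inputs with uniformly sampled output levels (a total extensional table by
#' construction). The result always passes [validate_model()].
#'
#' @param config A [generator_config()].
#' @return A [logical_model()].
#' @export
random_model <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    n <- config$n_nodes
    nm <- sprintf("n%02d", seq_len(n))
    cards <- config$cardinalities[sample.int(length(config$cardinalities), n,
                                             replace = TRUE)]
    is_input <- stats::runif(n) < config$input_fraction
    nodes <- do.call(rbind, lapply(seq_len(n), function(i) {
      node_spec(nm[i], cards[i], scale = "tissue",
                role = if (is_input[i]) "input" else "internal")
    }))
    rules <- list()
    for (i in seq_len(n)) {
      if (is_input[i]) next
      k <- sample.int(config$max_inputs, 1L)
      in_idx <- sample.int(n, k)
      in_cards <- cards[in_idx]
      levels <- sample.int(cards[i], prod(in_cards), replace = TRUE) - 1L
      rules[[length(rules) + 1L]] <- rule_table(nm[i], nm[in_idx], in_cards, levels)
    }
    m <- logical_model(nodes, rules)
    stopifnot(length(validate_model(m)) == 0L)
    m
  })
}

#' Draw a uniform random state for a model
#'
#' @param model A [logical_model()].
#' @param seed Integer seed; identical seed gives an identical state.
#' @return Named integer state vector with each node's level uniform over its
#'   admissible range.
#' @export
random_state <- function(model, seed = 1L) {
  withr::with_seed(as.integer(seed), {
    cards <- model_cards(model)
    stats::setNames(vapply(cards, function(c) sample.int(c, 1L) - 1L, integer(1)),
                    names(cards))
  })
}
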