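## Synchronous dynamics, attractor detection, exhaustive basin enumeration.

## Pre-resolve rule input positions and mixed-radix weights so the inner loop
## of enumeration is pure integer indexing on an unnamed state vector.
compile_model <- function(model, clamps = NULL) {
  clamps <- check_clamps(model, clamps)
  nm <- model$nodes$name
  n <- length(nm)
  kind <- integer(n)              # 0 = hold, 1 = rule, 2 = clamp
  clamp_level <- integer(n)
  idx <- vector("list", n)
  wts <- vector("list", n)
  tab <- vector("list", n)
  for (i in seq_len(n)) {
    node <- nm[i]
    if (node %in% names(clamps)) {
      kind[i] <- 2L
      clamp_level[i] <- clamps[[node]]
    } else if (node %in% names(model$rules)) {
      r <- model$rules[[node]]
      kind[i] <- 1L
      idx[[i]] <- match(r$inputs, nm)
      k <- length(r$input_cards)
      w <- integer(k)
      w[k] <- 1L
      if (k > 1L) for (j in (k - 1L):1L) w[j] <- w[j + 1L] * r$input_cards[j + 1L]
      wts[[i]] <- w
      tab[[i]] <- r$levels
    }
  }
  list(names = nm, n = n, cards = unname(model$nodes$cardinality),
       kind = kind, clamp_level = clamp_level, idx = idx, wts = wts, tab = tab,
       clamps = clamps)
}

step_compiled <- function(cm, s) {
  out <- s
  for (i in seq_len(cm$n)) {
    k <- cm$kind[i]
    if (k == 1L) {
      out[i] <- cm$tab[[i]][sum(s[cm$idx[[i]]] * cm$wts[[i]]) + 1L]
    } else if (k == 2L) {
      out[i] <- cm$clamp_level[i]
    }
  }
  out
}

## Apply clamp levels to a state (clamps override, including at initialization).
apply_clamps <- function(cm, s) {
  cl <- cm$kind == 2L
  s[cl] <- cm$clamp_level[cl]
  s
}

#' One synchronous update step
#'
#' Every unclamped node with a rule takes the rule's output evaluated on the
#' *current* state; clamped nodes take their clamp level; rule-less (input)
#' nodes hold their value.
#'
#' @param model A [logical_model()].
#' @param state Named integer state vector covering every model node.
#' @param clamps Optional named integer vector of clamped levels
#'   (knockout = 0); a clamped node's rule is ignored.
#' @return The next state, named, in model node order.
#' @export
synchronous_step <- function(model, state, clamps = NULL) {
  check_state(model, state)
  cm <- compile_model(model, clamps)
  ## clamps hold at every time, including the current state
  s <- apply_clamps(cm, unname(as.integer(state[cm$names])))
  stats::setNames(step_compiled(cm, s), cm$names)
}

new_attractor <- function(states_mat, node_names) {
  colnames(states_mat) <- node_names
  structure(list(kind = if (nrow(states_mat) == 1L) "fixed_point" else "cycle",
                 states = states_mat),
            class = "attractor")
}

## Canonical rotation: start a cycle at its lexicographically smallest state so
## identical cycles discovered from different entry points compare equal.
canonical_attractor <- function(states_mat, node_names) {
  if (nrow(states_mat) > 1L) {
    keys <- apply(states_mat, 1L, paste, collapse = ",")
    first <- which.min(match(keys, sort(keys)))
    ord <- c(first:nrow(states_mat), seq_len(first - 1L))
    states_mat <- states_mat[ord, , drop = FALSE]
  }
  new_attractor(states_mat, node_names)
}

attractor_key <- function(states_mat) {
  paste(apply(states_mat, 1L, paste, collapse = ","), collapse = ";")
}

#' @export
print.attractor <- function(x, ...) {
  cat(sprintf("Attractor (%s, period %d):\n", x$kind, nrow(x$states)))
  print(as.data.frame(x$states), row.names = FALSE)
  invisible(x)
}

#' Iterate to an attractor
#'
#' Repeats [synchronous_step()] from `initial`, detecting the first revisited
#' state; the trajectory segment from that revisit onward is the attractor
#' (a fixed point when the period is 1). The dynamics are deterministic, so
#' the attractor is unique for a given initial state and clamps.
#'
#' @inheritParams synchronous_step
#' @param initial Named integer state vector. Clamped nodes are forced to
#'   their clamp level from step 0 on.
#' @param max_steps Safety bound on the number of steps; with any value at
#'   least the state-space size a revisit is guaranteed.
#' @return List with `trajectory` (matrix, one row per visited state, row 1 =
#'   initial after clamping) and `attractor` (an `attractor` object).
#' @export
run_to_attractor <- function(model, initial, clamps = NULL, max_steps = 10000L) {
  stopifnot(max_steps >= 1L)
  check_state(model, initial)
  cm <- compile_model(model, clamps)
  s <- apply_clamps(cm, unname(as.integer(initial[cm$names])))
  seen <- new.env(parent = emptyenv(), hash = TRUE)
  traj <- vector("list", 64L)
  for (t in seq_len(max_steps + 1L)) {
    key <- paste(s, collapse = ",")
    hit <- get0(key, envir = seen)
    if (!is.null(hit)) {
      tm <- do.call(rbind, traj[seq_len(t - 1L)])
      colnames(tm) <- cm$names
      att <- canonical_attractor(tm[hit:(t - 1L), , drop = FALSE], cm$names)
      return(list(trajectory = tm, attractor = att))
    }
    assign(key, t, envir = seen)
    if (t > length(traj)) traj <- c(traj, vector("list", length(traj)))
    traj[[t]] <- s
    s <- step_compiled(cm, s)
  }
  stop("no attractor found within max_steps = ", max_steps,
       " (increase max_steps to at least the state-space size)")
}

#' Exhaustive attractor and basin enumeration
#'
#' Follows every initial state of an enumeration space to its attractor and
#' counts, per attractor, how many initial states reach it (its basin of
#' attraction). The space defaults to the full Cartesian product of node
#' levels, with clamped nodes fixed at their clamp level; `enumerate` and
#' `fixed` restrict it to a sub-space (non-enumerated nodes are fixed at the
#' stated levels). Enumeration order is the mixed-radix count over the
#' enumerated nodes in model node order (first node most significant); results
#' are order-independent, the ordering only makes reports reproducible.
#'
#' @inheritParams synchronous_step
#' @param enumerate Character vector of node names whose levels span the
#'   enumeration space. Default: all nodes not clamped and not in `fixed`.
#' @param fixed Named integer vector of levels for non-enumerated nodes.
#' @param max_steps Per-trajectory step bound, as in [run_to_attractor()].
#' @return A `basin_report`: list with `attractors` (list of `attractor`),
#'   `basins` (`data.frame` with columns `attractor`, `count`, `fraction`,
#'   `percent`), `total`, and the enumeration metadata (`enumerated`, `fixed`,
#'   `clamps`). Counts partition the space exactly; fractions sum to 1.
#' @export
enumerate_attractors <- function(model, clamps = NULL, enumerate = NULL,
                                 fixed = NULL, max_steps = 100000L) {
  cm <- compile_model(model, clamps)
  nm <- cm$names
  if (!is.null(fixed)) {
    fixed <- stats::setNames(as.integer(fixed), names(fixed))
    unknown <- setdiff(names(fixed), nm)
    if (length(unknown)) {
      stop("fixed names unknown node(s): ", paste(unknown, collapse = ", "))
    }
  }
  if (is.null(enumerate)) {
    enumerate <- setdiff(nm[cm$kind != 2L], names(fixed))
  } else {
    unknown <- setdiff(enumerate, nm)
    if (length(unknown)) {
      stop("enumerate names unknown node(s): ", paste(unknown, collapse = ", "))
    }
    enumerate <- nm[nm %in% enumerate]  # model node order
  }
  if (length(enumerate) == 0L) stop("empty enumeration space")
  epos <- match(enumerate, nm)
  ecards <- cm$cards[epos]
  total <- prod(ecards)
  if (total > 5e6) stop("enumeration space too large: ", total)
  total <- as.integer(total)

  base <- integer(cm$n)
  if (!is.null(fixed)) base[match(names(fixed), nm)] <- fixed
  base <- apply_clamps(cm, base)

  ## memoised attractor lookup: state key -> attractor index; every state is
  ## stepped at most once across the whole enumeration.
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  atts <- list()
  att_keys <- character(0)
  counts <- integer(0)

  for (i in seq_len(total)) {
    base[epos] <- mixed_radix_tuple(i, ecards)
    s <- base
    path_keys <- character(0)
    path_pos <- new.env(parent = emptyenv(), hash = TRUE)
    aid <- NULL
    repeat {
      key <- paste(s, collapse = ",")
      hit <- get0(key, envir = memo)
      if (!is.null(hit)) { aid <- hit; break }
      pos <- get0(key, envir = path_pos)
      if (!is.null(pos)) {
        ## new cycle discovered within this path
        cyc <- do.call(rbind, lapply(path_keys[pos:length(path_keys)],
                                     function(k) as.integer(strsplit(k, ",", fixed = TRUE)[[1]])))
        att <- canonical_attractor(cyc, nm)
        akey <- attractor_key(att$states)
        aid <- match(akey, att_keys)
        if (is.na(aid)) {
          atts[[length(atts) + 1L]] <- att
          att_keys <- c(att_keys, akey)
          counts <- c(counts, 0L)
          aid <- length(atts)
        }
        break
      }
      path_keys <- c(path_keys, key)
      assign(key, length(path_keys), envir = path_pos)
      if (length(path_keys) > max_steps) {
        stop("no attractor found within max_steps = ", max_steps)
      }
      s <- step_compiled(cm, s)
    }
    for (k in path_keys) assign(k, aid, envir = memo)
    counts[aid] <- counts[aid] + 1L
  }

  basins <- data.frame(
    attractor = seq_along(atts),
    count = counts,
    fraction = counts / total,
    percent = vapply(counts, format_percent_trunc, character(1), total = total),
    stringsAsFactors = FALSE
  )
  structure(list(attractors = atts, basins = basins, total = total,
                 enumerated = enumerate, fixed = fixed, clamps = cm$clamps),
            class = "basin_report")
}

#' @export
print.basin_report <- function(x, ...) {
  cat(sprintf("Basin report over %d enumerated initializations (nodes: %s)\n",
              x$total, paste(x$enumerated, collapse = ", ")))
  if (length(x$clamps)) {
    cat("Clamps:", paste(names(x$clamps), x$clamps, sep = "=", collapse = ", "), "\n")
  }
  for (i in seq_along(x$attractors)) {
    a <- x$attractors[[i]]
    cat(sprintf("\n#%d %s, basin %d/%d (%s)\n", i, a$kind,
                x$basins$count[i], x$total, x$basins$percent[i]))
    print(as.data.frame(a$states), row.names = FALSE)
  }
  invisible(x)
}

#' Truncated percentage formatting
#'
#' Basin percentages are *truncated* toward zero (not rounded) at the given
#' number of decimals: 1/6 prints as `16.66%` and 12/216 as `5.55%`. The
#' arithmetic is exact integer division, so no floating-point representation
#' issue can flip a digit.
#'
#' @param count,total Non-negative integers, `count <= total`, `total > 0`.
#' @param digits Decimal places kept after truncation.
#' @return A string like `"16.66%"`.
#' @export
format_percent_trunc <- function(count, total, digits = 2L) {
  stopifnot(total > 0, count >= 0, count <= total)
  scaled <- (as.double(count) * 10^(digits + 2L)) %/% as.double(total)
  sprintf("%.*f%%", digits, scaled / 10^digits)
}

#' Truncated percentage value
#'
#' Numeric companion of [format_percent_trunc()]: `100 * count / total`
#' truncated toward zero at `digits` decimals.
#'
#' @inheritParams format_percent_trunc
#' @return A numeric scalar.
#' @export
percent_trunc <- function(count, total, digits = 2L) {
  stopifnot(total > 0, count >= 0, count <= total)
  ((as.double(count) * 10^(digits + 2L)) %/% as.double(total)) / 10^digits
}

#' Basin percentages of a report
#'
#' @param report A `basin_report` from [enumerate_attractors()].
#' @param digits Decimal places kept after truncation.
#' @return Character vector of truncated percent strings, one per attractor.
#' @export
basin_percentages <- function(report, digits = 2L) {
  stopifnot(inherits(report, "basin_report"))
  vapply(report$basins$count, format_percent_trunc, character(1),
         total = report$total, digits = digits)
}
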