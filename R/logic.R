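#' Read a signed interaction network in SIF format
#'
#' Tab-separated rows `source <TAB> relationship <TAB> target`, with
#' relationship `1` (activating) or `-1` (inhibitory) — the standard prior
#' knowledge format for signalling networks.
#'
#' @param path File path.
#' @return A data frame with columns `source`, `sign`, `target`.
#' @export
read_sif <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE,
                          col.names = c("source", "sign", "target"))
  if (!all(df$sign %in% c(-1, 1))) {
    stop("SIF relationship column must be 1 or -1", call. = FALSE)
  }
  df
}

#' @rdname read_sif
#' @param sif A SIF data frame.
#' @export
write_sif <- function(sif, path) {
  utils::write.table(sif, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Expand a signed graph into candidate logic gates
#'
#' For every node with incoming edges, all non-empty subsets of its inputs
#' up to `max_fanin` become candidate hyperedges: a single-input hyperedge
#' is a plain (OR-combined) edge, a multi-input hyperedge is an AND gate
#' over its inputs. Selected hyperedges sharing an output are combined by
#' OR, so the expansion spans every AND/OR gate structure compatible with
#' the prior graph.
#'
#' @param sif A data frame from [read_sif()].
#' @param max_fanin Largest AND-gate input count generated.
#' @return List of hyperedges, each `list(inputs, signs, output)`.
#' @export
expand_hyperedges <- function(sif, max_fanin = 4L) {
  out <- list()
  for (target in unique(sif$target)) {
    rows <- sif[sif$target == target, , drop = FALSE]
    n_in <- nrow(rows)
    for (size in seq_len(min(n_in, max_fanin))) {
      combos <- utils::combn(n_in, size, simplify = FALSE)
      for (cc in combos) {
        out[[length(out) + 1L]] <- list(
          inputs = rows$source[cc],
          signs = as.integer(rows$sign[cc]),
          output = target
        )
      }
    }
  }
  out
}

#' Construct a logic model
#'
#' A logic model is a signed hypergraph over named nodes: each hyperedge has
#' one output node and one or more signed inputs (sign `-1` means the input
#' enters negated). Node roles: `stimuli` are experimentally clamped inputs,
#' `inhibitors` are nodes whose experimental inhibition clamps them to 0,
#' `readouts` are the measured nodes. The hyperedge input counts `v_e` and
#' their total `v_es` drive the complexity penalty of [logic_objective()].
#'
#' @param nodes Character vector of node names.
#' @param hyperedges List of `list(inputs, signs, output)` entries.
#' @param stimuli,inhibitors,readouts Node-role subsets of `nodes`.
#' @return An object of class `logic_model` with fields `nodes`,
#'   `hyperedges`, roles, `v_e`, `v_es`, `r`.
#' @export
logic_model <- function(nodes, hyperedges, stimuli = character(0),
                        inhibitors = character(0), readouts = character(0)) {
  nodes <- as.character(nodes)
  for (e in hyperedges) {
    if (!all(c(e$inputs, e$output) %in% nodes)) {
      stop("hyperedge refers to unknown node", call. = FALSE)
    }
    if (length(e$inputs) < 1L || length(e$inputs) != length(e$signs)) {
      stop("hyperedge needs >= 1 input with matching signs", call. = FALSE)
    }
  }
  stopifnot(all(stimuli %in% nodes), all(inhibitors %in% nodes),
            all(readouts %in% nodes))
  v_e <- vapply(hyperedges, function(e) length(e$inputs), integer(1))
  structure(list(nodes = nodes, hyperedges = hyperedges,
                 stimuli = stimuli, inhibitors = inhibitors,
                 readouts = readouts,
                 v_e = v_e, v_es = sum(v_e), r = length(hyperedges)),
            class = "logic_model")
}

#' @export
print.logic_model <- function(x, ...) {
  cat("<logic_model> ", length(x$nodes), " nodes, ", x$r,
      " candidate hyperedges (v_es = ", x$v_es, ")\n", sep = "")
  invisible(x)
}

#' Logical steady state under an experimental condition
#'
#' Synchronous Boolean iteration: each node's next value is the OR, over its
#' selected incoming hyperedges, of the AND of that hyperedge's inputs
#' (inputs with sign `-1` contribute the negated state). Stimulus nodes are
#' clamped to their set value, inhibited nodes to 0, and all other nodes
#' start at 0; nodes with no selected incoming hyperedge hold their value.
#' Iteration runs to a fixed point or at most `2 * length(nodes)` sweeps;
#' if no fixed point is reached (an oscillating loop), the nodes still
#' changing are reported as `NA` (undefined) — undefined is a value, not an
#' error.
#'
#' @param model A [logic_model()].
#' @param selection Binary vector of length `model$r`: which hyperedges are
#'   in the model.
#' @param stimuli Named 0/1 vector of stimulus settings (missing stimuli
#'   default to 0).
#' @param inhibited Character vector of nodes experimentally inhibited.
#' @return Named 0/1 vector over nodes, `NA` for non-converged nodes.
#' @export
logic_steady_state <- function(model, selection, stimuli = numeric(0),
                               inhibited = character(0)) {
  stopifnot(length(selection) == model$r)
  selection <- as.integer(selection != 0)
  nodes <- model$nodes
  state <- stats::setNames(rep(0, length(nodes)), nodes)
  clamp <- function(s) {
    if (length(stimuli)) s[names(stimuli)] <- as.numeric(stimuli)
    if (length(inhibited)) s[inhibited] <- 0
    s
  }
  state <- clamp(state)
  sel_edges <- model$hyperedges[selection == 1L]
  by_target <- split(sel_edges,
                     vapply(sel_edges, function(e) e$output, character(1)))
  max_sweeps <- 2L * length(nodes)
  converged <- FALSE
  for (sweep in seq_len(max_sweeps)) {
    new <- state
    for (target in names(by_target)) {
      vals <- vapply(by_target[[target]], function(e) {
        ins <- state[e$inputs]
        ins[e$signs < 0] <- 1 - ins[e$signs < 0]
        min(ins) # AND
      }, numeric(1))
      new[target] <- max(vals) # OR over selected hyperedges
    }
    new <- clamp(new)
    if (identical(new, state)) {
      converged <- TRUE
      break
    }
    state <- new
  }
  if (!converged) {
    # one more sweep to identify the oscillating nodes
    new <- state
    for (target in names(by_target)) {
      vals <- vapply(by_target[[target]], function(e) {
        ins <- state[e$inputs]
        ins[e$signs < 0] <- 1 - ins[e$signs < 0]
        min(ins)
      }, numeric(1))
      new[target] <- max(vals)
    }
    new <- clamp(new)
    state[new != state] <- NA
  }
  state
}

#' Experimental data cube for logic-model training
#'
#' Measurements are rows `(condition, readout, time, value)` with values in
#' `[0, 1)`; conditions are rows naming the stimulus settings and inhibited
#' nodes of each experimental condition. Missing combinations are simply
#' absent rows (`n_E` counts the defined points).
#'
#' @param measurements Data frame with columns `condition`, `readout`,
#'   `time`, `value`.
#' @param conditions Data frame with column `condition` plus stimulus
#'   columns `S:<node>` (0/1) and inhibition columns `I:<node>` (0/1).
#' @return An object of class `logic_data`.
#' @export
logic_data <- function(measurements, conditions) {
  stopifnot(all(c("condition", "readout", "time", "value") %in%
                  names(measurements)),
            "condition" %in% names(conditions))
  if (any(measurements$value < 0 | measurements$value >= 1)) {
    stop("data values must lie in [0, 1)", call. = FALSE)
  }
  if (!all(measurements$condition %in% conditions$condition)) {
    stop("measurement rows refer to unknown conditions", call. = FALSE)
  }
  structure(list(measurements = measurements, conditions = conditions,
                 n_E = nrow(measurements)),
            class = "logic_data")
}

#' @rdname logic_data
#' @param measurements_csv,conditions_csv File paths of the two CSV tables.
#' @export
read_logic_data <- function(measurements_csv, conditions_csv) {
  m <- utils::read.csv(measurements_csv, check.names = FALSE)
  k <- utils::read.csv(conditions_csv, check.names = FALSE)
  logic_data(m, k)
}

condition_settings <- function(conditions, cond_id) {
  row <- conditions[conditions$condition == cond_id, , drop = FALSE]
  scols <- grep("^S:", names(conditions), value = TRUE)
  icols <- grep("^I:", names(conditions), value = TRUE)
  stim <- stats::setNames(as.numeric(row[1, scols]), sub("^S:", "", scols))
  inh <- sub("^I:", "", icols[as.numeric(row[1, icols]) == 1])
  list(stimuli = stim, inhibited = inh)
}

#' Logic-model training objective
#'
#' The training score of a hyperedge selection `P` is
#' `theta = theta_f + alpha * theta_s`, where `theta_f` is the mean squared
#' mismatch between the model's logical steady state and the data over all
#' defined data points, and `theta_s = sum(v_e * P_e) / v_es` penalizes
#' model complexity: each selected hyperedge costs its input count, so a
#' 3-input AND gate is penalised three times as much as a single edge, and
#' OR gates (built from single-input edges) pay per edge. A non-converged
#' (undefined) prediction contributes the worst-case residual 1, penalizing
#' oscillatory models. `alpha` trades goodness-of-fit against parsimony.
#'
#' @param model A [logic_model()].
#' @param selection Binary hyperedge-inclusion vector of length `model$r`.
#' @param data A [logic_data()].
#' @param alpha Nonnegative complexity weight.
#' @return List with `theta`, `theta_f`, `theta_s`.
#' @export
logic_objective <- function(model, selection, data, alpha = 1e-4) {
  stopifnot(inherits(model, "logic_model"), inherits(data, "logic_data"))
  if (data$n_E == 0L) stop("no defined data points (n_E = 0)", call. = FALSE)
  selection <- as.integer(selection != 0)
  meas <- data$measurements
  sq <- 0
  for (cond_id in unique(meas$condition)) {
    cs <- condition_settings(data$conditions, cond_id)
    ss <- logic_steady_state(model, selection, cs$stimuli, cs$inhibited)
    rows <- meas[meas$condition == cond_id, , drop = FALSE]
    pred <- ss[rows$readout]
    res2 <- ifelse(is.na(pred), 1, (pred - rows$value)^2)
    sq <- sq + sum(res2)
  }
  theta_f <- sq / data$n_E
  theta_s <- sum(model$v_e * selection) / model$v_es
  list(theta = theta_f + alpha * theta_s, theta_f = theta_f,
       theta_s = theta_s)
}

#' Wrap logic-model training as an integer program
#'
#' The binary hyperedge-selection space becomes an all-integer
#' [op_problem()] over `{0,1}^r` whose objective is the training score
#' `theta`, ready for [vns_solve()] (or exhaustive enumeration when `r` is
#' small).
#'
#' @inheritParams logic_objective
#' @return An [op_problem()].
#' @export
make_logic_ip_problem <- function(model, data, alpha = 1e-4) {
  force(model); force(data); force(alpha)
  op_problem(
    function(p) logic_objective(model, p, data, alpha)$theta,
    lower = rep(0, model$r), upper = rep(1, model$r),
    integer_indices = seq_len(model$r),
    name = "logic_training"
  )
}

#' Enumerate all hyperedge selections
#'
#' Exhaustive scoring of all `2^r` selections; the brute-force oracle for
#' small training problems.
#'
#' @inheritParams logic_objective
#' @return Data frame with one row per selection: `id`, the selection bits
#'   as a string, `theta`, `theta_f`, `theta_s`, ordered as enumerated.
#' @export
enumerate_logic_selections <- function(model, data, alpha = 1e-4) {
  r <- model$r
  if (r > 20L) stop("enumeration over 2^r limited to r <= 20", call. = FALSE)
  n <- 2L^r
  theta <- theta_f <- theta_s <- numeric(n)
  bits <- character(n)
  for (i in seq_len(n)) {
    sel <- as.integer(intToBits(i - 1L)[seq_len(r)])
    sc <- logic_objective(model, sel, data, alpha)
    theta[i] <- sc$theta
    theta_f[i] <- sc$theta_f
    theta_s[i] <- sc$theta_s
    bits[i] <- paste(sel, collapse = "")
  }
  data.frame(id = seq_len(n) - 1L, selection = bits, theta = theta,
             theta_f = theta_f, theta_s = theta_s)
}
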