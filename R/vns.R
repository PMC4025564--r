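#' Options for variable neighbourhood search
#'
#' @param max_evaluations Objective-evaluation budget. Distinct points only:
#'   the solver memoises points it has already evaluated (see `cache`), and
#'   a memoised lookup does not call the objective, so it is not charged.
#' @param k_max Cap on the number of variables perturbed in one shake
#'   (decomposition-style neighbourhood cap); `NULL` gives `min(nvar, 10)`.
#' @param aggressive Aggressive local search: a single first-improvement
#'   sweep instead of repeated sweeps with go-beyond extension and pair
#'   intensification. Trades solution quality for speed, useful when a
#'   good-enough solution is wanted quickly or as a cooperative thread
#'   profile.
#' @param pair_intensify Extend the local search with two-variable scans:
#'   one variable of a pair sweeps its whole domain while the other is
#'   re-optimized by 1-D descent (warm-started from the previous scan
#'   value). This escapes the coordinate-wise local minima that trap
#'   unit-move searches on coupled objectives (ratios, products). `NULL`
#'   (default) enables it automatically when the problem is small enough
#'   for domain scans to be affordable (`nvar <= 12`, all domains <= 200
#'   values); ignored in aggressive mode.
#' @param cache Memoise evaluated points so revisits are free. Integer
#'   searches revisit points constantly; with the cache the evaluation
#'   budget buys distinct points.
#' @param memory_depth How many recent perturbation index sets are remembered
#'   and excluded from re-use (cycle avoidance).
#' @param seed Integer seed.
#' @return A list of class `vns_options`.
#' @export
vns_options <- function(max_evaluations = 10000L, k_max = NULL,
                        aggressive = FALSE, pair_intensify = NULL,
                        cache = TRUE, memory_depth = 10L, seed = 1L) {
  opts <- list(max_evaluations = as.integer(max_evaluations),
               k_max = if (!is.null(k_max)) as.integer(k_max) else NULL,
               aggressive = isTRUE(aggressive),
               pair_intensify = pair_intensify,
               cache = isTRUE(cache),
               memory_depth = as.integer(memory_depth),
               seed = as.integer(seed))
  stopifnot(opts$max_evaluations >= 1L, opts$memory_depth >= 1L)
  class(opts) <- "vns_options"
  opts
}

#' Shake: jump to a random point at neighbourhood distance k
#'
#' Exactly `k` variable positions are changed, each to a uniformly drawn
#' in-bounds integer different from its current value. The distance
#' criterion is the cardinality of the perturbed set: small `k` explores
#' nearby neighbourhoods, larger `k` progressively more distant ones. The
#' chosen index set must differ from every set in `memory` (no-repeat rule
#' against cycling); it is then appended, evicting the oldest entry beyond
#' `memory_depth`. Degenerate variables (single-valued domain) are never
#' perturbed; a substitute index is drawn instead. If the memory has
#' exhausted every possible index set of size `k`, it is cleared and the
#' draw repeated (flagged in the return value).
#'
#' @param x Integer decision vector.
#' @param k Number of positions to perturb (1..nvar).
#' @param lower,upper Integral bound vectors.
#' @param memory List of previously used index sets (sorted integer vectors).
#' @param memory_depth Retention horizon of the memory.
#' @return List with `x` (perturbed vector), `indices` (the perturbed set),
#'   `memory` (updated), and `memory_cleared` (logical).
#' @export
shake <- function(x, k, lower, upper, memory = list(), memory_depth = 10L) {
  nvar <- length(x)
  stopifnot(k >= 1L, k <= nvar)
  eligible <- which(upper > lower)
  if (!length(eligible)) {
    return(list(x = x, indices = integer(0), memory = memory,
                memory_cleared = FALSE))
  }
  k_eff <- min(k, length(eligible))
  n_sets <- choose(length(eligible), k_eff)
  in_memory <- function(idx) {
    any(vapply(memory, function(m) identical(m, idx), logical(1)))
  }
  mem_k <- Filter(function(m) length(m) == k_eff, memory)
  cleared <- FALSE
  if (length(unique(mem_k)) >= n_sets) {
    memory <- list()
    cleared <- TRUE
  }
  repeat {
    idx <- sort(eligible[sample.int(length(eligible), k_eff)])
    if (!in_memory(idx)) break
  }
  xp <- x
  for (i in idx) {
    vals <- lower[i]:upper[i]
    vals <- vals[vals != x[i]]
    xp[i] <- vals[1L + floor(stats::runif(1) * length(vals))]
  }
  memory[[length(memory) + 1L]] <- idx
  if (length(memory) > memory_depth) {
    memory <- memory[(length(memory) - memory_depth + 1L):length(memory)]
  }
  list(x = xp, indices = idx, memory = memory, memory_cleared = cleared)
}

# ---- internal search primitives --------------------------------------------
# All primitives speak to the objective through `evf(x) -> op_solution`,
# which may or may not memoise, and respect `limitf() -> TRUE when the
# budget is gone`.

# 1-D descent on coordinate j with go-beyond step doubling: the step doubles
# while improvement continues, falls back to 1 after a failed long step, and
# the coordinate stops only when a unit step fails. On a coordinate-wise
# unimodal objective this returns the exact 1-D minimum in O(log distance)
# evaluations.
vns_min1d <- function(sol, j, lower, upper, evf, limitf) {
  for (d in c(1, -1)) {
    step <- 1
    repeat {
      if (limitf()) return(sol)
      v <- sol$x[j] + d * step
      if (v < lower[j] || v > upper[j]) {
        if (step == 1) break
        step <- 1
        next
      }
      cand <- sol$x
      cand[j] <- v
      s <- evf(cand)
      if (s$penalized < sol$penalized) {
        sol <- s
        step <- step * 2
      } else {
        if (step == 1) break
        step <- 1
      }
    }
  }
  sol
}

# first-improvement sweeps in randomized coordinate order until a full sweep
# brings no improvement
vns_unit_sweeps <- function(sol, lower, upper, evf, limitf) {
  nvar <- length(sol$x)
  repeat {
    improved <- FALSE
    for (i in sample.int(nvar)) {
      s <- vns_min1d(sol, i, lower, upper, evf, limitf)
      if (s$penalized < sol$penalized) {
        sol <- s
        improved <- TRUE
      }
    }
    if (!improved || limitf()) break
  }
  sol
}

# two-variable intensification: for each pair (i, j), variable i sweeps its
# whole domain while j is re-optimized by 1-D descent, warm-started at the
# optimum found for the previous scan value; the best joint move is taken and
# the whole cycle repeats until no pair improves
vns_pair_sweeps <- function(sol, lower, upper, evf, limitf) {
  nvar <- length(sol$x)
  pairs <- utils::combn(nvar, 2L)
  repeat {
    sol <- vns_unit_sweeps(sol, lower, upper, evf, limitf)
    improved <- FALSE
    for (p in seq_len(ncol(pairs))) {
      if (limitf()) break
      i <- pairs[1L, p]; j <- pairs[2L, p]
      if (upper[i] <= lower[i]) next
      best <- sol
      warm <- sol$x[j]
      for (v in lower[i]:upper[i]) {
        if (limitf()) break
        cand <- sol$x
        cand[i] <- v
        cand[j] <- warm
        s <- vns_min1d(evf(cand), j, lower, upper, evf, limitf)
        warm <- s$x[j]
        if (s$penalized < best$penalized) best <- s
      }
      if (best$penalized < sol$penalized) {
        sol <- best
        improved <- TRUE
      }
    }
    if (!improved || limitf()) break
  }
  sol
}

# single aggressive sweep: first improving unit move per coordinate, no
# extension
vns_aggressive_sweep <- function(sol, lower, upper, evf, limitf) {
  nvar <- length(sol$x)
  for (i in sample.int(nvar)) {
    if (limitf()) break
    dirs <- if (stats::runif(1) < 0.5) c(1, -1) else c(-1, 1)
    for (d in dirs) {
      v <- sol$x[i] + d
      if (v < lower[i] || v > upper[i]) next
      cand <- sol$x
      cand[i] <- v
      s <- evf(cand)
      if (s$penalized < sol$penalized) {
        sol <- s
        break
      }
      if (limitf()) break
    }
  }
  sol
}

#' First-improvement integer local search with go-beyond extension
#'
#' Non-aggressive mode repeats sweeps over the coordinates (in randomized
#' order): each coordinate is descended by unit moves whose step doubles
#' while improvement continues (the go-beyond rule carried over from the
#' continuous search) and resets on failure, so each coordinate reaches its
#' exact 1-D minimum; sweeping stops when a full sweep yields no
#' improvement. Aggressive mode performs a single sweep, taking at most one
#' improving unit move per coordinate without extension. Ties never count as
#' improvements, which prevents cycling on plateaus. The returned solution
#' is never worse than the input. At a unit-move local minimum the
#' non-aggressive search spends exactly two evaluations per coordinate
#' confirming it.
#'
#' @param x Starting point: an evaluated `op_solution` (no evaluation is
#'   spent on it) or a raw integer vector (costs one evaluation).
#' @param problem All-integer [op_problem()].
#' @param counter Shared [new_counter()].
#' @param aggressive Single-sweep mode flag.
#' @param eval_limit Absolute counter value at which the search must stop.
#' @return The best `op_solution` found.
#' @export
integer_local_search <- function(x, problem, counter, aggressive = FALSE,
                                 eval_limit = Inf) {
  sol <- if (inherits(x, "op_solution")) x
  else evaluate(problem, snap_to_box(x, problem), counter)
  evf <- function(xv) evaluate(problem, xv, counter)
  limitf <- function() counter_value(counter) >= eval_limit
  if (aggressive) {
    vns_aggressive_sweep(sol, problem$lower, problem$upper, evf, limitf)
  } else {
    vns_unit_sweeps(sol, problem$lower, problem$upper, evf, limitf)
  }
}

# ---- resumable VNS state machine -------------------------------------------

vns_init <- function(problem, options) {
  stopifnot(inherits(problem, "op_problem"))
  if (length(problem$integer_indices) != problem$nvar) {
    stop("vns_solve requires an all-integer problem", call. = FALSE)
  }
  if (any(!is.finite(problem$lower)) || any(!is.finite(problem$upper))) {
    stop("vns_solve requires finite bounds", call. = FALSE)
  }
  if (is.null(options$k_max)) options$k_max <- min(problem$nvar, 10L)
  options$k_max <- max(1L, min(as.integer(options$k_max), problem$nvar))
  if (is.null(options$pair_intensify)) {
    options$pair_intensify <- problem$nvar <= 12L &&
      all(problem$upper - problem$lower <= 200)
  }

  st <- new.env(parent = emptyenv())
  st$problem <- problem
  st$options <- options
  st$counter <- new_counter()
  st$cache <- if (options$cache) new.env(parent = emptyenv()) else NULL
  st$history <- list()
  st$memory <- list()
  st$k <- 1L
  st$done <- FALSE
  st$memory_clear_count <- 0L
  # with memoisation the counter equals the number of distinct points seen,
  # so the search is exhausted once it reaches the search-space size
  st$space_size <- prod(problem$upper - problem$lower + 1)

  old_rng <- get_rng_state()
  set.seed(options$seed)
  x0 <- snap_to_box(problem$lower + stats::runif(problem$nvar) *
                      (problem$upper - problem$lower), problem)
  s0 <- vns_evf(st)(x0)
  st$incumbent <- vns_local_search(st, s0)
  st$best <- st$incumbent
  st$history <- history_push(st$history, counter_value(st$counter),
                             st$best$penalized)
  if (all(problem$upper == problem$lower)) st$done <- TRUE
  st$rng <- get_rng_state()
  set_rng_state(old_rng)
  st
}

# memoising evaluator bound to the solver state
vns_evf <- function(st) {
  if (is.null(st$cache)) {
    function(x) evaluate(st$problem, x, st$counter)
  } else {
    function(x) {
      key <- paste(x, collapse = ",")
      s <- st$cache[[key]]
      if (is.null(s)) {
        s <- evaluate(st$problem, x, st$counter)
        st$cache[[key]] <- s
      }
      s
    }
  }
}

vns_local_search <- function(st, sol) {
  evf <- vns_evf(st)
  limitf <- function() {
    counter_value(st$counter) >= st$options$max_evaluations
  }
  if (st$options$aggressive) {
    vns_aggressive_sweep(sol, st$problem$lower, st$problem$upper, evf, limitf)
  } else if (st$options$pair_intensify) {
    vns_pair_sweeps(sol, st$problem$lower, st$problem$upper, evf, limitf)
  } else {
    vns_unit_sweeps(sol, st$problem$lower, st$problem$upper, evf, limitf)
  }
}

vns_advance <- function(st, eval_limit) {
  if (st$done) return(st)
  limit <- min(eval_limit, st$options$max_evaluations)
  if (counter_value(st$counter) >= limit) return(st)
  old_rng <- get_rng_state()
  set_rng_state(st$rng)
  on.exit({ st$rng <- get_rng_state(); set_rng_state(old_rng) }, add = TRUE)

  problem <- st$problem
  opt <- st$options
  evf <- vns_evf(st)
  while (counter_value(st$counter) < limit &&
         counter_value(st$counter) < opt$max_evaluations) {
    if (!is.null(st$cache) && counter_value(st$counter) >= st$space_size) {
      st$done <- TRUE
      break
    }
    sh <- shake(st$incumbent$x, st$k, problem$lower, problem$upper,
                memory = st$memory, memory_depth = opt$memory_depth)
    st$memory <- sh$memory
    if (sh$memory_cleared) st$memory_clear_count <- st$memory_clear_count + 1L
    if (!length(sh$indices)) { st$done <- TRUE; break }
    before <- counter_value(st$counter)
    s <- evf(sh$x)
    fresh <- counter_value(st$counter) > before
    if (fresh || s$penalized < st$incumbent$penalized) {
      s <- vns_local_search(st, s)
    }
    # a memoised, non-improving shake point gets no fresh search: descending
    # again from a known point repeats work, and coverage of unseen points
    # is already guaranteed by the shakes themselves
    if (s$penalized < st$incumbent$penalized) {
      st$incumbent <- s
      st$k <- 1L
    } else {
      st$k <- st$k + 1L
      if (st$k > opt$k_max) st$k <- 1L
    }
    if (s$penalized < st$best$penalized) {
      st$best <- s
      st$history <- history_push(st$history, counter_value(st$counter),
                                 st$best$penalized)
    }
  }
  if (counter_value(st$counter) >= opt$max_evaluations) st$done <- TRUE
  st
}

vns_result <- function(st) {
  solver_result(
    best = st$best,
    history = history_matrix(st$history),
    total_evaluations = counter_value(st$counter),
    seed = st$options$seed,
    method = "vns",
    options = st$options,
    extra = list(incumbent = st$incumbent, k = st$k,
                 memory_clear_count = st$memory_clear_count)
  )
}

#' Variable neighbourhood search for integer programs
#'
#' Trajectory-based global search over an integral box. From a locally
#' optimal incumbent, a shake perturbs `k` variables to random in-bounds
#' values ([shake()]), a local search refines the perturbed point, and the
#' incumbent is recentred on strict improvement (resetting `k` to 1) or the
#' neighbourhood distance `k` grows (wrapping at `k_max`, the
#' decomposition-style cap). Recently perturbed index sets are remembered
#' and not repeated, avoiding cycles.
#'
#' The default local search runs first-improvement coordinate sweeps with
#' go-beyond step doubling, then (on small problems) two-variable domain
#' scans that escape coordinate-wise local minima of coupled objectives; all
#' evaluated points are memoised so only distinct points are charged to the
#' budget. Aggressive mode replaces this with a single cheap sweep.
#'
#' @param problem An all-integer [op_problem()] with finite bounds.
#' @param options A [vns_options()] list.
#' @return A `solver_result` (see [ess_solve()] for the fields).
#' @examples
#' p <- op_problem(function(x) sum((x - c(2, 9))^2), c(0, 0), c(10, 10),
#'                 integer_indices = 1:2)
#' vns_solve(p, vns_options(max_evaluations = 500, seed = 1))$best$x
#' @export
vns_solve <- function(problem, options = vns_options()) {
  st <- vns_init(problem, options)
  st <- vns_advance(st, options$max_evaluations)
  vns_result(st)
}
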