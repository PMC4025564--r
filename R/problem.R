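#' Define a black-box optimization problem
#'
#' An `op_problem` bundles everything a solver needs: the objective, box
#' bounds, which variables are integer, and how constraint violations are
#' penalized. The objective is treated as a black box: it receives a decision
#' vector and returns either a numeric scalar (the objective value) or a list
#' with elements `f` (scalar) and `g` (numeric vector of constraint
#' residuals). Residuals are compared against `constraint_lower` /
#' `constraint_upper`; the total amount by which they fall outside those
#' bounds is the violation, and solvers rank solutions by the penalized merit
#' `f + penalty_weight * violation`.
#'
#' The integer index set determines the problem class: empty gives a
#' continuous NLP, a proper subset a mixed-integer NLP, and the full set an
#' integer program (the class [vns_solve()] requires). Bounds on integer
#' variables are rounded inward to the nearest integers so that the feasible
#' integer box is exactly representable.
#'
#' @param objective Function of one numeric vector; returns a scalar or
#'   `list(f = scalar, g = residual vector)`.
#' @param lower,upper Numeric vectors of equal length, the box bounds.
#' @param integer_indices Integer vector of 1-based positions constrained to
#'   integer values. Default none (continuous problem).
#' @param constraint_lower,constraint_upper Optional numeric vectors bounding
#'   the residual vector `g`; use `-Inf`/`Inf` for one-sided constraints.
#' @param penalty_weight Nonnegative scalar multiplying the total constraint
#'   excess in the penalized merit. Default `1e3`.
#' @param name Label carried into results.
#' @return An object of class `op_problem`.
#' @examples
#' p <- op_problem(function(x) sum(x^2), lower = rep(-5, 3), upper = rep(5, 3))
#' ctr <- new_counter()
#' evaluate(p, c(0, 0, 0), ctr)$f
#' @seealso [evaluate()], [ess_solve()], [vns_solve()]
#' @export
op_problem <- function(objective, lower, upper, integer_indices = integer(0),
                       constraint_lower = NULL, constraint_upper = NULL,
                       penalty_weight = 1e3, name = "problem") {
  stopifnot(is.function(objective), is.numeric(lower), is.numeric(upper))
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper)) {
    stop("`lower` and `upper` must have the same length", call. = FALSE)
  }
  nvar <- length(lower)
  if (nvar < 1L) stop("problem must have at least one variable", call. = FALSE)
  if (any(lower > upper)) {
    stop("`lower` must not exceed `upper` in any coordinate", call. = FALSE)
  }
  integer_indices <- sort(unique(as.integer(integer_indices)))
  if (length(integer_indices) &&
      (min(integer_indices) < 1L || max(integer_indices) > nvar)) {
    stop("`integer_indices` out of range 1..nvar", call. = FALSE)
  }
  # integer variables live on an exactly integral box
  if (length(integer_indices)) {
    lower[integer_indices] <- ceiling(lower[integer_indices] - 1e-9)
    upper[integer_indices] <- floor(upper[integer_indices] + 1e-9)
    if (any(lower[integer_indices] > upper[integer_indices])) {
      stop("integer bounds leave no feasible value", call. = FALSE)
    }
  }
  if (!is.numeric(penalty_weight) || length(penalty_weight) != 1L ||
      penalty_weight < 0) {
    stop("`penalty_weight` must be a nonnegative scalar", call. = FALSE)
  }
  if (xor(is.null(constraint_lower), is.null(constraint_upper))) {
    if (is.null(constraint_lower)) constraint_lower <- rep(-Inf, length(constraint_upper))
    else constraint_upper <- rep(Inf, length(constraint_lower))
  }
  structure(
    list(
      objective = objective,
      lower = lower, upper = upper, nvar = nvar,
      integer_indices = integer_indices,
      constraint_lower = constraint_lower,
      constraint_upper = constraint_upper,
      penalty_weight = penalty_weight,
      name = name
    ),
    class = "op_problem"
  )
}

#' @export
print.op_problem <- function(x, ...) {
  kind <- if (length(x$integer_indices) == 0L) "continuous NLP"
  else if (length(x$integer_indices) == x$nvar) "integer program"
  else "mixed-integer NLP"
  cat("<op_problem> ", x$name, ": ", x$nvar, " variables (", kind, ")\n",
      sep = "")
  invisible(x)
}

#' Evaluation counter
#'
#' Solvers charge every objective call (including calls made inside local
#' searches) against a shared counter so that evaluation budgets mean the
#' same thing everywhere. The counter is a mutable environment; pass the same
#' counter to [evaluate()] and read it with [counter_value()].
#'
#' @return An environment of class `eval_counter` with a single field `n`.
#' @export
new_counter <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  class(e) <- "eval_counter"
  e
}

#' @rdname new_counter
#' @param counter An [new_counter()] object.
#' @export
counter_value <- function(counter) counter$n

#' Evaluate a problem at a point
#'
#' Calls the problem's objective once, computes the constraint violation (the
#' summed magnitude by which residuals exceed their bounds) and the penalized
#' merit, and advances the evaluation counter by exactly one. A non-finite
#' objective or residual does not abort the search: the solution is returned
#' with `penalized = Inf` and flagged, so solvers simply rank it last.
#'
#' @param problem An [op_problem()].
#' @param x Numeric decision vector, inside the bounds, integral at integer
#'   positions.
#' @param counter A [new_counter()] accountant (advanced by 1).
#' @return A list of class `op_solution` with fields `x`, `f`, `violation`,
#'   `penalized`, `feasible`, `finite`.
#' @export
evaluate <- function(problem, x, counter) {
  if (length(x) != problem$nvar) {
    stop("decision vector has length ", length(x), ", expected ",
         problem$nvar, call. = FALSE)
  }
  x <- as.numeric(x)
  out <- problem$objective(x)
  counter$n <- counter$n + 1L
  if (is.list(out)) {
    f <- as.numeric(out$f)[1L]
    g <- as.numeric(out$g)
  } else {
    f <- as.numeric(out)[1L]
    g <- numeric(0)
  }
  violation <- 0
  if (length(g)) {
    cl <- problem$constraint_lower
    cu <- problem$constraint_upper
    if (is.null(cl)) cl <- rep(-Inf, length(g))
    if (is.null(cu)) cu <- rep(Inf, length(g))
    violation <- sum(pmax(g - cu, 0), pmax(cl - g, 0))
  }
  finite <- is.finite(f) && is.finite(violation)
  penalized <- if (finite) f + problem$penalty_weight * violation else Inf
  structure(
    list(x = x, f = f, violation = violation, penalized = penalized,
         feasible = finite && violation == 0, finite = finite),
    class = "op_solution"
  )
}

#' @export
print.op_solution <- function(x, ...) {
  cat("<op_solution> f = ", format(x$f), if (x$violation > 0)
    paste0(", violation = ", format(x$violation)), "\n", sep = "")
  invisible(x)
}

#' Latin hypercube sample inside a box
#'
#' Stratified uniform design: for each coordinate the `n_points` equal-width
#' strata of `[lower, upper]` each receive exactly one point. Used to build
#' the diverse initial set of the scatter search and fresh replacement points.
#' A degenerate coordinate (`lower == upper`) is held constant.
#'
#' @param lower,upper Numeric bound vectors.
#' @param n_points Number of rows to generate (>= 1).
#' @param seed Optional integer; when given, the design is a pure function of
#'   the seed (the caller's RNG state is left untouched). When `NULL`, draws
#'   come from the current RNG stream.
#' @return Numeric matrix `n_points` x `length(lower)`, rows within bounds.
#' @export
latin_hypercube <- function(lower, upper, n_points, seed = NULL) {
  stopifnot(n_points >= 1)
  nvar <- length(lower)
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(set_rng_state(old), add = TRUE)
    set.seed(seed)
  }
  u <- lhs::randomLHS(as.integer(n_points), as.integer(nvar))
  sweep(sweep(u, 2L, upper - lower, `*`), 2L, lower, `+`)
}

# Save/restore the global RNG state (NULL when no state exists yet).
get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Round integer positions to the nearest in-bounds integer and clip the rest.
snap_to_box <- function(x, problem) {
  x <- pmin(pmax(x, problem$lower), problem$upper)
  ii <- problem$integer_indices
  if (length(ii)) {
    x[ii] <- pmin(pmax(round(x[ii]), problem$lower[ii]), problem$upper[ii])
  }
  x
}

# Shared constructor for solver outputs.
solver_result <- function(best, history, total_evaluations, seed, method,
                          options, warning = NULL, extra = list()) {
  history <- as.data.frame(history)
  names(history) <- c("evaluations", "best")
  structure(
    c(list(best = best, history = history,
           total_evaluations = as.integer(total_evaluations),
           seed = seed, method = method, options = options,
           warning = warning),
      extra),
    class = "solver_result"
  )
}

#' @export
print.solver_result <- function(x, ...) {
  cat("<solver_result> ", x$method, "\n", sep = "")
  cat("  best penalized objective: ", format(x$best$penalized), "\n", sep = "")
  cat("  evaluations used:         ", x$total_evaluations, "\n", sep = "")
  if (!is.null(x$warning)) cat("  warning: ", x$warning, "\n", sep = "")
  invisible(x)
}

# Append an improvement record to a history accumulator (list of rows).
history_push <- function(hist, evals, best) {
  hist[[length(hist) + 1L]] <- c(evals, best)
  hist
}

history_matrix <- function(hist) {
  if (!length(hist)) return(matrix(numeric(0), ncol = 2L))
  do.call(rbind, hist)
}
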