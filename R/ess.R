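#' Options for the enhanced scatter search
#'
#' Defaults follow the small-population philosophy of scatter search: a
#' RefSet of `max(8, 1 + sqrt(2 nvar))` (rounded up to an even number),
#' systematic pairwise combination with two offspring per directed pair,
#' strict 1+1 replacement, go-beyond intensification and a memory-filtered
#' bounded simplex local search.
#'
#' @param max_evaluations Objective-evaluation budget (all calls count,
#'   including those made inside local searches).
#' @param N RefSet size; `NULL` picks the dimension-based default. Must be
#'   even and at least 4.
#' @param diverse_set_size Size of the initial stratified (Latin hypercube)
#'   diverse set; `NULL` gives `10 * nvar` (at least `2 N`).
#' @param local_search_enabled Run the improvement method?
#' @param local_search_interval Iterations between local searches.
#' @param local_search_max_evals Evaluation cap per local search; `NULL`
#'   gives `250 * nvar`.
#' @param local_search_filter_radius Normalized distance below which a
#'   candidate start is considered already explored by a previous local
#'   search and skipped.
#' @param stagnation_threshold Iterations a member may remain unchanged
#'   before it is replaced by a fresh diverse point (the incumbent best is
#'   immune).
#' @param offspring_per_pair Offspring generated per directed RefSet pair.
#' @param combine_margin Stretch factor of the combination box toward the
#'   better parent, as a fraction of the parent-to-parent distance.
#' @param seed Integer seed; every random draw of the run derives from it.
#' @return A list of class `ess_options`.
#' @export
ess_options <- function(max_evaluations = 10000L, N = NULL,
                        diverse_set_size = NULL,
                        local_search_enabled = TRUE,
                        local_search_interval = 10L,
                        local_search_max_evals = NULL,
                        local_search_filter_radius = 0.05,
                        stagnation_threshold = 20L,
                        offspring_per_pair = 2L,
                        combine_margin = 0.5,
                        seed = 1L) {
  opts <- list(max_evaluations = as.integer(max_evaluations), N = N,
               diverse_set_size = diverse_set_size,
               local_search_enabled = isTRUE(local_search_enabled),
               local_search_interval = as.integer(local_search_interval),
               local_search_max_evals = local_search_max_evals,
               local_search_filter_radius = local_search_filter_radius,
               stagnation_threshold = as.integer(stagnation_threshold),
               offspring_per_pair = as.integer(offspring_per_pair),
               combine_margin = combine_margin,
               seed = as.integer(seed))
  stopifnot(opts$max_evaluations >= 1L, opts$local_search_interval >= 1L,
            opts$stagnation_threshold >= 1L, opts$offspring_per_pair >= 1L,
            opts$combine_margin >= 0, opts$local_search_filter_radius >= 0)
  class(opts) <- "ess_options"
  opts
}

ess_fill_defaults <- function(options, nvar) {
  if (is.null(options$N)) {
    n0 <- ceiling(1 + sqrt(2 * nvar))
    if (n0 %% 2 == 1) n0 <- n0 + 1
    options$N <- max(8L, as.integer(n0))
  }
  options$N <- as.integer(options$N)
  if (options$N < 4L || options$N %% 2L != 0L) {
    stop("RefSet size N must be even and >= 4", call. = FALSE)
  }
  if (is.null(options$diverse_set_size)) {
    options$diverse_set_size <- max(10L * nvar, 2L * options$N)
  }
  options$diverse_set_size <- as.integer(options$diverse_set_size)
  if (options$diverse_set_size < options$N) {
    stop("diverse_set_size must be at least N", call. = FALSE)
  }
  if (is.null(options$local_search_max_evals)) {
    options$local_search_max_evals <- 250L * nvar
  }
  options$local_search_max_evals <- as.integer(options$local_search_max_evals)
  options
}

# normalized euclidean distance (coordinates scaled by bound widths)
norm_dist <- function(x, y, width) {
  sqrt(sum(((x - y) / width)^2) / length(x))
}

#' Combine two solutions into offspring vectors
#'
#' Offspring are sampled uniformly inside the hyper-rectangle spanned by the
#' two parents, stretched by `margin` times the parent-to-parent distance
#' toward the better parent (the combination is biased into the promising
#' half-space), then clipped to the bounds; integer positions are rounded to
#' the nearest in-bounds integer. Identical parents yield perturbed copies of
#' the common point (never exact duplicates) so degenerate pairs still add
#' diversity.
#'
#' @param a,b Numeric parent vectors.
#' @param lower,upper Bound vectors.
#' @param f_a,f_b Optional merit values of the parents; when both are given
#'   the box is stretched toward the better one.
#' @param integer_indices Positions rounded to integers.
#' @param n_offspring Number of offspring vectors to return.
#' @param margin Stretch factor (0 disables the bias).
#' @return List of `n_offspring` in-bounds vectors.
#' @export
combine_pair <- function(a, b, lower, upper, f_a = NA_real_, f_b = NA_real_,
                         integer_indices = integer(0), n_offspring = 2L,
                         margin = 0.5) {
  a <- as.numeric(a); b <- as.numeric(b)
  width <- pmax(upper - lower, .Machine$double.eps)
  identical_parents <- all(a == b)
  if (identical_parents) {
    lo <- pmax(lower, a - 0.01 * width)
    hi <- pmin(upper, a + 0.01 * width)
  } else {
    lo <- pmin(a, b); hi <- pmax(a, b)
    if (!is.na(f_a) && !is.na(f_b) && f_a != f_b) {
      d <- abs(a - b) * margin
      if (f_a < f_b) { # stretch past a
        lo <- ifelse(a <= b, lo - d, lo)
        hi <- ifelse(a > b, hi + d, hi)
      } else {
        lo <- ifelse(b <= a, lo - d, lo)
        hi <- ifelse(b > a, hi + d, hi)
      }
    }
    lo <- pmax(lo, lower); hi <- pmin(hi, upper)
  }
  out <- vector("list", n_offspring)
  for (k in seq_len(n_offspring)) {
    x <- lo + stats::runif(length(a)) * (hi - lo)
    if (length(integer_indices)) {
      x[integer_indices] <- pmin(pmax(round(x[integer_indices]),
                                      ceiling(lower[integer_indices])),
                                 floor(upper[integer_indices]))
    }
    if (identical_parents && all(x == a)) {
      # forced move for all-integer degenerate pairs: bump one free coordinate
      free <- which(floor(upper) > ceiling(lower))
      if (length(free)) {
        i <- free[1L + floor(stats::runif(1) * length(free))]
        x[i] <- if (x[i] < upper[i]) x[i] + 1 else x[i] - 1
        if (i %in% integer_indices) x[i] <- round(x[i])
      }
    }
    out[[k]] <- x
  }
  out
}

#' 1+1 replacement in the reference set
#'
#' An offspring may replace only the member that generated it, and only on
#' strict improvement of the penalized merit; no other member is ever
#' touched. This is what keeps the RefSet diverse: a strong offspring cannot
#' displace unrelated members, so the population does not collapse onto one
#' basin.
#'
#' @param refset List with fields `members` (list of solutions) and
#'   `stagnation` (integer vector).
#' @param parent_index Position of the generating member.
#' @param offspring An evaluated solution ([evaluate()]).
#' @return The updated refset; `attr(, "replaced")` says whether replacement
#'   happened.
#' @export
replace_one_plus_one <- function(refset, parent_index, offspring) {
  stopifnot(parent_index >= 1L, parent_index <= length(refset$members))
  replaced <- offspring$penalized < refset$members[[parent_index]]$penalized
  if (replaced) {
    refset$members[[parent_index]] <- offspring
    refset$stagnation[parent_index] <- 0L
  } else {
    refset$stagnation[parent_index] <- refset$stagnation[parent_index] + 1L
  }
  attr(refset, "replaced") <- replaced
  refset
}

#' Go-beyond intensification along a promising direction
#'
#' When an offspring beats its parent, the segment parent -> offspring is
#' extrapolated: a probe is placed one step past the offspring, the step
#' doubling after every improvement, until a probe fails to improve or
#' clipping at the bounds stalls the movement. Returns the best solution
#' found. Called with an offspring that is not better than its parent, it
#' returns the offspring untouched without spending evaluations.
#'
#' @param parent,offspring Evaluated solutions, `offspring` generated from
#'   `parent`.
#' @param problem The [op_problem()].
#' @param counter Shared [new_counter()].
#' @return The best solution along the explored direction.
#' @export
go_beyond <- function(parent, offspring, problem, counter) {
  if (!(offspring$penalized < parent$penalized)) return(offspring)
  d <- offspring$x - parent$x
  base <- offspring
  lambda <- 1
  repeat {
    cand <- snap_to_box(base$x + lambda * d, problem)
    if (all(cand == base$x)) break # clipped against the box, no movement
    s <- evaluate(problem, cand, counter)
    if (s$penalized < base$penalized) {
      base <- s
      lambda <- lambda * 2
    } else break
  }
  base
}

#' Memory-guided local search step
#'
#' Picks the best RefSet member that lies farther than `filter_radius`
#' (normalized by the bound widths) from every final point of previous local
#' searches, refines it with the bounded simplex search (integer coordinates
#' frozen, then polished by unit moves), archives the initial and final
#' points, and replaces the member on improvement. When every member sits
#' inside the exclusion radius of some archived optimum, no search is run:
#' this is the memory that stops the improvement method from re-polishing
#' the same basin.
#'
#' @param refset RefSet structure (`members`, `stagnation`).
#' @param archive List with fields `starts` and `finals` (lists of vectors).
#' @param problem,counter Problem and shared evaluation counter.
#' @param filter_radius Normalized exclusion distance.
#' @param max_evals Evaluation cap for the refinement.
#' @return List `refset`, `archive`, `performed`, `evaluations`.
#' @export
memory_local_search <- function(refset, archive, problem, counter,
                                filter_radius = 0.05, max_evals = 500L) {
  width <- pmax(problem$upper - problem$lower, .Machine$double.eps)
  eligible <- vapply(refset$members, function(m) {
    !length(archive$finals) ||
      all(vapply(archive$finals,
                 function(fp) norm_dist(m$x, fp, width) > filter_radius,
                 logical(1)))
  }, logical(1))
  if (!any(eligible)) {
    return(list(refset = refset, archive = archive, performed = FALSE,
                evaluations = 0L))
  }
  pen <- vapply(refset$members, function(m) m$penalized, numeric(1))
  pen[!eligible] <- Inf
  i <- which.min(pen)
  start <- refset$members[[i]]
  before <- counter_value(counter)
  refined <- refine_solution(start, problem, counter, max_evals)
  spent <- counter_value(counter) - before
  archive$starts[[length(archive$starts) + 1L]] <- start$x
  archive$finals[[length(archive$finals) + 1L]] <- refined$x
  if (refined$penalized < start$penalized) {
    refset$members[[i]] <- refined
    refset$stagnation[i] <- 0L
  }
  list(refset = refset, archive = archive, performed = TRUE,
       evaluations = spent)
}

# Bounded simplex refinement on the continuous coordinates (integers frozen),
# followed by a unit-move polish of the integer coordinates.
refine_solution <- function(start, problem, counter, max_evals) {
  ii <- problem$integer_indices
  cont <- setdiff(seq_len(problem$nvar), ii)
  best <- start
  if (length(cont)) {
    fn <- function(xc) {
      x <- best$x
      x[cont] <- xc
      s <- evaluate(problem, x, counter)
      if (s$penalized < best$penalized) best <<- s
      s$penalized
    }
    nm_bounded(fn, start$x[cont], problem$lower[cont], problem$upper[cont],
               max_evals = max_evals)
  }
  if (length(ii)) {
    improved <- TRUE
    while (improved) {
      improved <- FALSE
      for (j in ii) {
        for (step in c(1, -1)) {
          cand <- best$x
          cand[j] <- cand[j] + step
          if (cand[j] < problem$lower[j] || cand[j] > problem$upper[j]) next
          s <- evaluate(problem, cand, counter)
          if (s$penalized < best$penalized) {
            best <- s
            improved <- TRUE
            break
          }
        }
      }
    }
  }
  best
}

# ---- resumable eSS state machine -------------------------------------------
# The solver is split into init / advance / result so the cooperative driver
# can advance a thread by tau evaluations at a time; pausing and resuming is
# bit-identical to one uninterrupted run because the RNG state travels with
# the solver state.

ess_init <- function(problem, options) {
  stopifnot(inherits(problem, "op_problem"))
  options <- ess_fill_defaults(options, problem$nvar)
  st <- new.env(parent = emptyenv())
  st$problem <- problem
  st$options <- options
  st$counter <- new_counter()
  st$history <- list()
  st$iter <- 0L
  st$archive <- list(starts = list(), finals = list())
  st$warning <- NULL
  st$done <- FALSE

  old_rng <- get_rng_state()
  set.seed(options$seed)

  D <- options$diverse_set_size
  pts <- latin_hypercube(problem$lower, problem$upper, D)
  n_eval <- min(D, options$max_evaluations)
  sols <- vector("list", n_eval)
  for (i in seq_len(n_eval)) {
    sols[[i]] <- evaluate(problem, snap_to_box(pts[i, ], problem), st$counter)
  }
  pen <- vapply(sols, function(s) s$penalized, numeric(1))
  st$best <- sols[[which.min(pen)]]
  st$history <- history_push(st$history, counter_value(st$counter),
                             st$best$penalized)
  if (n_eval < D || n_eval < options$N) {
    st$warning <- "budget exhausted during initialization"
    st$done <- TRUE
    st$refset <- list(members = sols, stagnation = rep(0L, length(sols)))
  } else {
    st$refset <- select_refset(sols, pen, options$N, problem)
  }
  st$rng <- get_rng_state()
  set_rng_state(old_rng)
  st
}

# Quality/diversity split: best N/2 members by merit, then greedy max-min
# normalized distance picks for the remaining half.
select_refset <- function(sols, pen, N, problem) {
  width <- pmax(problem$upper - problem$lower, .Machine$double.eps)
  ord <- order(pen)
  h <- N %/% 2L
  chosen <- ord[seq_len(h)]
  pool <- setdiff(ord, chosen)
  while (length(chosen) < N && length(pool)) {
    dmin <- vapply(pool, function(i) {
      min(vapply(chosen, function(j)
        norm_dist(sols[[i]]$x, sols[[j]]$x, width), numeric(1)))
    }, numeric(1))
    pick <- pool[which.max(dmin)]
    chosen <- c(chosen, pick)
    pool <- setdiff(pool, pick)
  }
  list(members = sols[chosen], stagnation = rep(0L, length(chosen)))
}

ess_advance <- function(st, eval_limit) {
  if (st$done) return(st)
  limit <- min(eval_limit, st$options$max_evaluations)
  if (counter_value(st$counter) >= limit) return(st)
  old_rng <- get_rng_state()
  set_rng_state(st$rng)
  on.exit({ st$rng <- get_rng_state(); set_rng_state(old_rng) }, add = TRUE)

  problem <- st$problem
  opt <- st$options
  N <- opt$N
  while (counter_value(st$counter) < limit &&
         counter_value(st$counter) < opt$max_evaluations) {
    # final intensification: once the remaining budget fits inside a single
    # local search, spend it polishing the incumbent best (the memory filter
    # only governs exploratory searches, not this last refinement)
    remaining <- opt$max_evaluations - counter_value(st$counter)
    if (opt$local_search_enabled && !isTRUE(st$final_polish_done) &&
        remaining <= opt$local_search_max_evals) {
      st$final_polish_done <- TRUE
      refined <- refine_solution(st$best, problem, st$counter, remaining)
      if (refined$penalized < st$best$penalized) {
        st$best <- refined
        st$history <- history_push(st$history, counter_value(st$counter),
                                   st$best$penalized)
      }
      next
    }
    st$iter <- st$iter + 1L

    # combination + 1+1 replacement (+ go-beyond)
    members_now <- st$refset$members # combine against the iteration snapshot
    for (i in seq_len(N)) {
      parent <- members_now[[i]]
      best_child <- NULL
      for (j in seq_len(N)) {
        if (j == i) next
        other <- members_now[[j]]
        kids <- combine_pair(parent$x, other$x, problem$lower, problem$upper,
                             f_a = parent$penalized, f_b = other$penalized,
                             integer_indices = problem$integer_indices,
                             n_offspring = opt$offspring_per_pair,
                             margin = opt$combine_margin)
        for (kx in kids) {
          s <- evaluate(problem, snap_to_box(kx, problem), st$counter)
          if (is.null(best_child) || s$penalized < best_child$penalized) {
            best_child <- s
          }
        }
      }
      if (!is.null(best_child)) {
        if (best_child$penalized < parent$penalized) {
          best_child <- go_beyond(parent, best_child, problem, st$counter)
        }
        st$refset <- replace_one_plus_one(st$refset, i, best_child)
        if (best_child$penalized < st$best$penalized) {
          st$best <- best_child
          st$history <- history_push(st$history,
                                     counter_value(st$counter),
                                     st$best$penalized)
        }
      }
    }

    # regenerate stagnated members (incumbent best is immune)
    pen <- vapply(st$refset$members, function(m) m$penalized, numeric(1))
    ibest <- which.min(pen)
    for (i in seq_len(N)) {
      if (i != ibest && st$refset$stagnation[i] >= opt$stagnation_threshold) {
        x <- problem$lower + stats::runif(problem$nvar) *
          (problem$upper - problem$lower)
        s <- evaluate(problem, snap_to_box(x, problem), st$counter)
        st$refset$members[[i]] <- s
        st$refset$stagnation[i] <- 0L
        if (s$penalized < st$best$penalized) {
          st$best <- s
          st$history <- history_push(st$history,
                                     counter_value(st$counter),
                                     st$best$penalized)
        }
      }
    }

    # improvement method, memory-filtered
    if (opt$local_search_enabled &&
        (st$iter %% opt$local_search_interval) == 1L %% opt$local_search_interval) {
      budget_left <- opt$max_evaluations - counter_value(st$counter)
      if (budget_left > 0) {
        ls <- memory_local_search(
          st$refset, st$archive, problem, st$counter,
          filter_radius = opt$local_search_filter_radius,
          max_evals = min(opt$local_search_max_evals, budget_left))
        st$refset <- ls$refset
        st$archive <- ls$archive
        pen <- vapply(st$refset$members, function(m) m$penalized, numeric(1))
        if (min(pen) < st$best$penalized) {
          st$best <- st$refset$members[[which.min(pen)]]
          st$history <- history_push(st$history,
                                     counter_value(st$counter),
                                     st$best$penalized)
        }
      }
    }
  }
  if (counter_value(st$counter) >= opt$max_evaluations) st$done <- TRUE
  st
}

ess_result <- function(st) {
  solver_result(
    best = st$best,
    history = history_matrix(st$history),
    total_evaluations = counter_value(st$counter),
    seed = st$options$seed,
    method = "ess",
    options = st$options,
    warning = st$warning,
    extra = list(refset = st$refset, iterations = st$iter)
  )
}

#' Enhanced scatter search
#'
#' Population-based global search for continuous and mixed-integer problems.
#' A small reference set (RefSet), seeded from a stratified diverse set, is
#' combined systematically: every directed pair of members spawns offspring
#' in the biased hyper-rectangle between them, an offspring may replace only
#' its own parent (1+1 replacement, which preserves diversity and prevents
#' premature stagnation), improving directions are extrapolated by the
#' go-beyond rule, stagnant members are regenerated, and a memory-filtered
#' bounded simplex local search periodically polishes the most promising
#' unexplored member. Integer coordinates are rounded before every
#' evaluation, so the objective only ever sees feasible mixed-integer points.
#'
#' @param problem An [op_problem()] with at least one continuous or integer
#'   variable.
#' @param options An [ess_options()] list.
#' @return A `solver_result`: best solution found, a monotone convergence
#'   history (`evaluations`, `best`), total evaluation count, the option
#'   snapshot, and the final RefSet.
#' @examples
#' p <- op_problem(function(x) sum(x^2), rep(-5, 3), rep(5, 3), name = "sphere")
#' r <- ess_solve(p, ess_options(max_evaluations = 3000, seed = 1))
#' r$best$f
#' @export
ess_solve <- function(problem, options = ess_options()) {
  st <- ess_init(problem, options)
  st <- ess_advance(st, options$max_evaluations)
  ess_result(st)
}
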