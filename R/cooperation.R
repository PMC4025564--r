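#' Configuration of the cooperative multi-thread strategy
#'
#' The cooperative strategy runs `eta` solver threads with heterogeneous
#' settings in synchronous rounds. Each round every thread advances its own
#' search by `tau` objective evaluations; at the round barrier the best
#' solution across all threads is broadcast to every thread, and optionally
#' (scatter-search threads only) the leading thread's second-best RefSet
#' member is shared as well. Rounds are measured in evaluations, not
#' wall-clock time, so cooperative runs are reproducible and
#' hardware-independent.
#'
#' @param eta Number of threads (>= 1).
#' @param tau Exchange interval in objective evaluations per thread per
#'   round.
#' @param total_rounds Number of rounds; each thread's budget is
#'   `tau * total_rounds`.
#' @param thread_profiles Optional list of `eta` option sets
#'   ([ess_options()] or [vns_options()]); `NULL` derives them with
#'   [make_profiles()], spanning conservative (diversification-heavy) to
#'   aggressive (intensification-heavy).
#' @param share_refset Also share the leading thread's second-best RefSet
#'   member (scatter search only).
#' @param seeds Integer vector of `eta` per-thread seeds; `NULL` gives
#'   `seed + 0:(eta-1)`.
#' @param seed Base seed used when `seeds` is `NULL`.
#' @return A list of class `cooperation_config`.
#' @export
cooperation_config <- function(eta = 4L, tau = 2500L, total_rounds = 4L,
                               thread_profiles = NULL, share_refset = FALSE,
                               seeds = NULL, seed = 1L) {
  eta <- as.integer(eta)
  tau <- as.integer(tau)
  total_rounds <- as.integer(total_rounds)
  stopifnot(eta >= 1L, tau >= 1L, total_rounds >= 1L)
  if (is.null(seeds)) seeds <- as.integer(seed) + 0:(eta - 1L)
  if (length(seeds) != eta) stop("need one seed per thread", call. = FALSE)
  if (!is.null(thread_profiles) && length(thread_profiles) != eta) {
    stop("need one option profile per thread", call. = FALSE)
  }
  structure(list(eta = eta, tau = tau, total_rounds = total_rounds,
                 thread_profiles = thread_profiles,
                 share_refset = isTRUE(share_refset),
                 seeds = as.integer(seeds)),
            class = "cooperation_config")
}

#' Derive heterogeneous thread profiles
#'
#' Interpolates `eta` option sets between a conservative endpoint
#' (diversification: large RefSet and rare local search for scatter search;
#' non-aggressive sweeps and an uncapped neighbourhood distance for VNS) and
#' an aggressive endpoint (intensification: small RefSet and frequent local
#' search; aggressive single-sweep search with a tight neighbourhood cap).
#' With `eta = 1` the base options are returned unchanged. Deterministic
#' given its inputs.
#'
#' @param eta Number of profiles.
#' @param base_options An [ess_options()] or [vns_options()] object used as
#'   the template (seed and budget are overridden per thread by
#'   [cooperative_solve()]).
#' @param kind `"ess"` or `"vns"`.
#' @param nvar Problem dimension, used to resolve dimension-dependent
#'   defaults of the scatter search.
#' @return List of `eta` option objects, conservative first.
#' @export
make_profiles <- function(eta, base_options, kind = c("ess", "vns"),
                          nvar = NULL) {
  kind <- match.arg(kind)
  eta <- as.integer(eta)
  stopifnot(eta >= 1L)
  if (eta == 1L) return(list(base_options))
  ts <- seq(0, 1, length.out = eta)
  if (kind == "ess") {
    base <- if (!is.null(nvar)) ess_fill_defaults(base_options, nvar)
    else base_options
    N0 <- if (is.null(base$N)) 10L else base$N
    n_cons <- 2L * N0
    n_aggr <- max(4L, as.integer(2 * floor(N0 / 4)))
    out <- vector("list", eta)
    prevN <- Inf
    for (i in seq_len(eta)) {
      o <- base_options
      Ni <- round(exp((1 - ts[i]) * log(n_cons) + ts[i] * log(n_aggr)))
      Ni <- as.integer(2 * ceiling(Ni / 2))
      if (Ni >= prevN) Ni <- max(4L, as.integer(prevN - 2L))
      prevN <- Ni
      o$N <- Ni
      o$local_search_interval <-
        max(1L, as.integer(round((1 - ts[i]) * 20 + ts[i] * 2)))
      out[[i]] <- o
    }
    out
  } else {
    out <- vector("list", eta)
    for (i in seq_len(eta)) {
      o <- base_options
      o$aggressive <- ts[i] > 0.5
      if (o$aggressive) o$k_max <- 3L
      out[[i]] <- o
    }
    out
  }
}

#' Cooperative scatter search / VNS
#'
#' Runs `eta` heterogeneous solver threads in synchronous rounds of `tau`
#' evaluations each and exchanges incumbents at the round barrier: the
#' global best solution is offered to every thread and adopted only when it
#' strictly improves the thread's own best (scatter-search threads splice it
#' in place of their worst RefSet member, protecting their own elite; VNS
#' threads recentre their incumbent on it). With `share_refset`, the leading
#' thread's second-best member is additionally offered against each other
#' thread's second-worst member. Threads are advanced round-robin within a
#' single process; each carries its own RNG stream, so the result is
#' deterministic and, with `eta = 1`, bit-identical to the plain solver.
#'
#' @param problem An [op_problem()] (all-integer for `solver = "vns"`).
#' @param config A [cooperation_config()].
#' @param solver `"ess"` (CeSS) or `"vns"` (CVNS).
#' @param base_options Template options for [make_profiles()]; `NULL` uses
#'   the solver's defaults.
#' @return A `solver_result` whose `best` is the global best; `extra` fields
#'   `thread_results` (per-thread `solver_result`s with their own
#'   histories) and `round_bests` (global best after each round). The merged
#'   history records the global best at each round barrier against
#'   cumulative evaluations across threads.
#' @export
cooperative_solve <- function(problem, config = cooperation_config(),
                              solver = c("ess", "vns"),
                              base_options = NULL) {
  solver <- match.arg(solver)
  stopifnot(inherits(config, "cooperation_config"))
  if (is.null(base_options)) {
    base_options <- if (solver == "ess") ess_options() else vns_options()
  }
  profiles <- config$thread_profiles
  if (is.null(profiles)) {
    profiles <- make_profiles(config$eta, base_options, solver,
                              nvar = problem$nvar)
  }
  budget <- config$tau * config$total_rounds
  states <- vector("list", config$eta)
  for (i in seq_len(config$eta)) {
    o <- profiles[[i]]
    o$max_evaluations <- budget
    o$seed <- config$seeds[i]
    states[[i]] <- if (solver == "ess") ess_init(problem, o)
    else vns_init(problem, o)
  }

  round_bests <- numeric(config$total_rounds)
  merged <- list()
  for (r in seq_len(config$total_rounds)) {
    for (i in seq_len(config$eta)) {
      states[[i]] <- if (solver == "ess") {
        ess_advance(states[[i]], r * config$tau)
      } else {
        vns_advance(states[[i]], r * config$tau)
      }
    }
    pens <- vapply(states, function(s) s$best$penalized, numeric(1))
    leader <- which.min(pens)
    gbest <- states[[leader]]$best
    round_bests[r] <- gbest$penalized
    evals_so_far <- sum(vapply(states, function(s)
      counter_value(s$counter), numeric(1)))
    merged <- history_push(merged, evals_so_far, gbest$penalized)

    for (i in seq_len(config$eta)) {
      st <- states[[i]]
      if (gbest$penalized < st$best$penalized) {
        if (solver == "ess") {
          pen_i <- vapply(st$refset$members, function(m) m$penalized,
                          numeric(1))
          w <- which.max(pen_i)
          st$refset$members[[w]] <- gbest
          st$refset$stagnation[w] <- 0L
        } else {
          st$incumbent <- gbest
          st$k <- 1L
        }
        st$best <- gbest
      }
      if (solver == "ess" && config$share_refset && i != leader) {
        lead_pens <- vapply(states[[leader]]$refset$members,
                            function(m) m$penalized, numeric(1))
        if (length(lead_pens) >= 2L) {
          second <- states[[leader]]$refset$members[[order(lead_pens)[2L]]]
          pen_i <- vapply(st$refset$members, function(m) m$penalized,
                          numeric(1))
          w2 <- order(pen_i, decreasing = TRUE)[min(2L, length(pen_i))]
          if (second$penalized < pen_i[w2]) {
            st$refset$members[[w2]] <- second
            st$refset$stagnation[w2] <- 0L
          }
        }
      }
    }
  }

  results <- lapply(states, function(s) {
    if (solver == "ess") ess_result(s) else vns_result(s)
  })
  pens <- vapply(states, function(s) s$best$penalized, numeric(1))
  leader <- which.min(pens)
  solver_result(
    best = states[[leader]]$best,
    history = history_matrix(merged),
    total_evaluations = sum(vapply(results, function(r)
      r$total_evaluations, numeric(1))),
    seed = config$seeds,
    method = paste0("c", solver),
    options = list(config = config, profiles = profiles),
    extra = list(thread_results = results, round_bests = round_bests)
  )
}
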