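#' Define a posterior sampling problem
#'
#' Bundles a log-likelihood, an optional log-prior and box bounds for the
#' multi-start Metropolis-Hastings sampler. The default prior is uniform
#' over the box (constant inside, `-Inf` outside); the log-posterior is the
#' sum of log-likelihood and log-prior. Points where either is non-finite
#' have zero posterior mass.
#'
#' @param log_likelihood Function of one numeric parameter vector returning
#'   a scalar log-likelihood.
#' @param lower,upper Numeric bound vectors (continuous parameters only).
#' @param log_prior Optional log-prior function; `NULL` means uniform over
#'   the box.
#' @param name Label carried into results.
#' @return An object of class `posterior_problem`.
#' @export
posterior_problem <- function(log_likelihood, lower, upper, log_prior = NULL,
                              name = "posterior") {
  stopifnot(is.function(log_likelihood), length(lower) == length(upper),
            all(lower <= upper))
  structure(list(log_likelihood = log_likelihood,
                 log_prior = log_prior,
                 lower = as.numeric(lower), upper = as.numeric(upper),
                 nvar = length(lower), name = name),
            class = "posterior_problem")
}

log_posterior <- function(problem, x) {
  if (any(x < problem$lower) || any(x > problem$upper)) return(-Inf)
  lp <- if (is.null(problem$log_prior)) 0 else problem$log_prior(x)
  if (!is.finite(lp)) return(-Inf)
  ll <- problem$log_likelihood(x)
  if (!is.finite(ll)) return(-Inf)
  ll + lp
}

#' Metropolis-Hastings acceptance rule
#'
#' Accept the proposal when `u < exp(min(0, logp_proposal - logp_current))`,
#' i.e. always when the proposal has higher posterior density, and with
#' probability equal to the posterior ratio otherwise. A proposal with zero
#' posterior mass (`-Inf` log-density) is always rejected.
#'
#' @param logp_current,logp_proposal Log-posterior of the current state and
#'   the proposal.
#' @param u A uniform draw in `[0, 1)`.
#' @return Logical: accept?
#' @export
metropolis_accept <- function(logp_current, logp_proposal, u) {
  if (!is.finite(logp_proposal) && logp_proposal < 0) return(FALSE)
  u < exp(min(0, logp_proposal - logp_current))
}

#' Multi-start Metropolis-Hastings sampling
#'
#' Runs `n_starts` independent Gaussian random-walk chains from distinct
#' uniform starting points inside the box. Per-parameter proposal scales
#' start at 5% of the bound width and adapt multiplicatively (x1.1 / /1.1
#' per 50-step window) toward an acceptance rate in the 0.2-0.45 band during
#' the burn-in fraction of each chain, then freeze, so the retained portion
#' of every chain is a valid fixed-kernel Metropolis-Hastings chain whose
#' visit frequencies are proportional to the posterior. Proposals falling
#' outside the box are rejected (a uniform-prior indicator). The single best
#' log-posterior point seen anywhere (burn-in included) is reported as the
#' best fit.
#'
#' @param problem A [posterior_problem()].
#' @param n_starts Number of chains (>= 1).
#' @param steps_per_chain Proposals per chain (>= 1).
#' @param seed Integer seed.
#' @param burn_in Fraction of each chain discarded (and used for
#'   adaptation).
#' @param thin Keep every `thin`-th post-burn-in sample.
#' @return An object of class `bayesfit` with `chains` (list of `mcmc_chain`
#'   objects: `samples` matrix, `log_posteriors`, `proposal_scales`,
#'   `accepted_count`, `start_index`), `best` (list `x`, `log_posterior`),
#'   `problem`, and the run settings.
#' @examples
#' pp <- posterior_problem(function(th) -(th - 2)^2 / 0.02, 0, 5)
#' fit <- bayesfit_sample(pp, n_starts = 2, steps_per_chain = 500, seed = 1)
#' colMeans(do.call(rbind, lapply(fit$chains, function(ch) ch$samples)))
#' @export
bayesfit_sample <- function(problem, n_starts = 4L, steps_per_chain = 5000L,
                            seed = 1L, burn_in = 0.5, thin = 1L) {
  stopifnot(inherits(problem, "posterior_problem"),
            n_starts >= 1L, steps_per_chain >= 1L,
            burn_in >= 0, burn_in < 1, thin >= 1L)
  old_rng <- get_rng_state()
  on.exit(set_rng_state(old_rng), add = TRUE)
  set.seed(seed)

  nvar <- problem$nvar
  width <- problem$upper - problem$lower
  draw_start <- function() {
    for (i in seq_len(100L * nvar)) {
      x <- problem$lower + stats::runif(nvar) * width
      lp <- log_posterior(problem, x)
      if (is.finite(lp)) return(list(x = x, lp = lp))
    }
    stop("no support found: posterior is -Inf at every tried start",
         call. = FALSE)
  }

  n_burn <- floor(burn_in * steps_per_chain)
  best <- list(x = NULL, log_posterior = -Inf)
  chains <- vector("list", n_starts)
  for (c_i in seq_len(n_starts)) {
    start <- draw_start()
    x <- start$x
    lp <- start$lp
    if (lp > best$log_posterior) best <- list(x = x, log_posterior = lp)
    scales <- 0.05 * pmax(width, .Machine$double.eps)
    kept <- matrix(NA_real_, nrow = 0L, ncol = nvar)
    kept_lp <- numeric(0)
    n_keep <- length(seq_len(steps_per_chain - n_burn)[
      seq_len(max(0L, steps_per_chain - n_burn)) %% thin == 0])
    kept <- matrix(NA_real_, nrow = n_keep, ncol = nvar)
    kept_lp <- numeric(n_keep)
    ki <- 0L
    accepted <- 0L
    win_acc <- 0L
    finite_props <- 0L
    finite_acc <- 0L
    for (step in seq_len(steps_per_chain)) {
      prop <- x + stats::rnorm(nvar) * scales
      lp_prop <- log_posterior(problem, prop)
      finite_prop <- is.finite(lp_prop)
      if (finite_prop) finite_props <- finite_props + 1L
      if (metropolis_accept(lp, lp_prop, stats::runif(1))) {
        if (finite_prop) finite_acc <- finite_acc + 1L
        x <- prop
        lp <- lp_prop
        accepted <- accepted + 1L
        win_acc <- win_acc + 1L
        if (lp > best$log_posterior) {
          best <- list(x = x, log_posterior = lp)
        }
      }
      if (step <= n_burn && step %% 50L == 0L) {
        rate <- win_acc / 50
        if (rate < 0.2) scales <- scales / 1.1
        else if (rate > 0.45) scales <- scales * 1.1
        win_acc <- 0L
      }
      if (step > n_burn) {
        post_i <- step - n_burn
        if (post_i %% thin == 0L) {
          ki <- ki + 1L
          kept[ki, ] <- x
          kept_lp[ki] <- lp
        }
      }
    }
    chains[[c_i]] <- structure(
      list(samples = kept, log_posteriors = kept_lp,
           proposal_scales = scales, accepted_count = accepted,
           n_proposals = steps_per_chain,
           in_support_proposals = finite_props,
           in_support_accepted = finite_acc,
           start_index = c_i),
      class = "mcmc_chain")
  }
  structure(list(chains = chains, best = best, problem = problem,
                 n_starts = n_starts, steps_per_chain = steps_per_chain,
                 burn_in = burn_in, thin = thin, seed = seed),
            class = "bayesfit")
}

#' @export
print.bayesfit <- function(x, ...) {
  n <- sum(vapply(x$chains, function(ch) nrow(ch$samples), numeric(1)))
  acc <- vapply(x$chains, function(ch) ch$accepted_count / ch$n_proposals,
                numeric(1))
  cat("<bayesfit> ", length(x$chains), " chains, ", n,
      " retained samples\n", sep = "")
  cat("  acceptance rates: ", paste(sprintf("%.2f", acc), collapse = " "),
      "\n", sep = "")
  cat("  best log-posterior: ", format(x$best$log_posterior), "\n", sep = "")
  invisible(x)
}

pooled_samples <- function(fit, index = NULL) {
  m <- do.call(rbind, lapply(fit$chains, function(ch) ch$samples))
  if (is.null(index)) m else m[, index]
}

#' Marginal posterior summary of one parameter
#'
#' Pools the retained samples of all chains and returns a histogram whose
#' bin edges span the parameter's prior bounds, the 2.5/25/50/75/97.5%
#' empirical quantiles, and the best-fit value. A multimodal marginal (or a
#' flat, bound-spanning one) is the sampler's signal of parameter
#' non-identifiability.
#'
#' @param fit A [bayesfit_sample()] result.
#' @param index Parameter position.
#' @param n_bins Number of histogram bins.
#' @return List with `breaks`, `counts`, `density`, `quantiles`, `best_fit`,
#'   `n`.
#' @export
marginal_summary <- function(fit, index, n_bins = 30L) {
  stopifnot(inherits(fit, "bayesfit"), index >= 1L,
            index <= fit$problem$nvar)
  x <- pooled_samples(fit, index)
  if (!length(x)) stop("no retained samples", call. = FALSE)
  breaks <- seq(fit$problem$lower[index], fit$problem$upper[index],
                length.out = n_bins + 1L)
  h <- graphics::hist(x, breaks = breaks, plot = FALSE)
  qs <- stats::quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = TRUE)
  list(breaks = h$breaks, counts = h$counts, density = h$density,
       quantiles = qs, best_fit = fit$best$x[index], n = length(x))
}

#' Pairwise covariation of two parameters
#'
#' 2-D histogram of the pooled samples of parameters `i` and `j` on the
#' bounds rectangle, using the same binning as [marginal_summary()] so that
#' the row/column sums of the 2-D table reproduce the two 1-D histograms
#' exactly. Ridges or multiple correlated peaks reveal covariation between
#' parameters that marginals alone can hide.
#'
#' @param fit A [bayesfit_sample()] result.
#' @param i,j Distinct parameter positions.
#' @param n_bins Bins per axis.
#' @return List with `breaks_i`, `breaks_j`, `counts` (matrix, rows = bins
#'   of `i`), `best_fit` (the pair), `n`.
#' @export
pairwise_covariation <- function(fit, i, j, n_bins = 30L) {
  stopifnot(inherits(fit, "bayesfit"))
  if (i == j) stop("i and j must be distinct parameters", call. = FALSE)
  xi <- pooled_samples(fit, i)
  xj <- pooled_samples(fit, j)
  if (!length(xi)) stop("no retained samples", call. = FALSE)
  br_i <- seq(fit$problem$lower[i], fit$problem$upper[i],
              length.out = n_bins + 1L)
  br_j <- seq(fit$problem$lower[j], fit$problem$upper[j],
              length.out = n_bins + 1L)
  ci <- cut(xi, breaks = br_i, include.lowest = TRUE)
  cj <- cut(xj, breaks = br_j, include.lowest = TRUE)
  counts <- table(ci, cj)
  list(breaks_i = br_i, breaks_j = br_j,
       counts = matrix(as.integer(counts), nrow = n_bins,
                       dimnames = NULL),
       best_fit = fit$best$x[c(i, j)], n = length(xi))
}
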