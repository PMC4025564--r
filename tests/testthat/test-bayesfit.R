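test_that("the acceptance rule implements the posterior-ratio threshold", {
  # better proposals are always accepted
  expect_true(metropolis_accept(-10, -5, 0.999999))
  # ratio exactly 0.5: accept iff u < 0.5
  expect_true(metropolis_accept(0, log(0.5), 0.49))
  expect_false(metropolis_accept(0, log(0.5), 0.51))
  # zero posterior mass is always rejected
  expect_false(metropolis_accept(-1, -Inf, 0))
})

test_that("chain bookkeeping: starts, retention, thinning", {
  flat <- posterior_problem(function(th) 0, c(0, 0), c(1, 1))
  fit <- bayesfit_sample(flat, n_starts = 3, steps_per_chain = 1000,
                         seed = 1, burn_in = 0.5)
  expect_length(fit$chains, 3L)
  for (ch in fit$chains) {
    expect_equal(nrow(ch$samples), 500L)
    expect_equal(length(ch$log_posteriors), 500L)
    expect_lte(ch$accepted_count, ch$n_proposals)
  }
  thin <- bayesfit_sample(flat, n_starts = 1, steps_per_chain = 1000,
                          seed = 1, burn_in = 0.5, thin = 5)
  expect_equal(nrow(thin$chains[[1]]$samples), 100L)
})

test_that("on a flat posterior every in-support proposal is accepted", {
  flat <- posterior_problem(function(th) 0, c(0, 0), c(1, 1))
  fit <- bayesfit_sample(flat, n_starts = 2, steps_per_chain = 3000, seed = 2)
  for (ch in fit$chains) {
    expect_equal(ch$in_support_accepted, ch$in_support_proposals)
  }
})

test_that("a posterior with no support raises a hard error", {
  none <- posterior_problem(function(th) -Inf, 0, 1)
  expect_error(bayesfit_sample(none, n_starts = 1, steps_per_chain = 10,
                               seed = 1), "no support")
})

test_that("the sampler recovers the conjugate Gaussian-mean posterior", {
  set.seed(31)
  n <- 25
  sigma <- 1.2
  y <- rnorm(n, 1.0, sigma)
  pp <- posterior_problem(function(th) -sum((y - th)^2) / (2 * sigma^2),
                          -10, 10)
  true_mean <- mean(y) # flat prior on a wide box: posterior ~ N(ybar, s2/n)
  true_var <- sigma^2 / n
  fit <- bayesfit_sample(pp, n_starts = 6, steps_per_chain = 6000, seed = 3)
  draws <- do.call(rbind, lapply(fit$chains, function(ch) ch$samples))[, 1]
  chain_means <- vapply(fit$chains, function(ch) mean(ch$samples[, 1]),
                        numeric(1))
  se <- sd(chain_means) / sqrt(length(chain_means))
  expect_lt(abs(mean(draws) - true_mean), 3 * se + 1e-12)
  expect_lt(abs(var(draws) / true_var - 1), 0.2)
  # the best fit is the posterior mode = sample mean
  expect_lt(abs(fit$best$x - true_mean), 0.05)
})

test_that("proposal adaptation happens only during burn-in", {
  set.seed(5)
  y <- rnorm(10)
  pp <- posterior_problem(function(th) -sum((y - th[1])^2) / 2 - th[2]^2,
                          c(-5, -5), c(5, 5))
  # with no burn-in there is no adaptation window: scales stay at 5% width
  fit0 <- bayesfit_sample(pp, n_starts = 1, steps_per_chain = 2000,
                          seed = 4, burn_in = 0)
  expect_equal(fit0$chains[[1]]$proposal_scales, 0.05 * c(10, 10))
  # with burn-in the peaked likelihood forces the scales off their start
  fit1 <- bayesfit_sample(pp, n_starts = 1, steps_per_chain = 2000,
                          seed = 4, burn_in = 0.5)
  expect_false(all(fit1$chains[[1]]$proposal_scales == 0.05 * c(10, 10)))
})

test_that("marginal summaries pool chains and pass quantile contracts", {
  flat <- posterior_problem(function(th) 0, 0, 10)
  fit <- bayesfit_sample(flat, n_starts = 2, steps_per_chain = 200, seed = 1)
  # point mass: every quantile equals the constant
  fit_pm <- fit
  for (i in 1:2) fit_pm$chains[[i]]$samples[] <- 0.7
  ms <- marginal_summary(fit_pm, 1)
  expect_true(all(ms$quantiles == 0.7))
  expect_equal(ms$best_fit, fit$best$x[1])

  # small-sample empirical quantile: median of {1,2,3,4} is 2.5
  fit_q <- fit
  fit_q$chains[[1]]$samples <- matrix(c(1, 2), ncol = 1)
  fit_q$chains[[2]]$samples <- matrix(c(3, 4), ncol = 1)
  expect_equal(unname(marginal_summary(fit_q, 1)$quantiles["50%"]), 2.5)
})

test_that("pairwise histograms marginalize consistently", {
  flat <- posterior_problem(function(th) 0, c(0, 0), c(1, 1))
  fit <- bayesfit_sample(flat, n_starts = 3, steps_per_chain = 2000, seed = 7)
  pw <- pairwise_covariation(fit, 1, 2, n_bins = 8)
  m1 <- marginal_summary(fit, 1, n_bins = 8)
  m2 <- marginal_summary(fit, 2, n_bins = 8)
  expect_equal(rowSums(pw$counts), m1$counts)
  expect_equal(colSums(pw$counts), m2$counts)
  expect_error(pairwise_covariation(fit, 2, 2), "distinct")

  # samples concentrated on the diagonal occupy only diagonal bins
  fit_d <- fit
  z <- seq(0.01, 0.99, length.out = 50)
  for (i in 1:3) fit_d$chains[[i]]$samples <- cbind(z, z)
  pw_d <- pairwise_covariation(fit_d, 1, 2, n_bins = 10)
  expect_equal(sum(diag(pw_d$counts)), pw_d$n)
})

test_that("independent uniform draws fill the 2-D histogram uniformly", {
  flat <- posterior_problem(function(th) 0, c(0, 0), c(1, 1))
  fit <- bayesfit_sample(flat, n_starts = 1, steps_per_chain = 100, seed = 1)
  set.seed(11)
  fit$chains[[1]]$samples <- cbind(runif(1e5), runif(1e5))
  pw <- pairwise_covariation(fit, 1, 2, n_bins = 4)
  freq <- pw$counts / pw$n
  expect_true(all(abs(freq - 1 / 16) < 0.01))
})

test_that("discrete two-state visits are proportional to the posterior", {
  # operationalized detailed balance on a 2-state posterior (p, 1-p)
  p <- 0.3
  logp <- log(c(p, 1 - p))
  set.seed(21)
  state <- 1L
  visits <- c(0L, 0L)
  n_steps <- 1e5
  us <- runif(n_steps)
  for (i in seq_len(n_steps)) {
    prop <- 3L - state
    if (metropolis_accept(logp[state], logp[prop], us[i])) state <- prop
    visits[state] <- visits[state] + 1L
  }
  se <- sqrt(p * (1 - p) / n_steps)
  expect_lt(abs(visits[1] / n_steps - p), 3 * se)
})
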