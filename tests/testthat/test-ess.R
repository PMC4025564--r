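test_that("combine_pair offspring stay in the parents' (possibly stretched) box", {
  set.seed(1)
  kids <- combine_pair(c(0, 0), c(1, 1), lower = c(0, 0), upper = c(1, 1),
                       margin = 0)
  for (k in kids) {
    expect_true(all(k >= 0 & k <= 1))
  }
  # integer coordinate: parents 2 and 5 -> offspring in {2,...,5}
  kids2 <- combine_pair(c(2), c(5), lower = 0, upper = 10,
                        integer_indices = 1, n_offspring = 20, margin = 0)
  vals <- unlist(kids2)
  expect_true(all(vals %in% 2:5))
  expect_true(all(vals == round(vals)))
})

test_that("identical parents never produce exact duplicates", {
  set.seed(2)
  for (rep in 1:20) {
    kids <- combine_pair(c(1, 1), c(1, 1), lower = c(0, 0), upper = c(2, 2))
    for (k in kids) expect_false(all(k == c(1, 1)))
  }
  # all-integer degenerate pair still moves
  kids_i <- combine_pair(c(1, 1), c(1, 1), lower = c(0, 0), upper = c(2, 2),
                         integer_indices = 1:2, n_offspring = 5)
  for (k in kids_i) expect_false(all(k == c(1, 1)))
})

test_that("1+1 replacement touches only the generating member", {
  p <- sphere_problem(2)
  members <- list(eval_at(p, c(3, 3)), eval_at(p, c(2, 2)),
                  eval_at(p, c(1, 1)))
  refset <- list(members = members, stagnation = c(0L, 0L, 0L))

  # offspring better than its parent but worse than others: parent replaced
  off <- eval_at(p, c(2.5, 2.5))
  r2 <- replace_one_plus_one(refset, 1L, off)
  expect_true(attr(r2, "replaced"))
  expect_equal(r2$members[[1]]$x, c(2.5, 2.5))
  expect_equal(r2$members[[2]]$x, c(2, 2))
  expect_equal(r2$members[[3]]$x, c(1, 1))

  # offspring worse than its parent: untouched, stagnation advances
  worse <- eval_at(p, c(4, 4))
  r3 <- replace_one_plus_one(refset, 2L, worse)
  expect_false(attr(r3, "replaced"))
  expect_equal(r3$members[[2]]$x, c(2, 2))
  expect_equal(r3$stagnation[2], 1L)

  # offspring better than a *different* member but worse than its parent:
  # unchanged (it may only replace its own parent)
  mid <- eval_at(p, c(2.2, 2.2)) # beats member 1 (3,3) but not parent (1,1)
  r4 <- replace_one_plus_one(refset, 3L, mid)
  expect_false(attr(r4, "replaced"))
  expect_equal(r4$members[[1]]$x, c(3, 3))
  expect_equal(r4$members[[3]]$x, c(1, 1))
})

test_that("go-beyond extrapolates improving directions and stops honestly", {
  p1 <- op_problem(function(x) x^2, -10, 10)
  ctr <- new_counter()
  parent <- evaluate(p1, 8, ctr)
  offspring <- evaluate(p1, 6, ctr)
  n0 <- counter_value(ctr)
  out <- go_beyond(parent, offspring, p1, ctr)
  expect_lt(out$f, 36)
  expect_lt(out$x, 6)
  expect_gt(counter_value(ctr), n0)

  # offspring not better: returned untouched at zero cost
  n1 <- counter_value(ctr)
  same <- go_beyond(offspring, parent, p1, ctr)
  expect_identical(same, parent)
  expect_equal(counter_value(ctr), n1)

  # doubling trace on the sphere from (4,4) -> (3,3): both coordinates < 3
  p2 <- sphere_problem(2)
  ctr2 <- new_counter()
  out2 <- go_beyond(evaluate(p2, c(4, 4), ctr2),
                    evaluate(p2, c(3, 3), ctr2), p2, ctr2)
  expect_true(all(out2$x < 3))
})

test_that("local-search memory filters starts near previous optima", {
  p <- op_problem(function(x) sum((x - c(1, 1))^2), c(-5, -5), c(5, 5))
  members <- list(eval_at(p, c(1.5, 1.5)), eval_at(p, c(-3, 4)))
  refset <- list(members = members, stagnation = c(0L, 0L))
  ctr <- new_counter()

  # empty archive: the best member is refined to the analytic minimizer
  out <- memory_local_search(refset, list(starts = list(), finals = list()),
                             p, ctr, filter_radius = 0.05, max_evals = 400)
  expect_true(out$performed)
  refined <- out$refset$members[[1]]
  expect_lt(sum((refined$x - c(1, 1))^2), 1e-6)

  # every member within the radius of an archived final: no search, no cost
  arch <- list(starts = list(), finals = list(c(1.5, 1.5), c(-3, 4)))
  n0 <- counter_value(ctr)
  out2 <- memory_local_search(refset, arch, p, ctr, filter_radius = 0.05,
                              max_evals = 400)
  expect_false(out2$performed)
  expect_equal(counter_value(ctr), n0)
})

test_that("eSS reaches analytic optima on convex and valley problems", {
  r <- ess_solve(sphere_problem(5), ess_options(max_evaluations = 20000,
                                                seed = 1))
  expect_lt(r$best$penalized, 1e-6)
  expect_monotone_history(r)
  expect_true(all(r$best$x >= -5 & r$best$x <= 5))

  r2 <- ess_solve(rosenbrock_problem(2),
                  ess_options(max_evaluations = 50000, seed = 1))
  expect_lt(r2$best$penalized, 1e-5)
})

test_that("eSS solves a mixed-integer problem to the brute-force optimum", {
  p <- op_problem(function(x) (x[1] - 0.3)^2 + (x[2] - 2)^2,
                  c(-1, 0), c(1, 5), integer_indices = 2)
  # brute force: minimize over y in 0..5 with exact continuous x = 0.3
  brute <- min(vapply(0:5, function(y) (y - 2)^2, numeric(1)))
  r <- ess_solve(p, ess_options(max_evaluations = 5000, seed = 1))
  expect_equal(r$best$x[2], 2)
  expect_equal(r$best$f, brute, tolerance = 1e-6)
  expect_lt(abs(r$best$x[1] - 0.3), 1e-3)
})

test_that("eSS is bit-reproducible and respects tiny budgets with a warning", {
  p <- sphere_problem(4)
  a <- ess_solve(p, ess_options(max_evaluations = 3000, seed = 9))
  b <- ess_solve(p, ess_options(max_evaluations = 3000, seed = 9))
  expect_identical(a$history, b$history)
  expect_identical(a$best, b$best)

  tiny <- ess_solve(p, ess_options(max_evaluations = 10, seed = 1))
  expect_false(is.null(tiny$warning))
  expect_lte(tiny$total_evaluations, 10)
  expect_true(is.finite(tiny$best$penalized))
})

test_that("every eSS evaluation of a MINLP sees integral integer positions", {
  seen <- new.env()
  seen$bad <- 0L
  p <- op_problem(function(x) {
    if (abs(x[2] - round(x[2])) > 1e-12) seen$bad <- seen$bad + 1L
    (x[1] - 0.5)^2 + x[2]^2
  }, c(-2, -3), c(2, 3), integer_indices = 2)
  invisible(ess_solve(p, ess_options(max_evaluations = 3000, seed = 4)))
  expect_equal(seen$bad, 0L)
})
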