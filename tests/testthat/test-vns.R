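test_that("shake changes exactly k positions to different in-bounds values", {
  set.seed(1)
  for (k in 1:3) {
    sh <- shake(c(2, 2, 2), k, lower = rep(0, 3), upper = rep(7, 3))
    expect_equal(sum(sh$x != c(2, 2, 2)), k)
    expect_length(sh$indices, k)
    expect_true(all(sh$x >= 0 & sh$x <= 7))
  }
})

test_that("shake honours the no-repeat memory and evicts beyond its depth", {
  set.seed(2)
  # nvar = 2, k = 1, memory already holds {1}: the only legal set is {2}
  sh <- shake(c(0, 0), 1, c(0, 0), c(5, 5), memory = list(1L))
  expect_identical(sh$indices, 2L)

  # exhausted memory is cleared and flagged
  sh2 <- shake(c(0, 0), 1, c(0, 0), c(5, 5), memory = list(1L, 2L))
  expect_true(sh2$memory_cleared)
  expect_length(sh2$indices, 1L)

  # eviction keeps the memory bounded
  mem <- list()
  for (i in 1:15) {
    sh3 <- shake(c(0, 0, 0, 0), 2, rep(0, 4), rep(9, 4), memory = mem,
                 memory_depth = 10)
    mem <- sh3$memory
  }
  expect_lte(length(mem), 10L)
})

test_that("shake never perturbs a single-valued domain", {
  set.seed(3)
  for (i in 1:10) {
    sh <- shake(c(5, 3), 1, lower = c(5, 0), upper = c(5, 9))
    expect_equal(sh$x[1], 5)
    expect_identical(sh$indices, 2L)
  }
})

test_that("integer local search descends 1-D convex functions exactly", {
  p <- op_problem(function(x) (x - 7)^2, 0, 15, integer_indices = 1)
  ctr <- new_counter()
  set.seed(1)
  out <- integer_local_search(eval_at(p, 3), p, ctr)
  expect_equal(out$x, 7)
})

test_that("a unit-move local minimum costs one failed sweep: 2 evals per coordinate", {
  p <- op_problem(function(x) sum((x - c(5, 5))^2), c(0, 0), c(10, 10),
                  integer_indices = 1:2)
  ctr <- new_counter()
  set.seed(1)
  out <- integer_local_search(eval_at(p, c(5, 5)), p, ctr)
  expect_equal(out$x, c(5, 5))
  expect_equal(counter_value(ctr), 4L) # 2 * nvar
})

test_that("integer local search matches brute force on a separable L1 grid", {
  p <- op_problem(function(x) abs(x[1] - 2) + abs(x[2] - 9),
                  c(0, 0), c(10, 10), integer_indices = 1:2)
  # brute force over the 121-point grid
  grid <- expand.grid(0:10, 0:10)
  brute <- min(abs(grid[, 1] - 2) + abs(grid[, 2] - 9))
  ctr <- new_counter()
  set.seed(2)
  out <- integer_local_search(eval_at(p, c(0, 0)), p, ctr)
  expect_equal(out$f, brute)
  expect_equal(out$x, c(2, 9))
})

test_that("aggressive sweeps never return something worse than the input", {
  set.seed(4)
  for (i in 1:10) {
    tp <- table_problem(3, 5, seed = 100 + i)
    x0 <- sample(0:4, 3, replace = TRUE)
    ctr <- new_counter()
    s0 <- eval_at(tp$problem, x0)
    out <- integer_local_search(s0, tp$problem, ctr, aggressive = TRUE)
    expect_lte(out$penalized, s0$penalized)
  }
})

test_that("VNS finds the exhaustive optimum of random lookup tables", {
  tp <- table_problem(2, 8, seed = 7)
  r <- vns_solve(tp$problem, vns_options(max_evaluations = 1000, seed = 1))
  expect_equal(r$best$f, tp$minimum)
  expect_monotone_history(r)
})

test_that("VNS handles a single-point search space in one evaluation", {
  p <- op_problem(function(x) sum(x), c(3, 3), c(3, 3),
                  integer_indices = 1:2)
  r <- vns_solve(p, vns_options(max_evaluations = 100, seed = 1))
  expect_equal(r$best$x, c(3, 3))
  expect_equal(r$total_evaluations, 1L)
})

test_that("VNS is bit-reproducible under a fixed seed", {
  p <- gear_train_problem()
  a <- vns_solve(p, vns_options(max_evaluations = 4000, seed = 5))
  b <- vns_solve(p, vns_options(max_evaluations = 4000, seed = 5))
  expect_identical(a$history, b$history)
  expect_identical(a$best, b$best)
})

test_that("VNS incumbents are unit-move local minima", {
  for (s in 1:5) {
    tp <- table_problem(3, 6, seed = 200 + s)
    r <- vns_solve(tp$problem, vns_options(max_evaluations = 2000, seed = s))
    x <- r$incumbent$x
    f0 <- r$incumbent$f
    for (i in seq_along(x)) {
      for (d in c(-1, 1)) {
        y <- x
        y[i] <- y[i] + d
        if (y[i] < 0 || y[i] > 5) next
        expect_gte(tp$problem$objective(y), f0)
      }
    }
  }
})

test_that("VNS requires an all-integer problem with finite bounds", {
  cont <- sphere_problem(2)
  expect_error(vns_solve(cont), "all-integer")
})
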