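# shared fixture builders; everything is generated in code at test time

sphere_problem <- function(n) {
  op_problem(function(x) sum(x^2), rep(-5, n), rep(5, n), name = "sphere")
}

rosenbrock_problem <- function(n) {
  op_problem(function(x) sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2),
             rep(-5, n), rep(10, n), name = "rosenbrock")
}

# random lookup-table integer problem with an almost-surely unique minimum
table_problem <- function(nvar, nvals, seed) {
  arr <- withr::with_seed(seed, array(stats::runif(nvals^nvar),
                                      dim = rep(nvals, nvar)))
  prob <- op_problem(function(x) arr[rbind(x + 1)],
                     lower = rep(0, nvar), upper = rep(nvals - 1, nvar),
                     integer_indices = seq_len(nvar), name = "table")
  list(problem = prob, table = arr, minimum = min(arr))
}

# evaluated solution shortcut
eval_at <- function(problem, x) {
  evaluate(problem, x, new_counter())
}

expect_monotone_history <- function(res) {
  expect_true(all(diff(res$history$best) <= 0))
}
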