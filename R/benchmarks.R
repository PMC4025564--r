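#' Gear-train design objective
#'
#' Classic integer design benchmark: choose the teeth counts of a compound
#' gear train, `x = (x1, x2, x3, x4)` with each count an integer in
#' `[12, 60]`, so that the transmission ratio `x1 x2 / (x3 x4)` approximates
#' the required ratio `1/6.931`. The objective is the squared deviation
#' `(1/6.931 - x1 x2 / (x3 x4))^2`. The global minimum over the integer box
#' is approximately `2.7e-12`, attained at teeth counts `(16, 19, 43, 49)`
#' up to the symmetry of swapping within each product pair.
#'
#' @param x Integer vector of length 4, each element in `[12, 60]`.
#' @return Nonnegative scalar.
#' @export
gear_train <- function(x) {
  if (length(x) != 4L) stop("gear_train expects 4 teeth counts", call. = FALSE)
  if (any(x < 12 | x > 60) || any(x != round(x))) {
    stop("teeth counts must be integers in [12, 60]", call. = FALSE)
  }
  (1 / 6.931 - (x[1] * x[2]) / (x[3] * x[4]))^2
}

#' @rdname gear_train
#' @return `gear_train_problem()` returns the benchmark wrapped as an
#'   all-integer [op_problem()] ready for [vns_solve()].
#' @export
gear_train_problem <- function() {
  op_problem(function(x) (1 / 6.931 - (x[1] * x[2]) / (x[3] * x[4]))^2,
             lower = rep(12, 4), upper = rep(60, 4),
             integer_indices = 1:4, name = "geartrain")
}

# ---- continuous test-function registry -------------------------------------

bench_sphere <- function(x) sum(x^2)
bench_rosenbrock <- function(x) {
  n <- length(x)
  sum(100 * (x[-1] - x[-n]^2)^2 + (1 - x[-n])^2)
}
bench_rastrigin <- function(x) 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x))
bench_ackley <- function(x) {
  n <- length(x)
  -20 * exp(-0.2 * sqrt(sum(x^2) / n)) - exp(sum(cos(2 * pi * x)) / n) +
    20 + exp(1)
}
bench_schwefel <- function(x) {
  418.9828872724339 * length(x) - sum(x * sin(sqrt(abs(x))))
}

base_registry <- list(
  sphere = list(fn = bench_sphere, lower = -5, upper = 5,
                fmin = 0, xmin = 0),
  rosenbrock = list(fn = bench_rosenbrock, lower = -5, upper = 10,
                    fmin = 0, xmin = 1),
  rastrigin = list(fn = bench_rastrigin, lower = -5.12, upper = 5.12,
                   fmin = 0, xmin = 0),
  ackley = list(fn = bench_ackley, lower = -32.768, upper = 32.768,
                fmin = 0, xmin = 0),
  schwefel = list(fn = bench_schwefel, lower = -500, upper = 500,
                  fmin = 0, xmin = 420.968746)
)

# Deterministic shift vector / rotation matrix per (name, dimension); these
# make the classic functions non-separable and move the optimum off the
# center, in the spirit of large-scale benchmark suites.
bench_shift <- function(name, n) {
  reg <- base_registry[[name]]
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(utils::head(utf8ToInt(name), 1) * 1000L + n)
  # keep the shifted optimum inside the middle half of the box
  width <- reg$upper - reg$lower
  center <- (reg$upper + reg$lower) / 2
  center + (stats::runif(n) - 0.5) * width / 2 + (reg$xmin - center) * 0
}

bench_rotation <- function(name, n) {
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(utils::head(utf8ToInt(name), 1) * 2000L + n)
  qr.Q(qr(matrix(stats::rnorm(n * n), n, n)))
}

#' Continuous benchmark function registry
#'
#' Classic global-optimization test functions (`sphere`, `rosenbrock`,
#' `rastrigin`, `ackley`, `schwefel`) and shifted / rotated variants
#' (`shifted_<name>`, `rotated_<name>`, `shifted_rotated_<name>`) in any
#' dimension. Shift vectors and rotation matrices are generated from fixed,
#' name- and dimension-derived seeds, so every variant is a deterministic,
#' reproducible function. Each registry entry records the known global
#' minimum value and a minimizer for testing.
#'
#' `benchmark_function(name, x)` evaluates a registry function;
#' `benchmark_problem(name, n)` wraps it as an [op_problem()] on its
#' canonical box; `list_benchmarks()` names all base functions.
#'
#' @param name Function name, e.g. `"rastrigin"` or `"shifted_rosenbrock"`.
#' @param x Numeric vector inside the canonical box.
#' @param n Dimension for `benchmark_problem()`.
#' @return `benchmark_function()`: a scalar. `benchmark_info(name, n)`: a
#'   list with `fn`, `lower`, `upper`, `fmin`, `xmin`.
#' @export
benchmark_function <- function(name, x) {
  info <- benchmark_info(name, length(x))
  if (any(x < info$lower - 1e-12) || any(x > info$upper + 1e-12)) {
    stop("x outside the canonical box of '", name, "'", call. = FALSE)
  }
  info$fn(x)
}

#' @rdname benchmark_function
#' @export
benchmark_info <- function(name, n) {
  shifted <- grepl("^shifted_", name)
  rest <- sub("^shifted_", "", name)
  rotated <- grepl("^rotated_", rest)
  base <- sub("^rotated_", "", rest)
  if (!base %in% names(base_registry)) {
    stop("unknown benchmark '", name, "'; available: ",
         paste(names(base_registry), collapse = ", "),
         " with optional shifted_/rotated_ prefixes", call. = FALSE)
  }
  reg <- base_registry[[base]]
  lower <- rep(reg$lower, n)
  upper <- rep(reg$upper, n)
  xmin <- rep(reg$xmin, n)
  fn <- reg$fn
  if (rotated) {
    R <- bench_rotation(base, n)
    xm <- xmin
    fn0 <- fn
    fn <- function(x) fn0(as.numeric(R %*% (x - xm)) + xm)
    # rotation about the optimum keeps the minimizer and value
  }
  if (shifted) {
    s <- bench_shift(base, n)
    delta <- s - xmin
    fn1 <- fn
    fn <- function(x) fn1(x - delta)
    xmin <- xmin + delta
  }
  list(fn = fn, lower = lower, upper = upper, fmin = reg$fmin, xmin = xmin,
       name = name)
}

#' @rdname benchmark_function
#' @export
benchmark_problem <- function(name, n) {
  info <- benchmark_info(name, n)
  op_problem(info$fn, info$lower, info$upper, name = name)
}

#' @rdname benchmark_function
#' @export
list_benchmarks <- function() names(base_registry)
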