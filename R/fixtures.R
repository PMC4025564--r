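#' Generate self-contained test fixtures
#'
#' Writes a synthetic stand-in for each class of case-study input, together
#' with a `ground_truth.json` sidecar recording how it was generated, so
#' every downstream analysis can be checked against a known answer:
#'
#' * `logic` — a small signed network in SIF format (9 candidate hyperedges
#'   after AND/OR expansion) plus a measurement cube simulated from a known
#'   hyperedge selection under all stimulus/inhibitor conditions, with
#'   truncated Gaussian noise. The sidecar records the generating selection
#'   and `alpha`; enumeration of all `2^9` selections recovers it as the
#'   score minimizer.
#' * `metabolic` — the toy knockout-design model as a reactions/genes CSV
#'   pair; the sidecar records the best knockout set over all subsets of
#'   size <= 3 from exhaustive enumeration.
#' * `posterior` — a saturating transfer-function (Hill) curve-fit dataset
#'   `y = x^n / (k^n + x^n) + noise` with known shape parameters `n`, `k`;
#'   the sidecar records the generating parameters, noise level and
#'   parameter bounds.
#'
#' @param kind `"logic"`, `"metabolic"` or `"posterior"`.
#' @param seed Integer seed driving the simulated noise.
#' @param outdir Output directory (created if needed).
#' @return Named character vector of written file paths (invisibly).
#' @export
generate_fixture <- function(kind = c("logic", "metabolic", "posterior"),
                             seed = 1L, outdir = ".") {
  kind <- match.arg(kind)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  old <- get_rng_state()
  on.exit(set_rng_state(old), add = TRUE)
  set.seed(seed)
  files <- switch(kind,
                  logic = generate_logic_fixture(outdir, seed),
                  metabolic = generate_metabolic_fixture(outdir, seed),
                  posterior = generate_posterior_fixture(outdir, seed))
  invisible(files)
}

# fixed 7-node topology; seeded noise on the simulated measurements
logic_fixture_sif <- function() {
  data.frame(
    source = c("S1", "S2", "S1", "B", "A", "B", "A"),
    sign = c(1, 1, 1, 1, 1, -1, 1),
    target = c("A", "A", "B", "R1", "R2", "R2", "R3"),
    stringsAsFactors = FALSE
  )
}

# hyperedge indices of the generating model in expansion order:
# A = S1 AND S2; B = S1; R1 = B; R2 = A AND (NOT B); R3 = A
logic_fixture_truth <- c(3L, 4L, 5L, 8L, 9L)

logic_fixture_roles <- function() {
  list(stimuli = c("S1", "S2"), inhibitors = "B",
       readouts = c("R1", "R2", "R3"))
}

generate_logic_fixture <- function(outdir, seed, noise_sd = 0.05,
                                   alpha = 1e-4) {
  sif <- logic_fixture_sif()
  roles <- logic_fixture_roles()
  hyper <- expand_hyperedges(sif)
  nodes <- unique(c(sif$source, sif$target))
  model <- logic_model(nodes, hyper, stimuli = roles$stimuli,
                       inhibitors = roles$inhibitors,
                       readouts = roles$readouts)
  truth <- rep(0L, model$r)
  truth[logic_fixture_truth] <- 1L

  combos <- expand.grid(S1 = 0:1, S2 = 0:1, inhB = 0:1)
  conditions <- data.frame(condition = paste0("c", seq_len(nrow(combos))),
                           `S:S1` = combos$S1, `S:S2` = combos$S2,
                           `I:B` = combos$inhB, check.names = FALSE)
  times <- c(5, 10, 15)
  rows <- list()
  for (i in seq_len(nrow(combos))) {
    ss <- logic_steady_state(model, truth,
                             stimuli = c(S1 = combos$S1[i],
                                         S2 = combos$S2[i]),
                             inhibited = if (combos$inhB[i] == 1) "B"
                             else character(0))
    for (ro in roles$readouts) {
      for (tt in times) {
        v <- ss[ro] + stats::rnorm(1, 0, noise_sd)
        rows[[length(rows) + 1L]] <- data.frame(
          condition = conditions$condition[i], readout = ro, time = tt,
          value = min(max(v, 0), 1 - 1e-6))
      }
    }
  }
  meas <- do.call(rbind, rows)

  sif_path <- file.path(outdir, "network.sif")
  meas_path <- file.path(outdir, "measurements.csv")
  cond_path <- file.path(outdir, "conditions.csv")
  truth_path <- file.path(outdir, "ground_truth.json")
  write_sif(sif, sif_path)
  utils::write.csv(meas, meas_path, row.names = FALSE)
  utils::write.csv(conditions, cond_path, row.names = FALSE)
  sc <- logic_objective(model, truth,
                        logic_data(meas, conditions), alpha)
  jsonlite::write_json(
    list(kind = "logic", seed = seed, alpha = alpha,
         selection = which(truth == 1L), r = model$r,
         noise_sd = noise_sd,
         theta_truth = sc$theta, theta_f_truth = sc$theta_f,
         stimuli = roles$stimuli, inhibitors = roles$inhibitors,
         readouts = roles$readouts),
    truth_path, auto_unbox = TRUE, digits = NA)
  c(sif = sif_path, measurements = meas_path, conditions = cond_path,
    ground_truth = truth_path)
}

generate_metabolic_fixture <- function(outdir, seed) {
  model <- metabolic_toy_model()
  files <- write_metabolic_model(model, outdir)
  enum <- enumerate_knockouts(model, max_size = 3L)
  truth_path <- file.path(outdir, "ground_truth.json")
  jsonlite::write_json(
    list(kind = "metabolic", seed = seed,
         best_genes = as.integer(strsplit(enum$genes[1], ";")[[1]]),
         best_value = enum$value[1], max_size = 3L),
    truth_path, auto_unbox = TRUE, digits = NA)
  c(files, ground_truth = truth_path)
}

generate_posterior_fixture <- function(outdir, seed, n_true = 2,
                                       k_true = 0.5, sigma = 0.05) {
  x <- seq(0.1, 2, length.out = 12)
  y <- x^n_true / (k_true^n_true + x^n_true) +
    stats::rnorm(length(x), 0, sigma)
  data_path <- file.path(outdir, "data.csv")
  truth_path <- file.path(outdir, "ground_truth.json")
  utils::write.csv(data.frame(x = x, y = y), data_path, row.names = FALSE)
  jsonlite::write_json(
    list(kind = "posterior", seed = seed, n = n_true, k = k_true,
         sigma = sigma, lower = c(n = 0.5, k = 0.05),
         upper = c(n = 8, k = 2)),
    truth_path, auto_unbox = TRUE, digits = NA)
  c(data = data_path, ground_truth = truth_path)
}

#' Load the logic fixture written by [generate_fixture()]
#'
#' @param dir Fixture directory.
#' @return List with `model` ([logic_model()]), `data` ([logic_data()]),
#'   and `truth` (the sidecar contents).
#' @export
load_logic_fixture <- function(dir) {
  sif <- read_sif(file.path(dir, "network.sif"))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  nodes <- unique(c(sif$source, sif$target))
  model <- logic_model(nodes, expand_hyperedges(sif),
                       stimuli = truth$stimuli,
                       inhibitors = truth$inhibitors,
                       readouts = truth$readouts)
  data <- read_logic_data(file.path(dir, "measurements.csv"),
                          file.path(dir, "conditions.csv"))
  list(model = model, data = data, truth = truth)
}

#' Transfer-function curve-fit posterior
#'
#' Builds the [posterior_problem()] for the saturating transfer-function
#' model `y = x^n / (k^n + x^n)` with Gaussian measurement error of known
#' standard deviation: the two shape parameters `n` (steepness) and `k`
#' (half-saturation) are given a uniform prior over their bounds. This is
#' the likelihood used by the `posterior` fixture.
#'
#' @param data Data frame with columns `x`, `y`.
#' @param sigma Known noise standard deviation.
#' @param lower,upper Bounds for `(n, k)`.
#' @return A [posterior_problem()] over `(n, k)`.
#' @export
hill_posterior <- function(data, sigma = 0.05, lower = c(0.5, 0.05),
                           upper = c(8, 2)) {
  stopifnot(all(c("x", "y") %in% names(data)), sigma > 0)
  x <- data$x
  y <- data$y
  posterior_problem(
    function(th) {
      mu <- x^th[1] / (th[2]^th[1] + x^th[1])
      -sum((y - mu)^2) / (2 * sigma^2)
    },
    lower = lower, upper = upper, name = "hill_transfer"
  )
}

#' @rdname hill_posterior
#' @param dir Directory holding the `posterior` fixture files.
#' @export
load_posterior_fixture <- function(dir) {
  data <- utils::read.csv(file.path(dir, "data.csv"))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  list(problem = hill_posterior(data, sigma = truth$sigma,
                                lower = truth$lower, upper = truth$upper),
       data = data, truth = truth)
}
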