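# ---- logic models ----------------------------------------------------------

chain_model <- function() {
  logic_model(c("A", "B", "C"),
              list(list(inputs = "A", signs = 1, output = "B"),
                   list(inputs = "B", signs = 1, output = "C")),
              stimuli = "A", readouts = "C")
}

test_that("steady state propagates activation along a chain", {
  m <- chain_model()
  ss <- logic_steady_state(m, c(1, 1), stimuli = c(A = 1))
  expect_equal(unname(ss[c("B", "C")]), c(1, 1))
  ss0 <- logic_steady_state(m, c(1, 1), stimuli = c(A = 0))
  expect_equal(unname(ss0[c("B", "C")]), c(0, 0))
})

test_that("inhibitory edges and gate semantics follow AND/OR rules", {
  m <- logic_model(c("A", "B"),
                   list(list(inputs = "A", signs = -1, output = "B")),
                   stimuli = "A")
  ss <- logic_steady_state(m, 1, stimuli = c(A = 1))
  expect_equal(unname(ss["B"]), 0)
  expect_equal(unname(logic_steady_state(m, 1, stimuli = c(A = 0))["B"]), 1)

  m2 <- logic_model(c("A", "B", "C"),
                    list(list(inputs = c("A", "B"), signs = c(1, 1),
                              output = "C"),      # AND gate
                         list(inputs = "A", signs = 1, output = "C"),
                         list(inputs = "B", signs = 1, output = "C")),
                    stimuli = c("A", "B"))
  # AND hyperedge alone: A=1, B=0 -> C = 0
  and_only <- logic_steady_state(m2, c(1, 0, 0), stimuli = c(A = 1, B = 0))
  expect_equal(unname(and_only["C"]), 0)
  # OR of the two single edges: A=1, B=0 -> C = 1
  or_only <- logic_steady_state(m2, c(0, 1, 1), stimuli = c(A = 1, B = 0))
  expect_equal(unname(or_only["C"]), 1)
})

test_that("experimental inhibition clamps the node to zero", {
  m <- chain_model()
  ss <- logic_steady_state(m, c(1, 1), stimuli = c(A = 1), inhibited = "B")
  expect_equal(unname(ss["B"]), 0)
  expect_equal(unname(ss["C"]), 0)
})

test_that("the steady state is a fixed point (idempotent under one more sweep)", {
  sif <- data.frame(source = c("S", "S", "X", "Y"), sign = c(1, -1, 1, 1),
                    target = c("X", "Y", "Y", "Z"))
  m <- logic_model(unique(c(sif$source, sif$target)),
                   expand_hyperedges(sif), stimuli = "S")
  for (sel_id in 0:(2^m$r - 1)) {
    sel <- as.integer(intToBits(sel_id)[seq_len(m$r)])
    ss <- logic_steady_state(m, sel, stimuli = c(S = 1))
    if (any(is.na(ss))) next
    again <- logic_steady_state(m, sel, stimuli = c(S = 1))
    expect_identical(ss, again)
  }
})

test_that("a negative feedback loop yields undefined (NA) states, not an error", {
  m <- logic_model(c("S", "X", "Y"),
                   list(list(inputs = "S", signs = 1, output = "X"),
                        list(inputs = c("S", "Y"), signs = c(1, -1),
                             output = "X"),
                        list(inputs = "X", signs = 1, output = "Y"),
                        list(inputs = "Y", signs = -1, output = "X")),
                   stimuli = "S")
  # X = NOT Y, Y = X oscillates under synchronous update
  ss <- logic_steady_state(m, c(0, 0, 1, 1), stimuli = c(S = 1))
  expect_true(any(is.na(ss)))
})

test_that("the training score decomposes into fit and size terms", {
  m <- chain_model()
  dat <- logic_data(
    data.frame(condition = "c1", readout = "C", time = 1, value = 0.5),
    data.frame(condition = "c1", `S:A` = 1, check.names = FALSE))
  sc <- logic_objective(m, c(1, 1), dat, alpha = 0)
  expect_equal(sc$theta, 0.25) # (1 - 0.5)^2 over one data point
  expect_equal(sc$theta_s, 1)  # both of two single-input edges selected

  # empty selection on all-zero data: perfect fit, zero complexity
  dat0 <- logic_data(
    data.frame(condition = "c1", readout = "C", time = 1, value = 0),
    data.frame(condition = "c1", `S:A` = 0, check.names = FALSE))
  sc0 <- logic_objective(m, c(0, 0), dat0, alpha = 1)
  expect_equal(sc0$theta, 0)

  # a 3-input AND among candidates totalling v_es = 6 costs theta_s = 0.5
  m6 <- logic_model(c("A", "B", "C", "X"),
                    list(list(inputs = c("A", "B", "C"), signs = rep(1, 3),
                              output = "X"),
                         list(inputs = "A", signs = 1, output = "X"),
                         list(inputs = "B", signs = 1, output = "X"),
                         list(inputs = "C", signs = 1, output = "X")),
                    readouts = "X")
  dd <- logic_data(data.frame(condition = "c1", readout = "X", time = 1,
                              value = 0),
                   data.frame(condition = "c1"))
  expect_equal(logic_objective(m6, c(1, 0, 0, 0), dd, 1)$theta_s, 0.5)
  expect_error(logic_objective(m, c(1, 1),
                               structure(list(measurements = dat$measurements[0, ],
                                              conditions = dat$conditions,
                                              n_E = 0L),
                                         class = "logic_data"), 0), "n_E")
})

test_that("theta is monotone in alpha and penalizes unused hyperedges", {
  fd <- withr::local_tempdir()
  generate_fixture("logic", seed = 3, outdir = fd)
  fx <- load_logic_fixture(fd)
  sel <- rep(0L, fx$model$r)
  sel[fx$truth$selection] <- 1L
  alphas <- c(0, 1e-4, 1e-2, 1)
  thetas <- vapply(alphas, function(a)
    logic_objective(fx$model, sel, fx$data, a)$theta, numeric(1))
  expect_true(all(diff(thetas) >= 0))

  # adding any extra hyperedge never decreases theta at alpha > 0 when the
  # base selection already fits the data at least as well
  base_sc <- logic_objective(fx$model, sel, fx$data, 1e-4)
  for (e in which(sel == 0L)) {
    bigger <- sel
    bigger[e] <- 1L
    sc <- logic_objective(fx$model, bigger, fx$data, 1e-4)
    expect_gte(sc$theta_s, base_sc$theta_s)
  }
})

test_that("with a dominant complexity weight the empty model is optimal", {
  fd <- withr::local_tempdir()
  generate_fixture("logic", seed = 4, outdir = fd)
  fx <- load_logic_fixture(fd)
  enum <- enumerate_logic_selections(fx$model, fx$data, alpha = 10)
  best <- enum$selection[which.min(enum$theta)]
  # theta_f is bounded by 1 while each selected edge costs alpha * v_e/v_es;
  # at alpha = 10 nothing is worth selecting
  expect_equal(best, paste(rep(0, fx$model$r), collapse = ""))
})

# ---- FBA knockout design ---------------------------------------------------

test_that("wild type earns no production credit at its growth optimum", {
  m <- metabolic_toy_model()
  expect_equal(fba_knockout_objective(m, rep(0, 5)), 0)
})

test_that("duplicate knockouts are filtered and slots are exchangeable", {
  m <- metabolic_toy_model()
  expect_equal(fba_knockout_objective(m, c(7, 7, 0, 0, 0)),
               fba_knockout_objective(m, c(7, 0, 0, 0, 0)))
  set.seed(8)
  for (i in 1:10) {
    ko <- sample(0:52, 5, replace = TRUE)
    v <- fba_knockout_objective(m, ko)
    expect_equal(fba_knockout_objective(m, sample(ko)), v)
    # duplicating one slot into another changes nothing
    dup <- ko
    dup[5] <- dup[1]
    expect_equal(fba_knockout_objective(m, dup),
                 fba_knockout_objective(m, c(ko[1:4], 0)))
  }
})

test_that("the engineered double knockout reroutes flux to the target", {
  m <- metabolic_toy_model()
  # hand-derived LP optima of the toy network:
  # wild type grows at 12 via the efficient route (no target made);
  # knocking out both alternative biomass routes forces the co-producing
  # route: growth 10, target flux 5
  expect_equal(fba_knockout_objective(m, c(1, 2, 0, 0, 0)), -5)
  expect_equal(fba_knockout_objective(m, c(1, 0, 0, 0, 0)), 0)
  expect_equal(fba_knockout_objective(m, c(2, 0, 0, 0, 0)), 0)
  # the essential uptake gene abolishes growth: no credit
  expect_equal(fba_knockout_objective(m, c(4, 0, 0, 0, 0)), 0)
  expect_error(fba_knockout_objective(m, c(99, 0, 0, 0, 0)), "52")
})

test_that("exhaustive enumeration confirms the optimal knockout set", {
  m <- metabolic_toy_model()
  enum <- enumerate_knockouts(m, max_size = 3)
  expect_equal(enum$value[1], -5)
  expect_equal(enum$genes[1], "1;2")
})

test_that("VNS reaches the enumerated knockout optimum", {
  m <- metabolic_toy_model()
  enum_best <- -5
  best <- Inf
  for (s in 1:3) {
    r <- vns_solve(make_fba_problem(m),
                   vns_options(max_evaluations = 20000, seed = s))
    best <- min(best, r$best$f)
    if (best <= enum_best) break
  }
  expect_equal(best, enum_best)
})

test_that("the model CSV pair round-trips", {
  m <- metabolic_toy_model()
  d <- withr::local_tempdir()
  paths <- write_metabolic_model(m, d)
  m2 <- read_metabolic_model(paths["reactions"], paths["genes"])
  expect_equal(m2$S[m$metabolites, m$reactions], m$S)
  expect_equal(unname(m2$upper_bounds), unname(m$upper_bounds))
  expect_equal(fba_knockout_objective(m2, c(1, 2, 0, 0, 0)), -5)
})

# ---- benchmarks ------------------------------------------------------------

test_that("gear-train arithmetic and symmetry", {
  expect_equal(gear_train(c(12, 12, 12, 12)), (1 / 6.931 - 1)^2)
  expect_equal(gear_train(c(16, 19, 43, 49)), 2.700857e-12,
               tolerance = 1e-6)
  x <- c(23, 41, 37, 55)
  expect_equal(gear_train(x), gear_train(x[c(2, 1, 3, 4)]))
  expect_equal(gear_train(x), gear_train(x[c(1, 2, 4, 3)]))
  expect_error(gear_train(c(10, 12, 12, 12)), "12")
  expect_error(gear_train(c(12.5, 12, 12, 12)), "integers")
})

test_that("registry functions vanish at their recorded optima", {
  for (name in list_benchmarks()) {
    for (variant in c(name, paste0("shifted_", name),
                      paste0("rotated_", name),
                      paste0("shifted_rotated_", name))) {
      info <- benchmark_info(variant, 6)
      expect_equal(info$fn(info$xmin), info$fmin, tolerance = 1e-8,
                   label = variant)
      expect_true(all(info$xmin >= info$lower & info$xmin <= info$upper),
                  label = variant)
    }
  }
  expect_error(benchmark_function("nope", c(0, 0)), "unknown benchmark")
  expect_error(benchmark_function("sphere", c(100, 0)), "box")
})

test_that("shifted and rotated variants are deterministic transformations", {
  i1 <- benchmark_info("shifted_rastrigin", 5)
  i2 <- benchmark_info("shifted_rastrigin", 5)
  x <- c(0.3, -1, 2, 0, 1)
  expect_identical(i1$fn(x), i2$fn(x))
  expect_identical(i1$xmin, i2$xmin)
  # rotation preserves the sphere exactly (orthogonal invariance)
  ir <- benchmark_info("rotated_sphere", 4)
  expect_equal(ir$fn(c(1, 1, 0, -1)), 3, tolerance = 1e-10)
})
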