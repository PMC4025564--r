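---
title: "Metaheuristic global optimization for systems biology: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaheuristic global optimization for systems biology: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaheur)
```

Model calibration, network inference and strain design in systems biology
reduce, again and again, to global optimization of a black-box objective:
a simulation, an inner linear program, a scoring function over discrete
structures. These landscapes are multimodal and derivative-free, so exact
methods are hopeless at realistic sizes and local solvers stall in the
nearest basin. `metaheur` implements the two metaheuristic families that
have proven most effective for these problem classes — scatter search for
continuous and mixed-integer problems, variable neighbourhood search (VNS)
for integer problems — plus a deterministic cooperative layer over either,
and a multi-start Metropolis–Hastings sampler when the question is not
"which parameters fit best" but "which parameters are consistent with the
data".

All solvers share one problem container (`op_problem()`): box bounds, an
integer-index set (empty for continuous problems, full for integer ones),
and an objective that may also return constraint residuals. Constraints are
handled by a penalized merit `f + w * excess` with `w = 1e3` by default —
the simplest merit function that is monotone in both fit and violation.
Every call of the objective, including calls made inside local searches, is
charged against the evaluation budget through a shared counter, so budgets
are comparable across solvers. Non-finite objective values are ranked last
rather than raised as errors: black-box simulations fail, and a robust
search should step around the crater, not fall into it.

## Enhanced scatter search

Scatter search keeps a small reference set (RefSet) rather than a large
population, and combines its members systematically rather than by random
mating. Our defaults follow that philosophy: `N = max(8, 1 + sqrt(2 nvar))`
rounded up to even, seeded by taking the best half plus a max–min-distance
diverse half from a Latin hypercube sample of `10 nvar` points. In each
iteration every directed pair of members produces two offspring inside the
hyper-rectangle spanned by the parents, stretched by half the
parent-to-parent distance toward the better parent — the combination is
biased into the promising half-space. Three rules shape the dynamics:

* **1+1 replacement.** An offspring may replace only the member that
  generated it, and only on strict improvement. A strong offspring cannot
  colonize the rest of the RefSet, which keeps the population spread over
  distinct basins.
* **Go-beyond.** When an offspring beats its parent, the direction
  parent → offspring is extrapolated with a step that doubles after every
  further improvement, until the first failure or until clipping at the
  bounds stalls movement. This converts a lucky combination into a line
  search at marginal cost.
* **Memory-filtered local search.** Every `local_search_interval = 10`
  iterations, the best RefSet member farther than a normalized radius
  (default 0.05) from all previous local-search endpoints is refined with a
  bounded simplex search. The memory prevents re-polishing the same basin;
  members stagnant for 20 iterations are replaced by fresh diverse points
  (the incumbent best is immune).

The local refinement is a projected Nelder–Mead with the
dimension-adaptive expansion/contraction coefficients of Gao & Han; with
the classic constants the simplex collapses prematurely above roughly five
dimensions, and the adaptive variant is what makes a simplex-type search
viable at the 10-dimensional scale we target. Integer coordinates are
frozen during the simplex phase and polished by unit moves afterwards, so
mixed-integer objectives are only ever evaluated at integral points. One
further design choice proved necessary: once the remaining budget fits
inside a single local search, it is spent polishing the incumbent best,
bypassing the exploration filter. The memory filter exists to diversify
*exploratory* searches; without this final intensification the filter
forbids ever finishing the best basin, and valley-shaped problems
(Rosenbrock-type) stall around `1e-6` instead of converging to machine
precision.

## Variable neighbourhood search

VNS explores an integral box from a locally optimal incumbent: a *shake*
redraws `k` randomly chosen variables uniformly within their domains, a
local search refines the shaken point, and the incumbent is recentred on
strict improvement (resetting `k` to 1) while failures grow `k` up to
`k_max = min(nvar, 10)` — the decomposition-style cap that keeps shakes
affordable on large problems. The distance criterion is the cardinality of
the perturbed set; recently used index sets are remembered (depth 10) and
never repeated, a cheap guard against cycling. Ties are never accepted as
improvements, which prevents drift on the large plateaus that integer
problems produce.

The local search is where the design departs from a textbook sketch, for a
measurable reason. A first-improvement sweep of unit moves (±1 per
coordinate) is the natural baseline, but on coupled objectives — ratios and
products of decision variables, exactly what gear-ratio design or
knockout-set selection produce — its fixed points are so dense that the
global optimum is unreachable: descending the gear-train objective from
2,000 random starts with unit moves never once reached the optimum. Three
upgrades, each generic, close the gap:

1. **Go-beyond step doubling.** Within one coordinate the improving step
   doubles (1, 2, 4, …) and resets on failure, so a coordinate reaches its
   1-D minimum in logarithmically many evaluations. Because these
   objectives are unimodal along any single coordinate, the sweep is then
   an exact cyclic coordinate descent.
2. **Pair intensification.** After unit sweeps stall, each variable pair
   `(i, j)` is scanned: `i` walks its whole domain while `j` is re-optimized
   by 1-D descent, warm-started from the previous scan value's optimum.
   This escapes coordinate-wise minima whenever the *other* variables
   already hold compatible values, which is precisely how compensating
   changes in a ratio must be found. The scan costs on the order of
   `choose(nvar, 2) * domain` evaluations, so it is auto-enabled only when
   `nvar <= 12` and no domain exceeds 200 values.
3. **Memoisation.** Integer searches revisit points constantly; evaluated
   points are cached per run, and only distinct points are charged to the
   budget. When the counter reaches the size of the search space the run
   stops — everything has been seen.

With these, a 20,000-evaluation run finds the gear-train global optimum
(`2.700857e-12` at teeth counts `(16, 19, 43, 49)`, confirmed by exhaustive
enumeration of the `49^4` grid) in roughly a third of runs, so a 10-seed
panel contains a hit with high probability; unit-move VNS finds it
essentially never. The aggressive mode — a single sweep, first improving
move per coordinate, no extension — is the intensification endpoint used by
cooperative thread profiles, where a cheap, shallow refinement per round is
preferable for some threads.

## Cooperation

The cooperative layer runs `eta` solver threads with heterogeneous
profiles — conservative threads emphasize diversification (large RefSet,
rare local search; non-aggressive VNS with an uncapped `k`), aggressive
threads intensification (small RefSet, frequent local search; aggressive
sweeps, `k_max = 3`) — and exchanges information every `tau` evaluations.
We measure the exchange interval in evaluations rather than wall-clock
time: the original motivation for time-based intervals is load balancing on
heterogeneous hardware, but evaluation-based rounds make runs bit-for-bit
reproducible on any machine, which we judged the more valuable property for
a scientific tool. For the same reason threads advance round-robin in one
process with their own RNG streams; the synchronous barrier is a semantic
contract, not a concurrency primitive.

At the barrier the global best is offered to every thread and adopted only
where it strictly improves the receiving thread's own best; scatter-search
threads splice it in place of their *worst* member (never displacing their
own elite, protecting diversity), VNS threads recentre their incumbent.
With `share_refset`, the leading thread's second-best member is offered
against each other thread's second-worst. A consequence of the
strict-improvement rule is that a single-thread cooperative run is
bit-identical to the plain solver — the degenerate case collapses cleanly
rather than perturbing its own state with echoes of itself. There is
deliberately no cooperative mode for the posterior sampler.

## BayesFit

For parameter estimation under experimental error and non-identifiability,
point estimates mislead; the sampler targets the full posterior. It runs
`n_starts` independent Gaussian random-walk chains from uniform draws over
the box (re-drawn until posterior support is found; after `100 * nvar`
failures the sampler raises an error rather than sample nonsense).
Proposals use independent per-parameter scales initialized at 5% of each
bound width and adapted multiplicatively (×1.1 / ÷1.1 per 50-step window)
toward an acceptance rate in the 0.2–0.45 band — but only during the
burn-in half of the chain. After burn-in the kernel is frozen, so the
retained samples come from a valid fixed-kernel Metropolis–Hastings chain;
adapting forever would bias the stationary distribution. Out-of-bounds
proposals are rejected, which is exactly a uniform-prior indicator; one
visible consequence is that on a *flat* posterior the adaptation inflates
the scales until boundary rejections cap the acceptance rate inside the
band, while every in-support proposal is still accepted with probability
one — the chains record both bookkeepings separately.

Multi-start chains are pooled for marginal histograms (binned over the
prior bounds, so histograms from different runs align) and pairwise 2-D
histograms whose row and column sums reproduce the 1-D histograms exactly.
Multimodal marginals, or ridges in a pairwise table, are the method's
signal of non-identifiability; the best-fit point (highest log-posterior
seen anywhere, burn-in included) is reported alongside, since the best fit
and the posterior mass need not coincide. No between-chain convergence
diagnostic is computed; for the well-conditioned posteriors tested here the
between-chain spread of means is itself the honest standard error, and
that is what the test suite uses.

## Application objectives

**Logic-model training.** A signed prior network (SIF format) is expanded
into all candidate AND/OR gates up to a fan-in cap (default 4): every
non-empty subset of a node's inputs becomes a candidate hyperedge, where a
multi-input hyperedge is an AND gate and hyperedges sharing an output
combine by OR. A binary selection over hyperedges is scored by
`theta = theta_f + alpha * theta_s`: `theta_f` is the mean squared mismatch
between the data (values in `[0, 1)`) and the model's logical steady state
(synchronous updates under clamped stimuli and inhibitions, from an
all-zero start, at most `2 * n_nodes` sweeps), and
`theta_s = sum(v_e P_e) / v_es` charges each selected hyperedge its input
count — a 3-input AND gate costs three times a single edge. Two numerical
choices matter: nodes still changing when the sweep limit is reached are
*undefined* and contribute the worst-case residual 1 per data point
(penalizing oscillatory models, consistent with steady-state semantics),
and the redundancy-compressed integer encoding of the selection space is
not implemented — the binary encoding is the primary interface, and at the
fixture sizes used here (`2^9` selections) enumeration is cheap enough to
serve as the oracle.

**Knockout design.** The decision vector holds five gene slots (0 = empty)
over a 52-gene toy model of central carbon metabolism; duplicates are
collapsed before simulation, so repeats and slot permutations score
identically. The inner problem is flux balance analysis: maximize biomass
by linear programming, then — because growth optima are routinely
degenerate — a secondary LP maximizes the target metabolite's exchange at
the fixed growth optimum, making the objective single-valued and
deterministic. Designs that abolish growth earn no production credit
(objective 0). The toy network is *synthetic* and engineered to be
enumerable: three genes route flux (the optimal design is a specific double
knockout with target flux 5 at growth 10, against wild-type growth 12 with
zero target flux — values derivable by hand from the stoichiometry), one
gene is essential, the rest are metabolically silent. The inner LP is a
dense two-phase simplex with Bland's rule written for this package: the
degenerate, zero-flux-branch LPs that knockouts create crash or fail the
general-purpose simplex routines available in the environment, and Bland's
pivoting is the textbook cure for exactly that degeneracy. It is suitable
for tens of variables, which is all the toy model needs; objective values
are memoised by affected reaction set, so the `~23,500` subsets of the
enumeration oracle reduce to a handful of distinct LP solves.

**Benchmarks.** The gear-train problem (squared deviation of a compound
gear ratio from `1/6.931`, four integer teeth counts in `[12, 60]`) is the
packaged integer benchmark with a known record value. The continuous
registry provides sphere, Rosenbrock, Rastrigin, Ackley and Schwefel in any
dimension, plus shifted and rotated variants whose offsets and orthogonal
matrices are generated from fixed name- and dimension-derived seeds — they
are deterministic functions, reproducible everywhere, with their optima
recorded for testing. They are documented analogues of the large-scale
benchmark style (separability broken by rotation, optima moved off-center),
not reproductions of any external suite's exact instances.

## The synthetic fixtures, and what passing them shows

`generate_fixture()` writes three self-contained datasets with
ground-truth sidecars. The logic fixture is a fixed 7-node, 9-hyperedge
topology (two stimuli, one inhibitable node, three readouts) whose data are
simulated from a known 5-hyperedge sub-model under all 8 stimulus/inhibitor
conditions, three time points per readout (72 points), with truncated
Gaussian noise (sd 0.05) — small against the `1/72`-quantized residual
steps, so the generating selection remains the unique score minimizer at
`alpha = 1e-4` for any noise seed, which the tests verify by full
enumeration rather than assume. The posterior fixture is a saturating
transfer-function curve `y = x^n / (k^n + x^n)` (shape parameters `n = 2`,
`k = 0.5`, the two-parameter interaction form used in logic-ODE models) at
12 design points with noise sd 0.05 and known-σ Gaussian likelihood. The
metabolic fixture is the toy model above, written as its CSV pair.

These fixtures emulate the *structure* of real calibration problems —
quantized residuals, redundant model space, degenerate inner optima,
correlated parameters — but not their scale, their measurement-error
heterogeneity, or the model misspecification that real data carry. Passing
the suite shows the machinery is correct and the search effective at
enumerable sizes; it does not certify performance on a thousand-hyperedge
network or a genome-scale metabolic model.

## Problem sizes, tolerances, reproducibility

The test suite exercises the solvers at the sizes a laptop verifies in
minutes: 10-D continuous panels (budgets `1e4`–`2e5`), the `49^4`
gear-train grid (enumerated in vectorized form via its product
decomposition), `2^9` logic selections, knockout subsets up to size 3, and
`5e4` retained posterior samples. Convergence assertions use the analytic
optima (`1e-6` on the sphere, `1e-5` on 10-D Rosenbrock); sampler
assertions use closed-form conjugate posteriors, with the standard error
taken from between-chain variation and a ±20% band on the posterior
variance. Every stochastic component takes an explicit integer seed, and
solver state (including the RNG stream) travels with the resumable solver
objects, so chunked cooperative execution and plain execution are
bit-identical. Degenerate inputs are defined, not special-cased: empty
bounds boxes are rejected at construction, single-point search spaces
return after one evaluation, identical scatter-search parents yield
perturbed offspring rather than duplicates, and a degenerate (constant)
coordinate simply stays constant in the Latin hypercube design.

Known limitations: penalties are the only constraint-handling mechanism
(no repair operators, no feasibility pumps); the simplex-type local search,
even with adaptive coefficients, degrades beyond a few tens of dimensions;
pair intensification is quadratic in dimension and disabled on large
problems, where VNS falls back to unit sweeps; the LP solver is for tiny
models only; and the sampler offers no convergence diagnostics beyond
multi-start pooling. These are the places a future version would look
first.
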