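# Bounded derivative-free refinement used by the scatter search improvement
# step: Nelder-Mead with the dimension-adaptive expansion/contraction
# coefficients of Gao & Han (2012), candidate points projected onto the box.
# The adaptive coefficients matter: with the classic constants the simplex
# collapses prematurely above ~5 dimensions.
#
# `fn` must accept an in-bounds vector and return the (penalized) objective;
# evaluation accounting is the caller's job (wrap `fn` around evaluate()).
# Returns list(x, value, evaluations).
nm_bounded <- function(fn, x0, lower, upper, max_evals = 500L,
                       tol = 1e-12, step_frac = 0.08) {
  n <- length(x0)
  alpha <- 1
  beta <- 1 + 2 / n          # expansion
  gamma <- 0.75 - 1 / (2 * n) # contraction
  delta <- 1 - 1 / n          # shrink
  proj <- function(x) pmin(pmax(x, lower), upper)

  evals <- 0L
  ev <- function(x) {
    evals <<- evals + 1L
    fn(x)
  }

  # initial simplex: steps of step_frac * bound width, flipped at the box edge
  width <- pmax(upper - lower, .Machine$double.eps)
  V <- matrix(rep(x0, n + 1L), nrow = n)
  for (i in seq_len(n)) {
    h <- step_frac * width[i]
    xi <- x0[i] + h
    if (xi > upper[i]) xi <- x0[i] - h
    V[i, i + 1L] <- max(lower[i], min(upper[i], xi))
    if (V[i, i + 1L] == x0[i]) V[i, i + 1L] <- x0[i] # degenerate coordinate
  }
  fv <- numeric(n + 1L)
  for (j in seq_len(n + 1L)) {
    fv[j] <- ev(V[, j])
    if (evals >= max_evals) break
  }

  while (evals < max_evals) {
    ord <- order(fv)
    V <- V[, ord, drop = FALSE]
    fv <- fv[ord]
    if (is.finite(fv[1L]) &&
        (fv[n + 1L] - fv[1L] <= tol * (abs(fv[1L]) + tol))) break
    xbar <- rowMeans(V[, seq_len(n), drop = FALSE])
    xr <- proj(xbar + alpha * (xbar - V[, n + 1L]))
    fr <- ev(xr)
    if (fr < fv[1L]) {
      if (evals >= max_evals) { V[, n + 1L] <- xr; fv[n + 1L] <- fr; break }
      xe <- proj(xbar + beta * (xr - xbar))
      fe <- ev(xe)
      if (fe < fr) { V[, n + 1L] <- xe; fv[n + 1L] <- fe }
      else { V[, n + 1L] <- xr; fv[n + 1L] <- fr }
    } else if (fr < fv[n]) {
      V[, n + 1L] <- xr
      fv[n + 1L] <- fr
    } else {
      if (fr < fv[n + 1L]) {
        xc <- proj(xbar + gamma * (xr - xbar))   # outside contraction
      } else {
        xc <- proj(xbar - gamma * (xbar - V[, n + 1L])) # inside contraction
      }
      if (evals >= max_evals) break
      fc <- ev(xc)
      if (fc < min(fr, fv[n + 1L])) {
        V[, n + 1L] <- xc
        fv[n + 1L] <- fc
      } else {
        for (j in 2L:(n + 1L)) { # shrink toward the best vertex
          V[, j] <- proj(V[, 1L] + delta * (V[, j] - V[, 1L]))
          fv[j] <- ev(V[, j])
          if (evals >= max_evals) break
        }
      }
    }
  }
  best <- which.min(fv)
  list(x = V[, best], value = fv[best], evaluations = evals)
}
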