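# Dense two-phase primal simplex with Bland's rule. Written for the tiny
# LPs of the toy metabolic model (tens of variables); Bland's pivoting
# guarantees termination on the degenerate LPs that knockouts create
# (zero-flux branches), which is where general-purpose routines in the
# installed packages break down.
#
# Solves: min c'x  s.t.  A x = b, x >= 0   (b may have any sign).
# Returns list(status = "optimal" | "infeasible" | "unbounded", x, value).
simplex_bland <- function(A, b, c, tol = 1e-9) {
  m <- nrow(A)
  n <- ncol(A)
  flip <- b < 0
  A[flip, ] <- -A[flip, , drop = FALSE]
  b[flip] <- -b[flip]

  # tableau over columns of `Afull`; phase 1 appends artificials
  Afull <- cbind(A, diag(m))
  Tb <- cbind(Afull, b) # working tableau, basis columns kept unit
  basis <- n + seq_len(m)

  run_phase <- function(Tb, basis, cost, active_cols) {
    repeat {
      cb <- cost[basis]
      # reduced costs on active columns
      red <- cost[active_cols] -
        as.numeric(crossprod(cb, Tb[, active_cols, drop = FALSE]))
      ent_rel <- which(red < -tol)
      if (!length(ent_rel)) return(list(Tb = Tb, basis = basis, status = "optimal"))
      j <- active_cols[min(ent_rel)] # Bland: smallest eligible index
      col <- Tb[, j]
      rows <- which(col > tol)
      if (!length(rows)) return(list(Tb = Tb, basis = basis, status = "unbounded"))
      ratio <- Tb[rows, ncol(Tb)] / col[rows]
      rmin <- min(ratio)
      cand <- rows[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])] # Bland tie-break on basis label
      piv <- Tb[i, j]
      Tb[i, ] <- Tb[i, ] / piv
      for (r in seq_len(nrow(Tb))) {
        if (r != i && abs(Tb[r, j]) > 0) Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
      }
      basis[i] <- j
    }
  }

  # phase 1: minimize the sum of artificials
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- run_phase(Tb, basis, cost1, seq_len(n + m))
  if (ph1$status != "optimal") return(list(status = "infeasible"))
  Tb <- ph1$Tb
  basis <- ph1$basis
  val1 <- sum(cost1[basis] * Tb[, ncol(Tb)])
  if (val1 > 1e-7) return(list(status = "infeasible"))
  # drive remaining artificials out of the basis where possible
  for (i in which(basis > n)) {
    piv_col <- which(abs(Tb[i, seq_len(n)]) > tol)
    if (length(piv_col)) {
      j <- piv_col[1]
      Tb[i, ] <- Tb[i, ] / Tb[i, j]
      for (r in seq_len(nrow(Tb))) {
        if (r != i && abs(Tb[r, j]) > 0) Tb[r, ] <- Tb[r, ] - Tb[r, j] * Tb[i, ]
      }
      basis[i] <- j
    } # else: redundant row, harmless to keep with its artificial at zero
  }

  cost2 <- c(c, rep(0, m))
  active <- seq_len(n) # artificials excluded from entering
  ph2 <- run_phase(Tb, basis, cost2, active)
  if (ph2$status == "unbounded") return(list(status = "unbounded"))
  Tb <- ph2$Tb
  basis <- ph2$basis
  x <- numeric(n)
  keep <- basis <= n
  x[basis[keep]] <- Tb[keep, ncol(Tb)]
  list(status = "optimal", x = x, value = sum(c * x))
}

# maximize obj'x s.t. Seq x = 0, 0 <= x <= ub, optional extra row a'x >= bge
fba_lp <- function(Seq, ub, obj, extra_a = NULL, extra_b = NULL) {
  m <- nrow(Seq)
  n <- ncol(Seq)
  n_extra <- if (is.null(extra_a)) 0L else 1L
  # columns: fluxes (n) + ub slacks (n) + surplus of the extra row
  A <- rbind(
    cbind(Seq, matrix(0, m, n + n_extra)),
    cbind(diag(n), diag(n), matrix(0, n, n_extra))
  )
  b <- c(rep(0, m), ub)
  if (n_extra) {
    A <- rbind(A, c(extra_a, rep(0, n), -1))
    b <- c(b, extra_b)
  }
  cc <- c(-obj, rep(0, n + n_extra)) # maximize
  res <- simplex_bland(A, b, cc)
  if (res$status != "optimal") return(res)
  list(status = "optimal", x = res$x[seq_len(n)], value = -res$value)
}

#' Toy metabolic network for knockout design
#'
#' A small irreversible steady-state model in the style of central carbon
#' metabolism, built for enumerable strain-design experiments: substrate
#' uptake feeds two branches, the efficient biomass route yields no target
#' metabolite (a succinate stand-in) while the inefficient route co-produces
#' it, and a third intermediate-yield route and a bypass make single
#' knockouts insufficient. Of the 52 genes, three control flux routing, one
#' is essential (its knockout abolishes growth) and the rest map to no
#' reaction, so the optimal knockout set is small and can be verified by
#' exhaustive enumeration. This is a synthetic fixture, not a published
#' genome-scale model.
#'
#' @return An object of class `metabolic_model`: stoichiometric matrix `S`
#'   (metabolites x reactions), `upper_bounds`, reaction/metabolite names,
#'   `biomass` and `target` reaction indices, and `gene_map` (list, gene ->
#'   reaction indices).
#' @export
metabolic_toy_model <- function() {
  metabolites <- c("A", "B", "C", "succ", "biomass")
  reactions <- c("v_upt", "v_ab", "v_ac", "v_b_bm", "v_c_bm", "v_bc",
                 "v_b_bm2", "ex_succ", "ex_bm")
  S <- matrix(0, 5, 9, dimnames = list(metabolites, reactions))
  S["A", "v_upt"] <- 1
  S["A", "v_ab"] <- -1; S["B", "v_ab"] <- 1
  S["A", "v_ac"] <- -1; S["C", "v_ac"] <- 1
  S["B", "v_b_bm"] <- -1; S["biomass", "v_b_bm"] <- 1; S["succ", "v_b_bm"] <- 0.5
  S["C", "v_c_bm"] <- -1; S["biomass", "v_c_bm"] <- 1.2
  S["B", "v_bc"] <- -1; S["C", "v_bc"] <- 1
  S["B", "v_b_bm2"] <- -1; S["biomass", "v_b_bm2"] <- 1.1
  S["succ", "ex_succ"] <- -1
  S["biomass", "ex_bm"] <- -1
  ub <- stats::setNames(rep(1000, 9), reactions)
  ub["v_upt"] <- 10
  gene_map <- c(
    list(g1 = "v_c_bm", g2 = "v_b_bm2", g3 = "v_bc", g4 = "v_upt"),
    stats::setNames(rep(list(character(0)), 48), paste0("g", 5:52))
  )
  structure(list(S = S, upper_bounds = ub,
                 metabolites = metabolites, reactions = reactions,
                 biomass = which(reactions == "ex_bm"),
                 target = which(reactions == "ex_succ"),
                 gene_map = gene_map, n_genes = length(gene_map)),
            class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat("<metabolic_model> ", length(x$metabolites), " metabolites, ",
      length(x$reactions), " reactions, ", x$n_genes, " genes\n", sep = "")
  invisible(x)
}

#' Write / read a metabolic model as a CSV pair
#'
#' `reactions.csv` holds one row per reaction with a stoichiometry string
#' (`"B -> 1 biomass + 0.5 succ"`; empty side for exchanges), the upper
#' flux bound and a role tag (`biomass`, `target` or empty);
#' `genes.csv` maps each gene to the reaction it controls (empty for
#' genes with no metabolic role).
#'
#' @param model A [metabolic_toy_model()]-style object.
#' @param dir Output directory (created if needed).
#' @return `write_metabolic_model()` returns the two file paths;
#'   `read_metabolic_model()` returns a `metabolic_model`.
#' @export
write_metabolic_model <- function(model, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  eqn <- vapply(seq_along(model$reactions), function(j) {
    col <- model$S[, j]
    side <- function(v) {
      paste(vapply(which(v != 0), function(i) {
        co <- v[i]
        if (co == 1) names(v)[i] else paste(co, names(v)[i])
      }, character(1)), collapse = " + ")
    }
    paste(side(pmax(-col, 0)), "->", side(pmax(col, 0)))
  }, character(1))
  role <- rep("", length(model$reactions))
  role[model$biomass] <- "biomass"
  role[model$target] <- "target"
  rf <- file.path(dir, "reactions.csv")
  gf <- file.path(dir, "genes.csv")
  utils::write.csv(data.frame(reaction = model$reactions, equation = eqn,
                              upper_bound = model$upper_bounds, role = role,
                              row.names = NULL),
                   rf, row.names = FALSE)
  utils::write.csv(data.frame(gene = names(model$gene_map),
                              reaction = vapply(model$gene_map, function(r)
                                paste(r, collapse = ";"), character(1))),
                   gf, row.names = FALSE)
  c(reactions = rf, genes = gf)
}

#' @rdname write_metabolic_model
#' @param reactions_csv,genes_csv The two file paths.
#' @export
read_metabolic_model <- function(reactions_csv, genes_csv) {
  rdf <- utils::read.csv(reactions_csv, stringsAsFactors = FALSE)
  gdf <- utils::read.csv(genes_csv, stringsAsFactors = FALSE)
  parse_side <- function(s) {
    s <- trimws(s)
    if (s == "") return(list())
    terms <- strsplit(s, "\\s*\\+\\s*")[[1]]
    lapply(terms, function(t) {
      parts <- strsplit(trimws(t), "\\s+")[[1]]
      if (length(parts) == 1L) list(coef = 1, met = parts[1])
      else list(coef = as.numeric(parts[1]), met = parts[2])
    })
  }
  parsed <- lapply(rdf$equation, function(e) {
    sides <- strsplit(e, "->")[[1]]
    list(lhs = parse_side(sides[1]),
         rhs = parse_side(if (length(sides) > 1) sides[2] else ""))
  })
  mets <- unique(unlist(lapply(parsed, function(p)
    vapply(c(p$lhs, p$rhs), function(t) t$met, character(1)))))
  S <- matrix(0, length(mets), nrow(rdf),
              dimnames = list(mets, rdf$reaction))
  for (j in seq_along(parsed)) {
    for (t in parsed[[j]]$lhs) S[t$met, j] <- S[t$met, j] - t$coef
    for (t in parsed[[j]]$rhs) S[t$met, j] <- S[t$met, j] + t$coef
  }
  gene_map <- stats::setNames(lapply(gdf$reaction, function(r) {
    if (is.na(r) || r == "") character(0) else strsplit(r, ";")[[1]]
  }), gdf$gene)
  structure(list(S = S, upper_bounds = stats::setNames(rdf$upper_bound,
                                                       rdf$reaction),
                 metabolites = mets, reactions = rdf$reaction,
                 biomass = which(rdf$role == "biomass"),
                 target = which(rdf$role == "target"),
                 gene_map = gene_map, n_genes = length(gene_map)),
            class = "metabolic_model")
}

#' Knockout-design objective by flux balance analysis
#'
#' The decision vector holds gene indices to knock out (`0` = empty slot);
#' duplicate knockouts are collapsed before simulation, so permutations and
#' repeats of the same gene set score identically. The knocked-out genes'
#' reactions are removed and the inner linear program maximizes biomass
#' (growth); at that growth optimum a secondary LP maximizes the target
#' metabolite's exchange flux, which makes the objective well-defined when
#' the growth optimum is degenerate. The returned value is minus the target
#' flux (a minimizer therefore maximizes production); designs that abolish
#' growth, or are infeasible, earn no production credit and return 0.
#'
#' @param model A `metabolic_model`.
#' @param ko Integer vector of gene indices in `[0, n_genes]`.
#' @return Scalar: `-(target flux at the growth optimum)`, or 0.
#' @export
fba_knockout_objective <- function(model, ko) {
  ko <- as.integer(round(ko))
  if (any(ko < 0L | ko > model$n_genes)) {
    stop("knockout indices must lie in [0, ", model$n_genes, "]",
         call. = FALSE)
  }
  genes <- unique(ko[ko > 0L]) # repeated KOs filtered
  rxns <- unique(unlist(lapply(genes, function(g)
    model$gene_map[[g]]), use.names = FALSE))
  drop_idx <- match(rxns, model$reactions)
  drop_idx <- drop_idx[!is.na(drop_idx)]
  keep <- setdiff(seq_along(model$reactions), drop_idx)
  Sm <- model$S[, keep, drop = FALSE]
  ub <- model$upper_bounds[keep]
  obj_bm <- as.numeric(keep == model$biomass)
  obj_tg <- as.numeric(keep == model$target)
  if (!any(obj_bm > 0)) return(0) # biomass reaction itself knocked out
  r1 <- fba_lp(Sm, ub, obj_bm)
  if (r1$status != "optimal") return(Inf) # solver failure: worst score
  if (r1$value <= 1e-9) return(0)         # no growth, no production credit
  if (!any(obj_tg > 0)) return(0)
  r2 <- fba_lp(Sm, ub, obj_tg, extra_a = obj_bm,
               extra_b = r1$value * (1 - 1e-9))
  if (r2$status != "optimal") return(Inf)
  # snap the slack the fixed-biomass constraint concedes (1e-9 relative)
  if (r2$value < 1e-6) return(0)
  -r2$value
}

#' Wrap knockout design as an integer program
#'
#' Five knockout slots, each choosing a gene in `[0, n_genes]` (0 = no
#' knockout), scored by [fba_knockout_objective()]. Scores are memoised by
#' the affected reaction set, so the many slot permutations, duplicate
#' knockouts and no-op genes that map to the same metabolic perturbation
#' cost one LP solve among them.
#'
#' @param model A `metabolic_model`.
#' @param n_slots Number of knockout slots.
#' @return An all-integer [op_problem()].
#' @export
make_fba_problem <- function(model, n_slots = 5L) {
  cache <- new.env(parent = emptyenv())
  objective <- function(x) {
    genes <- sort(unique(as.integer(round(x))))
    genes <- genes[genes > 0L]
    rxns <- sort(unique(unlist(lapply(genes, function(g)
      model$gene_map[[g]]), use.names = FALSE)))
    key <- paste0("r:", paste(rxns, collapse = ";"))
    v <- cache[[key]]
    if (is.null(v)) {
      v <- fba_knockout_objective(model, x)
      cache[[key]] <- v
    }
    v
  }
  op_problem(objective, lower = rep(0, n_slots),
             upper = rep(model$n_genes, n_slots),
             integer_indices = seq_len(n_slots), name = "fba_knockout")
}

#' Brute-force enumeration of small knockout sets
#'
#' Scores every gene subset of size at most `max_size` (memoised by
#' affected reaction set) and returns them ranked; the oracle against which
#' heuristic knockout searches are checked.
#'
#' @param model A `metabolic_model`.
#' @param max_size Largest subset size enumerated.
#' @return Data frame with `genes` (semicolon-joined indices) and `value`,
#'   sorted ascending by value.
#' @export
enumerate_knockouts <- function(model, max_size = 3L) {
  prob <- make_fba_problem(model, n_slots = max_size)
  ctr <- new_counter()
  sets <- list(integer(0))
  for (size in seq_len(max_size)) {
    sets <- c(sets, utils::combn(model$n_genes, size, simplify = FALSE))
  }
  vals <- vapply(sets, function(s) {
    ko <- c(s, rep(0L, max_size - length(s)))
    evaluate(prob, ko, ctr)$f
  }, numeric(1))
  out <- data.frame(
    genes = vapply(sets, paste, character(1), collapse = ";"),
    value = vals
  )
  out[order(out$value), , drop = FALSE]
}
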