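# Independent oracles used against the package's own solvers.

# LP oracle: scipy.optimize.linprog (HiGHS) through the system python.
# Solves max/min obj'v s.t. S v = 0, lb <= v <= ub; returns the objective.
scipy_lp <- function(obj, S, lb, ub, maximize = TRUE) {
  payload <- jsonlite::toJSON(list(obj = obj, S = as.matrix(S), lb = lb,
                                   ub = ub, maximize = maximize),
                              digits = NA)
  script <- '
import sys, json
import numpy as np
from scipy.optimize import linprog
p = json.load(sys.stdin)
c = np.array(p["obj"], float)
if p["maximize"][0]: c = -c
S = np.array(p["S"], float)
bounds = list(zip(p["lb"], p["ub"]))
r = linprog(c=c, A_eq=S, b_eq=np.zeros(S.shape[0]), bounds=bounds, method="highs")
out = {"status": int(r.status), "obj": (-r.fun if p["maximize"][0] else r.fun) if r.status == 0 else None}
print(json.dumps(out))
'
  res <- system2("python", c("-c", shQuote(script)), input = as.character(payload),
                 stdout = TRUE, stderr = FALSE)
  jsonlite::fromJSON(res[length(res)])
}

# QP oracle for the EBA objective: PORT routines (stats::nlminb) minimizing
# eps' H eps over box-constrained free TF expressions; independent of the
# package's coordinate-descent/active-set path.
nlminb_eba_objective <- function(model, fixed = numeric(0), H = NULL) {
  tfs <- model$tf_set
  n_tf <- length(tfs)
  if (is.null(H)) H <- diag(n_tf)
  B_tt <- as.matrix(model$beta[tfs, , drop = FALSE])
  M <- diag(n_tf) - B_tt
  fixed_tf <- intersect(names(fixed), tfs)
  free_tf <- setdiff(tfs, fixed_tf)
  iF <- match(fixed_tf, tfs); iU <- match(free_tf, tfs)
  y_t <- numeric(n_tf)
  if (length(iF) > 0) y_t[iF] <- fixed[fixed_tf]
  fn <- function(x) {
    y <- y_t; y[iU] <- x
    eps <- as.numeric(M %*% y - model$beta0[tfs])
    as.numeric(t(eps) %*% H %*% eps)
  }
  if (length(iU) == 0) return(fn(numeric(0)))
  best <- Inf
  for (start in list(model$y_wt[free_tf],
                     model$y_min[free_tf],
                     (model$y_min[free_tf] + model$y_max[free_tf]) / 2)) {
    r <- stats::nlminb(as.numeric(start), fn, lower = model$y_min[free_tf],
                       upper = model$y_max[free_tf],
                       control = list(abs.tol = 1e-14, rel.tol = 1e-13,
                                      iter.max = 500, eval.max = 2000))
    best <- min(best, r$objective)
  }
  best
}

# All-pairs shortest paths (Floyd-Warshall) over a directed edge list.
floyd_warshall_reach <- function(network, seeds, radius) {
  nodes <- sort(union(union(network$regulator, network$target), seeds))
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  D[cbind(match(network$regulator, nodes), match(network$target, nodes))] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
  }
  reach <- apply(D[seeds, , drop = FALSE], 2, min) <= radius
  sort(nodes[reach])
}

# Exhaustive best coverage over all candidate subsets of size <= budget.
exhaustive_coverage <- function(annotation, terms, candidates, budget, k = 1) {
  best <- 0
  idx <- seq_along(candidates)
  for (size in seq_len(min(budget, length(candidates)))) {
    combos <- utils::combn(idx, size, simplify = FALSE)
    for (cc in combos) {
      cov <- length(go_coverage(annotation, terms, candidates[cc], k))
      if (cov > best) best <- cov
    }
  }
  best
}

# Random feasible toy LP instance (v = 0 always feasible).
random_lp_instance <- function(seed, n_mets = 5, n_rxns = 10) {
  with_seed(seed, {
    S <- matrix(0, n_mets, n_rxns)
    for (j in seq_len(n_rxns)) {
      rows <- sample(n_mets, sample(1:2, 1))
      S[rows, j] <- sample(c(-1, 1), length(rows), replace = TRUE)
    }
    lb <- runif(n_rxns, -5, 0)
    ub <- runif(n_rxns, 0, 10)
    obj <- as.numeric(seq_len(n_rxns) == sample(n_rxns, 1))
    list(S = S, lb = lb, ub = ub, obj = obj)
  })
}
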