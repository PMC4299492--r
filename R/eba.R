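## Expression Balance Analysis.  Under a perturbation scenario the
## genome-wide profile is predicted by minimizing the squared slacks of the
## TF equations ("phenomenological" constraints) subject to per-gene
## capacity bounds, environmental (effector-fixed) values and genetic
## (knockout / over-expression / rewiring) edits.  The quadratic program is
## solved over the TF subnetwork only -- the objective sums TF slacks --
## and non-TF genes are then propagated linearly and clamped.

#' Construct a perturbation scenario
#'
#' @param knockouts gene ids fixed at their expression floor
#' @param overexpressions gene ids fixed at their expression ceiling
#' @param rewirings data.frame (target, donor): target's basal and
#'   regulatory coefficients are replaced by the donor's
#' @param effectors data.frame (id, delta): environmental effector changes
#' @param exchange_overrides data.frame (reaction, lb, ub): metabolic
#'   exchange-bound overrides
#' @return `perturbation_scenario`
#' @export
perturbation_scenario <- function(knockouts = character(0),
                                  overexpressions = character(0),
                                  rewirings = NULL, effectors = NULL,
                                  exchange_overrides = NULL) {
  rewirings <- rewirings %||% data.frame(target = character(), donor = character())
  effectors <- effectors %||% data.frame(id = character(), delta = numeric())
  exchange_overrides <- exchange_overrides %||%
    data.frame(reaction = character(), lb = numeric(), ub = numeric())
  genetic <- c(knockouts, overexpressions, rewirings$target)
  if (anyDuplicated(genetic))
    stop_eb("gene(s) in more than one genetic category: ",
            paste(unique(genetic[duplicated(genetic)]), collapse = ", "))
  if (nrow(rewirings) > 0L && any(rewirings$target == rewirings$donor))
    stop_eb("rewiring donor must differ from target")
  structure(list(knockouts = knockouts, overexpressions = overexpressions,
                 rewirings = rewirings, effectors = effectors,
                 exchange_overrides = exchange_overrides),
            class = "perturbation_scenario")
}

is_wt_scenario <- function(sc) {
  length(sc$knockouts) == 0L && length(sc$overexpressions) == 0L &&
    nrow(sc$rewirings) == 0L && nrow(sc$effectors) == 0L &&
    nrow(sc$exchange_overrides) == 0L
}

#' Read a scenario from JSON
#'
#' Schema: `{"knockouts": [], "overexpressions": [], "rewirings":
#' [{"target":, "donor":}], "effectors": [{"id":, "delta":}],
#' "exchange_overrides": [{"reaction":, "lb":, "ub":}]}` (all keys optional).
#'
#' @param path JSON file
#' @return `perturbation_scenario`
#' @export
read_scenario <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_df <- function(x, proto) {
    if (is.null(x) || length(x) == 0L) return(proto)
    as.data.frame(x, stringsAsFactors = FALSE)
  }
  perturbation_scenario(
    knockouts = as.character(j$knockouts %||% character(0)),
    overexpressions = as.character(j$overexpressions %||% character(0)),
    rewirings = as_df(j$rewirings, data.frame(target = character(), donor = character())),
    effectors = as_df(j$effectors, data.frame(id = character(), delta = numeric())),
    exchange_overrides = as_df(j$exchange_overrides,
                               data.frame(reaction = character(), lb = numeric(), ub = numeric())))
}

#' Write a scenario to JSON
#' @param scenario `perturbation_scenario`
#' @param path output file
#' @export
write_scenario <- function(scenario, path) {
  jsonlite::write_json(unclass(scenario), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  invisible(path)
}

#' Apply a perturbation scenario to a regulatory model
#'
#' Genetic edits: knockouts are fixed at the gene's capacity floor,
#' over-expressions at its ceiling (the knocked-out gene's regulatory
#' column stays active at that floor value unless `hard_knockout`);
#' rewiring (target, donor) copies the donor's basal coefficient and
#' regulatory row onto the target.  Environmental effectors become fixed TF
#' values and/or inactive TFs (regulatory column zeroed) through the
#' signal-transduction layer.
#'
#' @param model `regulatory_model`
#' @param system `signal_system` (may be `NULL` when the scenario has no
#'   effectors)
#' @param scenario `perturbation_scenario`
#' @param hard_knockout also zero the knocked-out TF's regulatory column
#' @return list with `model` (edited) and `fixed` (named numeric map)
#' @export
apply_scenario <- function(model, system, scenario, hard_knockout = FALSE) {
  gen_genes <- c(scenario$knockouts, scenario$overexpressions,
                 scenario$rewirings$target, scenario$rewirings$donor)
  absent <- setdiff(gen_genes, model$genes)
  if (length(absent) > 0L)
    stop_eb("scenario gene(s) not in model: ", paste(absent, collapse = ", "))

  fixed <- numeric(0)
  for (g in scenario$knockouts) fixed[g] <- unname(model$y_min[[g]])
  for (g in scenario$overexpressions) fixed[g] <- unname(model$y_max[[g]])

  if (nrow(scenario$rewirings) > 0L) {
    beta <- model$beta
    for (r in seq_len(nrow(scenario$rewirings))) {
      t <- scenario$rewirings$target[r]; d <- scenario$rewirings$donor[r]
      model$beta0[t] <- model$beta0[[d]]
      beta[t, ] <- beta[d, ]
    }
    model$beta <- beta
  }

  if (nrow(scenario$effectors) > 0L) {
    if (is.null(system)) stop_eb("scenario has effectors but no signal system given")
    env <- environment_to_constraints(system, model, scenario$effectors)
    clashes <- intersect(names(env$fixed), names(fixed))
    if (length(clashes) > 0L)
      stop_eb("conflicting fixed values for gene(s) ",
              paste(clashes, collapse = ", "),
              ": genetic edit vs environmental constraint")
    fixed <- c(fixed, env$fixed)
    if (length(env$inactive) > 0L) {
      beta <- model$beta
      beta[, intersect(env$inactive, colnames(beta))] <- 0
      model$beta <- beta
    }
  }

  if (hard_knockout) {
    beta <- model$beta
    kos <- intersect(scenario$knockouts, colnames(beta))
    if (length(kos) > 0L) { beta[, kos] <- 0; model$beta <- beta }
  }

  list(model = model, fixed = fixed)
}

#' Solve the EBA quadratic program
#'
#' Stage 1: over the TF subnetwork, minimize `t(eps) %*% H %*% eps` where
#' `eps_j = y_j - beta0_j - sum_k beta_jk y_k` for every TF j, subject to
#' the capacity bounds on unfixed TFs (fixed values substituted as
#' constants).  Stage 2: each non-TF gene is set to its linear prediction
#' from the optimal TF profile, clamped to its capacity bounds; fixed genes
#' keep their fixed values verbatim.
#'
#' @param model `regulatory_model` (already scenario-edited)
#' @param fixed named numeric map of fixed expression values
#' @param H positive-definite TF weight matrix (default identity)
#' @param tolerance QP convergence tolerance
#' @return an `eba_result`: `y_hat`, per-TF `epsilon`, `objective`,
#'   `status` (`optimal` or `infeasible_relaxed`), `relaxation`
#' @export
eba_solve <- function(model, fixed = numeric(0), H = NULL, tolerance = 1e-8) {
  tfs <- model$tf_set
  n_tf <- length(tfs)
  if (length(fixed) > 0L) {
    bad <- names(fixed)[fixed < model$y_min[names(fixed)] - 1e-9 |
                        fixed > model$y_max[names(fixed)] + 1e-9]
    if (length(bad) > 0L)
      stop_eb("fixed value outside capacity bounds for: ",
              paste(bad, collapse = ", "))
  }
  if (is.null(H)) H <- diag(n_tf)
  stopifnot(identical(dim(H), c(n_tf, n_tf)))

  B_tt <- as.matrix(model$beta[tfs, , drop = FALSE])   # TF x TF
  beta0_t <- model$beta0[tfs]
  M <- diag(n_tf) - B_tt                               # eps = M y_t - beta0_t

  fixed_tf <- intersect(names(fixed), tfs)
  free_tf <- setdiff(tfs, fixed_tf)
  iF <- match(fixed_tf, tfs); iU <- match(free_tf, tfs)

  relaxation <- 0
  status <- "optimal"
  lo <- model$y_min[free_tf]; hi <- model$y_max[free_tf]
  if (any(lo > hi)) {                                  # degenerate bounds
    relaxation <- max(lo - hi)
    mid <- (lo + hi) / 2
    lo <- pmin(lo, mid - relaxation / 2); hi <- pmax(hi, mid + relaxation / 2)
    status <- "infeasible_relaxed"
    warning("capacity bounds relaxed by ", format(relaxation))
  }

  y_t <- numeric(n_tf); names(y_t) <- tfs
  if (length(iF) > 0L) y_t[iF] <- fixed[fixed_tf]

  if (length(iU) > 0L) {
    A <- M[, iU, drop = FALSE]
    r <- -beta0_t
    if (length(iF) > 0L) r <- r + as.numeric(M[, iF, drop = FALSE] %*% y_t[iF])
    HA <- H %*% A
    Q <- 2 * crossprod(A, HA)
    cvec <- 2 * as.numeric(crossprod(HA, r))
    x0 <- clamp(model$y_wt[free_tf], lo, hi)
    sol <- qp_solve_box(Q, cvec, as.numeric(lo), as.numeric(hi),
                        x0 = as.numeric(x0), tol = tolerance * 1e-4)
    y_t[iU] <- sol$x
  }

  eps <- as.numeric(M %*% y_t - beta0_t)
  names(eps) <- tfs
  objective <- as.numeric(t(eps) %*% H %*% eps)

  ## stage 2: propagate to all genes
  y_hat <- model$beta0 + as.numeric(model$beta %*% y_t)
  y_hat <- clamp(y_hat, model$y_min, model$y_max)
  names(y_hat) <- model$genes
  y_hat[tfs] <- y_t                                    # TF values from the QP
  if (length(fixed) > 0L) y_hat[names(fixed)] <- fixed # fixed verbatim

  structure(list(y_hat = y_hat, epsilon = eps, objective = objective,
                 status = status, relaxation = relaxation),
            class = "eba_result")
}

#' @export
print.eba_result <- function(x, ...) {
  cat(sprintf("eba_result: %d genes, objective %.6g, status %s\n",
              length(x$y_hat), x$objective, x$status))
  invisible(x)
}

#' Predict the genome-wide expression profile under a scenario
#'
#' Composition of [apply_scenario()] and [eba_solve()] with the default
#' (identity) weight and tolerance 1e-8.
#'
#' @param model `regulatory_model`
#' @param system `signal_system` or `NULL`
#' @param scenario `perturbation_scenario`
#' @param hard_knockout passed to [apply_scenario()]
#' @return `eba_result`
#' @export
predict_expression <- function(model, system, scenario,
                               hard_knockout = FALSE) {
  ed <- apply_scenario(model, system, scenario, hard_knockout = hard_knockout)
  eba_solve(ed$model, ed$fixed)
}
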