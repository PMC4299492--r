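## Seeded generators for every input artifact: a scale-free signed TRN with
## ground-truth coefficients, a steady-state-plus-noise expression
## compendium, a toy chain metabolic network wired to synthetic enzymes, a
## signal-transduction table, a random GO annotation, and perturbation
## scenarios with analytic growth truth.  A single master seed is threaded
## through counter-based sub-seeds (see [split_seed()]) so each artifact is
## independently regenerable, bit-identically.

EXPR_FLOOR <- 0
EXPR_CEIL <- 14   # log2 dynamic range of the synthetic world

#' Generate a scale-free signed regulatory network with ground truth
#'
#' TF out-degrees follow preferential attachment (heavy-tailed); edge signs
#' are `+` with probability `p_activator` (a small fraction are dual
#' `+/-`); coefficient magnitudes are log-normal (meanlog -1, sdlog 0.5)
#' and are rescaled, if needed, so the TF-subnetwork spectral radius stays
#' below 0.9 (stable fixed point).  Basal coefficients are chosen so the
#' wild-type fixed point sits mid-range.
#'
#' @param n_genes,n_tfs network size (`n_tfs < n_genes`); TFs are the
#'   first `n_tfs` genes
#' @param mean_out_degree mean TF out-degree (>= 1)
#' @param p_activator probability of a `+` edge
#' @param p_dual probability of a dual `+/-` edge
#' @param beta_meanlog,beta_sdlog log-normal parameters of the coefficient
#'   magnitudes (defaults -1, 0.5); smaller magnitudes keep perturbation
#'   responses inside the linear (unclamped) range
#' @param seed integer seed
#' @return list with `network` (`network_table`) and `truth` (genes,
#'   tf_set, beta0, beta, y_star, config)
#' @export
generate_trn <- function(n_genes = 200L, n_tfs = 20L, mean_out_degree = 5,
                         p_activator = 0.6, p_dual = 0.05,
                         beta_meanlog = -1, beta_sdlog = 0.5, seed = 1L) {
  stopifnot(n_tfs < n_genes, mean_out_degree >= 1, n_tfs >= 1)
  with_seed(split_seed(seed, "trn"), {
    genes <- sprintf("g%04d", seq_len(n_genes))
    tfs <- genes[seq_len(n_tfs)]
    n_edges <- round(n_tfs * mean_out_degree)
    outdeg <- stats::setNames(rep(0L, n_tfs), tfs)
    reg <- character(0); tgt <- character(0)
    existing <- new.env(parent = emptyenv())
    for (e in seq_len(n_edges)) {
      tf <- sample(tfs, 1L, prob = outdeg + 1)   # preferential attachment
      for (try in 1:50) {
        t <- sample(setdiff(genes, tf), 1L)
        key <- paste(tf, t)
        if (is.null(existing[[key]])) break
        t <- NA_character_
      }
      if (is.na(t)) next
      existing[[paste(tf, t)]] <- TRUE
      reg <- c(reg, tf); tgt <- c(tgt, t)
      outdeg[tf] <- outdeg[tf] + 1L
    }
    m <- length(reg)
    dual <- stats::runif(m) < p_dual
    sign <- ifelse(dual, "+/-", ifelse(stats::runif(m) < p_activator, "+", "-"))
    evidence <- sample(c("confirmed", "strong", "weak"), m, replace = TRUE,
                       prob = c(0.3, 0.4, 0.3))
    net <- network_table(data.frame(regulator = reg, target = tgt,
                                    sign = sign, evidence = evidence,
                                    stringsAsFactors = FALSE))
    mag <- stats::rlnorm(nrow(net), meanlog = beta_meanlog, sdlog = beta_sdlog)
    bsign <- ifelse(net$sign == "+", 1,
                    ifelse(net$sign == "-", -1, base::sign(stats::runif(nrow(net)) - 0.5)))
    beta <- matrix(0, n_genes, n_tfs, dimnames = list(genes, tfs))
    beta[cbind(match(net$target, genes), match(net$regulator, tfs))] <- mag * bsign
    B_tt <- beta[tfs, , drop = FALSE]
    rho <- if (n_tfs > 0) max(Mod(eigen(B_tt, only.values = TRUE)$values)) else 0
    if (rho >= 0.9) {
      beta <- beta * (0.85 / rho)
    }
    y_star <- stats::runif(n_genes, 5, 9)
    beta0 <- y_star - as.numeric(beta %*% y_star[seq_len(n_tfs)])
    names(beta0) <- genes
    truth <- structure(list(genes = genes, tf_set = tfs, beta0 = beta0,
                            beta = beta, y_star = stats::setNames(y_star, genes),
                            config = list(n_genes = n_genes, n_tfs = n_tfs,
                                          mean_out_degree = mean_out_degree,
                                          p_activator = p_activator,
                                          p_dual = p_dual, seed = seed)),
                       class = "trn_truth")
    list(network = net, truth = truth)
  })
}

#' Regulatory-model view of a ground truth
#'
#' Wraps the true coefficients as a `regulatory_model` with the full
#' synthetic dynamic range as capacity bounds; useful as the oracle side of
#' recovery and growth tests.
#'
#' @param truth from [generate_trn()]
#' @param sigma_wt wild-type sd assigned to every gene (default 0.1)
#' @return `regulatory_model`
#' @export
truth_to_model <- function(truth, sigma_wt = 0.1) {
  n <- length(truth$genes)
  regulatory_model(truth$genes, truth$tf_set, truth$beta0,
                   Matrix::Matrix(truth$beta, sparse = TRUE),
                   y_min = rep(EXPR_FLOOR, n), y_max = rep(EXPR_CEIL, n),
                   y_wt = truth$y_star, sigma_wt = rep(sigma_wt, n))
}

#' Deterministic steady state of the ground-truth model under a scenario
#'
#' Fixed genes (knockouts at the floor, over-expressions at the ceiling,
#' effector-shifted TFs) are removed from the linear TF system and
#' substituted as constants; `eta` is a per-gene additive input (noise).
#'
#' @param truth from [generate_trn()]
#' @param eta per-gene additive input (default zero)
#' @param scenario optional `perturbation_scenario`
#' @param system `signal_system` for effector scenarios
#' @return named per-gene expression, clamped to the synthetic range
#' @export
truth_steady_state <- function(truth, eta = NULL, scenario = NULL,
                               system = NULL) {
  genes <- truth$genes; tfs <- truth$tf_set
  n <- length(genes); n_tf <- length(tfs)
  if (is.null(eta)) eta <- numeric(n)
  beta0 <- truth$beta0; beta <- truth$beta
  fixed <- numeric(0)
  if (!is.null(scenario)) {
    if (nrow(scenario$rewirings) > 0L) {
      for (r in seq_len(nrow(scenario$rewirings))) {
        t <- scenario$rewirings$target[r]; d <- scenario$rewirings$donor[r]
        beta0[t] <- beta0[[d]]; beta[t, ] <- beta[d, ]
      }
    }
    for (g in scenario$knockouts) fixed[g] <- EXPR_FLOOR
    for (g in scenario$overexpressions) fixed[g] <- EXPR_CEIL
    if (nrow(scenario$effectors) > 0L) {
      if (is.null(system)) stop_eb("effectors in scenario but no signal system")
      env <- environment_to_constraints(system, truth_to_model(truth),
                                        scenario$effectors)
      fixed <- c(fixed, env$fixed[setdiff(names(env$fixed), names(fixed))])
      if (length(env$inactive) > 0L) beta[, intersect(env$inactive, tfs)] <- 0
    }
  }
  B_tt <- beta[tfs, , drop = FALSE]
  rho <- max(Mod(eigen(B_tt, only.values = TRUE)$values))
  if (rho >= 0.95)
    stop_eb("unstable ground truth: TF-subnetwork spectral radius ", round(rho, 3))
  fixed_tf <- intersect(names(fixed), tfs)
  iF <- match(fixed_tf, tfs); iU <- setdiff(seq_len(n_tf), iF)
  y_t <- numeric(n_tf); names(y_t) <- tfs
  if (length(iF) > 0L) y_t[iF] <- fixed[fixed_tf]
  if (length(iU) > 0L) {
    A <- diag(n_tf)[iU, iU, drop = FALSE] - B_tt[iU, iU, drop = FALSE]
    rhs <- beta0[tfs][iU] + eta[match(tfs[iU], genes)]
    if (length(iF) > 0L)
      rhs <- rhs + as.numeric(B_tt[iU, iF, drop = FALSE] %*% y_t[iF])
    y_t[iU] <- solve(A, rhs)
  }
  y <- beta0 + eta + as.numeric(beta %*% y_t)
  names(y) <- genes
  y[tfs] <- y_t
  if (length(fixed) > 0L) y[names(fixed)] <- fixed
  clamp(y, EXPR_FLOOR, EXPR_CEIL)
}

#' Simulate an expression compendium from a ground-truth network
#'
#' Each array is the steady state of the true linear model with per-gene
#' Gaussian input noise, under its scenario's overrides (knockout to the
#' expression floor, over-expression to the ceiling, effectors to shifted
#' TF values), clamped to the global log2 range \[0, 14\].
#'
#' @param truth from [generate_trn()]
#' @param n_wt number of wild-type replicate arrays
#' @param scenarios list of `perturbation_scenario` (one array each)
#' @param noise_sd input noise sd (log2 units)
#' @param seed integer seed
#' @param system `signal_system` for effector scenarios
#' @return `expression_table` with metadata
#' @export
simulate_compendium <- function(truth, n_wt = 10L, scenarios = list(),
                                noise_sd = 0.1, seed = 1L, system = NULL) {
  stopifnot(noise_sd >= 0, n_wt >= 0)
  with_seed(split_seed(seed, "compendium"), {
    n <- length(truth$genes)
    n_arr <- n_wt + length(scenarios)
    ids <- c(sprintf("wt%03d", seq_len(n_wt)),
             if (length(scenarios) > 0L) sprintf("pert%03d", seq_along(scenarios)))
    vals <- matrix(NA_real_, n, n_arr, dimnames = list(truth$genes, ids))
    meta <- empty_array_meta(ids)
    for (a in seq_len(n_arr)) {
      eta <- stats::rnorm(n, 0, noise_sd)
      sc <- if (a > n_wt) scenarios[[a - n_wt]] else NULL
      vals[, a] <- truth_steady_state(truth, eta, sc, system)
      if (!is.null(sc)) {
        genetic <- c(sc$knockouts, sc$overexpressions, sc$rewirings$target)
        meta$class[a] <- if (length(genetic) > 0L) "genetic" else "environmental"
        meta$perturbed_genes[[a]] <- genetic
        meta$perturbation_kind[a] <-
          if (length(sc$knockouts) > 0L) "knockout"
          else if (length(sc$overexpressions) > 0L) "overexpression"
          else if (nrow(sc$rewirings) > 0L) "rewiring" else "none"
        meta$effectors[[a]] <- sc$effectors
      }
    }
    expression_table(vals, meta)
  })
}

#' Generate a toy chain metabolic model wired to synthetic enzymes
#'
#' Substrate uptake (capacity 10) feeds a linear chain of `n_internal`
#' enzymatic steps into a biomass drain.  One middle step carries
#' `redundancy` additional parallel isozyme reactions, each with its own
#' gene (OR-redundant).  Enzyme genes are drawn from the ground-truth
#' network's non-TF genes (preferring regulated ones) so the pipeline
#' closes end to end.  The analytic optimum (growth 10) and the
#' essential/non-essential split are recorded.
#'
#' @param truth from [generate_trn()] (or `NULL` for free-standing enzyme
#'   ids `enz01`, ...)
#' @param n_internal number of chain steps (>= 3)
#' @param redundancy extra isozyme branches on the middle step
#' @param seed integer seed
#' @return list with `model` (`metabolic_model`) and `truth` (list:
#'   enzymes, essential, non_essential, optimal_growth, uptake_capacity)
#' @export
generate_toy_metabolic_model <- function(truth = NULL, n_internal = 5L,
                                         redundancy = 1L, seed = 1L) {
  stopifnot(n_internal >= 3L, redundancy >= 0L)
  with_seed(split_seed(seed, "metabolic"), {
    n_enz <- n_internal + redundancy
    if (is.null(truth)) {
      enz <- sprintf("enz%02d", seq_len(n_enz))
    } else {
      pool <- setdiff(truth$genes, truth$tf_set)
      regulated <- intersect(pool, rownames(truth$beta)[rowSums(truth$beta != 0) > 0])
      pool <- c(sample(regulated), sample(setdiff(pool, regulated)))
      if (length(pool) < n_enz) stop_eb("ground truth has too few non-TF genes")
      enz <- pool[seq_len(n_enz)]
    }
    mets <- sprintf("M%02d", seq_len(n_internal + 1L))
    uptake_cap <- 10
    rxns <- list(list(id = "EX_S", stoich = stats::setNames(1, mets[1]),
                      lb = 0, ub = uptake_cap, gpr = "", is_exchange = TRUE))
    mid <- as.integer(ceiling(n_internal / 2))
    ei <- 0L
    iso_genes <- character(0)
    primary_genes <- character(n_internal)
    for (i in seq_len(n_internal)) {
      ei <- ei + 1L
      primary_genes[i] <- enz[ei]
      rxns[[length(rxns) + 1L]] <- list(
        id = sprintf("R%02d", i),
        stoich = stats::setNames(c(-1, 1), mets[c(i, i + 1L)]),
        lb = 0, ub = 100, gpr = enz[ei], is_exchange = FALSE)
      if (i == mid && redundancy > 0L) {
        for (j in seq_len(redundancy)) {
          ei <- ei + 1L
          iso_genes <- c(iso_genes, enz[ei])
          rxns[[length(rxns) + 1L]] <- list(
            id = sprintf("R%02d_iso%d", i, j),
            stoich = stats::setNames(c(-1, 1), mets[c(i, i + 1L)]),
            lb = 0, ub = 100, gpr = enz[ei], is_exchange = FALSE)
        }
      }
    }
    rxns[[length(rxns) + 1L]] <- list(
      id = "BIO", stoich = stats::setNames(-1, mets[n_internal + 1L]),
      lb = 0, ub = 1000, gpr = "", is_exchange = FALSE)
    model <- metabolic_model(mets, rxns, biomass = "BIO")
    ## a step with isozymes keeps growing when any one gene is deleted
    essential <- if (redundancy > 0L) primary_genes[-mid] else primary_genes
    non_essential <- if (redundancy > 0L) c(primary_genes[mid], iso_genes) else character(0)
    list(model = model,
         truth = list(enzymes = enz, essential = essential,
                      non_essential = non_essential,
                      isozyme_step = if (redundancy > 0L) sprintf("R%02d", mid) else NA,
                      optimal_growth = uptake_cap,
                      uptake_capacity = uptake_cap))
  })
}

#' Generate a random signal-transduction table
#'
#' Assigns effectors to `n_systems` distinct TFs; kappa magnitudes are
#' log-uniform on \[0.1, 2\] with Bernoulli(0.5) signs; 20% of entries are
#' activity-only with a random functionality rule.
#'
#' @param truth from [generate_trn()]
#' @param n_systems number of (tf, effector) entries (<= number of TFs)
#' @param seed integer seed
#' @param omega global scale
#' @return `signal_system`
#' @export
generate_sts <- function(truth, n_systems, seed = 1L, omega = 1) {
  stopifnot(n_systems <= length(truth$tf_set), n_systems >= 0)
  with_seed(split_seed(seed, "sts"), {
    if (n_systems == 0L) {
      return(signal_system(data.frame(tf = character(), effector = character(),
                                      type = character(), kappa = numeric(),
                                      functional_with_effector = logical()),
                           omega = omega))
    }
    tfs <- sample(truth$tf_set, n_systems)
    act <- stats::runif(n_systems) < 0.2
    kappa <- exp(stats::runif(n_systems, log(0.1), log(2))) *
      ifelse(stats::runif(n_systems) < 0.5, 1, -1)
    entries <- data.frame(
      tf = tfs, effector = sprintf("eff%02d", seq_len(n_systems)),
      type = ifelse(act, "activity_only",
                    sample(c("I", "II", "III", "IV"), n_systems, replace = TRUE)),
      kappa = ifelse(act, NA, kappa),
      functional_with_effector = ifelse(act, stats::runif(n_systems) < 0.5, NA),
      stringsAsFactors = FALSE)
    signal_system(entries, omega = omega)
  })
}

#' Generate a random GO annotation
#'
#' @param truth from [generate_trn()] (gene universe)
#' @param n_terms number of terms
#' @param seed integer seed
#' @param max_level deepest level sampled
#' @param size_range term gene-set size range
#' @return `go_annotation`
#' @export
generate_go_annotation <- function(truth, n_terms = 25L, seed = 1L,
                                   max_level = 7L, size_range = c(2L, 30L)) {
  with_seed(split_seed(seed, "go"), {
    rows <- do.call(rbind, lapply(seq_len(n_terms), function(i) {
      size <- sample(seq(size_range[1], size_range[2]), 1L)
      data.frame(term_id = sprintf("T%03d", i),
                 level = sample(seq_len(max_level), 1L),
                 gene_id = sample(truth$genes, min(size, length(truth$genes))),
                 stringsAsFactors = FALSE)
    }))
    go_annotation(rows)
  })
}

#' Generate perturbation scenarios with analytic growth truth
#'
#' Draws a mixture of enzyme knockouts, TF knockouts/over-expressions and
#' graded environmental effector shifts, and computes each scenario's true
#' relative growth by running the cost-benefit pipeline on the ground-truth
#' coefficients, plus Gaussian observation noise.  TF perturbations and
#' effectors prefer TFs with a regulatory path (two hops or fewer) to an
#' enzyme gene, so the scenario set spans the growth range instead of
#' collapsing onto the all-or-nothing extremes -- the design goal of a
#' growth-recovery experiment.
#'
#' @param truth from [generate_trn()]
#' @param met toy model list from [generate_toy_metabolic_model()]
#' @param system `signal_system` (or `NULL` to skip environmental scenarios)
#' @param n number of scenarios
#' @param seed integer seed
#' @param noise_sd observation noise on the true growth
#' @param params pipeline parameters (see [predict_growth()])
#' @return list with `scenarios` (list) and `true_growth` (numeric;
#'   `B_true - c_true + noise`)
#' @export
generate_scenarios <- function(truth, met, system = NULL, n = 50L, seed = 1L,
                               noise_sd = 0.05, params = list()) {
  model_true <- truth_to_model(truth)
  enz <- met$truth$enzymes
  tfs <- truth$tf_set
  ## TFs with a <= 2-hop regulatory path to an enzyme gene
  adj <- truth$beta != 0
  reach1 <- tfs[colSums(adj[enz, , drop = FALSE]) > 0]
  reach2 <- tfs[colSums(adj[intersect(reach1, rownames(adj)), , drop = FALSE]) > 0]
  enz_tfs <- union(reach1, reach2)
  if (length(enz_tfs) == 0L) enz_tfs <- tfs
  expr_entries <- if (!is.null(system)) {
    system$entries[system$entries$type != "activity_only", , drop = FALSE]
  } else NULL
  pref_eff <- if (!is.null(expr_entries)) {
    pe <- expr_entries$effector[expr_entries$tf %in% enz_tfs]
    if (length(pe) > 0L) pe else expr_entries$effector
  } else character(0)
  uptake <- reaction_ids(met$model)[vapply(met$model$reactions, `[[`, TRUE,
                                           "is_exchange")][1]
  cap <- met$truth$uptake_capacity
  with_seed(split_seed(seed, "scenarios"), {
    kinds <- c("ko_enzyme", "ko_tf", "oe_tf", "nutrient", "nutrient",
               if (length(pref_eff) > 0) "env")
    scenarios <- lapply(seq_len(n), function(i) {
      kind <- sample(kinds, 1L)
      switch(kind,
             ko_enzyme = perturbation_scenario(knockouts = sample(enz, 1L)),
             ko_tf = perturbation_scenario(knockouts = sample(enz_tfs, 1L)),
             oe_tf = perturbation_scenario(overexpressions = sample(enz_tfs, 1L)),
             ## nutrient abundance/limitation: vary the uptake capacity
             nutrient = perturbation_scenario(exchange_overrides = data.frame(
               reaction = uptake, lb = 0,
               ub = stats::runif(1, 0.05, 1.2) * cap)),
             env = perturbation_scenario(effectors = data.frame(
               id = sample(pref_eff, 1L),
               delta = stats::runif(1, -4, 4))))
    })
    noise <- stats::rnorm(n, 0, noise_sd)
    true_growth <- vapply(seq_len(n), function(i) {
      gp <- predict_growth(model_true, system, met$model, scenarios[[i]],
                           params = params)
      gp$benefit - gp$cost
    }, 0) + noise
    list(scenarios = scenarios, true_growth = true_growth)
  })
}
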