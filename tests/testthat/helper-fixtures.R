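# Shared fixtures, built in code and cached for the duration of the run.

.fx_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fx_cache[[name]])) .fx_cache[[name]] <- force(expr)
  .fx_cache[[name]]
}

# Noise-free, interior-linear world: exact recovery and a self-consistent
# fitted model (WT fixed point reproduces y_wt exactly).
fx_exact <- function() fixture("exact", {
  gen <- generate_trn(20, 5, mean_out_degree = 4, beta_meanlog = -1.8,
                      beta_sdlog = 0.4, seed = 3)
  tr <- gen$truth
  scen <- c(lapply(tr$tf_set, function(tf) perturbation_scenario(knockouts = tf)),
            lapply(tr$tf_set, function(tf) perturbation_scenario(overexpressions = tf)))
  comp <- simulate_compendium(tr, n_wt = 5, scenarios = scen, noise_sd = 0,
                              seed = 1)
  model <- fit_regulatory_model(gen$network, comp, ridge = 0)
  list(gen = gen, truth = tr, compendium = comp, model = model)
})

# Noisy mid-sized world with metabolism, STS and GO for pipeline tests.
fx_world <- function() fixture("world", {
  gen <- generate_trn(60, 8, seed = 5)
  tr <- gen$truth
  met <- generate_toy_metabolic_model(tr, n_internal = 5, redundancy = 1, seed = 5)
  system <- generate_sts(tr, 5, seed = 5)
  scen <- c(lapply(tr$tf_set, function(tf) perturbation_scenario(knockouts = tf)),
            lapply(tr$tf_set, function(tf) perturbation_scenario(overexpressions = tf)))
  comp <- simulate_compendium(tr, n_wt = 8, scenarios = scen, noise_sd = 0.1,
                              seed = 5, system = system)
  model <- fit_regulatory_model(gen$network, comp, ridge = 0)
  ann <- generate_go_annotation(tr, n_terms = 20, seed = 5)
  list(gen = gen, truth = tr, met = met, system = system,
       compendium = comp, model = model, annotation = ann)
})

# Hand-built diamond network: uptake -> A, A -> B via R2 or R3, biomass B -> .
fx_diamond <- function() fixture("diamond", {
  metabolic_model(
    c("A", "B"),
    list(list(id = "EX_A", stoich = c(A = 1), lb = 0, ub = 10, gpr = "",
              is_exchange = TRUE),
         list(id = "R2", stoich = c(A = -1, B = 1), lb = 0, ub = 10, gpr = "g1",
              is_exchange = FALSE),
         list(id = "R3", stoich = c(A = -1, B = 1), lb = 0, ub = 10, gpr = "g2",
              is_exchange = FALSE),
         list(id = "BIO", stoich = c(B = -1), lb = 0, ub = 1000, gpr = "",
              is_exchange = FALSE)),
    biomass = "BIO")
})

# Minimal regulatory model built by hand (for formula-level tests).
fx_tiny_model <- function(beta_val = 1, y_wt = c(5, 5), bounds = c(0, 10)) {
  beta <- Matrix::sparseMatrix(i = 2L, j = 1L, x = beta_val, dims = c(2L, 1L),
                               dimnames = list(c("TF1", "g2"), "TF1"))
  regulatory_model(genes = c("TF1", "g2"), tf_set = "TF1",
                   beta0 = c(0, 0), beta = beta,
                   y_min = rep(bounds[1], 2), y_max = rep(bounds[2], 2),
                   y_wt = y_wt, sigma_wt = c(0.1, 0.1))
}
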