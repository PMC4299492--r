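## Cost-benefit integration.  The metabolic benefit is the WT-normalized
## FBA growth under TRAME-rescaled bounds; the expression cost is the
## range-normalized mean deviation of the predicted profile from wild type,
## scaled by gamma.  Predicted relative growth is mu = max(0, B - c);
## everything is in WT-relative units so cost and benefit are
## commensurable.

#' Expression-deviation cost
#'
#' `c = gamma * (1/N) * sum_i |y_hat_i - y_wt_i| / (y_max_i - y_min_i)`,
#' skipping genes with zero dynamic range (N decremented accordingly).
#'
#' @param y_hat named predicted expression profile
#' @param reg_model `regulatory_model`
#' @param gamma nonnegative cost scale (default 1)
#' @return nonnegative cost
#' @export
expression_cost <- function(y_hat, reg_model, gamma = 1) {
  stopifnot(gamma >= 0)
  if (gamma == 0) return(0)
  g <- reg_model$genes
  rng <- reg_model$y_max[g] - reg_model$y_min[g]
  keep <- rng > 0
  if (!any(keep)) return(0)
  dev <- abs(y_hat[g][keep] - reg_model$y_wt[g][keep]) / rng[keep]
  gamma * mean(dev)
}

#' Metabolic benefit
#'
#' Ratio of the FBA growth under the supplied (TRAME-rescaled,
#' exchange-overridden) bounds to the wild-type growth in the reference
#' environment.  An infeasible perturbed model yields 0.
#'
#' @param model `metabolic_model`
#' @param bounds `flux_bounds` after TRAME and exchange overrides
#' @param reference_bounds optional `flux_bounds` defining the reference
#'   (wild-type) environment; defaults to the model's own bounds
#' @return nonnegative benefit (WT = 1)
#' @export
metabolic_benefit <- function(model, bounds, reference_bounds = NULL) {
  ref <- fba(model, reference_bounds)
  if (ref$status != "optimal" || !is.finite(ref$growth) || ref$growth <= 0)
    stop_eb("wild-type growth must be positive in the reference environment")
  pert <- fba(model, bounds)
  if (pert$status != "optimal" || !is.finite(pert$growth)) return(0)
  max(0, pert$growth / ref$growth)
}

#' Predict relative growth under a perturbation scenario
#'
#' Pipeline: EBA expression prediction, TRAME bound rescaling of the FVA
#' envelope (knocked-out genes contribute zero enzyme), FBA benefit, and
#' the expression-deviation cost; `mu = max(0, B - c)`.
#'
#' @param reg_model `regulatory_model`
#' @param system `signal_system` or `NULL`
#' @param met_model `metabolic_model`
#' @param scenario `perturbation_scenario`
#' @param params list of tunables: `gamma` (cost scale, default 1),
#'   `trame` (list `n`, `p_cap`), `fva_fraction` (default 0),
#'   `hard_knockout`, `or_mode`
#' @param extra_zero_genes genes outside the regulatory model treated as
#'   deleted enzymes
#' @return `growth_prediction`: `benefit`, `cost`, `mu`, `y_hat`, `fluxes`,
#'   `diagnostics`
#' @export
predict_growth <- function(reg_model, system, met_model, scenario,
                           params = list(), extra_zero_genes = character(0)) {
  gamma <- params$gamma %||% 1
  trame <- params$trame %||% list(n = 2, p_cap = 10)
  fva_fraction <- params$fva_fraction %||% 0
  hard_knockout <- isTRUE(params$hard_knockout)
  or_mode <- params$or_mode %||% "max"

  eba_res <- predict_expression(reg_model, system, scenario,
                                hard_knockout = hard_knockout)

  env_bounds <- override_bounds(model_bounds(met_model),
                                scenario$exchange_overrides)
  envelope <- fva(met_model, env_bounds, biomass_fraction = fva_fraction)
  tb <- trame_bounds(envelope, met_model, eba_res$y_hat, reg_model,
                     params = trame,
                     zero_genes = c(scenario$knockouts, extra_zero_genes),
                     or_mode = or_mode)

  benefit <- metabolic_benefit(met_model, tb)
  cost <- expression_cost(eba_res$y_hat, reg_model, gamma = gamma)
  mu <- max(0, benefit - cost)

  fl <- fba(met_model, tb)
  structure(list(benefit = benefit, cost = cost, mu = mu,
                 y_hat = eba_res$y_hat, fluxes = fl,
                 diagnostics = list(eba_status = eba_res$status,
                                    eba_objective = eba_res$objective,
                                    relaxation = eba_res$relaxation,
                                    fba_status = fl$status,
                                    negative_growth = benefit - cost < 0)),
            class = "growth_prediction")
}

#' @export
print.growth_prediction <- function(x, ...) {
  cat(sprintf("growth_prediction: mu = %.4f (benefit %.4f, cost %.4f)\n",
              x$mu, x$benefit, x$cost))
  invisible(x)
}
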