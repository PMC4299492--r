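## Metabolic layer: FBA/FVA linear programs over the stoichiometric matrix
## and TRAME -- transcription-based flux enrichment -- which rescales the
## FVA flux envelope by enzyme expression relative to wild type, gated by
## the wild-type expression variability.

#' Construct flux bounds
#' @param reaction reaction ids
#' @param vmin,vmax per-reaction bounds (vmin <= vmax)
#' @return `flux_bounds` data.frame
#' @export
flux_bounds <- function(reaction, vmin, vmax) {
  if (any(vmin > vmax + 1e-9)) stop_eb("vmin must not exceed vmax")
  structure(data.frame(reaction = reaction, vmin = as.numeric(vmin),
                       vmax = as.numeric(vmax), stringsAsFactors = FALSE),
            class = c("flux_bounds", "data.frame"))
}

#' The bounds declared in a metabolic model, as `flux_bounds`
#' @param model `metabolic_model`
#' @return `flux_bounds`
#' @export
model_bounds <- function(model) {
  flux_bounds(reaction_ids(model),
              vapply(model$reactions, `[[`, 0, "lb"),
              vapply(model$reactions, `[[`, 0, "ub"))
}

## merge override bounds (a flux_bounds or data.frame subset) into base
override_bounds <- function(base, overrides) {
  if (is.null(overrides) || nrow(overrides) == 0L) return(base)
  lbcol <- if ("vmin" %in% names(overrides)) "vmin" else "lb"
  ubcol <- if ("vmax" %in% names(overrides)) "vmax" else "ub"
  idx <- match(overrides$reaction, base$reaction)
  if (anyNA(idx))
    stop_eb("override for unknown reaction: ",
            paste(overrides$reaction[is.na(idx)], collapse = ", "))
  base$vmin[idx] <- as.numeric(overrides[[lbcol]])
  base$vmax[idx] <- as.numeric(overrides[[ubcol]])
  base
}

#' Flux balance analysis
#'
#' Maximizes the objective reaction's flux subject to steady-state mass
#' balance `S v = 0` and the reaction bounds.  The simplex is deterministic
#' (Bland's rule), so the returned vertex is reproducible; only the
#' objective value is contract-bearing when alternate optima exist.
#'
#' @param model `metabolic_model`
#' @param bounds optional `flux_bounds` overriding the model's bounds
#' @param objective objective reaction id (default: the biomass reaction)
#' @return `flux_state`: `v` (named fluxes), `growth` (objective flux),
#'   `status`
#' @export
fba <- function(model, bounds = NULL, objective = NULL) {
  objective <- objective %||% model$biomass
  ids <- reaction_ids(model)
  if (!(objective %in% ids)) stop_eb("objective reaction '", objective, "' not found")
  b <- if (is.null(bounds)) model_bounds(model) else bounds
  stopifnot(identical(b$reaction, ids))
  S <- as.matrix(met_stoich_matrix(model))
  obj <- as.numeric(ids == objective)
  sol <- lp_solve(obj, S, numeric(nrow(S)), b$vmin, b$vmax, maximize = TRUE)
  if (sol$status != "optimal") {
    return(structure(list(v = stats::setNames(rep(NA_real_, length(ids)), ids),
                          growth = NA_real_, status = "infeasible"),
                     class = "flux_state"))
  }
  v <- stats::setNames(sol$x, ids)
  structure(list(v = v, growth = unname(v[objective]), status = "optimal"),
            class = "flux_state")
}

#' @export
print.flux_state <- function(x, ...) {
  cat(sprintf("flux_state: %s, growth = %s\n", x$status, format(x$growth)))
  invisible(x)
}

#' Flux variability analysis
#'
#' Per-reaction minimum and maximum flux subject to mass balance, the
#' bounds, and (when `biomass_fraction > 0`) biomass at or above that
#' fraction of its optimum.  The default fraction 0 yields the full
#' physical flux envelope, which is what TRAME rescales.
#'
#' @param model `metabolic_model`
#' @param bounds optional `flux_bounds`
#' @param biomass_fraction in \[0, 1\]
#' @return `flux_bounds`
#' @export
fva <- function(model, bounds = NULL, biomass_fraction = 0) {
  stopifnot(biomass_fraction >= 0, biomass_fraction <= 1)
  ids <- reaction_ids(model)
  b <- if (is.null(bounds)) model_bounds(model) else bounds
  if (biomass_fraction > 0) {
    opt <- fba(model, b)
    if (opt$status != "optimal") stop_eb("model infeasible; FVA undefined")
    i <- match(model$biomass, ids)
    b$vmin[i] <- max(b$vmin[i], biomass_fraction * opt$growth)
  }
  S <- as.matrix(met_stoich_matrix(model))
  z <- numeric(nrow(S))
  vmin <- vmax <- numeric(length(ids))
  for (r in seq_along(ids)) {
    obj <- as.numeric(seq_along(ids) == r)
    lo <- lp_solve(obj, S, z, b$vmin, b$vmax, maximize = FALSE)
    hi <- lp_solve(obj, S, z, b$vmin, b$vmax, maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop_eb("FVA infeasible at reaction '", ids[r], "'")
    vmin[r] <- lo$objval; vmax[r] <- hi$objval
  }
  ## numerical guard: LP round-off can invert a degenerate range
  flux_bounds(ids, pmin(vmin, vmax), vmax)
}

#' Evaluate a GPR tree on relative enzyme expression
#'
#' AND (enzyme complex) takes the minimum of its children, OR (isozymes)
#' the maximum (or the sum with `or_mode = "sum"`); a leaf is that gene's
#' expression ratio.  Genes without a ratio default to 1 (wild-type level).
#'
#' @param gpr GPR tree from [parse_gpr()] (`NULL` means no requirement)
#' @param rel_expr named numeric of per-gene relative expression ratios
#' @param or_mode `"max"` (default) or `"sum"`
#' @return nonnegative activity scalar (1 when `gpr` is `NULL`)
#' @export
reaction_activity <- function(gpr, rel_expr, or_mode = c("max", "sum")) {
  or_mode <- match.arg(or_mode)
  if (is.null(gpr)) return(1)
  ev <- function(node) {
    if (node$op == "gene") {
      if (node$gene %in% names(rel_expr)) return(unname(rel_expr[[node$gene]]))
      return(1)
    }
    vals <- vapply(node$args, ev, 0)
    if (node$op == "and") min(vals)
    else if (or_mode == "max") max(vals) else sum(vals)
  }
  ev(gpr)
}

#' TRAME: expression-gated flux bound modulation
#'
#' Per enzyme gene e, the relative expression ratio is 1 when the predicted
#' expression sits within `n` wild-type standard deviations of the
#' wild-type mean (the variability gate), else `2^(y_hat_e - y_wt_e)` (log2
#' difference to fold change).  Per reaction, the GPR activity of these
#' ratios is passed through `P(a) = min(a, p_cap)` and scales the FVA
#' bound magnitudes: `vmax * P` when `vmax > 0`, `vmin * P` when
#' `vmin < 0` (signs preserved).  Reactions without a GPR are unchanged.
#'
#' @param fva_bounds `flux_bounds` from [fva()]
#' @param model `metabolic_model`
#' @param y_hat named predicted expression (log2)
#' @param reg_model `regulatory_model` supplying y_wt and sigma_wt
#' @param params list with `n` (gate width in sd units, default 2) and
#'   `p_cap` (upper cap, default 10)
#' @param zero_genes genes treated as deleted (ratio forced to 0),
#'   e.g. hard knockouts
#' @param or_mode passed to [reaction_activity()]
#' @return `flux_bounds`
#' @export
trame_bounds <- function(fva_bounds, model, y_hat, reg_model,
                         params = list(n = 2, p_cap = 10),
                         zero_genes = character(0), or_mode = "max") {
  n <- params$n %||% 2
  p_cap <- params$p_cap %||% 10
  stopifnot(n >= 0, p_cap >= 1)
  enzyme_genes <- unique(unlist(lapply(model$reactions, function(r)
    gpr_genes(r$gpr_tree))))
  rho <- stats::setNames(rep(1, length(enzyme_genes)), enzyme_genes)
  common <- intersect(enzyme_genes, reg_model$genes)
  common <- intersect(common, names(y_hat))
  d <- y_hat[common] - reg_model$y_wt[common]
  gate <- if (!is.finite(n)) rep(TRUE, length(d))
          else abs(d) <= n * reg_model$sigma_wt[common]
  rho[common] <- ifelse(gate, 1, 2^d)
  rho[intersect(zero_genes, enzyme_genes)] <- 0

  out <- fva_bounds
  for (r in seq_along(model$reactions)) {
    rx <- model$reactions[[r]]
    if (is.null(rx$gpr_tree)) next
    a <- reaction_activity(rx$gpr_tree, rho, or_mode = or_mode)
    P <- min(a, p_cap)
    i <- match(rx$id, out$reaction)
    if (out$vmax[i] > 0) out$vmax[i] <- out$vmax[i] * P
    if (out$vmin[i] < 0) out$vmin[i] <- out$vmin[i] * P
    ## keep the interval well-formed if a positive floor outruns the ceiling
    if (out$vmin[i] > out$vmax[i]) out$vmin[i] <- out$vmax[i]
  }
  out
}

#' In-silico gene essentiality
#'
#' Runs the full expression-to-growth pipeline with a single-gene knockout
#' in the given environment and calls the gene essential when the
#' predicted relative growth falls below `threshold` (default 0.05) of the
#' wild-type growth in the same environment.  Infeasibility propagates as
#' essential.
#'
#' @param met_model `metabolic_model`
#' @param reg_model `regulatory_model`
#' @param system `signal_system` or `NULL`
#' @param gene gene id (must be in the regulatory model or some GPR)
#' @param environment optional data.frame of effector deltas and/or
#'   `exchange_overrides` data.frame (reaction, lb, ub)
#' @param params pipeline parameters, see [predict_growth()]
#' @param threshold relative-growth cutoff
#' @return `"essential"` or `"non_essential"`
#' @export
essentiality <- function(met_model, reg_model, system = NULL, gene,
                         environment = NULL, params = list(),
                         threshold = 0.05) {
  in_gpr <- gene %in% unlist(lapply(met_model$reactions, function(r)
    gpr_genes(r$gpr_tree)))
  if (!(gene %in% reg_model$genes) && !in_gpr)
    stop_eb("gene '", gene, "' absent from regulatory model and every GPR")
  env_eff <- NULL; env_ex <- NULL
  if (!is.null(environment)) {
    env_eff <- environment$effectors %||% NULL
    env_ex <- environment$exchange_overrides %||% NULL
  }
  sc <- perturbation_scenario(
    knockouts = if (gene %in% reg_model$genes) gene else character(0),
    effectors = env_eff, exchange_overrides = env_ex)
  extra_zero <- if (!(gene %in% reg_model$genes)) gene else character(0)
  pred <- predict_growth(reg_model, system, met_model, sc, params = params,
                         extra_zero_genes = extra_zero)
  ## normalize against the unperturbed strain in the same environment
  sc_wt <- perturbation_scenario(effectors = env_eff, exchange_overrides = env_ex)
  wt <- predict_growth(reg_model, system, met_model, sc_wt, params = params)
  if (!is.finite(wt$mu) || wt$mu <= 0)
    stop_eb("wild type does not grow in this environment; essentiality undefined")
  if (!is.finite(pred$benefit) || pred$mu < threshold * wt$mu)
    "essential" else "non_essential"
}
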