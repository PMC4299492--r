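## Assessment protocol: Pearson correlation between predicted and measured
## profiles, globally and over the radius-2 downstream neighborhood of the
## perturbed genes, with significance against an empirical null of random
## compendium profiles.

#' Pearson product-moment correlation
#'
#' Direct implementation with explicit degenerate-input handling: vectors
#' must have equal length >= 3 and nonzero variance, otherwise `NA` is
#' returned with a warning.
#'
#' @param x,y numeric vectors
#' @return correlation in \[-1, 1\], or `NA` when undefined
#' @export
pcc <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L) {
    warning("pcc undefined: need equal length >= 3")
    return(NA_real_)
  }
  xd <- x - mean(x); yd <- y - mean(y)
  sx <- sqrt(sum(xd^2)); sy <- sqrt(sum(yd^2))
  if (sx == 0 || sy == 0) {
    warning("pcc undefined: zero variance")
    return(NA_real_)
  }
  sum(xd * yd) / (sx * sy)
}

#' Evaluate one predicted array against its measurement
#'
#' Computes the global PCC over all shared genes and the local PCC over the
#' radius-2 downstream neighborhood of the perturbed genes (flagged `NA`
#' when that neighborhood has fewer than 3 genes).  Significance: an
#' empirical one-sided p-value against the PCCs of `n_null` compendium
#' columns (drawn uniformly with replacement, excluding `exclude_array`)
#' with the measured profile, with add-one smoothing
#' `p = (1 + #\{null >= observed\}) / (1 + n_null)`.  A local p-value
#' against the same null restricted to the neighborhood is also reported.
#'
#' @param pred named predicted expression profile
#' @param measured named measured profile
#' @param compendium `expression_table` providing the null profiles
#' @param network `network_table` for the neighborhood
#' @param perturbed_genes genes perturbed on this array
#' @param n_null number of null draws (>= 100)
#' @param seed integer seed (fixed seed = bit-reproducible record)
#' @param exclude_array array id excluded from the null draws
#' @return one-row data.frame: pcc_global, pcc_local, p_value,
#'   p_value_local, well_predicted, n_local
#' @export
evaluate_array <- function(pred, measured, compendium, network,
                           perturbed_genes, n_null = 1000L, seed = 1L,
                           exclude_array = NULL) {
  stopifnot(n_null >= 100L)
  genes <- intersect(names(pred), names(measured))
  genes <- intersect(genes, rownames(compendium$values))
  pred <- pred[genes]; measured <- measured[genes]
  pcc_global <- pcc(pred, measured)

  local_genes <- intersect(neighborhood(network, perturbed_genes, 2L), genes)
  pcc_local <- if (length(local_genes) >= 3L) {
    suppressWarnings(pcc(pred[local_genes], measured[local_genes]))
  } else NA_real_

  pool <- setdiff(colnames(compendium$values), exclude_array)
  cols <- with_seed(seed, sample(pool, n_null, replace = TRUE))
  nullmat <- compendium$values[genes, cols, drop = FALSE]
  null_pccs <- suppressWarnings(
    as.numeric(stats::cor(nullmat, measured)))
  p <- (1 + sum(null_pccs >= pcc_global, na.rm = TRUE)) / (1 + n_null)

  p_local <- NA_real_
  if (length(local_genes) >= 3L) {
    null_local <- suppressWarnings(as.numeric(
      stats::cor(nullmat[local_genes, , drop = FALSE], measured[local_genes])))
    p_local <- (1 + sum(null_local >= pcc_local, na.rm = TRUE)) / (1 + n_null)
  }

  data.frame(pcc_global = pcc_global, pcc_local = pcc_local,
             p_value = p, p_value_local = p_local,
             well_predicted = p < 0.05, n_local = length(local_genes))
}

#' Summarize per-array evaluation records
#'
#' TH is the mean global PCC over all records; the report counts arrays
#' strictly above TH (ties fall below) and the well-predicted fraction.
#'
#' @param records data.frame of rows from [evaluate_array()]
#' @return `evaluation_report`: list with `records`, `th`,
#'   `fraction_above_th`, `fraction_well_predicted`
#' @export
summarize_evaluation <- function(records) {
  stopifnot(nrow(records) >= 1L)
  th <- mean(records$pcc_global, na.rm = TRUE)
  structure(list(records = records, th = th,
                 fraction_above_th = mean(records$pcc_global > th, na.rm = TRUE),
                 fraction_well_predicted = mean(records$well_predicted)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation_report: %d arrays, TH = %.3f, %.1f%% above TH, %.1f%% well predicted\n",
              nrow(x$records), x$th, 100 * x$fraction_above_th,
              100 * x$fraction_well_predicted))
  invisible(x)
}
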