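## Linear transcriptional model.  Each gene's log2 expression is modeled as
## a basal coefficient plus a weighted sum of its regulators' (TF)
## expression; only the steady state is used downstream (the perturbation
## response is a static QP, not a time course).

#' Fit the linear transcriptional model from a network and compendium
#'
#' For each gene i with regulator set R_i, solves the ridge-penalized least
#' squares of y_i on the expression of its regulators across training
#' arrays.  Arrays where gene i itself is genetically perturbed are dropped
#' for that gene only (its equation is overridden there).  With
#' `sign_constrained = TRUE` coefficients on `+` edges are constrained
#' nonnegative, `-` edges nonpositive, `+/-` free (solved as a
#' bound-constrained least squares).  Capacity bounds are the per-gene
#' min/max over the compendium; wild-type mean/sd come from the wild-type
#' arrays.
#'
#' @param network `network_table`
#' @param compendium `expression_table`; every network gene must be present
#'   and at least 2 wild-type arrays are required
#' @param ridge nonnegative ridge penalty (a floor of 1e-3 is enforced, with
#'   a warning, for genes with fewer arrays than regressors)
#' @param sign_constrained constrain coefficient signs to the annotated edge
#'   signs
#' @return a `regulatory_model`: genes, tf_set, beta0, sparse beta
#'   (genes x TFs), capacity bounds, WT statistics
#' @export
fit_regulatory_model <- function(network, compendium, ridge = 0,
                                 sign_constrained = FALSE) {
  stopifnot(inherits(compendium, "expression_table"), ridge >= 0)
  Y <- compendium$values
  genes <- rownames(Y)
  net_genes <- union(network$regulator, network$target)
  absent <- setdiff(net_genes, genes)
  if (length(absent) > 0L)
    stop_eb("network gene(s) absent from compendium: ",
            paste(utils::head(absent, 5), collapse = ", "))
  wt <- compendium$meta$class == "wild_type"
  if (sum(wt) < 2L) stop_eb("need >= 2 wild-type arrays for WT statistics")

  tf_set <- sort(unique(network$regulator))
  regulators <- split(seq_len(nrow(network)), network$target)

  beta0 <- stats::setNames(numeric(length(genes)), genes)
  trip <- list(i = integer(0), j = integer(0), x = numeric(0))
  ridge_warned <- character(0)

  ## arrays where a given gene is genetically perturbed (dropped for its fit)
  pert_of <- compendium$meta$perturbed_genes
  genetic <- compendium$meta$class == "genetic"

  for (gi in seq_along(genes)) {
    g <- genes[gi]
    keep <- rep(TRUE, ncol(Y))
    if (any(genetic)) {
      hit <- vapply(seq_len(ncol(Y)), function(a)
        genetic[a] && g %in% pert_of[[a]], logical(1))
      keep <- !hit
    }
    yv <- Y[gi, keep]
    edges <- regulators[[g]]
    if (is.null(edges) || length(edges) == 0L) {
      beta0[gi] <- mean(yv)
      next
    }
    regs <- network$regulator[edges]
    signs <- network$sign[edges]
    X <- t(Y[regs, keep, drop = FALSE])
    p <- length(regs)
    lam <- ridge
    if (length(yv) < p + 1L) {
      lam <- max(lam, 1e-3)
      ridge_warned <- c(ridge_warned, g)
    }
    ## center to keep the intercept unpenalized
    xm <- colMeans(X); ym <- mean(yv)
    Xc <- sweep(X, 2, xm)
    Q <- crossprod(Xc) + diag(lam, p)
    cvec <- -crossprod(Xc, yv - ym)
    if (sign_constrained) {
      lo <- ifelse(signs == "+", 0, ifelse(signs == "-", -Inf, -Inf))
      hi <- ifelse(signs == "+", Inf, ifelse(signs == "-", 0, Inf))
      b <- qp_solve_box(Q, as.numeric(cvec), lo, hi,
                        x0 = numeric(p), tol = 1e-13)$x
    } else {
      b <- tryCatch(as.numeric(solve(Q, -cvec)),
                    error = function(e) {
                      as.numeric(solve(Q + diag(1e-8, p), -cvec))
                    })
    }
    beta0[gi] <- ym - sum(b * xm)
    nz <- which(abs(b) > 0)
    if (length(nz) > 0L) {
      trip$i <- c(trip$i, rep(gi, length(nz)))
      trip$j <- c(trip$j, match(regs[nz], tf_set))
      trip$x <- c(trip$x, b[nz])
    }
  }
  if (length(ridge_warned) > 0L)
    warning("ridge floor 1e-3 enforced for ", length(ridge_warned),
            " gene(s) with fewer arrays than regressors+1")

  beta <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$x,
                               dims = c(length(genes), length(tf_set)),
                               dimnames = list(genes, tf_set))
  regulatory_model(genes = genes, tf_set = tf_set, beta0 = beta0, beta = beta,
                   y_min = apply(Y, 1, min), y_max = apply(Y, 1, max),
                   y_wt = rowMeans(Y[, wt, drop = FALSE]),
                   sigma_wt = apply(Y[, wt, drop = FALSE], 1, stats::sd),
                   ridge = ridge, sign_constrained = sign_constrained)
}

#' Construct/validate a regulatory model
#'
#' @param genes ordered gene ids
#' @param tf_set TF subset of `genes`
#' @param beta0 named basal coefficients (log2 units)
#' @param beta sparse genes x TFs coefficient matrix
#' @param y_min,y_max per-gene capacity bounds
#' @param y_wt,sigma_wt wild-type mean and sd
#' @param ridge,sign_constrained fitting record
#' @return `regulatory_model`
#' @export
regulatory_model <- function(genes, tf_set, beta0, beta, y_min, y_max,
                             y_wt, sigma_wt, ridge = 0, sign_constrained = FALSE) {
  stopifnot(all(tf_set %in% genes),
            identical(dim(beta), c(length(genes), length(tf_set))))
  beta <- methods::as(methods::as(beta, "CsparseMatrix"), "generalMatrix")
  dimnames(beta) <- list(genes, tf_set)
  for (v in c("beta0", "y_min", "y_max", "y_wt", "sigma_wt")) {
    x <- get(v)
    stopifnot(length(x) == length(genes))
  }
  if (any(sigma_wt < 0)) stop_eb("sigma_wt must be nonnegative")
  if (any(y_min > y_wt + 1e-9) || any(y_wt > y_max + 1e-9))
    stop_eb("capacity bounds must satisfy y_min <= y_wt <= y_max")
  nm <- function(x) stats::setNames(as.numeric(x), genes)
  structure(list(genes = genes, tf_set = tf_set, beta0 = nm(beta0),
                 beta = beta, y_min = nm(y_min), y_max = nm(y_max),
                 y_wt = nm(y_wt), sigma_wt = nm(sigma_wt),
                 ridge = ridge, sign_constrained = sign_constrained),
            class = "regulatory_model")
}

#' @export
print.regulatory_model <- function(x, ...) {
  cat(sprintf("regulatory_model: %d genes, %d TFs, %d nonzero coefficients\n",
              length(x$genes), length(x$tf_set), Matrix::nnzero(x$beta)))
  invisible(x)
}

#' Steady-state expression for a given TF profile
#'
#' For each gene i returns `beta0_i + sum_j beta_ij * tf_profile_j`, clamped
#' to the gene's capacity bounds.
#'
#' @param model `regulatory_model`
#' @param tf_profile named numeric covering all TFs in the model
#' @return named per-gene expression vector
#' @export
predict_steady_state <- function(model, tf_profile) {
  missing <- setdiff(model$tf_set, names(tf_profile))
  if (length(missing) > 0L)
    stop_eb("tf_profile missing TF(s): ", paste(missing, collapse = ", "))
  y <- model$beta0 + as.numeric(model$beta %*% tf_profile[model$tf_set])
  stats::setNames(clamp(y, model$y_min, model$y_max), model$genes)
}

#' Downstream regulatory neighborhood
#'
#' Genes reachable from any seed in at most `radius` hops following edge
#' direction (regulator to target); seeds are included.  With
#' `directed = FALSE` edges are followed both ways.
#'
#' @param network `network_table`
#' @param seeds gene ids (seeds absent from the network are kept in the
#'   output with a warning)
#' @param radius nonnegative integer hop limit
#' @param directed follow edge direction only (default)
#' @return character vector of gene ids (sorted)
#' @export
neighborhood <- function(network, seeds, radius = 2L, directed = TRUE) {
  stopifnot(radius >= 0)
  known <- union(network$regulator, network$target)
  lost <- setdiff(seeds, known)
  if (length(lost) > 0L)
    warning("seed(s) not in network: ", paste(lost, collapse = ", "))
  adj <- split(network$target, network$regulator)
  if (!directed) {
    back <- split(network$regulator, network$target)
    for (g in names(back)) adj[[g]] <- c(adj[[g]], back[[g]])
  }
  frontier <- unique(seeds)
  seen <- frontier
  hops <- 0L
  while (hops < radius && length(frontier) > 0L) {
    nxt <- unique(unlist(adj[intersect(frontier, names(adj))], use.names = FALSE))
    frontier <- setdiff(nxt, seen)
    seen <- c(seen, frontier)
    hops <- hops + 1L
  }
  sort(seen)
}

#' Serialize a trained regulatory model to JSON
#' @param model `regulatory_model`
#' @param path output file
#' @export
write_regulatory_model <- function(model, path) {
  tr <- Matrix::summary(model$beta)
  jsonlite::write_json(list(
    genes = model$genes, tf_set = model$tf_set,
    beta0 = unname(model$beta0),
    beta = list(gene = model$genes[tr$i], tf = model$tf_set[tr$j], value = tr$x),
    y_min = unname(model$y_min), y_max = unname(model$y_max),
    y_wt = unname(model$y_wt), sigma_wt = unname(model$sigma_wt),
    ridge = model$ridge, sign_constrained = model$sign_constrained
  ), path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a serialized regulatory model
#' @param path JSON file written by [write_regulatory_model()]
#' @return `regulatory_model`
#' @export
read_regulatory_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  genes <- j$genes; tfs <- j$tf_set
  if (length(j$beta$gene) > 0L) {
    beta <- Matrix::sparseMatrix(i = match(j$beta$gene, genes),
                                 j = match(j$beta$tf, tfs),
                                 x = j$beta$value,
                                 dims = c(length(genes), length(tfs)),
                                 dimnames = list(genes, tfs))
  } else {
    beta <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                 dims = c(length(genes), length(tfs)),
                                 dimnames = list(genes, tfs))
  }
  regulatory_model(genes, tfs, j$beta0, beta, j$y_min, j$y_max, j$y_wt,
                   j$sigma_wt, ridge = j$ridge,
                   sign_constrained = j$sign_constrained)
}
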