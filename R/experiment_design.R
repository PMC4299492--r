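## Experiment design: a greedy knockout ranking that maximizes marginal
## GO-term coverage, breaking ties by the expected expression variability
## of the candidate's downstream neighborhood.  Coverage of a monotone set
## function by greedy selection carries the classic (1 - 1/e) guarantee.

#' Filter GO terms eligible for coverage accounting
#'
#' Terms at hierarchy level `max_level` or shallower whose annotated gene
#' set size lies in `[size_min, size_max]`.
#'
#' @param annotation `go_annotation`
#' @param max_level deepest eligible level (default 5)
#' @param size_min,size_max gene-set size window (defaults 3 and 500)
#' @return character vector of eligible term ids
#' @export
eligible_terms <- function(annotation, max_level = 5L, size_min = 3L,
                           size_max = 500L) {
  stopifnot(size_min >= 1L)
  keep <- vapply(annotation$terms, function(t) {
    t$level <= max_level && length(t$genes) >= size_min &&
      length(t$genes) <= size_max
  }, logical(1))
  names(annotation$terms)[keep]
}

#' GO terms covered by a perturbed gene set
#'
#' A term is covered when at least `k` of its annotated genes are in the
#' perturbed set.
#'
#' @param annotation `go_annotation`
#' @param terms term ids to consider (e.g. from [eligible_terms()])
#' @param perturbed gene ids
#' @param k minimum perturbed genes per term (default 1)
#' @return character vector of covered term ids
#' @export
go_coverage <- function(annotation, terms, perturbed, k = 1L) {
  stopifnot(k >= 1L)
  hit <- vapply(terms, function(tid) {
    sum(annotation$terms[[tid]]$genes %in% perturbed) >= k
  }, logical(1))
  terms[hit]
}

#' Expected expression variability of a candidate knockout
#'
#' Mean, over the gene's radius-2 downstream neighborhood (the gene itself
#' excluded), of each neighbor's expression variance across the compendium
#' arrays; a gene with no downstream neighbors falls back to its own
#' variance.  The compendium can be restricted to an array class
#' (`"genetic"`, `"environmental"`) to obtain the class-specific variants.
#'
#' @param gene candidate gene id (must be in the network)
#' @param network `network_table`
#' @param compendium `expression_table`
#' @param array_class optional class filter
#' @return nonnegative score
#' @export
variability_score <- function(gene, network, compendium, array_class = NULL) {
  if (!(gene %in% union(network$regulator, network$target)))
    stop_eb("gene '", gene, "' not in network")
  Y <- compendium$values
  if (!is.null(array_class)) {
    Y <- Y[, compendium$meta$class %in% array_class, drop = FALSE]
    if (ncol(Y) < 2L) stop_eb("fewer than 2 arrays in class ", array_class)
  }
  vr <- function(g) stats::var(Y[g, ])
  nb <- setdiff(neighborhood(network, gene, 2L), gene)
  nb <- intersect(nb, rownames(Y))
  if (length(nb) == 0L) {
    if (!(gene %in% rownames(Y))) return(0)
    return(vr(gene))
  }
  mean(vapply(nb, vr, 0))
}

#' Greedy knockout design for GO-term coverage
#'
#' Iteratively selects the candidate with the largest number of newly
#' covered eligible terms; ties are broken by higher variability score,
#' then lexicographic gene id.  Once no candidate covers anything new, the
#' remaining budget is filled in variability order.
#'
#' @param annotation `go_annotation`
#' @param network `network_table`
#' @param compendium `expression_table`
#' @param current_perturbed genes already perturbed (terms they cover are
#'   not counted as new)
#' @param candidates candidate genes, disjoint from `current_perturbed`
#' @param budget maximum number of picks
#' @param k coverage multiplicity, see [go_coverage()]
#' @param max_level,size_min,size_max eligibility filter
#' @param array_class variability-score compendium filter
#' @return `design_result` data.frame: gene, new_terms, cumulative,
#'   variability
#' @export
greedy_design <- function(annotation, network, compendium,
                          current_perturbed = character(0), candidates,
                          budget, k = 1L, max_level = 5L, size_min = 3L,
                          size_max = 500L, array_class = NULL) {
  stopifnot(budget >= 1L)
  if (length(intersect(candidates, current_perturbed)) > 0L)
    stop_eb("candidates must be disjoint from current_perturbed")
  terms <- eligible_terms(annotation, max_level, size_min, size_max)
  covered <- go_coverage(annotation, terms, current_perturbed, k)
  vscore <- vapply(candidates, function(g) {
    tryCatch(variability_score(g, network, compendium, array_class),
             ebaflux_error = function(e) 0)
  }, 0)

  picked <- character(0); new_counts <- integer(0)
  pool <- sort(candidates)
  perturbed <- current_perturbed
  while (length(picked) < budget && length(pool) > 0L) {
    gains <- vapply(pool, function(g) {
      length(setdiff(go_coverage(annotation, terms, c(perturbed, g), k), covered))
    }, 0L)
    if (max(gains) > 0L) {
      best <- pool[gains == max(gains)]
      best <- best[order(-vscore[best], best)][1]
    } else {
      ## nothing new anywhere: fall back to variability order for the rest
      best <- pool[order(-vscore[pool], pool)][1]
    }
    picked <- c(picked, best)
    new_counts <- c(new_counts, unname(gains[best]))
    perturbed <- c(perturbed, best)
    covered <- union(covered, go_coverage(annotation, terms, perturbed, k))
    pool <- setdiff(pool, best)
  }
  structure(data.frame(gene = picked, new_terms = new_counts,
                       cumulative = cumsum(new_counts),
                       variability = unname(vscore[picked]),
                       stringsAsFactors = FALSE),
            class = c("design_result", "data.frame"))
}
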