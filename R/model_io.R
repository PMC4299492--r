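## On-disk formats.  Everything is plain text so fixtures stay diff-able:
## tab-separated tables for networks, expression, signal-transduction and GO
## annotation; a small documented JSON dialect for metabolic models (with a
## minimal SBML-L3/fbc reader as a secondary entry point); JSON for trained
## regulatory models and perturbation scenarios.

EVIDENCE_TIERS <- c(confirmed = 1L, strong = 2L, weak = 3L, inferred = 4L)
SIGN_TOKENS <- c("+", "-", "+/-")

#' Read a signed transcriptional regulatory network
#'
#' The file is tab-separated with columns (regulator, target, sign, evidence);
#' a header row is detected and skipped.  `sign` must be one of `+`, `-`,
#' `+/-`; `evidence` one of `confirmed`, `strong`, `weak`, `inferred`
#' (ordered confirmed > strong > weak > inferred).  Rows below `min_evidence`
#' are dropped, then duplicate (regulator, target) pairs are merged: the
#' highest evidence tier is kept and conflicting signs collapse to `+/-`.
#'
#' @param path network TSV file
#' @param min_evidence minimum evidence tier to retain
#' @return a `network_table` data.frame (regulator, target, sign, evidence)
#' @export
read_network <- function(path, min_evidence = c("inferred", "weak", "strong", "confirmed")) {
  min_evidence <- match.arg(min_evidence)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    warning("empty network file: ", path)
    return(network_table(data.frame(regulator = character(), target = character(),
                                    sign = character(), evidence = character())))
  }
  first <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  has_header <- length(first) >= 4 &&
    (tolower(first[3]) == "sign" || tolower(first[4]) == "evidence")
  start <- if (has_header) 2L else 1L
  rows <- vector("list", length(lines))
  for (i in seq_len(length(lines) - start + 1L) + start - 1L) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 4L) stop_eb("network line ", i, ": expected 4 tab-separated fields")
    if (!nzchar(f[1]) || !nzchar(f[2]))
      stop_eb("network line ", i, ": empty regulator/target id")
    if (!(f[3] %in% SIGN_TOKENS))
      stop_eb("network line ", i, ": invalid sign token '", f[3],
              "' (expected one of +, -, +/-)")
    if (!(f[4] %in% names(EVIDENCE_TIERS)))
      stop_eb("network line ", i, ": invalid evidence tier '", f[4], "'")
    rows[[i]] <- f[1:4]
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(df) <- c("regulator", "target", "sign", "evidence")
  df <- df[EVIDENCE_TIERS[df$evidence] <= EVIDENCE_TIERS[min_evidence], , drop = FALSE]
  if (nrow(df) == 0L) warning("no interactions at or above tier '", min_evidence, "'")
  network_table(df)
}

#' Construct/validate a network table
#'
#' Merges duplicate (regulator, target) pairs: best evidence tier wins,
#' conflicting signs become `+/-`.
#'
#' @param df data.frame with columns regulator, target, sign, evidence
#' @return `network_table`
#' @export
network_table <- function(df) {
  stopifnot(all(c("regulator", "target", "sign", "evidence") %in% names(df)))
  if (nrow(df) > 0L) {
    if (any(!df$sign %in% SIGN_TOKENS)) stop_eb("invalid sign token in network table")
    key <- paste(df$regulator, df$target, sep = "\r")
    if (anyDuplicated(key)) {
      merged <- lapply(split(seq_len(nrow(df)), key), function(idx) {
        sub <- df[idx, , drop = FALSE]
        sign <- if (length(unique(sub$sign)) > 1L) "+/-" else sub$sign[1]
        ev <- names(EVIDENCE_TIERS)[min(EVIDENCE_TIERS[sub$evidence])]
        data.frame(regulator = sub$regulator[1], target = sub$target[1],
                   sign = sign, evidence = ev, stringsAsFactors = FALSE)
      })
      df <- do.call(rbind, merged)
      df <- df[order(df$regulator, df$target), , drop = FALSE]
    }
  }
  rownames(df) <- NULL
  class(df) <- c("network_table", "data.frame")
  df
}

#' Write a network table as TSV
#' @param network `network_table`
#' @param path output file
#' @export
write_network <- function(network, path) {
  utils::write.table(as.data.frame(network)[, c("regulator", "target", "sign", "evidence")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

ARRAY_CLASSES <- c("wild_type", "genetic", "environmental")
PERT_KINDS <- c("none", "knockout", "overexpression", "rewiring")

#' Read an expression compendium (matrix + array metadata)
#'
#' The matrix file is tab-separated: first column gene ids, header row array
#' ids, cells log2 expression.  The metadata file has columns
#' (array_id, class, perturbation_kind, perturbed_genes, effectors) where
#' `perturbed_genes` is comma-separated (may be empty) and `effectors` is a
#' `;`-separated list of `id:delta` pairs.  Arrays absent from the metadata
#' default to wild type with a warning.
#'
#' @param path expression matrix TSV
#' @param meta_path array metadata TSV
#' @return an `expression_table`
#' @export
read_expression <- function(path, meta_path) {
  raw <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "")
  gene_ids <- raw[[1]]
  if (anyDuplicated(gene_ids))
    stop_eb("duplicate gene id in expression matrix: ",
            gene_ids[duplicated(gene_ids)][1])
  vals <- as.matrix(raw[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(!is.finite(num), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop_eb("non-numeric/non-finite expression value at gene '",
            gene_ids[bad[1, 1]], "', array '", colnames(vals)[bad[1, 2]], "'")
  dimnames(num) <- list(gene_ids, colnames(vals))

  meta_raw <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                                colClasses = "character", quote = "")
  meta <- empty_array_meta(colnames(num))
  idx <- match(colnames(num), meta_raw$array_id)
  missing <- colnames(num)[is.na(idx)]
  if (length(missing) > 0L)
    warning("arrays missing from metadata, defaulting to wild_type: ",
            paste(missing, collapse = ", "))
  for (j in which(!is.na(idx))) {
    r <- meta_raw[idx[j], ]
    if (!(r$class %in% ARRAY_CLASSES)) stop_eb("invalid array class '", r$class, "'")
    meta$class[j] <- r$class
    meta$perturbation_kind[j] <- r$perturbation_kind %||% "none"
    meta$perturbed_genes[[j]] <- parse_gene_list(r$perturbed_genes)
    meta$effectors[[j]] <- parse_effector_list(r$effectors)
  }
  expression_table(num, meta)
}

empty_array_meta <- function(array_ids) {
  n <- length(array_ids)
  data.frame(array_id = array_ids,
             class = rep("wild_type", n),
             perturbation_kind = rep("none", n),
             perturbed_genes = I(replicate(n, character(0), simplify = FALSE)),
             effectors = I(replicate(n, empty_effectors(), simplify = FALSE)),
             stringsAsFactors = FALSE)
}

empty_effectors <- function() data.frame(id = character(), delta = numeric())

parse_gene_list <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(character(0))
  trimws(strsplit(s, ",", fixed = TRUE)[[1]])
}

parse_effector_list <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(empty_effectors())
  parts <- strsplit(trimws(strsplit(s, ";", fixed = TRUE)[[1]]), ":", fixed = TRUE)
  data.frame(id = vapply(parts, `[`, "", 1),
             delta = as.numeric(vapply(parts, `[`, "", 2)),
             stringsAsFactors = FALSE)
}

#' Construct an expression table from a matrix and metadata
#' @param values numeric matrix, genes x arrays, dimnames set
#' @param meta data.frame as produced by [empty_array_meta()]; `NULL` means
#'   all wild type
#' @return `expression_table`
#' @export
expression_table <- function(values, meta = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)), !is.null(colnames(values)))
  if (any(!is.finite(values))) stop_eb("expression values must be finite")
  if (is.null(meta)) meta <- empty_array_meta(colnames(values))
  stopifnot(identical(meta$array_id, colnames(values)))
  for (pg in meta$perturbed_genes) {
    if (length(pg) > 0L && !all(pg %in% rownames(values)))
      stop_eb("perturbed gene(s) absent from gene ids: ",
              paste(setdiff(pg, rownames(values)), collapse = ", "))
  }
  structure(list(values = values, meta = meta), class = "expression_table")
}

#' @export
print.expression_table <- function(x, ...) {
  cat(sprintf("expression_table: %d genes x %d arrays (%d wild_type, %d genetic, %d environmental)\n",
              nrow(x$values), ncol(x$values),
              sum(x$meta$class == "wild_type"), sum(x$meta$class == "genetic"),
              sum(x$meta$class == "environmental")))
  invisible(x)
}

#' Write an expression table (matrix + metadata TSVs)
#' @param x `expression_table`
#' @param path matrix file
#' @param meta_path metadata file
#' @export
write_expression <- function(x, path, meta_path) {
  df <- data.frame(gene_id = rownames(x$values), x$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  enc_eff <- vapply(x$meta$effectors, function(e) {
    if (nrow(e) == 0L) "" else paste(sprintf("%s:%.10g", e$id, e$delta), collapse = ";")
  }, "")
  meta <- data.frame(array_id = x$meta$array_id, class = x$meta$class,
                     perturbation_kind = x$meta$perturbation_kind,
                     perturbed_genes = vapply(x$meta$perturbed_genes, paste,
                                              "", collapse = ","),
                     effectors = enc_eff, stringsAsFactors = FALSE)
  utils::write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## ---- gene-protein-reaction rules ----------------------------------------

#' Parse a gene-protein-reaction rule into an expression tree
#'
#' Grammar: `expr := term ('or' term)*; term := factor ('and' factor)*;
#' factor := gene | '(' expr ')'`.  `and`/`or` are case-insensitive.  The
#' tree is nested lists with `op` in `"and"`, `"or"`, `"gene"`.
#'
#' @param s rule string; empty/NA yields `NULL` (no gene requirement)
#' @return expression tree or `NULL`
#' @export
parse_gpr <- function(s) {
  if (is.null(s) || is.na(s) || !nzchar(trimws(s))) return(NULL)
  toks <- regmatches(s, gregexpr("\\(|\\)|[^()[:space:]]+", s))[[1]]
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[[pos]] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  parse_expr <- function() {
    args <- list(parse_term())
    while (!is.na(peek()) && tolower(peek()) == "or") {
      take(); args[[length(args) + 1L]] <- parse_term()
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }
  parse_term <- function() {
    args <- list(parse_factor())
    while (!is.na(peek()) && tolower(peek()) == "and") {
      take(); args[[length(args) + 1L]] <- parse_factor()
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_factor <- function() {
    t <- take()
    if (is.na(t)) stop_eb("GPR parse error in '", s, "': unexpected end")
    if (t == "(") {
      e <- parse_expr()
      if (!identical(take(), ")")) stop_eb("GPR parse error in '", s, "': missing ')'")
      return(e)
    }
    if (t == ")" || tolower(t) %in% c("and", "or"))
      stop_eb("GPR parse error in '", s, "': unexpected token '", t, "'")
    list(op = "gene", gene = t)
  }
  tree <- parse_expr()
  if (!is.na(peek())) stop_eb("GPR parse error in '", s, "': trailing tokens")
  tree
}

#' Genes referenced by a GPR tree
#' @param tree from [parse_gpr()]
#' @return character vector (empty for `NULL`)
#' @export
gpr_genes <- function(tree) {
  if (is.null(tree)) return(character(0))
  if (tree$op == "gene") return(tree$gene)
  unique(unlist(lapply(tree$args, gpr_genes)))
}

## ---- metabolic models ----------------------------------------------------

#' Construct/validate a metabolic model
#'
#' @param metabolites character vector of metabolite ids
#' @param reactions list of records: `list(id, stoich = named numeric,
#'   lb, ub, gpr = string, is_exchange = logical)`
#' @param biomass id of the biomass/objective reaction
#' @return `metabolic_model` with parsed GPR trees attached
#' @export
metabolic_model <- function(metabolites, reactions, biomass) {
  ids <- vapply(reactions, `[[`, "", "id")
  if (anyDuplicated(ids)) stop_eb("duplicate reaction id")
  if (!(biomass %in% ids)) stop_eb("biomass reaction '", biomass, "' not found")
  reactions <- lapply(reactions, function(r) {
    r$lb <- as.numeric(r$lb); r$ub <- as.numeric(r$ub)
    if (r$lb > r$ub) stop_eb("reaction '", r$id, "': lower bound ", r$lb,
                             " exceeds upper bound ", r$ub)
    unknown <- setdiff(names(r$stoich), metabolites)
    if (length(unknown) > 0L)
      stop_eb("reaction '", r$id, "': undeclared metabolite(s) ",
              paste(unknown, collapse = ", "))
    r$gpr <- r$gpr %||% ""
    if (is.na(r$gpr)) r$gpr <- ""
    r$gpr_tree <- tryCatch(parse_gpr(r$gpr), error = function(e)
      stop_eb("reaction '", r$id, "': ", conditionMessage(e)))
    r$is_exchange <- isTRUE(r$is_exchange)
    r
  })
  structure(list(metabolites = metabolites, reactions = reactions,
                 biomass = biomass), class = "metabolic_model")
}

#' @export
print.metabolic_model <- function(x, ...) {
  cat(sprintf("metabolic_model: %d metabolites, %d reactions, biomass = '%s'\n",
              length(x$metabolites), length(x$reactions), x$biomass))
  invisible(x)
}

#' Reaction ids of a metabolic model, in declaration order
#' @param model `metabolic_model`
#' @return character vector
#' @export
reaction_ids <- function(model) vapply(model$reactions, `[[`, "", "id")

## sparse stoichiometric matrix (metabolites x reactions)
met_stoich_matrix <- function(model) {
  ids <- reaction_ids(model)
  i <- integer(0); j <- integer(0); v <- numeric(0)
  for (r in seq_along(model$reactions)) {
    st <- model$reactions[[r]]$stoich
    if (length(st) == 0L) next
    i <- c(i, match(names(st), model$metabolites))
    j <- c(j, rep(r, length(st)))
    v <- c(v, as.numeric(st))
  }
  Matrix::sparseMatrix(i = i, j = j, x = v,
                       dims = c(length(model$metabolites), length(ids)),
                       dimnames = list(model$metabolites, ids))
}

#' Read a metabolic model from the JSON dialect
#'
#' Dialect: `{"metabolites": [...], "reactions": [{"id":, "stoich": {met:
#' coef}, "lb":, "ub":, "gpr":, "is_exchange":}], "biomass": "..."}`.
#'
#' @param path JSON file
#' @return `metabolic_model`
#' @export
read_metabolic_model <- function(path) {
  j <- jsonlite::read_json(path)
  reactions <- lapply(j$reactions, function(r) {
    list(id = r$id, stoich = unlist(r$stoich) %||% stats::setNames(numeric(0), character(0)),
         lb = r$lb, ub = r$ub, gpr = r$gpr %||% "",
         is_exchange = isTRUE(r$is_exchange))
  })
  metabolic_model(unlist(j$metabolites) %||% character(0), reactions, j$biomass)
}

#' Write a metabolic model to the JSON dialect
#' @param model `metabolic_model`
#' @param path output file
#' @export
write_metabolic_model <- function(model, path) {
  reactions <- lapply(model$reactions, function(r) {
    list(id = r$id, stoich = as.list(r$stoich), lb = r$lb, ub = r$ub,
         gpr = r$gpr, is_exchange = r$is_exchange)
  })
  jsonlite::write_json(list(metabolites = model$metabolites,
                            reactions = reactions, biomass = model$biomass),
                       path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a metabolic model from a minimal SBML-L3 (fbc) file
#'
#' Secondary entry point; supports listOfSpecies, listOfReactions with
#' speciesReference stoichiometries, fbc flux-bound parameters and fbc
#' geneProductAssociation (and/or/geneProductRef).  The biomass reaction is
#' taken from the active fbc objective.
#'
#' @param path SBML file
#' @return `metabolic_model`
#' @export
read_sbml_model <- function(path) {
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  mets <- xml2::xml_attr(xml2::xml_find_all(doc, ".//listOfSpecies/species"), "id")
  pars <- xml2::xml_find_all(doc, ".//listOfParameters/parameter")
  pval <- stats::setNames(as.numeric(xml2::xml_attr(pars, "value")),
                          xml2::xml_attr(pars, "id"))
  gp <- xml2::xml_find_all(doc, ".//listOfGeneProducts/geneProduct")
  glab <- stats::setNames(xml2::xml_attr(gp, "label"), xml2::xml_attr(gp, "id"))

  gpa_to_string <- function(node) {
    nm <- xml2::xml_name(node)
    if (nm == "geneProductRef") {
      ref <- xml2::xml_attr(node, "geneProduct")
      return(if (ref %in% names(glab)) unname(glab[[ref]]) else ref)
    }
    kids <- xml2::xml_children(node)
    parts <- vapply(kids, gpa_to_string, "")
    paste0("(", paste(parts, collapse = paste0(" ", nm, " ")), ")")
  }

  rx_nodes <- xml2::xml_find_all(doc, ".//listOfReactions/reaction")
  reactions <- lapply(rx_nodes, function(rn) {
    id <- xml2::xml_attr(rn, "id")
    st <- numeric(0)
    for (sr in xml2::xml_find_all(rn, "./listOfReactants/speciesReference")) {
      st[xml2::xml_attr(sr, "species")] <- -as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
    }
    for (sr in xml2::xml_find_all(rn, "./listOfProducts/speciesReference")) {
      st[xml2::xml_attr(sr, "species")] <- as.numeric(xml2::xml_attr(sr, "stoichiometry") %||% "1")
    }
    lbid <- xml2::xml_attr(rn, "lowerFluxBound")
    ubid <- xml2::xml_attr(rn, "upperFluxBound")
    gpa <- xml2::xml_find_first(rn, "./geneProductAssociation")
    gpr <- if (inherits(gpa, "xml_missing")) "" else {
      kids <- xml2::xml_children(gpa)
      if (length(kids) == 0L) "" else gpa_to_string(kids[[1]])
    }
    list(id = id, stoich = st,
         lb = if (is.na(lbid)) -LP_BIG else pval[[lbid]],
         ub = if (is.na(ubid)) LP_BIG else pval[[ubid]],
         gpr = gpr, is_exchange = grepl("^EX_", id))
  })
  obj <- xml2::xml_find_first(doc, ".//listOfObjectives/objective/listOfFluxObjectives/fluxObjective")
  biomass <- xml2::xml_attr(obj, "reaction")
  metabolic_model(mets, reactions, biomass)
}

## ---- GO annotation -------------------------------------------------------

#' Read a GO annotation table
#'
#' TSV with columns (term_id, level, gene_id), one gene per row; levels are
#' an input column (no ontology parsing).
#'
#' @param path annotation TSV
#' @return `go_annotation`: list with `terms` (list of
#'   `list(term_id, level, genes)`) and `universe`
#' @export
read_go_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = c("character", "integer", "character"),
                          quote = "")
  go_annotation(df)
}

#' Construct a GO annotation from a long-format data.frame
#' @param df data.frame with columns term_id, level, gene_id
#' @return `go_annotation`
#' @export
go_annotation <- function(df) {
  stopifnot(all(c("term_id", "level", "gene_id") %in% names(df)))
  if (any(df$level < 1L)) stop_eb("GO levels must be >= 1")
  terms <- lapply(split(df, df$term_id), function(sub) {
    list(term_id = sub$term_id[1], level = sub$level[1],
         genes = sort(unique(sub$gene_id)))
  })
  terms <- terms[order(names(terms))]
  structure(list(terms = terms, universe = sort(unique(df$gene_id))),
            class = "go_annotation")
}

#' Write a GO annotation as TSV
#' @param annotation `go_annotation`
#' @param path output file
#' @export
write_go_annotation <- function(annotation, path) {
  rows <- do.call(rbind, lapply(annotation$terms, function(t) {
    data.frame(term_id = t$term_id, level = t$level, gene_id = t$genes,
               stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a file against one of the package formats
#'
#' @param path file to check
#' @param format one of `network`, `expression`, `metabolic`, `sts`, `go`
#' @param meta_path metadata file (expression only)
#' @return TRUE invisibly on success; errors otherwise
#' @export
validate_file <- function(path, format = c("network", "expression", "metabolic",
                                           "sts", "go"), meta_path = NULL) {
  format <- match.arg(format)
  switch(format,
         network = read_network(path),
         expression = read_expression(path, meta_path),
         metabolic = if (grepl("\\.xml$|\\.sbml$", path)) read_sbml_model(path)
                     else read_metabolic_model(path),
         sts = read_sts(path),
         go = read_go_annotation(path))
  invisible(TRUE)
}
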