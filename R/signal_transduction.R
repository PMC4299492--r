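## Signal-transduction systems: an effector either shifts a TF's expression
## linearly (kappa, scaled by the global omega) or abolishes its activity
## (binary functionality).  Mechanistic subtypes I-III collapse to the
## sign/strength of kappa; only the expression-vs-activity distinction
## changes the math.

STS_TYPES <- c("I", "II", "III", "IV", "activity_only")

#' Construct a signal-transduction system
#'
#' @param entries data.frame with columns `tf`, `effector`, `type` (I-IV or
#'   `activity_only`), `kappa` (log2 expression per unit effector change; NA
#'   for activity entries), `functional_with_effector` (logical; NA for
#'   expression entries)
#' @param omega global positive scale applied to every kappa
#' @return `signal_system`
#' @export
signal_system <- function(entries, omega = 1) {
  stopifnot(is.data.frame(entries), omega > 0)
  need <- c("tf", "effector", "type", "kappa", "functional_with_effector")
  for (col in setdiff(need, names(entries))) entries[[col]] <- NA
  if (any(!entries$type %in% STS_TYPES)) stop_eb("invalid STS type")
  key <- paste(entries$tf, entries$effector)
  if (anyDuplicated(key)) stop_eb("duplicate (tf, effector) entry")
  expr <- entries$type != "activity_only"
  if (any(expr & !is.finite(entries$kappa)))
    stop_eb("expression-type entries need finite kappa")
  if (any(!expr & is.na(entries$functional_with_effector)))
    stop_eb("activity_only entries need functional_with_effector")
  rownames(entries) <- NULL
  structure(list(entries = entries[, need], omega = omega),
            class = "signal_system")
}

#' @export
print.signal_system <- function(x, ...) {
  cat(sprintf("signal_system: %d entries (%d expression-type, %d activity-only), omega = %g\n",
              nrow(x$entries), sum(x$entries$type != "activity_only"),
              sum(x$entries$type == "activity_only"), x$omega))
  invisible(x)
}

#' Read a signal-transduction table
#'
#' TSV columns: (tf, effector, type, kappa_or_brule).  For types I-IV the
#' fourth column is numeric kappa; for `activity_only` it is `true`/`false`
#' (functional with the effector present).
#'
#' @param path STS TSV
#' @param omega global scale
#' @return `signal_system`
#' @export
read_sts <- function(path, omega = 1) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  act <- df$type == "activity_only"
  entries <- data.frame(tf = df$tf, effector = df$effector, type = df$type,
                        kappa = ifelse(act, NA, suppressWarnings(as.numeric(df$kappa_or_brule))),
                        functional_with_effector = ifelse(act, tolower(df$kappa_or_brule) == "true", NA),
                        stringsAsFactors = FALSE)
  signal_system(entries, omega = omega)
}

#' Write a signal-transduction table as TSV
#' @param system `signal_system`
#' @param path output file
#' @export
write_sts <- function(system, path) {
  e <- system$entries
  act <- e$type == "activity_only"
  out <- data.frame(tf = e$tf, effector = e$effector, type = e$type,
                    kappa_or_brule = ifelse(act,
                                            tolower(as.character(e$functional_with_effector)),
                                            sprintf("%.10g", e$kappa)),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

sts_entry <- function(system, tf, effector) {
  hit <- system$entries$tf == tf & system$entries$effector == effector
  if (!any(hit)) return(NULL)
  system$entries[which(hit)[1], ]
}

#' TF expression under an effector concentration change
#'
#' For an expression-type system, the TF expression is fixed at
#' `clamp(y_wt + omega * kappa * delta_n, y_min, y_max)` where `delta_n` is
#' the effector concentration difference from the reference (wild-type)
#' level.
#'
#' @param system `signal_system`
#' @param model `regulatory_model` supplying y_wt and capacity bounds
#' @param tf TF gene id
#' @param effector effector id
#' @param delta_n effector concentration change (dimensionless)
#' @return the fixed expression value
#' @export
tf_expression_constraint <- function(system, model, tf, effector, delta_n) {
  e <- sts_entry(system, tf, effector)
  if (is.null(e))
    stop_eb("unknown effector '", effector, "' for TF '", tf, "'")
  if (e$type == "activity_only")
    stop_eb("(", tf, ", ", effector, ") is an activity-only system; ",
            "use tf_functionality()")
  if (!(tf %in% model$genes)) stop_eb("TF '", tf, "' not in model")
  unname(clamp(model$y_wt[[tf]] + system$omega * e$kappa * delta_n,
               model$y_min[[tf]], model$y_max[[tf]]))
}

#' Binary TF functionality under effector presence/absence
#'
#' For activity-only systems: returns 1 if the TF is functional in the
#' stated condition, else 0.  A 0 means the EBA layer zeroes the TF's
#' regulatory column.
#'
#' @param system `signal_system`
#' @param tf TF gene id
#' @param effector effector id
#' @param effector_present logical
#' @return 0 or 1
#' @export
tf_functionality <- function(system, tf, effector, effector_present) {
  e <- sts_entry(system, tf, effector)
  if (is.null(e)) stop_eb("unknown effector '", effector, "' for TF '", tf, "'")
  if (e$type != "activity_only")
    stop_eb("(", tf, ", ", effector, ") is an expression-type system; ",
            "use tf_expression_constraint()")
  functional <- if (effector_present) e$functional_with_effector else !e$functional_with_effector
  as.integer(functional)
}

#' Translate an environment into TF-level constraints
#'
#' Expression-type hits accumulate additively (`sum of omega*kappa*delta`)
#' per TF before a single clamp to the capacity bounds; activity-only hits
#' with the effector present (`delta > 0`) or removed (`delta <= 0`) toggle
#' functionality.
#'
#' @param system `signal_system`
#' @param model `regulatory_model`
#' @param environment data.frame with columns `id` (effector) and `delta`
#' @return list with `fixed` (named numeric of fixed TF expressions) and
#'   `inactive` (character vector of non-functional TFs)
#' @export
environment_to_constraints <- function(system, model, environment) {
  fixed <- numeric(0)
  inactive <- character(0)
  if (is.null(environment) || nrow(environment) == 0L)
    return(list(fixed = fixed, inactive = inactive))
  known <- unique(system$entries$effector)
  unknown <- setdiff(environment$id, known)
  if (length(unknown) > 0L)
    stop_eb("unknown effector(s): ", paste(unknown, collapse = ", "),
            " (known: ", paste(known, collapse = ", "), ")")
  shift <- numeric(0)
  for (r in seq_len(nrow(environment))) {
    eff <- environment$id[r]; delta <- environment$delta[r]
    hits <- system$entries[system$entries$effector == eff, , drop = FALSE]
    for (h in seq_len(nrow(hits))) {
      e <- hits[h, ]
      if (e$type == "activity_only") {
        if (tf_functionality(system, e$tf, eff, effector_present = delta > 0) == 0L)
          inactive <- union(inactive, e$tf)
      } else {
        shift[e$tf] <- (if (e$tf %in% names(shift)) shift[[e$tf]] else 0) +
          system$omega * e$kappa * delta
      }
    }
  }
  for (tf in names(shift)) {
    fixed[tf] <- unname(clamp(model$y_wt[[tf]] + shift[[tf]],
                              model$y_min[[tf]], model$y_max[[tf]]))
  }
  list(fixed = fixed, inactive = inactive)
}
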