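#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible sub-seed from a master seed and a string key
#'
#' All stochastic components take a single integer seed; sub-streams
#' (network topology, noise, null draws, ...) are derived with this
#' counter-based scheme so each artifact can be regenerated independently.
#' Result is always in \[1, 2^31 - 2\].
#'
#' @param seed master integer seed
#' @param key character tag naming the sub-stream
#' @return integer sub-seed
#' @export
split_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(key))
  h <- 0
  for (cp in utf8ToInt(key)) h <- (h * 31 + cp) %% 2147483647
  s <- (abs(as.numeric(seed)) * 7919 + h) %% 2147483646
  as.integer(s + 1)
}

## Evaluate `code` under a fixed RNG seed without disturbing the caller's
## RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

eb_log <- function(stage, ..., verbose = getOption("ebaflux.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf("[%s] %s", stage, paste0(...)))
  invisible(NULL)
}

stop_eb <- function(..., class = "ebaflux_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
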