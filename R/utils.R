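#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor median pt runif setNames
#' @importFrom utils read.delim write.table head
NULL

abort_lgtree <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "lgtree_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded generators are pure functions of their arguments.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# round-half-up to integer, matching how whole percentages are usually printed
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
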