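# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's `.Random.seed`, so seeded generators do
#' not perturb the global RNG stream. A `NULL` seed evaluates the expression
#' under the current stream.
#' @param seed integer seed or `NULL`.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Deterministic per-stream child seed below 2^31, so one master seed drives
# every stage without cross-stage coupling.
derive_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L)
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((abs(master) * 69821 + h * 7919 + 13) %% 2147483587)
}

stop_if_not_scalar_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min || x > max)
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name, min, max),
         call. = FALSE)
  invisible(x)
}
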