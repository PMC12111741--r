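#' @keywords internal
"_PACKAGE"

# Deterministically derive a child seed from a global seed and a tag, so every
# stochastic stage (simulation, noise, init, shuffling) gets its own stream.
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647)
}

# Run expr with a temporary RNG state; restores the caller's stream.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

stop_bad <- function(...) stop(..., call. = FALSE)

check_scalar_num <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_bad(sprintf("`%s` must be a single non-missing number", name))
  if (strict_lower && x <= lower)
    stop_bad(sprintf("`%s` must be > %s", name, lower))
  if (!strict_lower && x < lower)
    stop_bad(sprintf("`%s` must be >= %s", name, lower))
  if (x > upper)
    stop_bad(sprintf("`%s` must be <= %s", name, upper))
  invisible(x)
}
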