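# Internal helpers: classed conditions and local RNG handling.

# Error categories used across the package (and mapped to exit codes by the
# command-line front end): parse, format, domain, configuration,
# insufficient_data, conditioning, inconsistency, not_found.
secmp_stop <- function(category, msg, ...) {
  msg <- sprintf(msg, ...)
  cond <- structure(
    class = c(paste0("secmp_", category, "_error"), "secmp_error",
              "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

secmp_warn <- function(category, msg, ...) {
  msg <- sprintf(msg, ...)
  cond <- structure(
    class = c(paste0("secmp_", category, "_warning"), "secmp_warning",
              "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  warning(cond)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# A NULL seed leaves the global stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    secmp_stop("domain", "seed must be a single finite number, got %s",
               deparse(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_pos <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    secmp_stop("domain", "'%s' must be a single finite %s number",
               name, if (strict) "positive" else "non-negative")
  invisible(x)
}

# Avogadro constant (mol^-1), CODATA exact value.
N_AVOGADRO <- 6.02214076e23

`%||%` <- function(a, b) if (is.null(a)) b else a
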