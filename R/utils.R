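## Internal helpers shared across modules.

#' @importFrom stats rnorm runif rbinom rmultinom rgamma rlnorm pchisq pnorm
#'   kruskal.test setNames aggregate sd plogis qlogis cmdscale dist
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
## RNG stream is untouched. A NULL seed uses (and advances) the global stream.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Raise a classed validation error so callers (and the CLI) can distinguish
## bad input from internal failure.
validationError <- function(...) {
  stop(errorCondition(paste0(...), class = c("dnecValidationError", "error")))
}

assertColumns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing))
    validationError(what, ": missing column(s) ", paste(missing, collapse = ", "))
  invisible(df)
}

## Stable md5 of an R object via its canonical JSON serialization (used for
## provenance manifests).
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE), f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
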