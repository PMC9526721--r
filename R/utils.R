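## Internal helpers shared across modules.

## Row means/variances without extra dependencies.
rowVars_ <- function(m) {
  n <- ncol(m)
  if (n < 2) return(setNames(rep(NA_real_, nrow(m)), rownames(m)))
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (n - 1)
}

## Evaluate `expr` under a temporary RNG state seeded with `seed`,
## restoring the caller's RNG afterwards. `seed = NULL` leaves RNG alone.
withSeed_ <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Deterministically mixes a global integer seed with a stage name so that
#' pipeline stages draw from independent, reproducible streams and can be
#' re-run in isolation. The result is always a non-negative integer below
#' 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return A single integer seed.
#' @examples
#' deriveSeed(1, "signature") != deriveSeed(1, "connectivity")
#' @export
deriveSeed <- function(seed, stage) {
  stopifnot(length(seed) == 1, is.finite(seed), is.character(stage))
  m <- 2147483629  # largest prime < 2^31
  h <- as.double(seed %% m)
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% m
  as.integer(h)
}

## Minimal leveled logger: messages go through message() so callers can
## suppress or sink them.
logMsg_ <- function(...) message("[coexscreen] ", ...)
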