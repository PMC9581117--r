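# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

# p clipped away from {0,1} before loss / residual computation
clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals never disturb
#' the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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

# binomial deviance per instance, mean over instances (optionally weighted)
mean_deviance <- function(y, p, w = NULL) {
  p <- clamp_prob(p)
  ll <- -(y * log(p) + (1 - y) * log(1 - p))
  if (is.null(w)) mean(ll) else sum(w * ll) / sum(w)
}

# short stable fingerprint of an R object (seed/config provenance stamps)
fingerprint <- function(x) {
  s <- paste(deparse(x, control = "all"), collapse = "")
  raw <- utf8ToInt(s)
  h <- 5381
  for (v in raw) h <- (h * 33 + v) %% 2147483647
  sprintf("%08x", h)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
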