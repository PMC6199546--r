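#' Derive a reproducible sub-stream seed
#'
#' Deterministically maps a master seed plus a sequence of string/integer
#' labels (site, year, stage, ...) to a 32-bit-safe positive integer seed.
#' Used throughout the pipeline so that every (site, year, stage) draws from
#' its own reproducible stream.
#'
#' @param seed Master integer seed.
#' @param ... Labels (coerced to character) identifying the sub-stream.
#' @return A positive integer seed strictly below 2^31.
#' @export
#' @examples
#' derive_seed(1L, "novi_sad", 2006, "ensemble")
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  key <- paste(c(format(seed, scientific = FALSE), ...), collapse = "/")
  codes <- utf8ToInt(key)
  # polynomial rolling hash; modulus is a prime < 2^31, products stay < 2^53
  m <- 2147483629
  h <- (abs(seed) + 1) %% m
  for (cc in codes) h <- (h * 131 + cc) %% m
  as.integer(h %% (m - 1L) + 1L)
}

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(code)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a
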