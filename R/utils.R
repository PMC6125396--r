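# Internal helpers shared across the package.

`%||%` <- function(a, b) if (is.null(a)) b else a

.pkg_cache <- new.env(parent = emptyenv())

#' Run an expression under a local, restorable RNG seed
#'
#' All stochastic functions in the package take an explicit `seed` argument
#' and evaluate under it without disturbing the caller's RNG stream.
#' @noRd
local_seed_eval <- function(seed, expr) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a reproducible per-stage seed from a base seed
#'
#' A single pipeline seed fans out to one seed per named stage so each
#' stage is independently reproducible. The derivation is a small
#' deterministic string hash folded into the base seed, kept below 2^31.
#' @noRd
derive_seed <- function(base_seed, stage) {
  h <- 0
  for (c in utf8ToInt(stage)) h <- (h * 31 + c) %% 1000000007
  as.integer((as.numeric(base_seed) * 2654435 + h) %% 2147483647L)
}

# popcount lookup for 16-bit words; built lazily, cached for the session
.popcount16 <- function() {
  pc <- .pkg_cache$popcount16
  if (is.null(pc)) {
    pc <- integer(65536L)
    for (i in 1:65535) pc[i + 1L] <- pc[bitwShiftR(i, 1L) + 1L] + (i %% 2L)
    .pkg_cache$popcount16 <- pc
  }
  pc
}

# number of set bits in each element of an integer vector (values < 2^16)
.popcount <- function(x) .popcount16()[x + 1L]

.stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
.warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

.assert_scalar_int <- function(x, name, lower = -Inf) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != round(x))
    .stopf("`%s` must be a single integer", name)
  if (x < lower) .stopf("`%s` must be >= %s", name, lower)
  invisible(as.integer(x))
}
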