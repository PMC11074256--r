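# Internal helpers shared across modules.

#' Derive a reproducible substream seed from a master seed and a stream name
#'
#' Each generator in the package draws from its own named substream so that
#' adding or reordering generators never shifts another generator's stream.
#' The derived seed is a deterministic 31-bit hash of `(seed, name)`.
#'
#' @param seed integer master seed.
#' @param name character stream name (e.g. `"scene"`, `"tree_7"`).
#' @return an integer in `[1, 2^31 - 2]` suitable for [set.seed()].
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(length(seed) == 1L, is.finite(seed), is.character(name))
  m <- 2147483629 # largest prime < 2^31
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer(h %% (m - 2) + 1)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

# -sum(p * log2(p)) over positive entries of a probability vector.
plogp2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

is_count <- function(x) length(x) == 1L && is.finite(x) && x >= 0 && x == round(x)

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of the canonical JSON rendering of a list; used to stamp artifacts.
config_hash <- function(x) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(x, f, auto_unbox = TRUE, digits = NA, sort_keys = TRUE)
  unname(tools::md5sum(f))
}
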