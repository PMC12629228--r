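#' @keywords internal
"_PACKAGE"

#' @importFrom stats cor rnorm runif sd pt quantile ks.test
#' @importFrom utils head tail
NULL

# Deterministic 31-bit hash of a character key (polynomial rolling hash).
# Used to derive independent RNG substreams per (sig_id, method, K) so that
# permutation backgrounds are reproducible regardless of build order or
# parallel scheduling.
.string_hash <- function(key) {
  stopifnot(is.character(key), length(key) == 1L)
  mod <- 2147483629
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 131 + ch) %% mod
  h
}

#' Derive a reproducible RNG substream seed
#'
#' Combines a master seed with arbitrary string components into a seed in
#' `[1, 2^31 - 22]`, deterministically. Identical inputs always yield the same
#' seed; distinct keys yield (with overwhelming probability) distinct streams.
#'
#' @param master integer master seed.
#' @param ... components (coerced to character) identifying the substream,
#'   e.g. a signature id, a method name and K.
#' @return an integer seed usable with [set.seed()].
#' @export
derive_seed <- function(master, ...) {
  mod <- 2147483629
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "\r")
  h <- .string_hash(key)
  as.integer((h + (as.numeric(master) %% mod) * 48271) %% mod) + 1L
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# global .Random.seed is restored afterwards.
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

.log_msg <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}
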