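#' @keywords internal
#' @useDynLib structf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

.onLoad <- function(libname, pkgname) {
  cpp_tune_allocator()
  invisible()
}

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All stochastic operations in the package go through
# this so that a single integer makes a result reproducible without clobbering
# the session RNG.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single non-missing number", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a child seed from a master seed and a stream label, kept within the
# 32-bit integer range R requires. Streams with different labels are
# decorrelated by a small multiplicative hash.
derive_seed <- function(master_seed, ...) {
  labels <- paste(c(...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(labels)) h <- (h * 31 + ch) %% 2147480009
  as.integer((as.numeric(master_seed) * 48271 + h) %% 2147480009 + 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Single string -> character vector of single characters.
str_chars <- function(s) {
  if (nchar(s) == 0L) character(0) else strsplit(s, "", fixed = TRUE)[[1L]]
}
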