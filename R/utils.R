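#' @keywords internal
#' @importFrom stats approx cor delete.response lsfit model.frame model.matrix
#'   model.response pchisq pf pt reshape rgamma rnorm runif sd
#' @importFrom utils read.csv write.csv head
#' @importFrom graphics abline lines matplot
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route through this so they are pure functions of their seed.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("`seed` must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sub-stream seeds: stage `offset` of a run seeded with `seed`. Keeps the
# derived seed inside the 32-bit integer range expected by set.seed().
substream_seed <- function(seed, offset) {
  as.integer((as.double(seed) * 131L + offset) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
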