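# Internal helpers shared across modules.

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All package randomness funnels through this so
# user session state is never perturbed.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Independent RNG streams derived from one master seed, so e.g. toggling
# augmentation cannot shift the initialisation draws. A stream is a captured
# .Random.seed vector; withStream() runs code under it and saves it back.
makeStream <- function(seed) {
  withSeed(seed, get(".Random.seed", envir = globalenv()))
}

withStream <- function(streams, name, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  assign(".Random.seed", streams[[name]], envir = globalenv())
  res <- force(expr)
  streams[[name]] <- get(".Random.seed", envir = globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  list(value = res, streams = streams)
}

# Derive sub-seeds from a master seed, kept inside 32-bit integer range.
deriveSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 1103L + offset * 7919L) %% 2147483629)
}

assertArray3 <- function(x, what = "image") {
  if (!is.array(x) || length(dim(x)) != 3L)
    stop(what, " must be a 3-d array with dim c(C, H, W)", call. = FALSE)
  invisible(x)
}

# Coerce H x W matrix to 1 x H x W.
asCHW <- function(x) {
  if (is.matrix(x)) array(x, c(1L, nrow(x), ncol(x))) else x
}

l1Mean <- function(a, b) mean(abs(a - b))

l1Grad <- function(a, b) sign(a - b) / length(a)

isScalarNumber <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
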