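# internal helpers shared across the package

# greatest common divisor of a vector of nonnegative numbers (doubles holding
# exact integers); gcd(0, x) = x, gcd of all zeros = 0
gcd2 <- function(a, b) {
  while (b != 0) {
    r <- a %% b
    a <- b
    b <- r
  }
  a
}

gcdv <- function(x) {
  x <- abs(x[x != 0])
  if (length(x) == 0L) return(0)
  Reduce(gcd2, x)
}

# run code with a private RNG stream derived from `seed`, restoring the
# caller's .Random.seed afterwards; every stochastic entry point goes through
# this so a mandatory seed gives full determinism
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("a single numeric seed is required", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

is_count <- function(x, min = 0) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x >= min && x == floor(x)
}

# all entries integral (stored as doubles)
all_integral <- function(x) all(is.finite(x)) && all(x == floor(x))

`%||%` <- function(a, b) if (is.null(a)) b else a
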