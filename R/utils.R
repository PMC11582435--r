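# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

is_prime <- function(x) {
  if (x < 2 || x != round(x)) return(FALSE)
  if (x < 4) return(TRUE)
  if (x %% 2 == 0) return(FALSE)
  d <- 3
  while (d * d <= x) {
    if (x %% d == 0) return(FALSE)
    d <- d + 2
  }
  TRUE
}

# first n primes (2, 3, 5, ...)
first_primes <- function(n) {
  out <- integer(0)
  cand <- 2L
  while (length(out) < n) {
    if (is_prime(cand)) out <- c(out, cand)
    cand <- cand + 1L
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
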