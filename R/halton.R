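#' Halton low-discrepancy sequence
#'
#' Radical-inverse sequence in a prime base: element i is obtained by
#' writing i in the base and mirroring its digits about the radix point.
#' Consecutive elements fill the unit interval far more evenly than
#' pseudo-random draws, which is why quasi-Monte-Carlo simulation of the
#' mixing integral converges with far fewer draws.
#'
#' @param base Prime base (>= 2).
#' @param n Number of points to return.
#' @param burn Number of initial points to discard (burn-in); the returned
#'   points are elements `burn + 1` to `burn + n`.
#' @return Numeric vector of `n` points in (0, 1).
#' @export
#' @examples
#' halton_sequence(2, 3)  # 0.50 0.25 0.75
halton_sequence <- function(base, n, burn = 0) {
  stopifnot(n >= 1, burn >= 0)
  if (!is_prime(base)) stop("base must be a prime number >= 2")
  idx <- (burn + 1):(burn + n)
  halton_radical_inverse(as.numeric(idx), as.integer(base))
}

#' Standard-normal Halton draw array
#'
#' Builds the quasi-random draw array used by the simulated likelihood: for
#' each random-coefficient dimension a Halton sequence in its own prime base
#' (consecutive primes 2, 3, 5, ... by default) is generated, mapped through
#' the standard-normal inverse CDF, and allocated to observations in
#' row-major blocks (observation 1 receives points 1..R, observation 2
#' points R+1..2R, and so on). The construction is fully deterministic given
#' (bases, burn, n_obs, R), which makes estimation bit-reproducible.
#'
#' @param n_obs Number of observations.
#' @param n_dims Number of random-coefficient dimensions.
#' @param R Draws per observation (the study default is 1000).
#' @param burn Burn-in points discarded from the start of each sequence
#'   (default 100; must be >= 1 so no point maps to +/-Inf).
#' @param bases Optional integer vector of prime bases, one per dimension.
#' @return An object of class `halton_draws`: a numeric array with
#'   dim `c(n_obs, n_dims, R)` plus attributes `bases` and `burn`.
#' @export
normal_halton_draws <- function(n_obs, n_dims, R, burn = 100, bases = NULL) {
  stopifnot(n_obs >= 1, n_dims >= 0)
  if (R <= 0) stop("R must be a positive number of draws")
  if (burn < 1) stop("burn-in must be >= 1 (the first Halton point is 0 in base expansions with index 0 conventions; a positive burn keeps all points strictly inside (0,1))")
  if (is.null(bases)) bases <- first_primes(max(n_dims, 1))[seq_len(n_dims)]
  if (length(bases) != n_dims) stop("need one prime base per random dimension")
  arr <- array(numeric(0), dim = c(n_obs, n_dims, R))
  for (d in seq_len(n_dims)) {
    u <- halton_sequence(bases[d], n_obs * R, burn = burn)
    # row-major blocks: obs i gets points (i-1)*R + 1 .. i*R
    arr[, d, ] <- matrix(stats::qnorm(u), nrow = n_obs, ncol = R, byrow = TRUE)
  }
  structure(arr, bases = bases, burn = burn, class = "halton_draws")
}

#' @export
print.halton_draws <- function(x, ...) {
  d <- dim(x)
  cat("halton_draws:", d[1], "obs x", d[2], "dims x", d[3],
      "draws (bases", paste(attr(x, "bases"), collapse = ","),
      "; burn", attr(x, "burn"), ")\n")
  invisible(x)
}
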