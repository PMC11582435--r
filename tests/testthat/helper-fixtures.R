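# Shared fixtures and independent oracles. The oracles below deliberately
# recompute probabilities by looping over records, draws and the spec's own
# bookkeeping, touching none of the package's vectorized/C++ paths.

toy_scheme <- function() {
  covariate_scheme(
    blocks = list(
      pair = list(names = c("a1", "a2"), probabilities = c(0.5, 0.5),
                  exhaustive = TRUE)),
    indicators = c(b = 0.4, w = 0.3))
}

toy_spec <- function(random = TRUE) {
  mixl_spec(
    fixed = list(SI = c("constant", "a1"), FI = c("constant", "b")),
    random = if (random)
      list(random_coef("FI", "a1", mean_covariates = "b",
                       var_covariates = "w"))
    else list())
}

toy_covariates <- function(n, seed = 7) {
  sample_covariates(toy_scheme(), n, seed = seed)
}

# Brute-force simulated choice probabilities: straight loops over records,
# draws, alternatives, reading coefficients off param_names().
oracle_probs <- function(df, spec, params, draws = NULL) {
  params <- stats::setNames(as.numeric(params), param_names(spec))
  J <- length(spec$alternatives)
  n <- nrow(df)
  R <- if (length(spec$random)) dim(draws)[3] else 1L
  val <- function(v, i) if (v == "constant") 1 else df[[v]][i]
  P <- matrix(0, n, J)
  for (i in seq_len(n)) {
    acc <- numeric(J)
    for (d in seq_len(R)) {
      u <- numeric(J)
      for (j in seq_len(J)) {
        a <- spec$alternatives[j]
        for (v in spec$fixed[[a]]) {
          u[j] <- u[j] + params[[paste0("[", a, "] ", v)]] * val(v, i)
        }
      }
      for (e in seq_along(spec$random)) {
        rc <- spec$random[[e]]
        j <- match(rc$alternative, spec$alternatives)
        key <- paste0("[", rc$alternative, "] ", rc$covariate)
        b <- params[[paste0(key, " (mean)")]]
        for (zv in rc$mean_covariates) {
          b <- b + params[[paste0(key, " : ", zv, " (het.mean)")]] * val(zv, i)
        }
        lnsc <- 0
        for (wv in rc$var_covariates) {
          lnsc <- lnsc + params[[paste0(key, " : ", wv, " (het.sd)")]] * val(wv, i)
        }
        b <- b + params[[paste0(key, " (sd)")]] * exp(lnsc) * draws[i, e, d]
        u[j] <- u[j] + b * val(rc$covariate, i)
      }
      eu <- exp(u - max(u))
      acc <- acc + eu / sum(eu)
    }
    P[i, ] <- acc / R
  }
  P
}

oracle_loglik <- function(df, spec, params, draws = NULL) {
  P <- oracle_probs(df, spec, params, draws)
  y <- match(as.character(df$severity), spec$alternatives)
  sum(log(P[cbind(seq_len(nrow(df)), y)]))
}

# Star discrepancy of 1-D points by direct evaluation on the sorted sample.
star_discrepancy <- function(x) {
  x <- sort(x)
  n <- length(x)
  i <- seq_len(n)
  max(pmax(i / n - x, x - (i - 1) / n))
}

table2_counts <- function(year = 2015) {
  switch(as.character(year),
         "2015" = rbind(rainy = c(925, 1502, 796), dry = c(800, 1171, 576)),
         "2016" = rbind(rainy = c(778, 1386, 679), dry = c(571, 1178, 611)))
}
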