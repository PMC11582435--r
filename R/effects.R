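#' Average marginal effect of an indicator covariate
#'
#' For a binary covariate the marginal effect on a severity level is the
#' change in its average predicted probability when the indicator is
#' switched from 0 to 1 with everything else held fixed: probabilities are
#' computed for every record under both counterfactuals, averaged across
#' the full sample, and differenced. For random coefficients the same
#' Halton draw array as estimation is used under both counterfactuals
#' (common random numbers), so simulation noise cancels in the difference.
#'
#' @param fit A [mixl_fit()].
#' @param covariate Covariate name (must exist in the fit's data).
#' @param data Dataset to average over; defaults to the fit's own data.
#' @return Named numeric vector of per-severity probability changes,
#'   summing to ~0 (probability conservation).
#' @export
average_marginal_effect <- function(fit, covariate, data = fit$data) {
  df <- if (inherits(data, "crash_dataset")) data$data else data
  if (!covariate %in% names(df)) stop("covariate '", covariate,
                                      "' absent from the data")
  nre <- length(fit$spec$random)
  draws <- if (nre) normal_halton_draws(nrow(df), nre, fit$R, fit$burn)
           else NULL
  d1 <- df; d1[[covariate]] <- 1
  d0 <- df; d0[[covariate]] <- 0
  p1 <- simulated_probability(d1, fit$spec, fit$raw_estimates, draws = draws)
  p0 <- simulated_probability(d0, fit$spec, fit$raw_estimates, draws = draws)
  colMeans(p1) - colMeans(p0)
}

#' Average marginal effects table
#'
#' [average_marginal_effect()] for every covariate the specification uses
#' (or a caller-supplied set), assembled as one row per covariate with one
#' column per severity level.
#'
#' @param fit A [mixl_fit()].
#' @param covariates Character vector; defaults to every covariate entering
#'   the fit's utilities.
#' @param data Dataset to average over; defaults to the fit's own data.
#' @return Data.frame of class `me_table` with severity-level columns and a
#'   `covariate` column; `attr(, "N")` records the sample size used.
#' @export
marginal_effects <- function(fit, covariates = NULL, data = fit$data) {
  if (is.null(covariates)) {
    covariates <- spec_covariates(fit$spec)
    # Z/W-only covariates still shift probabilities; own-utility entries first
  }
  rows <- t(vapply(covariates,
                   function(v) average_marginal_effect(fit, v, data = data),
                   numeric(length(fit$spec$alternatives))))
  out <- data.frame(covariate = covariates, rows, row.names = NULL)
  names(out) <- c("covariate", fit$spec$alternatives)
  df <- if (inherits(data, "crash_dataset")) data$data else data
  attr(out, "N") <- nrow(df)
  class(out) <- c("me_table", "data.frame")
  out
}

#' @export
print.me_table <- function(x, digits = 4, ...) {
  cat("Average marginal effects (N =", attr(x, "N"), ")\n")
  y <- x
  for (j in 2:ncol(y)) y[[j]] <- round(y[[j]], digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Share of a normal random coefficient above zero
#'
#' For a coefficient distributed N(mean, sd^2), the proportion of
#' casualties whose realized coefficient is positive, Phi(mean/sd) — the
#' usual summary of how much of the population a random effect pushes
#' toward (or away from) an outcome.
#'
#' @param mean Estimated mean of the random coefficient.
#' @param sd Estimated standard deviation (> 0).
#' @return Proportion in [0, 1].
#' @export
#' @examples
#' share_positive(0.451, 1.672)  # 0.606
share_positive <- function(mean, sd) {
  if (any(sd <= 0)) stop("sd must be positive")
  stats::pnorm(mean / sd)
}

#' Side-by-side results table for several fitted models
#'
#' Assembles the standard report layout: one column per fit (e.g. per
#' season-year cell) with "estimate (z)" coefficient cells, a statistics
#' footer (K, N, log-likelihood at zero and at convergence, AIC, McFadden
#' rho-squared), and optionally marginal-effect blocks.
#'
#' @param fits List of [mixl_fit()] objects; names (or fit labels) become
#'   column headers.
#' @param effects Optional list of [marginal_effects()] tables, same length.
#' @param digits Decimals for coefficient formatting.
#' @return A data.frame of class `mixl_results` (character cells; empty
#'   where a term is absent from a model).
#' @export
results_table <- function(fits, effects = NULL, digits = 3) {
  if (inherits(fits, "mixl_fit")) fits <- list(fits)
  labs <- names(fits)
  if (is.null(labs)) labs <- vapply(fits, function(f)
    if (nzchar(f$label)) f$label else "model", "")
  alts <- lapply(fits, function(f) f$spec$alternatives)
  if (length(unique(lapply(alts, paste, collapse = ","))) != 1) {
    stop("fits must share the same severity levels")
  }
  terms <- unique(unlist(lapply(fits, function(f) names(f$estimates))))
  fmt <- function(est, z) sprintf(paste0("%.", digits, "f (%.3f)"), est, z)
  body <- sapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    cells <- rep("", length(terms))
    idx <- match(names(f$estimates), terms)
    cells[idx] <- fmt(f$estimates, f$z)
    cells
  })
  body <- matrix(body, nrow = length(terms))
  footer_terms <- c("Number of parameters (K)", "Number of observations (N)",
                    "Log-likelihood at zero", "Log-likelihood at convergence",
                    "AIC", "McFadden rho2")
  footer <- sapply(fits, function(f) {
    c(as.character(f$K), as.character(f$N), sprintf("%.3f", f$ll0),
      sprintf("%.3f", f$ll), sprintf("%.3f", f$aic), sprintf("%.3f", f$rho2))
  })
  footer <- matrix(footer, nrow = length(footer_terms))
  tab <- data.frame(term = c(terms, footer_terms),
                    rbind(body, footer), check.names = FALSE)
  names(tab) <- c("term", labs)
  if (!is.null(effects)) attr(tab, "effects") <- effects
  class(tab) <- c("mixl_results", "data.frame")
  tab
}

#' @export
print.mixl_results <- function(x, ...) {
  print.data.frame(x, row.names = FALSE, right = FALSE)
  invisible(x)
}
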