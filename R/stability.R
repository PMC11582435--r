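confidence_bracket <- function(confidence) {
  cuts <- c(0.9999, 0.999, 0.99, 0.95, 0.90)
  labs <- c(">99.99 %", ">99.9 %", ">99 %", ">95 %", ">90 %")
  for (i in seq_along(cuts)) {
    if (confidence > cuts[i]) return(labs[i])
  }
  "n.s."
}

#' Pearson chi-square test of independence
#'
#' Tests whether the severity distribution differs across the rows of a
#' season-by-severity contingency table (no continuity correction). The
#' confidence level is reported both numerically and as the conventional
#' bracket category (">95 %", ">99.99 %", ...).
#'
#' @param table A [contingency_table()] or plain count matrix.
#' @return An object of class `chi2_test`: list with `statistic`, `df`,
#'   `p_value`, `confidence`, `bracket`.
#' @export
#' @examples
#' tab <- contingency_table(rbind(c(925, 1502, 796), c(800, 1171, 576)))
#' chi_square_independence(tab)  # 6.210 (2) [>95 %]
chi_square_independence <- function(table) {
  m <- unclass(as.matrix(table))
  if (any(rowSums(m) <= 0) || any(colSums(m) <= 0)) {
    stop("zero row or column margin")
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  if (any(ct$expected <= 0)) stop("expected cell counts must be positive")
  conf <- unname(stats::pchisq(ct$statistic, ct$parameter))
  structure(list(statistic = unname(ct$statistic),
                 df = unname(ct$parameter),
                 p_value = unname(ct$p.value),
                 confidence = conf,
                 bracket = confidence_bracket(conf)),
            class = "chi2_test")
}

#' @export
print.chi2_test <- function(x, ...) {
  cat(sprintf("%.3f (%d) [%s]\n", x$statistic, x$df, x$bracket))
  invisible(x)
}

#' Likelihood-ratio transferability test
#'
#' Tests whether the converged parameters of a model fitted on one dataset
#' (the source) are transferable to another (the target): the statistic is
#' \deqn{-2\,[LL_{target}(\hat\beta_{source}) - LL_{target}(\hat\beta_{target})],}
#' i.e. both log-likelihoods are evaluated on the same target data —
#' transferred parameters against the native fit. Under the null of equal
#' parameters the statistic is chi-square with df equal to the parameter
#' count K of the transferred specification. The same construction with
#' source/target as different years gives the temporal-stability test.
#'
#' Draws for the transferred-likelihood evaluation are regenerated for the
#' target dataset's size with the source fit's bases and burn-in
#' (common-structure, not common-index).
#'
#' @param fit_source A [mixl_fit()] fitted on the source dataset.
#' @param data_target The target [crash_dataset()].
#' @param fit_target A [mixl_fit()] of the same spec fitted on
#'   `data_target`.
#' @return An object of class `lr_test`: `statistic`, `df`, `confidence`,
#'   `bracket`, `direction`.
#' @export
lr_transfer_test <- function(fit_source, data_target, fit_target) {
  if (!identical(param_names(fit_source$spec), param_names(fit_target$spec))) {
    stop("source and target fits must share the same specification")
  }
  ll_transfer <- simulated_loglik(data_target, fit_source$spec,
                                  fit_source$raw_estimates,
                                  R = max(fit_source$R, 1),
                                  burn = fit_source$burn)
  stat <- -2 * (ll_transfer - fit_target$ll)
  df <- fit_source$K
  conf <- stats::pchisq(max(stat, 0), df)
  structure(list(statistic = stat, df = df,
                 confidence = conf, bracket = confidence_bracket(conf),
                 ll_transfer = ll_transfer, ll_native = fit_target$ll,
                 direction = c(source = fit_source$label,
                               target = fit_target$label)),
            class = "lr_test")
}

#' @export
print.lr_test <- function(x, ...) {
  cat(sprintf("%.3f [%d] (%s)", x$statistic, x$df, x$bracket))
  if (any(nzchar(x$direction))) {
    cat("   ", x$direction[["source"]], "->", x$direction[["target"]])
  }
  cat("\n")
  invisible(x)
}

#' Pairwise transferability / temporal-stability test matrix
#'
#' Runs [lr_transfer_test()] for every ordered pair of fitted models (both
#' directions, mirroring the reversed-test protocol); the diagonal is
#' empty. Entry (a, b) transfers model a's parameters onto dataset b.
#'
#' @param fits Named list of [mixl_fit()] objects sharing one spec.
#' @param datasets Named list of [crash_dataset()] objects aligned with
#'   `fits`.
#' @return An object of class `lr_matrix`: a character matrix of
#'   `"stat [df] (bracket)"` cells with the full results in
#'   `attr(, "tests")`.
#' @export
pairwise_test_matrix <- function(fits, datasets) {
  labs <- names(fits)
  if (is.null(labs) || !identical(sort(labs), sort(names(datasets)))) {
    stop("fits and datasets must be named lists with matching labels")
  }
  k <- length(labs)
  out <- matrix("", k, k, dimnames = list(source = labs, target = labs))
  tests <- list()
  for (a in labs) for (b in labs) {
    if (a == b) next
    tst <- lr_transfer_test(fits[[a]], datasets[[b]], fits[[b]])
    tst$direction <- c(source = a, target = b)
    out[a, b] <- sprintf("%.3f [%d] (%s)", tst$statistic, tst$df, tst$bracket)
    tests[[paste(a, "->", b)]] <- tst
  }
  structure(out, tests = tests, class = c("lr_matrix", "matrix"))
}

#' @export
print.lr_matrix <- function(x, ...) {
  print(unclass(x)[, , drop = FALSE], quote = FALSE)
  invisible(x)
}
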