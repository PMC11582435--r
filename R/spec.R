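#' Declare a random coefficient
#'
#' A random coefficient attaches to one (alternative, covariate) utility
#' entry and varies across casualties as
#' \deqn{\beta_m = \beta + \delta' Z_m + \sigma \exp(\omega' W_m) v_m,}
#' where \eqn{v_m} is standard normal, \eqn{Z_m} are covariates shifting the
#' mean (heterogeneity in means, coefficients \eqn{\delta}) and \eqn{W_m}
#' covariates scaling the standard deviation (heterogeneity in variances,
#' coefficients \eqn{\omega}). With empty `mean_covariates` and
#' `var_covariates` this is the plain normally-distributed random parameter.
#'
#' @param alternative Severity level whose utility the coefficient enters.
#' @param covariate Covariate name, or `"constant"`.
#' @param mean_covariates Character vector of Z covariate names.
#' @param var_covariates Character vector of W covariate names.
#' @param distribution Mixing distribution; only `"normal"` is implemented
#'   (the architecture admits others).
#' @return An object of class `random_coef`.
#' @export
random_coef <- function(alternative, covariate,
                        mean_covariates = character(0),
                        var_covariates = character(0),
                        distribution = "normal") {
  distribution <- match.arg(distribution, "normal")
  structure(list(alternative = alternative, covariate = covariate,
                 mean_covariates = as.character(mean_covariates),
                 var_covariates = as.character(var_covariates),
                 distribution = distribution),
            class = "random_coef")
}

#' Specify a mixed multinomial logit model
#'
#' Declares which covariates enter which severity utility, fixed or random.
#' One alternative is the reference with utility normalised to zero (the
#' standard multinomial-logit location normalisation); a constant may still
#' be declared explicitly on the reference if a different normalisation is
#' wanted.
#'
#' @param alternatives Ordered character vector of outcome levels
#'   (default MI/SI/FI).
#' @param reference The reference alternative (default the first).
#' @param fixed Named list: for each alternative, a character vector of
#'   covariate names (use `"constant"` for an alternative-specific constant)
#'   entering its utility with a fixed coefficient.
#' @param random List of [random_coef()] entries.
#' @return An object of class `mixl_spec`.
#' @export
mixl_spec <- function(alternatives = severity_levels(),
                      reference = alternatives[1],
                      fixed = list(), random = list()) {
  stopifnot(length(alternatives) >= 2, reference %in% alternatives)
  bad <- setdiff(names(fixed), alternatives)
  if (length(bad)) stop("fixed entries for unknown alternatives: ",
                        paste(bad, collapse = ", "))
  if (length(random) && inherits(random, "random_coef")) random <- list(random)
  for (rc in random) {
    if (!inherits(rc, "random_coef")) stop("'random' must be random_coef objects")
    if (!rc$alternative %in% alternatives) {
      stop("random coefficient on unknown alternative ", rc$alternative)
    }
  }
  # no duplicate (alternative, covariate) entries across fixed + random
  keys <- c(unlist(lapply(alternatives, function(a)
              paste(a, fixed[[a]], sep = ":"))),
            vapply(random, function(rc)
              paste(rc$alternative, rc$covariate, sep = ":"), ""))
  if (anyDuplicated(keys)) {
    stop("duplicate (alternative, covariate) entries: ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "))
  }
  spec <- structure(list(alternatives = alternatives, reference = reference,
                         fixed = fixed, random = random),
                    class = "mixl_spec")
  spec
}

#' @export
print.mixl_spec <- function(x, ...) {
  cat("Mixed multinomial logit specification\n")
  cat("  alternatives:", paste(x$alternatives, collapse = ", "),
      "(reference:", x$reference, ")\n")
  for (a in x$alternatives) {
    fx <- x$fixed[[a]]
    if (length(fx)) cat("  [", a, "] fixed: ", paste(fx, collapse = ", "),
                        "\n", sep = "")
  }
  for (rc in x$random) {
    cat("  [", rc$alternative, "] random: ", rc$covariate, sep = "")
    if (length(rc$mean_covariates))
      cat(" | mean ~ ", paste(rc$mean_covariates, collapse = " + "), sep = "")
    if (length(rc$var_covariates))
      cat(" | sd ~ ", paste(rc$var_covariates, collapse = " + "), sep = "")
    cat("\n")
  }
  cat("  K =", n_parameters(x), "parameters\n")
  invisible(x)
}

#' Number of estimable parameters of a specification
#'
#' Counts fixed coefficients plus, for each random entry, its mean, its
#' standard deviation, and one coefficient per mean-/variance-heterogeneity
#' covariate. This is the K reported in fit statistics and used as the
#' degrees of freedom of transferability tests.
#'
#' @param spec A [mixl_spec()].
#' @return Integer parameter count K.
#' @export
n_parameters <- function(spec) {
  length(param_names(spec))
}

#' Parameter names in packing order
#'
#' The packing order is stable and documented: fixed coefficients by
#' alternative (in `spec$alternatives` order) and declaration order, then
#' for each random entry its mean, the delta coefficients (one per Z
#' covariate), sigma, and the omega coefficients (one per W covariate).
#'
#' @param spec A [mixl_spec()].
#' @return Character vector of parameter names.
#' @export
param_names <- function(spec) {
  nm <- character(0)
  for (a in spec$alternatives) {
    fx <- spec$fixed[[a]]
    if (length(fx)) nm <- c(nm, paste0("[", a, "] ", fx))
  }
  for (rc in spec$random) {
    base <- paste0("[", rc$alternative, "] ", rc$covariate)
    nm <- c(nm, paste0(base, " (mean)"))
    if (length(rc$mean_covariates))
      nm <- c(nm, paste0(base, " : ", rc$mean_covariates, " (het.mean)"))
    nm <- c(nm, paste0(base, " (sd)"))
    if (length(rc$var_covariates))
      nm <- c(nm, paste0(base, " : ", rc$var_covariates, " (het.sd)"))
  }
  nm
}

# All covariate names a spec touches (excluding "constant").
spec_covariates <- function(spec) {
  nm <- unlist(spec$fixed, use.names = FALSE)
  for (rc in spec$random) {
    nm <- c(nm, rc$covariate, rc$mean_covariates, rc$var_covariates)
  }
  setdiff(unique(nm), "constant")
}

# Replace every random entry by a fixed entry for its own covariate
# (used for MNL starting values and for sigma -> 0 degeneracy checks).
fixedize_spec <- function(spec) {
  fixed <- spec$fixed
  for (rc in spec$random) {
    fixed[[rc$alternative]] <- c(fixed[[rc$alternative]], rc$covariate)
  }
  mixl_spec(spec$alternatives, spec$reference, fixed = fixed, random = list())
}

# Internal: design structure consumed by the C++ likelihood kernel.
# `data` is a crash_dataset or a data.frame; y is NULL when no severity
# column is present (simulation use).
build_model_frame <- function(data, spec) {
  df <- if (inherits(data, "crash_dataset")) data$data else data
  need <- spec_covariates(spec)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("specification references unknown covariates: ",
                         paste(miss, collapse = ", "))
  n <- nrow(df)
  getcol <- function(v) {
    if (v == "constant") rep(1, n) else as.numeric(df[[v]])
  }
  Xfix <- lapply(spec$alternatives, function(a) {
    fx <- spec$fixed[[a]]
    m <- if (length(fx)) sapply(fx, getcol) else matrix(0, n, 0)
    matrix(as.numeric(m), nrow = n, ncol = length(fx))
  })
  re <- lapply(spec$random, function(rc) {
    list(alt = match(rc$alternative, spec$alternatives),
         x = getcol(rc$covariate),
         Z = if (length(rc$mean_covariates))
               sapply(rc$mean_covariates, getcol, simplify = "array")
             else matrix(0, n, 0),
         W = if (length(rc$var_covariates))
               sapply(rc$var_covariates, getcol)
             else matrix(0, n, 0))
  })
  re <- lapply(re, function(e) {
    e$Z <- matrix(as.numeric(e$Z), nrow = n)
    e$W <- matrix(as.numeric(e$W), nrow = n)
    e
  })
  y <- NULL
  if ("severity" %in% names(df)) {
    y <- match(as.character(df$severity), spec$alternatives)
    if (anyNA(y)) stop("severity values outside the spec's alternatives")
  }
  list(n = n, J = length(spec$alternatives), y = y, Xfix = Xfix, re = re)
}

# Split a packed parameter vector into fixed betas and random-entry pieces.
unpack_params <- function(spec, theta) {
  K <- n_parameters(spec)
  if (length(theta) != K) {
    stop("parameter vector has length ", length(theta), "; spec needs K = ", K)
  }
  out <- list(fixed = list(), random = list())
  i <- 0L
  for (a in spec$alternatives) {
    p <- length(spec$fixed[[a]])
    out$fixed[[a]] <- theta[seq_len(p) + i]
    i <- i + p
  }
  for (e in seq_along(spec$random)) {
    rc <- spec$random[[e]]
    q <- length(rc$mean_covariates); s <- length(rc$var_covariates)
    out$random[[e]] <- list(
      mean  = theta[i + 1L],
      delta = theta[i + 1L + seq_len(q)],
      sigma = theta[i + q + 2L],
      omega = theta[i + q + 2L + seq_len(s)])
    i <- i + 2L + q + s
  }
  out
}
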