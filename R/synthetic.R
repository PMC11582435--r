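#' Declare a covariate-generation scheme
#'
#' Describes the marginal structure of the binary indicator covariates of a
#' casualty record: mutually exclusive blocks (one categorical draw per
#' record, guaranteeing exclusivity) and independent Bernoulli indicators.
#' Exhaustive blocks must have probabilities summing to 1 (small printing
#' slack is renormalised); non-exhaustive blocks may leave a residual
#' "none" category.
#'
#' @param blocks Named list; each element is
#'   `list(names =, probabilities =, exhaustive =)`.
#' @param indicators Named numeric vector of prevalences for independent
#'   indicators.
#' @return An object of class `covariate_scheme`.
#' @export
covariate_scheme <- function(blocks = list(), indicators = numeric(0)) {
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    stopifnot(length(b$names) == length(b$probabilities))
    if (any(b$probabilities < 0) || any(b$probabilities > 1)) {
      stop("block '", nm, "': probabilities must lie in [0,1]")
    }
    s <- sum(b$probabilities)
    if (isTRUE(b$exhaustive)) {
      if (abs(s - 1) > 0.005) {
        stop("block '", nm, "' is exhaustive but probabilities sum to ", s)
      }
      blocks[[nm]]$probabilities <- b$probabilities / s
    } else if (s > 1 + 1e-12) {
      stop("block '", nm, "': probabilities sum to ", s, " > 1")
    }
  }
  if (any(indicators < 0) || any(indicators > 1)) {
    stop("indicator prevalences must lie in [0,1]")
  }
  structure(list(blocks = blocks, indicators = indicators),
            class = "covariate_scheme")
}

#' @export
print.covariate_scheme <- function(x, ...) {
  cat("covariate_scheme:", length(x$blocks), "exclusive blocks,",
      length(x$indicators), "independent indicators,",
      length(scheme_covariates(x)), "covariates total\n")
  invisible(x)
}

scheme_covariates <- function(scheme) {
  c(unlist(lapply(scheme$blocks, `[[`, "names"), use.names = FALSE),
    names(scheme$indicators))
}

#' Default covariate scheme
#'
#' The packaged default emulates the marginal prevalences of a
#' casualty-level motorcycle-crash registry (2015 rainy-season values):
#' counterpart type and collision type as non-exhaustive exclusive blocks;
#' victim role, sex, age band and weekday/weekend as exhaustive blocks;
#' road class / surface / area blocks; and the human-error indicators
#' (speeding, right-of-way, against-flow, overtaking, alcohol) plus helmet
#' use as independent Bernoulli indicators. Blocks are sampled
#' independently of one another, a documented simplification (only the
#' marginals of the source registry are public).
#'
#' @return A [covariate_scheme()].
#' @export
default_scheme <- function() {
  covariate_scheme(
    blocks = list(
      counterpart = list(
        names = c("hit_motorcycle", "hit_pedestrian", "hit_passenger_vehicle"),
        probabilities = c(0.444, 0.267, 0.129), exhaustive = FALSE),
      collision = list(
        names = c("head_on", "rear_end", "right_angle", "side_swipe",
                  "fall_alone"),
        probabilities = c(0.364, 0.164, 0.261, 0.096, 0.047),
        exhaustive = FALSE),
      victim = list(
        names = c("rider", "pillion"),
        probabilities = c(0.668, 0.332), exhaustive = TRUE),
      age = list(
        names = c("age_below_20", "age_20_29", "age_30_39", "age_40_49",
                  "age_above_50"),
        probabilities = c(0.216, 0.420, 0.177, 0.087, 0.099),
        exhaustive = TRUE),
      sex = list(
        names = c("male", "female"),
        probabilities = c(0.795, 0.205), exhaustive = TRUE),
      road_class = list(
        names = c("national_road", "provincial_road", "major_road",
                  "minor_road", "local_road"),
        probabilities = c(0.597, 0.197, 0.022, 0.036, 0.141),
        exhaustive = FALSE),
      surface = list(
        names = c("paved", "cemented"),
        probabilities = c(0.848, 0.032), exhaustive = FALSE),
      area = list(
        names = c("urban", "rural"),
        probabilities = c(0.411, 0.096), exhaustive = FALSE),
      day = list(
        names = c("weekday", "weekend"),
        probabilities = c(0.671, 0.329), exhaustive = TRUE)),
    indicators = c(helmet = 0.137, speeding = 0.326,
                   not_respect_row = 0.099, against_flow = 0.057,
                   overtaking = 0.129, alcohol = 0.165))
}

#' Schema implied by a covariate scheme
#'
#' @param scheme A [covariate_scheme()].
#' @param severity_coding Passed to [crash_schema()].
#' @return A [crash_schema()] whose exclusive blocks mirror the scheme's.
#' @export
scheme_to_schema <- function(scheme, severity_coding = "label") {
  crash_schema(
    covariates = scheme_covariates(scheme),
    exclusive_blocks = lapply(scheme$blocks, `[[`, "names"),
    exhaustive = names(Filter(function(b) isTRUE(b$exhaustive),
                              scheme$blocks)),
    severity_coding = severity_coding)
}

#' Sample covariates from a scheme
#'
#' Each exclusive block is drawn as a single categorical draw per record
#' (guaranteeing mutual exclusivity; non-exhaustive blocks carry an
#' implicit residual category), and each independent indicator as a
#' Bernoulli draw. Deterministic given `seed`.
#'
#' @param scheme A [covariate_scheme()].
#' @param n Number of records.
#' @param seed Integer seed.
#' @return A data.frame of 0/1 indicator columns with `n` rows.
#' @export
sample_covariates <- function(scheme, n, seed) {
  stopifnot(n >= 1)
  with_seed(seed, {
    out <- list()
    for (nm in names(scheme$blocks)) {
      b <- scheme$blocks[[nm]]
      k <- length(b$names)
      pr <- c(b$probabilities, max(0, 1 - sum(b$probabilities)))
      draw <- sample.int(k + 1L, n, replace = TRUE, prob = pr)
      for (i in seq_len(k)) out[[b$names[i]]] <- as.integer(draw == i)
    }
    for (v in names(scheme$indicators)) {
      out[[v]] <- stats::rbinom(n, 1L, scheme$indicators[[v]])
    }
    as.data.frame(out)
  })
}

#' Bundle a specification with true parameter values
#'
#' The ground-truth data-generating process for simulation studies: the
#' coefficient-realization law used generatively.
#'
#' @param spec A [mixl_spec()].
#' @param params Numeric vector of length `n_parameters(spec)` in packing
#'   order (named vectors are checked against [param_names()]).
#' @return An object of class `true_dgp`.
#' @export
true_dgp <- function(spec, params) {
  nm <- param_names(spec)
  if (!is.null(names(params))) {
    miss <- setdiff(nm, names(params))
    if (length(miss)) stop("params missing: ", paste(miss, collapse = ", "))
    params <- params[nm]
  }
  unpack_params(spec, params)
  structure(list(spec = spec, params = setNames(as.numeric(params), nm)),
            class = "true_dgp")
}

#' @export
print.true_dgp <- function(x, ...) {
  cat("true_dgp with K =", length(x$params), "parameters\n")
  print(round(x$params, 4))
  invisible(x)
}

#' Simulate severity outcomes from a data-generating process
#'
#' For each record, random coefficients are realized (standard-normal
#' disturbances, mean shifts and variance scaling per the DGP), utilities
#' are computed and perturbed with independent standard Gumbel errors, and
#' the severity with maximal utility is assigned (Gumbel-max sampling,
#' exactly equivalent to drawing from the conditional logit probabilities).
#' Deterministic given `seed`.
#'
#' @param dgp A [true_dgp()].
#' @param covariates Data.frame of indicator columns (e.g. from
#'   [sample_covariates()]), or a [crash_dataset()] whose severities are
#'   ignored.
#' @param seed Integer seed.
#' @return `covariates` with a `severity` factor column prepended.
#' @export
simulate_outcomes <- function(dgp, covariates, seed) {
  spec <- dgp$spec
  df <- if (inherits(covariates, "crash_dataset")) covariates$data else covariates
  df <- df[, setdiff(names(df), "severity"), drop = FALSE]
  frame <- build_model_frame(df, spec)
  up <- unpack_params(spec, dgp$params)
  n <- frame$n; J <- frame$J
  with_seed(seed, {
    U <- matrix(0, n, J)
    for (j in seq_len(J)) {
      p <- length(spec$fixed[[spec$alternatives[j]]])
      if (p) U[, j] <- frame$Xfix[[j]] %*% up$fixed[[spec$alternatives[j]]]
    }
    for (e in seq_along(frame$re)) {
      re <- frame$re[[e]]; pe <- up$random[[e]]
      v <- stats::rnorm(n)
      b <- pe$mean +
        (if (ncol(re$Z)) as.numeric(re$Z %*% pe$delta) else 0) +
        pe$sigma * exp(if (ncol(re$W)) as.numeric(re$W %*% pe$omega) else 0) * v
      U[, re$alt] <- U[, re$alt] + b * re$x
    }
    gumbel <- -log(-log(matrix(stats::runif(n * J), n, J)))
    sev <- spec$alternatives[max.col(U + gumbel, ties.method = "first")]
    cbind(data.frame(severity = factor(sev, levels = spec$alternatives)), df)
  })
}

#' Season-year record counts of the study window
#'
#' The six season-year cell totals of the three-year study window
#' (2015-2017, rainy and dry), summing to 15,990 casualties.
#'
#' @return Data.frame with columns `year`, `season`, `n`.
#' @export
study_counts <- function() {
  data.frame(year = rep(2015:2017, each = 2),
             season = rep(c("rainy", "dry"), 3),
             n = c(3223L, 2547L, 2843L, 2360L, 2734L, 2283L))
}

#' Generate a full multi-season synthetic study
#'
#' One labelled [crash_dataset()] per season-year cell, each with exactly
#' the requested number of records: covariates from `scheme`, severities
#' from `dgp`. The truth object is returned alongside for parameter
#' recovery testing.
#'
#' @param scheme A [covariate_scheme()] (default [default_scheme()]).
#' @param dgp A [true_dgp()].
#' @param counts Data.frame with columns `year`, `season`, `n`
#'   (default [study_counts()]).
#' @param seed Integer seed; cell seeds are derived deterministically.
#' @return List with elements `datasets` (named list of [crash_dataset()])
#'   and `dgp`.
#' @export
generate_study <- function(scheme = default_scheme(), dgp,
                           counts = study_counts(), seed = 1) {
  stopifnot(all(counts$n > 0))
  schema <- scheme_to_schema(scheme)
  datasets <- list()
  for (i in seq_len(nrow(counts))) {
    lab <- paste(counts$year[i], counts$season[i])
    cell_seed <- (as.integer(seed) * 101L + i * 7919L) %% .Machine$integer.max
    cov <- sample_covariates(scheme, counts$n[i], seed = cell_seed)
    df <- simulate_outcomes(dgp, cov, seed = cell_seed + 1L)
    df$season <- counts$season[i]
    df$year <- counts$year[i]
    datasets[[lab]] <- crash_dataset(df, schema, label = lab)
  }
  list(datasets = datasets, dgp = dgp)
}

#' Packaged example data-generating process
#'
#' A moderate RPL-HMV truth over the [default_scheme()] covariates: SI and
#' FI constants and a few fixed effects, plus one normally distributed
#' random coefficient (speeding on the fatal utility) with one
#' heterogeneity-in-means covariate (male) and one
#' heterogeneity-in-variances covariate (rider). Used by the command-line
#' `simulate` subcommand when no DGP is configured, and convenient for
#' examples.
#'
#' @return A [true_dgp()].
#' @export
default_dgp <- function() {
  spec <- mixl_spec(
    fixed = list(
      SI = c("constant", "hit_pedestrian", "rider", "helmet"),
      FI = c("constant", "hit_pedestrian", "rider", "helmet")),
    random = list(random_coef("FI", "speeding",
                              mean_covariates = "male",
                              var_covariates = "rider")))
  true_dgp(spec, c(-0.5, 0.9, 0.4, -0.3,
                   -1.2, 1.2, 1.0, -0.8,
                   0.8, 0.5, 1.2, 0.3))
}
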