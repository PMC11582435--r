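#' Realize a random coefficient for one casualty
#'
#' Evaluates \eqn{\beta + \delta' z + \sigma \exp(\omega' w) v}: the mean,
#' shifted by the heterogeneity-in-means covariates and scaled in spread by
#' the heterogeneity-in-variances covariates, plus the standard-normal
#' disturbance `v`.
#'
#' @param beta Mean coefficient.
#' @param delta,z Heterogeneity-in-means coefficients and covariate values
#'   (same length; may be empty).
#' @param sigma Standard-deviation parameter.
#' @param omega,w Heterogeneity-in-variances coefficients and covariate
#'   values (same length; may be empty).
#' @param v Standard-normal draw(s); vectorized.
#' @return Realized coefficient value(s), same length as `v`.
#' @export
#' @examples
#' realized_coefficient(0.451, sigma = 1.672, v = 1)  # 2.123
realized_coefficient <- function(beta, delta = numeric(0), z = numeric(0),
                                 sigma = 0, omega = numeric(0),
                                 w = numeric(0), v = 0) {
  stopifnot(length(delta) == length(z), length(omega) == length(w))
  beta + sum(delta * z) + sigma * exp(sum(omega * w)) * v
}

#' Multinomial logit choice probabilities
#'
#' Softmax of the utilities, computed with max-subtraction so that very
#' large utilities do not overflow. Rows of a matrix are treated as
#' observations.
#'
#' @param utilities Numeric vector of per-alternative utilities, or a matrix
#'   with one row per observation.
#' @return Probability vector (or matrix) summing to 1 by row.
#' @export
#' @examples
#' choice_probabilities(c(log(2), 0, 0))  # 0.50 0.25 0.25
choice_probabilities <- function(utilities) {
  if (is.matrix(utilities)) {
    e <- exp(utilities - apply(utilities, 1, max))
    return(e / rowSums(e))
  }
  if (any(!is.finite(utilities))) stop("utilities must be finite")
  e <- exp(utilities - max(utilities))
  e / sum(e)
}

frame_cpp_args <- function(frame) {
  list(Xfix = frame$Xfix,
       reAlt = lapply(frame$re, `[[`, "alt"),
       reX = lapply(frame$re, `[[`, "x"),
       reZ = lapply(frame$re, `[[`, "Z"),
       reW = lapply(frame$re, `[[`, "W"))
}

draws_for <- function(frame, draws, R, burn) {
  nre <- length(frame$re)
  if (nre == 0) return(array(0, dim = c(frame$n, 0, 1)))
  if (is.null(draws)) draws <- normal_halton_draws(frame$n, nre, R, burn)
  d <- dim(draws)
  if (d[1] != frame$n || d[2] != nre) {
    stop("draw array dimensions (", paste(d, collapse = "x"),
         ") do not cover ", frame$n, " observations x ", nre,
         " random dimensions")
  }
  unclass(draws)
}

#' Simulated choice probabilities
#'
#' Approximates the mixed-logit probability — the logit kernel integrated
#' over the random-coefficient distribution — by averaging the kernel over
#' the quasi-random draws. With no random entries (or sigma = 0) this
#' reduces exactly to the analytic multinomial-logit probabilities.
#'
#' @param data A [crash_dataset()] or data.frame of covariates.
#' @param spec A [mixl_spec()].
#' @param params Packed parameter vector (see [param_names()]).
#' @param draws A [normal_halton_draws()] array, or `NULL` to generate one.
#' @param R,burn Draw count and burn-in used when `draws` is `NULL`.
#' @return N x J matrix of probabilities; rows sum to 1.
#' @export
simulated_probability <- function(data, spec, params, draws = NULL,
                                  R = 1000, burn = 100) {
  frame <- build_model_frame(data, spec)
  unpack_params(spec, params)  # length/dimension check
  a <- frame_cpp_args(frame)
  dr <- draws_for(frame, draws, R, burn)
  P <- mixl_eval_cpp(as.numeric(params), integer(frame$n), a$Xfix, a$reAlt,
                     a$reX, a$reZ, a$reW, dr, 3L)$prob
  dimnames(P) <- list(NULL, spec$alternatives)
  P
}

#' Simulated log-likelihood
#'
#' Sum over casualties of the log simulated probability of the observed
#' severity. A simulated probability of exactly zero is reported as an
#' error rather than silently returning `-Inf`.
#'
#' @inheritParams simulated_probability
#' @param gradient If `TRUE`, attach the analytic score vector as attribute
#'   `"gradient"`.
#' @return Scalar log-likelihood.
#' @export
simulated_loglik <- function(data, spec, params, draws = NULL,
                             R = 1000, burn = 100, gradient = FALSE) {
  frame <- build_model_frame(data, spec)
  if (is.null(frame$y)) stop("data has no severity column")
  unpack_params(spec, params)
  a <- frame_cpp_args(frame)
  dr <- draws_for(frame, draws, R, burn)
  res <- mixl_eval_cpp(as.numeric(params), frame$y, a$Xfix, a$reAlt,
                       a$reX, a$reZ, a$reW, dr, if (gradient) 1L else 0L)
  if (isTRUE(res$zero_prob)) {
    stop("simulated probability of an observed outcome is zero; ",
         "increase R or rescale the parameters")
  }
  ll <- res$ll
  if (gradient) attr(ll, "gradient") <- as.numeric(res$grad)
  ll
}

#' Log-likelihood of the zero model
#'
#' Two conventions are in use for the "log-likelihood at zero" baseline of
#' McFadden's rho-squared: `equal_shares` is the likelihood with all
#' parameters zero, \eqn{N \ln(1/J)}; `constants_only` is the likelihood of
#' the constants-only model, \eqn{\sum_k n_k \ln(n_k/N)}, which only
#' requires the observed severity counts.
#'
#' @param N Number of observations (taken from `dataset` if supplied).
#' @param J Number of alternatives.
#' @param mode `"equal_shares"` or `"constants_only"`.
#' @param dataset A [crash_dataset()]; required for `constants_only`.
#' @return Scalar log-likelihood (<= 0).
#' @export
ll_zero <- function(N = NULL, J = 3, mode = c("equal_shares", "constants_only"),
                    dataset = NULL) {
  mode <- match.arg(mode)
  if (!is.null(dataset)) N <- n_records(dataset)
  stopifnot(N >= 1, J >= 1)
  if (mode == "equal_shares") return(N * log(1 / J))
  if (is.null(dataset)) stop("constants_only mode requires a dataset")
  nk <- table(dataset$data$severity)
  nk <- nk[nk > 0]
  if (length(nk) < length(severity_levels())) {
    warning("empty severity categories dropped from the constants-only baseline")
  }
  sum(nk * log(nk / N))
}

#' Akaike information criterion
#' @param K Number of estimated parameters.
#' @param ll Log-likelihood at convergence.
#' @return `2K - 2 ll`.
#' @export
aic <- function(K, ll) 2 * K - 2 * ll

#' McFadden's pseudo r-squared
#' @param ll Log-likelihood at convergence.
#' @param ll0 Log-likelihood at zero (must be negative).
#' @return `1 - ll / ll0`.
#' @export
mcfadden_rho2 <- function(ll, ll0) {
  if (ll0 == 0) stop("ll0 must be nonzero")
  1 - ll / ll0
}

fd_hessian <- function(gradfun, theta, h = 1e-5) {
  K <- length(theta)
  H <- matrix(0, K, K)
  for (k in seq_len(K)) {
    hk <- h * (1 + abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + hk
    tm <- theta; tm[k] <- tm[k] - hk
    H[, k] <- (gradfun(tp) - gradfun(tm)) / (2 * hk)
  }
  (H + t(H)) / 2
}

#' Fit a mixed multinomial logit by simulated maximum likelihood
#'
#' Maximizes the simulated log-likelihood over Halton draws by quasi-Newton
#' (BFGS) ascent with the analytic score. Starting values come from a
#' fixed-parameter multinomial logit fit of the same utility structure
#' (random entries started at their MNL means, sigma at 0.1, delta and
#' omega at 0). Standard errors come from the inverse numerical Hessian of
#' the simulated log-likelihood, with a BHHH (outer-product-of-scores)
#' fallback when the Hessian is not positive definite.
#'
#' Sigma parameters are sign-normalized on output: a normal random
#' coefficient is unchanged under a sign flip of sigma, so `|sigma|` is
#' reported (the standard normalization).
#'
#' @param data A [crash_dataset()] (or data.frame with a `severity` column).
#' @param spec A [mixl_spec()].
#' @param R Number of Halton draws per observation (study default 1000).
#' @param burn Halton burn-in (default 100).
#' @param draws Optional pre-built [normal_halton_draws()].
#' @param start Optional start vector (length K).
#' @param ll0_mode Baseline convention for rho-squared, see [ll_zero()].
#' @param control Passed to [stats::optim()]; defaults
#'   `list(maxit = 500, reltol = 1e-8)`.
#' @return An object of class `mixl_fit`.
#' @export
mixl_fit <- function(data, spec, R = 1000, burn = 100, draws = NULL,
                     start = NULL, ll0_mode = "equal_shares",
                     control = list()) {
  if (is.data.frame(data)) {
    frame <- build_model_frame(data, spec)
    N <- frame$n
  } else {
    frame <- build_model_frame(data, spec)
    N <- n_records(data)
  }
  if (is.null(frame$y)) stop("data has no severity column")
  K <- n_parameters(spec)
  if (N <= K) stop("need more observations than parameters (N > K)")
  control <- modifyList(list(maxit = 500, reltol = 1e-8, fnscale = -1),
                        control)
  a <- frame_cpp_args(frame)
  dr <- draws_for(frame, draws, R, burn)

  evalfun <- function(theta, mode) {
    mixl_eval_cpp(theta, frame$y, a$Xfix, a$reAlt, a$reX, a$reZ, a$reW,
                  dr, mode)
  }
  fn <- function(theta) evalfun(theta, 0L)$ll
  gr <- function(theta) as.numeric(evalfun(theta, 1L)$grad)

  if (is.null(start)) {
    start <- mnl_start(frame, spec, control)
  } else if (length(start) != K) {
    stop("start vector must have length K = ", K)
  }

  # quasi-Newton ascent, restarted until the score is numerically zero
  # (convergence requires both a stationary likelihood value and a small
  # gradient norm; BFGS alone can stop in flat stretches of the simulated
  # surface with the score still non-negligible)
  opt <- stats::optim(start, fn, gr, method = "BFGS", control = control)
  if (max(abs(gr(opt$par))) > 0.05) {
    # one restart when BFGS stopped with a clearly non-zero score (the
    # simulated surface has flat stretches along weakly identified
    # directions where the line search can stall)
    opt2 <- stats::optim(opt$par, fn, gr, method = "BFGS", control = control)
    if (opt2$value >= opt$value) opt <- opt2
  }
  theta <- opt$par
  converged <- opt$convergence == 0 || max(abs(gr(theta))) < 1e-5 * N

  H <- fd_hessian(gr, theta)
  se <- rep(NA_real_, K)
  vcov <- matrix(NA_real_, K, K)
  se_method <- "hessian"
  ih <- tryCatch(solve(-H), error = function(e) NULL)
  if (!is.null(ih) && all(is.finite(diag(ih))) && all(diag(ih) > 0)) {
    vcov <- ih
    se <- sqrt(diag(ih))
  } else {
    sc <- evalfun(theta, 2L)$scores
    bh <- tryCatch(solve(crossprod(sc)), error = function(e) NULL)
    if (!is.null(bh) && all(diag(bh) > 0)) {
      vcov <- bh
      se <- sqrt(diag(bh))
      se_method <- "bhhh"
    } else {
      se_method <- "unavailable"
    }
  }

  # sign-normalize sigmas
  up <- unpack_params(spec, theta)
  nm <- param_names(spec)
  est <- theta
  sigma_idx <- grep("\\(sd\\)$", nm)
  est[sigma_idx] <- abs(est[sigma_idx])
  names(est) <- nm
  names(se) <- nm
  dimnames(vcov) <- list(nm, nm)

  ll <- opt$value
  ll0 <- ll_zero(N = N, J = frame$J, mode = ll0_mode,
                 dataset = if (inherits(data, "crash_dataset")) data else NULL)
  structure(list(spec = spec, estimates = est, raw_estimates = theta,
                 se = se, z = est / se, vcov = vcov,
                 ll = ll, ll0 = ll0, ll0_mode = ll0_mode,
                 K = K, N = N, aic = aic(K, ll),
                 rho2 = mcfadden_rho2(ll, ll0),
                 converged = converged, se_method = se_method,
                 R = if (length(frame$re)) dim(dr)[3] else 0,
                 burn = burn, data = data,
                 label = if (inherits(data, "crash_dataset")) data$label else "",
                 counts = opt$counts),
            class = "mixl_fit")
}

# Fixed-parameter MNL fit used for starting values: random entries are
# treated as fixed, sigma starts at 0.1, delta/omega at 0.
mnl_start <- function(frame, spec, control) {
  fspec <- fixedize_spec(spec)
  fframe <- frame
  fframe$Xfix <- build_fixedized_Xfix(frame, spec)
  fframe$re <- list()
  a <- frame_cpp_args(fframe)
  dr <- array(0, dim = c(frame$n, 0, 1))
  fn <- function(theta)
    mixl_eval_cpp(theta, fframe$y, a$Xfix, a$reAlt, a$reX, a$reZ, a$reW,
                  dr, 0L)$ll
  gr <- function(theta)
    as.numeric(mixl_eval_cpp(theta, fframe$y, a$Xfix, a$reAlt, a$reX, a$reZ,
                             a$reW, dr, 1L)$grad)
  Kf <- n_parameters(fspec)
  opt <- stats::optim(rep(0, Kf), fn, gr, method = "BFGS", control = control)
  # map fixedized estimates back into the random spec's packing
  fnm <- param_names(fspec)
  names(opt$par) <- fnm
  start <- numeric(n_parameters(spec))
  nm <- param_names(spec)
  i <- 0L
  for (a2 in spec$alternatives) {
    for (v in spec$fixed[[a2]]) {
      i <- i + 1L
      start[i] <- opt$par[[paste0("[", a2, "] ", v)]]
    }
  }
  for (rc in spec$random) {
    i <- i + 1L
    start[i] <- opt$par[[paste0("[", rc$alternative, "] ", rc$covariate)]]
    i <- i + length(rc$mean_covariates)        # delta = 0
    i <- i + 1L
    start[i] <- 0.5                            # sigma (see vignette: the
    # simulated likelihood is locally flat in sigma at 0, so a start away
    # from the origin avoids the degenerate stationary point)
    i <- i + length(rc$var_covariates)         # omega = 0
  }
  start
}

# Xfix for the fixedized spec, aligned with fixedize_spec()'s ordering
# (original fixed entries then the randoms' own covariates, per alternative).
build_fixedized_Xfix <- function(frame, spec) {
  out <- frame$Xfix
  for (e in seq_along(spec$random)) {
    rc <- spec$random[[e]]
    j <- match(rc$alternative, spec$alternatives)
    out[[j]] <- cbind(out[[j]], frame$re[[e]]$x)
  }
  out
}

#' @export
print.mixl_fit <- function(x, ...) {
  cat("Mixed multinomial logit fit",
      if (nzchar(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  N =", x$N, " K =", x$K, " R =", x$R, "draws\n")
  cat(sprintf("  LL(0) = %.3f  LL(convergence) = %.3f\n", x$ll0, x$ll))
  cat(sprintf("  AIC = %.3f  McFadden rho2 = %.3f\n", x$aic, x$rho2))
  if (!x$converged) cat("  WARNING: optimizer did not report convergence\n")
  invisible(x)
}

#' @export
summary.mixl_fit <- function(object, ...) {
  tab <- data.frame(estimate = object$estimates, se = object$se,
                    z = object$z,
                    significant_90 = abs(object$z) >= stats::qnorm(0.95))
  out <- list(fit = object, coefficients = tab)
  class(out) <- "summary.mixl_fit"
  out
}

#' @export
print.summary.mixl_fit <- function(x, ...) {
  print(x$fit)
  m <- cbind(Estimate = x$coefficients$estimate,
             `Std.Err` = x$coefficients$se,
             `z` = x$coefficients$z)
  rownames(m) <- rownames(x$coefficients)
  printCoefmat(m, digits = 4)
  invisible(x)
}

#' @export
coef.mixl_fit <- function(object, ...) object$estimates

#' @export
vcov.mixl_fit <- function(object, ...) object$vcov

#' @export
logLik.mixl_fit <- function(object, ...) {
  structure(object$ll, df = object$K, nobs = object$N, class = "logLik")
}
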