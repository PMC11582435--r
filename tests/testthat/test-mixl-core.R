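test_that("coefficient realization follows the mean/variance-shift formula", {
  expect_equal(realized_coefficient(0.451, v = 0), 0.451)
  expect_equal(realized_coefficient(0.451, sigma = 1.672, v = 1), 2.123)
  expect_equal(realized_coefficient(0, delta = 0.5, z = 1, sigma = 1,
                                    omega = log(2), w = 1, v = -1), -1.5)
  # vectorized over draws
  expect_equal(realized_coefficient(1, sigma = 2, v = c(-1, 0, 1)),
               c(-1, 1, 3))
})

test_that("choice probabilities are a numerically safe softmax", {
  expect_equal(choice_probabilities(c(0, 0, 0)), rep(1 / 3, 3))
  expect_equal(choice_probabilities(c(log(2), 0, 0)), c(0.5, 0.25, 0.25))
  p <- choice_probabilities(c(1000, 0, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p[1], 1, tolerance = 1e-12)
  # location invariance
  u <- c(0.3, -1.2, 0.8)
  expect_equal(choice_probabilities(u), choice_probabilities(u + 57))
  # matrix form normalizes rows
  m <- choice_probabilities(rbind(u, u + 3))
  expect_equal(rowSums(m), c(1, 1), ignore_attr = TRUE)
})

test_that("simulated probabilities collapse to analytic MNL without mixing", {
  spec <- toy_spec(random = FALSE)
  theta <- c(-0.4, 0.7, -1.0, 1.1)
  df <- toy_covariates(50)
  P <- simulated_probability(df, spec, theta)
  expect_equal(rowSums(P), rep(1, 50), tolerance = 1e-12)
  expect_equal(P, oracle_probs(df, spec, theta), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("sigma = 0 reduces the mixed model to the MNL at the means", {
  spec <- toy_spec()
  df <- toy_covariates(40)
  dr <- normal_halton_draws(40, 1, 25)
  theta <- c(-0.4, 0.7, -1.0, 1.1, 0.6, 0.2, 0, 0.5)  # sigma = 0
  P <- simulated_probability(df, spec, theta, draws = dr)
  # with sigma = 0 every draw realizes the same coefficient, so the analytic
  # reference is the oracle evaluated at a single zero draw
  Pan <- oracle_probs(df, spec, theta, draws = array(0, c(40, 1, 1)))
  expect_equal(P, Pan, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("one-dimensional mixing matches deterministic quadrature", {
  # single record, random constant N(mu, s) on FI; oracle by adaptive
  # quadrature of the logit kernel against the normal density
  spec <- mixl_spec(fixed = list(SI = "constant"),
                    random = list(random_coef("FI", "constant")))
  df <- data.frame(dummy = 1)
  mu <- 0.4; s <- 1; c_si <- -0.2
  theta <- c(c_si, mu, s)
  dr <- normal_halton_draws(1, 1, 10000)
  P <- simulated_probability(df, spec, theta, draws = dr)
  kernel <- function(v, k) {
    u <- cbind(0, c_si, mu + s * v)
    e <- exp(u - apply(u, 1, max))
    (e / rowSums(e))[, k] * dnorm(v)
  }
  Pq <- vapply(1:3, function(k)
    integrate(kernel, -Inf, Inf, k = k, rel.tol = 1e-10)$value, 0)
  expect_equal(as.numeric(P), Pq, tolerance = 5e-4)
  expect_equal(sum(P), 1, tolerance = 1e-12)
})

test_that("simulated log-likelihood equals brute-force enumeration on toys", {
  spec <- toy_spec()
  theta <- c(-0.4, 0.7, -1.0, 1.1, 0.6, 0.2, 0.9, 0.5)
  dgp <- true_dgp(spec, theta)
  df <- simulate_outcomes(dgp, toy_covariates(5), seed = 51)
  dr <- normal_halton_draws(5, 1, 30)
  ll <- simulated_loglik(df, spec, theta, draws = dr)
  expect_equal(ll, oracle_loglik(df, spec, theta, dr), tolerance = 1e-12)
  # ten records, two random entries
  spec2 <- mixl_spec(
    fixed = list(SI = "constant", FI = "constant"),
    random = list(random_coef("SI", "a1"),
                  random_coef("FI", "b", var_covariates = "w")))
  theta2 <- c(-0.2, -0.8, 0.5, 1.0, 1.2, 0.8, -0.4)
  dgp2 <- true_dgp(spec2, theta2)
  df2 <- simulate_outcomes(dgp2, toy_covariates(10, seed = 8), seed = 52)
  dr2 <- normal_halton_draws(10, 2, 40)
  expect_equal(simulated_loglik(df2, spec2, theta2, draws = dr2),
               oracle_loglik(df2, spec2, theta2, dr2), tolerance = 1e-12)
})

test_that("all-zero parameters give the closed-form equal-shares likelihood", {
  spec <- toy_spec(random = FALSE)
  dgp <- true_dgp(spec, rep(0, 4))
  df <- simulate_outcomes(dgp, toy_covariates(200), seed = 53)
  expect_equal(simulated_loglik(df, spec, rep(0, 4)), 200 * log(1 / 3))
})

test_that("a dominant observed utility drives the log-likelihood to zero", {
  spec <- mixl_spec(fixed = list(FI = "constant"))
  df <- data.frame(severity = "FI", dummy = 1)
  ll <- simulated_loglik(df, spec, 1000)
  expect_gt(ll, -1e-10)
  expect_lte(ll, 0)
})

test_that("simulated likelihood stabilizes as the draw count grows", {
  spec <- toy_spec()
  theta <- c(-0.4, 0.7, -1.0, 1.1, 0.6, 0.2, 0.9, 0.5)
  dgp <- true_dgp(spec, theta)
  df <- simulate_outcomes(dgp, toy_covariates(100), seed = 54)
  lls <- vapply(c(250, 1000, 4000), function(R)
    simulated_loglik(df, spec, theta, R = R), 0)
  expect_lt(abs(lls[2] - lls[3]), abs(lls[1] - lls[2]) + 0.05)
  expect_lt(abs(lls[2] - lls[3]), 0.05)
})

test_that("analytic score matches central finite differences", {
  spec <- toy_spec()
  theta <- c(-0.4, 0.7, -1.0, 1.1, 0.6, 0.2, 0.9, 0.5)
  dgp <- true_dgp(spec, theta)
  df <- simulate_outcomes(dgp, toy_covariates(60), seed = 55)
  dr <- normal_halton_draws(60, 1, 40)
  g <- attr(simulated_loglik(df, spec, theta, draws = dr, gradient = TRUE),
            "gradient")
  ng <- vapply(seq_along(theta), function(k) {
    h <- 1e-6 * (1 + abs(theta[k]))
    tp <- theta; tp[k] <- tp[k] + h
    tm <- theta; tm[k] <- tm[k] - h
    (simulated_loglik(df, spec, tp, draws = dr) -
       simulated_loglik(df, spec, tm, draws = dr)) / (2 * h)
  }, 0)
  expect_equal(g, ng, tolerance = 1e-5)
})

test_that("zero-model likelihood conventions are the documented closed forms", {
  expect_equal(ll_zero(N = 3223, J = 3), -3540.827, tolerance = 1e-3)
  sch <- crash_schema("x")
  df <- data.frame(
    severity = rep(severity_levels(), times = c(925, 1502, 796)), x = 0)
  ds <- crash_dataset(df, sch)
  expect_equal(ll_zero(dataset = ds, mode = "constants_only"), -3414.634,
               tolerance = 1e-3)
  expect_equal(ll_zero(N = 1, J = 1), 0)
  expect_error(ll_zero(N = 10, mode = "constants_only"), "dataset")
})

test_that("fit statistics satisfy their defining identities", {
  expect_equal(aic(23, -2587.037), 5220.074)
  expect_equal(mcfadden_rho2(-5, -5), 0)
  expect_error(mcfadden_rho2(-1, 0), "nonzero")
  # internal consistency on a fitted object
  spec <- toy_spec(random = FALSE)
  dgp <- true_dgp(spec, c(-0.4, 0.7, -1.0, 1.1))
  df <- simulate_outcomes(dgp, toy_covariates(300), seed = 56)
  fit <- mixl_fit(df, spec)
  expect_equal(fit$aic, 2 * fit$K - 2 * fit$ll)
  expect_equal(fit$rho2, 1 - fit$ll / fit$ll0)
  expect_gte(fit$ll, fit$ll0)  # zero model is nested
  expect_equal(fit$K, n_parameters(spec))
})

test_that("parameter packing is stable and validated", {
  spec <- toy_spec()
  expect_equal(param_names(spec),
               c("[SI] constant", "[SI] a1", "[FI] constant", "[FI] b",
                 "[FI] a1 (mean)", "[FI] a1 : b (het.mean)", "[FI] a1 (sd)",
                 "[FI] a1 : w (het.sd)"))
  expect_equal(n_parameters(spec), 8)
  expect_error(simulated_probability(toy_covariates(5), spec, rep(0, 3)),
               "length")
  expect_error(mixl_spec(fixed = list(SI = c("constant", "constant"))),
               "duplicate")
})
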