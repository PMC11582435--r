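test_that("seasonal chi-square statistics match the published 2015/2016 values", {
  t15 <- chi_square_independence(contingency_table(table2_counts(2015)))
  expect_equal(t15$statistic, 6.210, tolerance = 5e-4)
  expect_equal(t15$df, 2)
  expect_equal(t15$bracket, ">95 %")
  t16 <- chi_square_independence(contingency_table(table2_counts(2016)))
  expect_equal(t16$statistic, 7.448, tolerance = 5e-4)
  expect_output(print(t15), "6.210 \\(2\\) \\[>95 %\\]")
})

test_that("chi-square statistic has its structural invariances", {
  m <- table2_counts(2015)
  s0 <- chi_square_independence(m)$statistic
  # simultaneous row and column permutation
  mp <- m[c(2, 1), c(3, 1, 2)]
  expect_equal(chi_square_independence(mp)$statistic, s0)
  # linear scaling in the counts
  expect_equal(chi_square_independence(3 * m)$statistic, 3 * s0)
  # proportional rows give exactly zero
  expect_equal(chi_square_independence(rbind(c(10, 20, 30),
                                             c(20, 40, 60)))$statistic, 0)
  expect_error(chi_square_independence(rbind(c(0, 0, 0), c(1, 2, 3))),
               "margin")
})

make_split <- function(theta_a, theta_b, n = 800, seed = 1,
                       spec = toy_spec(random = FALSE)) {
  da <- simulate_outcomes(true_dgp(spec, theta_a),
                          toy_covariates(n, seed = seed), seed = seed + 1)
  db <- simulate_outcomes(true_dgp(spec, theta_b),
                          toy_covariates(n, seed = seed + 2), seed = seed + 3)
  list(a = da, b = db, spec = spec)
}

test_that("self-transfer yields a zero statistic", {
  sp <- make_split(c(-0.4, 0.7, -1.0, 1.1), c(-0.4, 0.7, -1.0, 1.1),
                   n = 300, seed = 101)
  fit <- mixl_fit(sp$a, sp$spec)
  tst <- lr_transfer_test(fit, sp$a, fit)
  expect_equal(tst$statistic, 0, tolerance = 1e-8)
  expect_equal(tst$df, fit$K)
})

test_that("transfer statistic is nonnegative and direction-asymmetric", {
  th_a <- c(-0.4, 0.7, -1.0, 1.1)
  th_b <- c(-0.4, 0.7, -1.0, 0.1)
  sp <- make_split(th_a, th_b, n = 700, seed = 111)
  fa <- mixl_fit(sp$a, sp$spec)
  fb <- mixl_fit(sp$b, sp$spec)
  ab <- lr_transfer_test(fa, sp$b, fb)
  ba <- lr_transfer_test(fb, sp$a, fa)
  expect_gte(ab$statistic, -1e-6)
  expect_gte(ba$statistic, -1e-6)
  expect_false(isTRUE(all.equal(ab$statistic, ba$statistic)))
  expect_error(lr_transfer_test(fa, sp$b, mixl_fit(sp$b, toy_spec())),
               "same specification")
})

test_that("a unit coefficient shift is detected with high power", {
  # two data-generating processes differing by 1.0 in one coefficient
  th_a <- c(-0.4, 0.7, -1.0, 1.1)
  th_b <- th_a; th_b[4] <- th_b[4] - 1.0
  rejections <- vapply(1:5, function(r) {
    sp <- make_split(th_a, th_b, n = 2000, seed = 200 + 10 * r)
    fa <- mixl_fit(sp$a, sp$spec)
    fb <- mixl_fit(sp$b, sp$spec)
    lr_transfer_test(fa, sp$b, fb)$confidence > 0.95
  }, NA)
  expect_true(all(rejections))
})

test_that("pairwise matrices cover all ordered pairs with an empty diagonal", {
  th <- c(-0.4, 0.7, -1.0, 1.1)
  spec <- toy_spec(random = FALSE)
  dss <- lapply(1:3, function(i)
    simulate_outcomes(true_dgp(spec, th), toy_covariates(300, seed = 300 + i),
                      seed = 400 + i))
  names(dss) <- c("2015", "2016", "2017")
  fits <- lapply(dss, mixl_fit, spec = spec)
  mat <- pairwise_test_matrix(fits, dss)
  expect_equal(sum(nzchar(mat)), 6)
  expect_true(all(diag(unclass(mat)) == ""))
  tests <- attr(mat, "tests")
  expect_length(tests, 6)
  expect_equal(tests[["2015 -> 2016"]]$direction,
               c(source = "2015", target = "2016"))
  # identical data and spec in every cell: all statistics collapse to zero
  same <- list(x = dss[[1]], y = dss[[1]])
  fsame <- list(x = fits[[1]], y = fits[[1]])
  mat0 <- pairwise_test_matrix(fsame, same)
  stats0 <- vapply(attr(mat0, "tests"), `[[`, 0, "statistic")
  expect_true(all(abs(stats0) < 1e-8))
})

test_that("confidence brackets follow the conventional thresholds", {
  expect_equal(rpmlogit:::confidence_bracket(0.99995), ">99.99 %")
  expect_equal(rpmlogit:::confidence_bracket(0.996), ">99 %")
  expect_equal(rpmlogit:::confidence_bracket(0.97), ">95 %")
  expect_equal(rpmlogit:::confidence_bracket(0.5), "n.s.")
})
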