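# Model zoo, BIC, likelihood-ratio test, KDE two-sample test, stratified fits.

test_that("through-origin OLS matches hand arithmetic and exact data interpolate", {
  d <- tibble::tibble(q_n = c(0, 1, 2, 3, 0.5, 1.5, 2.5, 0.2, 1.2, 2.2),
                      f_bn = 0)
  d$f_bn <- 0.32 + 0.690 * d$q_n
  zoo <- fit_model_zoo(d)
  lin <- zoo[zoo$form == "linear", ]
  expect_lt(lin$rss, 1e-20)
  expect_equal(c(lin$a, lin$b), c(0.32, 0.690), tolerance = 1e-10)

  # y = ax on (0,1,2,3)/(0,1,2,4): a = sum(xy)/sum(x^2) = 17/14
  x <- c(0, 1, 2, 3); y <- c(0, 1, 2, 4)
  f <- fit_model_zoo(tibble::tibble(q_n = rep(x, 3), f_bn = rep(y, 3)),
                     forms = "proportional")
  expect_equal(f$a, 17 / 14, tolerance = 1e-12)
})

test_that("polynomial fits agree with a brute-force normal-equations solve", {
  set.seed(12)
  x <- runif(60, 0, 2.5)
  y <- 0.2 + 1.1 * x - 0.3 * x^2 + rnorm(60, 0, 0.1)
  zoo <- fit_model_zoo(tibble::tibble(q_n = x, f_bn = y))
  for (form in c("proportional", "linear", "quadratic_origin", "quadratic")) {
    X <- switch(form,
      proportional = cbind(x),
      linear = cbind(1, x),
      quadratic_origin = cbind(x, x^2),
      quadratic = cbind(1, x, x^2)
    )
    beta <- solve(t(X) %*% X, t(X) %*% y)
    row <- zoo[zoo$form == form, ]
    got <- as.numeric(stats::na.omit(c(row$a, row$b, row$c)))
    expect_equal(got, unname(as.vector(beta)), tolerance = 1e-10)
    expect_equal(row$rss, sum((y - X %*% beta)^2), tolerance = 1e-8)
  }
})

test_that("BIC follows the stated convention and its basic monotonicities", {
  expect_equal(bic_score(0.35714, n = 4, k = 1),
               4 * log(0.35714 / 4) + 2 * log(4), tolerance = 1e-12)
  expect_equal(bic_score(0.35714, n = 4, k = 1), -6.891, tolerance = 1e-3)
  # same RSS/n and k, larger n
  expect_equal(bic_score(2, 8, 1) - bic_score(1, 4, 1),
               8 * log(0.25) + 2 * log(8) - 4 * log(0.25) - 2 * log(4))
  # lower RSS at equal k wins
  expect_lt(bic_score(1, 50, 2), bic_score(2, 50, 2))
  expect_error(bic_score(0, 10, 1), "RSS = 0")
  # conventions differ by a constant only
  expect_equal(bic_score(1.3, 40, 2, "gaussian") - bic_score(1.3, 40, 2),
               40 * (log(2 * pi) + 1))
})

test_that("likelihood-ratio test follows the RSS-ratio formula", {
  mk <- function(form, n, k, rss) {
    tibble::tibble(form = form, orientation = "f_bn ~ q_n", n = n, k = k, rss = rss)
  }
  same <- likelihood_ratio_test(mk("linear", 50, 2, 1.2), mk("quadratic", 50, 3, 1.2))
  expect_equal(same$chi_square, 0)
  expect_equal(same$p_value, 1)

  r <- likelihood_ratio_test(mk("linear", 100, 2, exp(1)), mk("quadratic", 100, 3, 1))
  expect_equal(r$chi_square, 100)
  expect_equal(r$df, 1)

  expect_error(
    likelihood_ratio_test(mk("exp_rate", 50, 1, 2), mk("quadratic", 50, 3, 1)),
    "not nested"
  )
})

test_that("stratified linear fits recover global lines and expose curvature", {
  x <- seq(0.05, 2.45, length.out = 90)
  h <- seq(0, 1, length.out = 90)
  lin <- tibble::tibble(q_n = x, f_bn = 0.3 + 0.7 * x, height_fraction = h)
  s <- fit_stratified_linear(lin, n_strata = 3)
  expect_equal(s$b, rep(0.7, 3), tolerance = 1e-9)
  expect_equal(s$a, rep(0.3, 3), tolerance = 1e-9)

  # concave quadratic: secant slopes decrease with increasing Q_n; height
  # tracks Q_n downwards in the lung so order strata by their Q_n midpoint
  quad <- tibble::tibble(q_n = x, f_bn = 1.684 * x - 0.538 * x^2,
                         height_fraction = 1 - h)
  s2 <- fit_stratified_linear(quad, n_strata = 3)
  s2 <- s2[order(s2$x_mid), ]
  expect_true(all(diff(s2$b) < 0))

  one <- fit_stratified_linear(lin, n_strata = 1)
  glob <- fit_model_zoo(lin, forms = "linear")
  expect_equal(one$b, glob$b, tolerance = 1e-12)
  expect_error(fit_stratified_linear(lin[1:8, ], n_strata = 3), "fewer than")
})

test_that("plug-in bandwidths are symmetric positive definite and affine-equivariant", {
  set.seed(5)
  x <- matrix(rnorm(600), ncol = 2)
  h <- bandwidth_plugin(x)
  expect_equal(h, t(h))
  expect_true(all(eigen(h, only.values = TRUE)$values > 0))
  a_mat <- matrix(c(2, 0.5, 0, 1.5), 2, 2)
  h_t <- bandwidth_plugin(x %*% t(a_mat))
  expect_equal(h_t, a_mat %*% h %*% t(a_mat), tolerance = 1e-4)
})

test_that("KDE test is symmetric in its arguments and detects a shift", {
  set.seed(9)
  x <- matrix(rnorm(500), ncol = 2)
  y <- matrix(rnorm(500), ncol = 2)
  k1 <- kde_two_sample_test(x, y)
  k2 <- kde_two_sample_test(y, x)
  expect_equal(k1$p_value, k2$p_value, tolerance = 1e-12)
  expect_equal(k1$statistic, k2$statistic, tolerance = 1e-12)

  y_shift <- matrix(rnorm(1000), ncol = 2) + 1
  x_big <- matrix(rnorm(1000), ncol = 2)
  expect_lt(kde_two_sample_test(x_big, y_shift)$p_value, 1e-3)

  degen <- cbind(rnorm(50), 1)
  expect_error(kde_two_sample_test(degen, x), "zero variance")
})

test_that("KDE test is invariant under a common affine transform (permutation method)", {
  cfg <- phantom_config(seed = 77)
  x <- as.matrix(simulate_coupling_cloud(cfg, "baseline", n_animals = 2)[, c("q_n", "f_bn")])
  y <- as.matrix(simulate_coupling_cloud(cfg, "injury", n_animals = 2)[, c("q_n", "f_bn")])
  a_mat <- matrix(c(1.3, -0.4, 0.2, 0.8), 2, 2)
  shift <- c(2, -1)
  tx <- sweep(x %*% t(a_mat), 2, shift, "+")
  ty <- sweep(y %*% t(a_mat), 2, shift, "+")
  p1 <- kde_two_sample_test(x, y, method = "permutation",
                            n_permutations = 199, seed = 3)$p_value
  p2 <- kde_two_sample_test(tx, ty, method = "permutation",
                            n_permutations = 199, seed = 3)$p_value
  expect_equal(p1, p2, tolerance = 1e-6)
})

test_that("permutation and asymptotic p-values agree on the study-sized clouds", {
  # phantom defaults: the two conditions differ strongly, both methods must
  # call the difference; also check agreement under the null
  diffs <- vapply(1:10, function(s) {
    cfg <- phantom_config(seed = 400 + s)
    x <- as.matrix(simulate_coupling_cloud(cfg, "baseline")[, c("q_n", "f_bn")])
    y <- as.matrix(simulate_coupling_cloud(cfg, "injury")[, c("q_n", "f_bn")])
    pa <- kde_two_sample_test(x, y)$p_value
    pp <- kde_two_sample_test(x, y, method = "permutation",
                              n_permutations = 999, seed = s)$p_value
    abs(pa - pp)
  }, numeric(1))
  expect_lte(stats::median(diffs), 0.02)

  # under the null both methods should mostly agree on *not* rejecting
  null_agree <- vapply(1:10, function(s) {
    set.seed(1500 + s)
    x <- matrix(rnorm(300), ncol = 2)
    y <- matrix(rnorm(300), ncol = 2)
    pa <- kde_two_sample_test(x, y)$p_value
    pp <- kde_two_sample_test(x, y, method = "permutation",
                              n_permutations = 999, seed = s)$p_value
    (pa < 0.01) == (pp < 0.01)
  }, logical(1))
  expect_gte(mean(null_agree), 0.8)
})

test_that("tidiers return one-row summaries", {
  set.seed(2)
  k <- kde_two_sample_test(matrix(rnorm(100), ncol = 2), matrix(rnorm(100), ncol = 2))
  expect_equal(nrow(tidy(k)), 1)
  expect_true(all(c("statistic", "p_value", "z") %in% names(tidy(k))))
  l <- likelihood_ratio_test(
    tibble::tibble(form = "linear", orientation = "o", n = 50, k = 2, rss = 2),
    tibble::tibble(form = "quadratic", orientation = "o", n = 50, k = 3, rss = 1.5)
  )
  expect_equal(nrow(tidy(l)), 1)
})
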