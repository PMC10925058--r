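# Sokoloff forward model, its inversion, and the 13NN estimator.

test_that("forward model matches the closed-form solution for a constant input", {
  cp <- constant_input_function(1)
  # no uptake: pure vascular term
  cur0 <- sokoloff_curve(0.1, 0, 0, 0, cp, c(50, 500))
  expect_equal(cur0$activity, c(0.1, 0.1), tolerance = 1e-12)
  # irreversible uptake without efflux: C_e = K1 t (rates per minute)
  cur1 <- sokoloff_curve(0.1, 0.01, 0, 0, cp, 100)
  expect_equal(cur1$activity, 0.1 + 0.01 * 100 / 60, tolerance = 1e-8)
  # full cascade vs analytic two-compartment solution
  k1 <- 0.005; k2 <- 0.05; k3 <- 0.01
  lam <- (k2 + k3) / 60; kk1 <- k1 / 60; kk3 <- k3 / 60
  t <- c(120, 480, 840)
  analytic <- 0.15 + kk1 / lam * (1 - exp(-lam * t)) +
    kk3 * kk1 * (t / lam - (1 - exp(-lam * t)) / lam^2)
  cur2 <- sokoloff_curve(0.15, k1, k2, k3, cp, t)
  expect_equal(cur2$activity, analytic, tolerance = 1e-8)
})

test_that("frame-averaged activity is linear in F_b and K1 when there is no efflux", {
  cp <- test_input_function()
  frames <- default_fdg_frames()
  base <- sokoloff_forward(0.1, 0.01, 0, 0, cp, frames)
  half <- sokoloff_forward(0.05, 0.005, 0, 0, cp, frames)
  expect_equal(half$activity, base$activity / 2, tolerance = 1e-12)
})

test_that("forward model refuses frames outside the input function support", {
  cp <- test_input_function(t_end = 300)
  expect_error(
    sokoloff_forward(0.1, 0.005, 0.05, 0.01, cp, default_fdg_frames()),
    "cover"
  )
})

test_that("fitting a noiseless forward simulation recovers the parameters", {
  cp <- test_input_function()
  truth <- c(f_b = 0.15, k1 = 0.005, k2 = 0.05, k3 = 0.01)
  tac <- sokoloff_forward(truth[["f_b"]], truth[["k1"]], truth[["k2"]], truth[["k3"]],
                          cp, default_fdg_frames())
  fit <- fit_sokoloff(tac, cp)
  expect_true(fit$converged)
  expect_lt(max(abs(fit$estimate - truth)), 1e-3)
  expect_named(tidy(fit), c("term", "estimate"))
})

test_that("an all-zero TAC yields a zero blood fraction and influx", {
  cp <- test_input_function()
  tac <- default_fdg_frames()
  tac$activity <- 0
  fit <- fit_sokoloff(tac, cp)
  expect_equal(unname(fit$estimate[["f_b"]]), 0, tolerance = 1e-8)
  expect_equal(unname(fit$estimate[["k1"]]), 0, tolerance = 1e-8)
})

test_that("fitted F_b increases with true F_b (noiseless monotonicity)", {
  cp <- test_input_function()
  fits <- vapply(c(0.05, 0.15, 0.3), function(fb) {
    tac <- sokoloff_forward(fb, 0.005, 0.05, 0.01, cp, default_fdg_frames())
    fit_sokoloff(tac, cp, multistart = fast_multistart())$estimate[["f_b"]]
  }, numeric(1))
  expect_true(all(diff(fits) > 0))
})

test_that("13NN estimator reads plateau, peak and shunt as constructed", {
  flat <- nn13_test_tac(plateau = 5, peak = 5)
  est <- estimate_nn13_perfusion(flat)
  expect_equal(est$plateau, 5, tolerance = 1e-9)
  expect_equal(est$shunt_component, 0)
  expect_equal(est$q_r, 5, tolerance = 1e-9)

  shunted <- nn13_test_tac(plateau = 5, peak = 8)
  est2 <- estimate_nn13_perfusion(shunted)
  expect_equal(est2$peak, 8)
  expect_equal(est2$q_r, 8, tolerance = 1e-9)

  zero <- nn13_test_tac(plateau = 0, peak = 0)
  expect_equal(estimate_nn13_perfusion(zero)$q_r, 0)

  expect_error(estimate_nn13_perfusion(flat, plateau_window_s = 40, peak_window_s = 30),
               "overlap")

  # relative shunt definition scales the plateau instead
  est3 <- estimate_nn13_perfusion(shunted, shunt_definition = "relative")
  expect_equal(est3$q_r, 5 / (1 - 3 / 8), tolerance = 1e-9)
})

test_that("13NN estimate is stable under frame re-binning", {
  frames3 <- tibble::tibble(frame_start_s = seq(0, 57, 3), frame_end_s = seq(3, 60, 3))
  q2 <- estimate_nn13_perfusion(nn13_test_tac(5, 8))$q_r
  q3 <- estimate_nn13_perfusion(nn13_test_tac(5, 8, frames = frames3))$q_r
  expect_lt(abs(q2 - q3) / q2, 0.02)
})
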