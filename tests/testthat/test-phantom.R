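# Synthetic phantom and study generator.

test_that("identical configuration and seed regenerate the study bit-identically", {
  cfg <- tiny_config(seed = 42)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1$truth, b2$truth)
  expect_identical(b1$tacs, b2$tacs)
  expect_identical(b1$hemodynamics, b2$hemodynamics)
})

test_that("input function is zero at t = 0, peaks near the end of the infusion, and is dose-linear", {
  times <- seq(0, 900, by = 1)
  cp <- make_input_function(times)
  expect_equal(cp$cp[1], 0)
  t_peak <- cp$time_s[which.max(cp$cp)]
  expect_gte(t_peak, 55)
  expect_lte(t_peak, 70)
  expect_true(all(cp$cp >= 0))
  cp2 <- make_input_function(times, params = list(dose = 80))
  expect_equal(cp2$cp, 2 * cp$cp)
  expect_error(make_input_function(c(0, 10, 5)), "increasing")
})

test_that("noiseless baseline phantom puts the normalized cloud exactly on a constraint-compatible line", {
  # a + b = 1 satisfies the identity mean(F_bn * F_tis,n) = 1, so the loop
  # through absolute quantities and back is exact
  cfg <- phantom_config(
    residual_sd_baseline = 0, residual_sd_injury = 0,
    coupling_baseline = coupling_model("linear", c(a = 0.31, b = 0.69)),
    seed = 5
  )
  ph <- build_phantom(cfg, 1, "baseline")
  tab <- tibble::tibble(
    f_gas = ph$f_gas_true, f_b = ph$f_b_true, q_r = ph$q_r_true
  ) |>
    tissue_fractions() |>
    normalize_metrics()
  expect_lt(max(abs(tab$f_bn - (0.31 + 0.69 * tab$q_n))), 1e-9)
  expect_lt(max(abs(tab$q_n - ph$q_n_true)), 1e-9)
  expect_lt(max(abs(tab$f_bn - ph$f_bn_true)), 1e-9)
})

test_that("with the default coefficients the noiseless loop recovers the realized (projected) model", {
  cfg <- phantom_config(residual_sd_baseline = 0, residual_sd_injury = 0, seed = 5)
  ph <- build_phantom(cfg, 1, "baseline")
  realized <- attr(ph, "coupling_realized")$coefficients
  # projection scales the printed model by the weighted mean of predictions
  expect_equal(attr(ph, "c_factor"), 0.32 + 0.690, tolerance = 1e-10)
  tab <- tibble::tibble(f_gas = ph$f_gas_true, f_b = ph$f_b_true, q_r = ph$q_r_true) |>
    tissue_fractions() |>
    normalize_metrics()
  expect_lt(max(abs(tab$f_bn - (realized[1] + realized[2] * tab$q_n))), 1e-9)
  # the realized line stays within 2% of the printed one
  expect_lt(max(abs(realized - c(0.32, 0.690)) / c(0.32, 0.690)), 0.02)
})

test_that("injury perfusion is depressed at the top of the lung", {
  ph <- build_phantom(phantom_config(seed = 2), 1, "injury")
  top <- ph$q_r_true[ph$layer == max(ph$layer)]
  bottom <- ph$q_r_true[ph$layer == 1]
  expect_true(all(top < bottom))
  # top two layers essentially unperfused
  expect_lt(max(ph$q_r_true[ph$layer >= 14]) / max(ph$q_r_true), 1e-6)
  # non-dependent injury ROIs shunt
  expect_true(all(ph$shunt_true[ph$height_fraction > 0.8] > 0))
  expect_true(all(ph$shunt_true[ph$height_fraction < 0.5] == 0))
})

test_that("gas, blood and tissue fractions partition unity exactly", {
  for (cond in c("baseline", "injury")) {
    ph <- build_phantom(phantom_config(seed = 3), 2, cond)
    expect_equal(ph$f_gas_true + ph$f_b_true + ph$f_tis_true, rep(1, nrow(ph)))
    expect_true(all(ph$f_gas_true >= 0 & ph$f_b_true >= 0 & ph$f_tis_true >= 0))
    expect_true(all(diff(ph$height_fraction[ph$axial_section == 1]) > 0))
  }
})

test_that("FDG TAC simulation matches the forward model and its noise is unbiased", {
  cfg <- tiny_config(seed = 8)
  ph <- build_phantom(cfg, 1, "baseline")
  roi <- ph[1, ]
  cp <- test_input_function()
  noiseless <- simulate_fdg_tac(roi, cp)
  fwd <- sokoloff_forward(roi$f_b_true, roi$k1_true, roi$k2_true, roi$k3_true,
                          cp, default_fdg_frames())
  expect_equal(noiseless$activity, fwd$activity, tolerance = 1e-12)

  zero_roi <- roi
  zero_roi$f_b_true <- 0; zero_roi$k1_true <- 0
  expect_equal(simulate_fdg_tac(zero_roi, cp)$activity,
               rep(0, nrow(default_fdg_frames())))

  reps <- vapply(1:100, function(i) {
    simulate_fdg_tac(roi, cp, noise_scale = 0.05, seed = i)$activity
  }, numeric(nrow(noiseless)))
  mc_mean <- rowMeans(reps)
  se <- apply(reps, 1, sd) / sqrt(ncol(reps))
  expect_true(all(abs(mc_mean - noiseless$activity) <= 3 * se + 1e-12))
})

test_that("13NN curves expose plateau and shunt peak by construction", {
  flat <- nn13_test_tac(plateau = 5, peak = 5)
  last15 <- flat[flat$frame_start_s >= 45, ]
  expect_true(all(abs(last15$activity - 5) / 5 < 0.01))

  shunted <- nn13_test_tac(plateau = 5, peak = 8)
  expect_equal(max(shunted$activity), 8)

  zero <- tibble::tibble(q_r_true = 0, shunt_true = 0)
  expect_equal(simulate_nn13_tac(zero)$activity, rep(0, 30))
})

test_that("study bundles have the right shape and exercise the missing-CO rule", {
  b <- simulate_study(phantom_config(n_animals = 5, seed = 21))
  counts <- dplyr::count(b$truth, condition)
  expect_equal(counts$n, c(150, 150))
  expect_equal(sum(is.na(b$hemodynamics$co_l_min)), 1)
  missing <- b$hemodynamics[is.na(b$hemodynamics$co_l_min), ]
  expect_equal(missing$condition, "injury")

  b1 <- simulate_study(tiny_config(seed = 22))
  expect_equal(dplyr::count(b1$truth, condition)$n, c(30, 30))

  b_nc <- simulate_study(phantom_config(n_animals = 2, missing_co = FALSE, seed = 23))
  expect_equal(sum(is.na(b_nc$hemodynamics$co_l_min)), 0)
})

test_that("residual scatter about the generating model is higher at baseline than injury", {
  resid_sd <- function(cloud, model) {
    sd(cloud$f_bn - predict(model, cloud$q_n))
  }
  cfg0 <- phantom_config()
  hits <- vapply(1:30, function(s) {
    cfg <- phantom_config(seed = 3000 + s)
    rb <- resid_sd(simulate_coupling_cloud(cfg, "baseline"), cfg$coupling_baseline)
    ri <- resid_sd(simulate_coupling_cloud(cfg, "injury"), cfg$coupling_injury)
    rb > ri
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("study bundles round-trip through the on-disk layout", {
  dir <- withr::local_tempdir()
  b <- simulate_study(tiny_config(seed = 31))
  write_study_bundle(b, dir)
  expect_true(file.exists(file.path(dir, "manifest.yaml")))
  b2 <- read_study_bundle(dir)
  expect_equal(nrow(b2$truth), nrow(b$truth))
  expect_equal(b2$tacs$activity, b$tacs$activity)
})
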