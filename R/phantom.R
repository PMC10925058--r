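# Synthetic lung phantom: ground-truth generator for the study conditions.

#' Configure the synthetic lung phantom
#'
#' Builds the configuration object used by [build_phantom()] and
#' [simulate_study()]. The defaults emulate the study design this package
#' targets: 5 animals, 30 regions of interest each (15 isogravitational
#' layers x 2 axial sections), two conditions (baseline and endotoxin lung
#' injury), a linear F_bn-Q_n coupling at baseline and a
#' quadratic-through-origin coupling at injury, with more residual scatter
#' at baseline than injury.
#'
#' @param n_animals Number of animals (default 5).
#' @param n_layers Number of vertical (isogravitational) layers (default 15).
#' @param n_axial Number of axial sections (default 2).
#' @param coupling_baseline,coupling_injury [coupling_model()] objects giving
#'   the F_bn ~ Q_n relationship per condition. Defaults are the linear model
#'   `F_bn = 0.32 + 0.690 Q_n` (baseline) and the through-origin quadratic
#'   `F_bn = 1.684 Q_n - 0.538 Q_n^2` (injury).
#' @param residual_sd_baseline,residual_sd_injury Gaussian residual standard
#'   deviation of F_bn about the coupling model, per condition (defaults
#'   0.15 and 0.08; baseline must exceed injury).
#' @param perfusion_gradient List with components `baseline` and `injury`
#'   parameterizing the vertical perfusion profile. Baseline is an affine
#'   decrease with height with dependent:non-dependent ratio `ratio`;
#'   injury is a convex power decay `((h0 - h)/h0)^p` reaching zero above
#'   height `h0`.
#' @param tissue_profile List with `baseline` and `injury` components
#'   `c(intercept, slope)` for the tissue-fraction profile
#'   `F_tis(h) = intercept + slope * h`.
#' @param mean_blood_fraction Named vector: target mean absolute blood
#'   fraction per condition.
#' @param axial_offset Relative perfusion offset between the two axial
#'   sections (default 0.10, i.e. +/-10%).
#' @param perfusion_jitter_sd Lognormal sd of per-ROI multiplicative
#'   perfusion jitter (default 0.05).
#' @param tissue_jitter_sd Lognormal sd of per-ROI tissue-fraction jitter
#'   (default 0.03).
#' @param shunt_height_onset,shunt_max Injury ROIs with height fraction above
#'   the onset receive a shunt fraction rising linearly to `shunt_max` at the
#'   lung top.
#' @param cardiac_output Named vector of mean cardiac output (l/min) per
#'   condition; per-animal values are jittered around these.
#' @param cardiac_output_jitter_sd Lognormal sd of the per-animal cardiac
#'   output jitter.
#' @param missing_co If `TRUE` (default) one designated animal lacks the
#'   injury cardiac output, exercising the exclusion rule of the adjusted
#'   longitudinal analysis.
#' @param sokoloff_truth Named vector `c(k1, k2, k3)` (1/min; `k1` in
#'   ml/ml/min) of central Sokoloff rate constants; per-ROI truths are
#'   lognormally jittered around these.
#' @param sokoloff_jitter_sd Lognormal sd of the per-ROI rate-constant jitter.
#' @param tac_noise Noise model for simulated time-activity curves: a list
#'   with `fdg_scale` (named per condition; injury is lower, reflecting the
#'   higher injected dose), `nn13_scale`, and `floor` (kBq/ml). Frame noise
#'   is additive Gaussian with sd `scale * sqrt(max(activity, floor))`.
#' @param input_function Parameters of the plasma FDG input function: `dose`
#'   (named per condition, MBq), `cp_per_mbq` (peak plasma concentration per
#'   MBq injected, kBq/ml), `infusion_s`, `frac_fast`, `thalf_fast_s`,
#'   `thalf_slow_s`.
#' @param fdg_frames,nn13_frames Frame schedules (tibbles with
#'   `frame_start_s`, `frame_end_s`); defaults [default_fdg_frames()] and
#'   [default_nn13_frames()].
#' @param seed Integer seed giving bit-identical regeneration.
#' @return A list of class `phantom_config`.
#' @examples
#' cfg <- phantom_config(n_animals = 2, seed = 7)
#' cfg$coupling_baseline
#' @export
phantom_config <- function(n_animals = 5,
                           n_layers = 15,
                           n_axial = 2,
                           coupling_baseline = coupling_model("linear", c(a = 0.32, b = 0.690)),
                           coupling_injury = coupling_model("quadratic_origin", c(a = 1.684, b = -0.538)),
                           residual_sd_baseline = 0.15,
                           residual_sd_injury = 0.08,
                           perfusion_gradient = list(
                             baseline = list(kind = "affine", ratio = 3),
                             injury = list(kind = "power", h0 = 0.9, p = 1.5)
                           ),
                           tissue_profile = list(
                             baseline = c(intercept = 0.35, slope = -0.15),
                             injury = c(intercept = 0.55, slope = -0.35)
                           ),
                           mean_blood_fraction = c(baseline = 0.15, injury = 0.13),
                           axial_offset = 0.10,
                           perfusion_jitter_sd = 0.05,
                           tissue_jitter_sd = 0.03,
                           shunt_height_onset = 0.65,
                           shunt_max = 0.5,
                           cardiac_output = c(baseline = 4.8, injury = 3.7),
                           cardiac_output_jitter_sd = 0.10,
                           missing_co = TRUE,
                           sokoloff_truth = c(k1 = 0.005, k2 = 0.05, k3 = 0.01),
                           sokoloff_jitter_sd = 0.2,
                           tac_noise = list(
                             fdg_scale = c(baseline = 0.05, injury = 0.02),
                             nn13_scale = 0.05,
                             floor = 0.1
                           ),
                           input_function = list(
                             dose = c(baseline = 40, injury = 200),
                             cp_per_mbq = 0.5,
                             infusion_s = 60,
                             frac_fast = 0.6,
                             thalf_fast_s = 120,
                             thalf_slow_s = 1800
                           ),
                           fdg_frames = default_fdg_frames(),
                           nn13_frames = default_nn13_frames(),
                           seed = 1L) {
  cfg <- as.list(environment())
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stopifnot(
    cfg$n_animals >= 1, cfg$n_layers >= 2, cfg$n_axial >= 1,
    cfg$residual_sd_baseline >= 0, cfg$residual_sd_injury >= 0
  )
  if (!inherits(cfg$coupling_baseline, "coupling_model") ||
      !inherits(cfg$coupling_injury, "coupling_model")) {
    cli::cli_abort("{.arg coupling_baseline} and {.arg coupling_injury} must be {.fn coupling_model} objects.")
  }
  if (cfg$residual_sd_baseline < cfg$residual_sd_injury) {
    cli::cli_abort(
      "Residual scatter must be at least as high at baseline as at injury (got {cfg$residual_sd_baseline} < {cfg$residual_sd_injury})."
    )
  }
  if (any(cfg$mean_blood_fraction <= 0 | cfg$mean_blood_fraction >= 1)) {
    cli::cli_abort("{.arg mean_blood_fraction} values must lie in (0, 1).")
  }
  invisible(cfg)
}

#' @export
print.phantom_config <- function(x, ...) {
  cat("<phantom_config>\n")
  cat("  animals:", x$n_animals, " ROIs:", x$n_layers, "layers x", x$n_axial, "sections\n")
  cat("  baseline coupling: "); print(x$coupling_baseline)
  cat("  injury coupling:   "); print(x$coupling_injury)
  cat("  residual sd: baseline", x$residual_sd_baseline, "/ injury", x$residual_sd_injury, "\n")
  cat("  seed:", x$seed, "\n")
  invisible(x)
}

#' Default dynamic frame schedules
#'
#' `default_fdg_frames()` is a 15-min dynamic FDG schedule (6 x 10 s,
#' 8 x 30 s, 10 x 60 s). `default_nn13_frames()` covers a 60-s breathhold
#' with 30 x 2 s frames.
#'
#' @return A tibble with columns `frame_start_s` and `frame_end_s`.
#' @export
default_fdg_frames <- function() {
  durations <- c(rep(10, 6), rep(30, 8), rep(60, 10))
  ends <- cumsum(durations)
  tibble::tibble(frame_start_s = ends - durations, frame_end_s = ends)
}

#' @rdname default_fdg_frames
#' @export
default_nn13_frames <- function() {
  ends <- seq(2, 60, by = 2)
  tibble::tibble(frame_start_s = ends - 2, frame_end_s = ends)
}

# Vertical perfusion profile evaluated at height fractions h in [0, 1]
# (0 = most dependent). Returned on an arbitrary positive scale.
perfusion_profile <- function(h, grad) {
  if (identical(grad$kind, "affine")) {
    # dependent:non-dependent ratio r: q(0)/q(1) = r with mean 1 over [0,1]
    r <- grad$ratio
    top <- 2 / (r + 1)
    bottom <- 2 * r / (r + 1)
    bottom + (top - bottom) * h
  } else if (identical(grad$kind, "power")) {
    pmax(0, (grad$h0 - h) / grad$h0)^grad$p
  } else {
    cli::cli_abort("Unknown perfusion gradient kind {.val {grad$kind}}.")
  }
}

condition_field <- function(x, condition) {
  if (is.list(x) && !is.null(x[[condition]])) x[[condition]] else x[[condition]]
}

#' Build one synthetic lung phantom
#'
#' Generates the per-ROI ground truth for one animal under one condition:
#' layer geometry, gas / blood / tissue fractions, regional perfusion,
#' shunt fractions and Sokoloff rate constants. Perfusion follows the
#' condition's vertical profile (gradual decrease with height at baseline;
#' steep convex decrease reaching zero in the top layers at injury). The
#' blood fraction is generated from perfusion through the condition's
#' coupling model in normalized space plus a Gaussian residual, then
#' back-transformed so that running the downstream normalization algebra on
#' the absolute quantities recovers the intended F_bn-Q_n cloud.
#'
#' The intended normalized cloud is projected onto the algebraic constraint
#' `mean(F_bn * F_tis,n) = 1` that downstream normalization enforces; the
#' projection rescales the coupling prediction by its weighted mean `c`.
#' The phantom therefore records both the configured coupling model and the
#' realized one (`attr(., "coupling_realized")`, coefficients divided by
#' `c`); the two coincide exactly when the configured coefficients already
#' satisfy the constraint.
#'
#' @param config A [phantom_config()].
#' @param animal_id Integer animal index (1-based).
#' @param condition `"baseline"` or `"injury"`.
#' @param seed Optional integer seed; defaults to a sub-seed derived from
#'   `config$seed`, the animal and the condition.
#' @return A tibble of class `lung_phantom`, one row per ROI, with ground
#'   truth columns (`f_gas_true`, `f_b_true`, `q_r_true`, `shunt_true`,
#'   `k1_true`, `k2_true`, `k3_true`) and the intended normalized cloud
#'   (`q_n_true`, `f_bn_true`).
#' @examples
#' ph <- build_phantom(phantom_config(seed = 1), animal_id = 1, condition = "baseline")
#' head(ph)
#' @export
build_phantom <- function(config, animal_id, condition = c("baseline", "injury"),
                          seed = NULL) {
  condition <- rlang::arg_match(condition)
  validate_phantom_config(config)
  if (is.null(seed)) {
    seed <- (config$seed %% 1000000L) * 2000L + animal_id * 2L +
      (condition == "injury") + 7L
  }

  n_layers <- config$n_layers
  n_axial <- config$n_axial
  layer <- rep(seq_len(n_layers), times = n_axial)
  section <- rep(seq_len(n_axial), each = n_layers)
  h <- (layer - 0.5) / n_layers
  n_roi <- length(layer)

  grad <- config$perfusion_gradient[[condition]]
  tis <- config$tissue_profile[[condition]]
  coupling <- if (condition == "baseline") config$coupling_baseline else config$coupling_injury
  resid_sd <- if (condition == "baseline") config$residual_sd_baseline else config$residual_sd_injury
  m_fb <- config$mean_blood_fraction[[condition]]

  with_seed_opt(seed, {
    # perfusion shape: vertical profile x axial offset x mild ROI jitter
    axial_mult <- 1 + config$axial_offset * (2 * (section - 1) / max(1, n_axial - 1) - 1) *
      (n_axial > 1)
    q_raw <- perfusion_profile(h, grad) * axial_mult *
      exp(rnorm(n_roi, 0, config$perfusion_jitter_sd))

    # tissue fraction profile (recovered exactly downstream: F_gas is set last)
    f_tis <- (tis[["intercept"]] + tis[["slope"]] * h) *
      exp(rnorm(n_roi, 0, config$tissue_jitter_sd))
    f_tis <- pmin(pmax(f_tis, 0.02), 0.9)
    f_tis_n <- f_tis / mean(f_tis)

    # intended normalized perfusion: mean(q_n * f_tis_n) = 1 exactly
    denom <- mean(q_raw * f_tis_n)
    if (denom <= 0) cli::cli_abort("Degenerate perfusion profile: non-positive weighted mean.")
    q_n <- q_raw / denom

    # intended normalized blood volume from the coupling model + residual,
    # resampled within bounds, then projected onto mean(f_bn * f_tis_n) = 1
    f_pred <- predict(coupling, q_n)
    f_bn <- f_pred + rnorm(n_roi, 0, resid_sd)
    lo <- 0.02
    hi <- (0.98 - f_tis) / (f_tis_n * m_fb) # keeps F_gas >= 0.02
    bad <- which(f_bn < lo | f_bn > hi)
    tries <- 0L
    while (length(bad) > 0 && tries < 100L) {
      f_bn[bad] <- f_pred[bad] + rnorm(length(bad), 0, resid_sd)
      if (resid_sd == 0) f_bn[bad] <- pmin(pmax(f_bn[bad], lo), hi[bad])
      bad <- which(f_bn < lo | f_bn > hi)
      tries <- tries + 1L
    }
    if (length(bad) > 0) {
      cli::cli_abort(
        "Coupling model yields blood fractions outside (0, 1 - F_gas) for ROI{?s} {bad} after 100 resampling attempts."
      )
    }
    c_factor <- mean(f_bn * f_tis_n)
    f_bn <- f_bn / c_factor

    f_b <- f_bn * f_tis_n * m_fb
    f_gas <- 1 - f_tis - f_b
    q_scale <- config$cardiac_output[[condition]] * 1000 * 0.7 / n_roi
    q_r <- q_n * f_tis_n * q_scale

    shunt <- if (condition == "injury") {
      pmax(0, (h - config$shunt_height_onset) / (1 - config$shunt_height_onset)) *
        config$shunt_max
    } else {
      rep(0, n_roi)
    }

    sk <- config$sokoloff_truth
    jit <- function(mu) mu * exp(rnorm(n_roi, 0, config$sokoloff_jitter_sd))
    roi_volume <- 45 * (0.75 + 0.5 * sin(pi * h))

    out <- tibble::tibble(
      animal = as.integer(animal_id),
      condition = condition,
      roi_id = (section - 1L) * n_layers + layer,
      layer = as.integer(layer),
      axial_section = as.integer(section),
      height_fraction = h,
      f_gas_true = f_gas,
      f_b_true = f_b,
      f_tis_true = f_tis,
      q_r_true = q_r,
      shunt_true = shunt,
      roi_volume_ml = roi_volume,
      k1_true = jit(sk[["k1"]]),
      k2_true = jit(sk[["k2"]]),
      k3_true = jit(sk[["k3"]]),
      q_n_true = q_n,
      f_bn_true = f_bn
    )
    out <- dplyr::arrange(out, .data$axial_section, .data$layer)
    structure(
      out,
      condition = condition,
      animal_id = animal_id,
      coupling_configured = coupling,
      coupling_realized = rescale_coupling(coupling, c_factor),
      c_factor = c_factor,
      class = c("lung_phantom", class(out))
    )
  })
}

#' Simulate F_bn-Q_n point clouds directly from the coupling models
#'
#' Generates normalized perfusion values from the phantom's vertical profile
#' (normalized to mean 1 within each animal) and normalized blood volume
#' from the condition's coupling model plus Gaussian residual, without
#' passing through the absolute-quantity back-transformation. This is the
#' generator used for coefficient-recovery experiments, where the printed
#' coupling coefficients themselves are the ground truth.
#'
#' @inheritParams build_phantom
#' @param n_animals Number of animals (30 ROIs each).
#' @param seed Integer seed.
#' @return A tibble with columns `animal`, `roi_id`, `height_fraction`,
#'   `condition`, `q_n`, `f_bn`.
#' @examples
#' cloud <- simulate_coupling_cloud(phantom_config(), "baseline", seed = 1)
#' nrow(cloud)
#' @export
simulate_coupling_cloud <- function(config = phantom_config(),
                                    condition = c("baseline", "injury"),
                                    n_animals = config$n_animals,
                                    seed = config$seed) {
  condition <- rlang::arg_match(condition)
  grad <- config$perfusion_gradient[[condition]]
  coupling <- if (condition == "baseline") config$coupling_baseline else config$coupling_injury
  resid_sd <- if (condition == "baseline") config$residual_sd_baseline else config$residual_sd_injury
  n_layers <- config$n_layers
  n_axial <- config$n_axial

  with_seed_opt(seed, {
    purrr::map_dfr(seq_len(n_animals), function(a) {
      layer <- rep(seq_len(n_layers), times = n_axial)
      section <- rep(seq_len(n_axial), each = n_layers)
      h <- (layer - 0.5) / n_layers
      axial_mult <- 1 + config$axial_offset *
        (2 * (section - 1) / max(1, n_axial - 1) - 1) * (n_axial > 1)
      q <- perfusion_profile(h, grad) * axial_mult *
        exp(rnorm(length(h), 0, config$perfusion_jitter_sd))
      q_n <- q / mean(q)
      f_bn <- predict(coupling, q_n) + rnorm(length(h), 0, resid_sd)
      tibble::tibble(
        animal = a,
        roi_id = (section - 1L) * n_layers + layer,
        height_fraction = h,
        condition = condition,
        q_n = q_n,
        f_bn = f_bn
      )
    })
  })
}
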