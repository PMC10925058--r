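# Tracer time-activity curve simulation and full study bundles.

# Additive pseudo-Poisson noise: sd proportional to sqrt(signal) with a floor.
add_tac_noise <- function(activity, scale, floor) {
  if (scale <= 0) return(activity)
  activity + rnorm(length(activity), 0, scale * sqrt(pmax(activity, floor)))
}

#' Simulate a dynamic FDG time-activity curve for one ROI
#'
#' The noiseless curve is the Sokoloff forward model evaluated at the ROI's
#' ground-truth parameters and frame-averaged; optional noise is additive
#' Gaussian with sd `scale * sqrt(max(activity, floor))`, independent across
#' frames (pseudo-Poisson, mimicking PET count statistics).
#'
#' @param roi One row of a [build_phantom()] tibble.
#' @param input_function Plasma input function covering the frames.
#' @param frames Frame schedule; default [default_fdg_frames()].
#' @param noise_scale Noise scale (0 disables noise).
#' @param noise_floor Signal floor (kBq/ml) for the noise sd.
#' @param seed Optional seed for the noise draw.
#' @return A `tac` tibble (`frame_start_s`, `frame_end_s`, `activity`,
#'   `tracer`).
#' @export
simulate_fdg_tac <- function(roi, input_function, frames = default_fdg_frames(),
                             noise_scale = 0, noise_floor = 0.1, seed = NULL) {
  assert_cols(roi, c("f_b_true", "k1_true", "k2_true", "k3_true"), "simulate_fdg_tac")
  stopifnot(nrow(roi) == 1)
  if (max(frames$frame_end_s) - min(frames$frame_start_s) < 600) {
    cli::cli_abort("FDG frames must cover at least 10 min.")
  }
  tac <- sokoloff_forward(roi$f_b_true, roi$k1_true, roi$k2_true, roi$k3_true,
                          input_function, frames)
  with_seed_opt(seed, {
    tac$activity <- add_tac_noise(tac$activity, noise_scale, noise_floor)
  })
  tac
}

# Piecewise-linear breathhold retention curve. All breakpoints are chosen so
# that with the default 2-s frames the peak frames average exactly to the
# peak level and the terminal frames sit exactly on the plateau:
# rise to the plateau over [0, 6] s, a trapezoidal shunt transient with flat
# top [12, 16] s decaying to zero by 26 s.
nn13_curve <- function(t, plateau, peak) {
  rise <- pmin(1, t / 6)
  bump_up <- pmin(1, pmax(0, (t - 6) / 6))
  bump_down <- pmin(1, pmax(0, (26 - t) / 10))
  bump <- pmin(bump_up, bump_down)
  plateau * rise + (peak - plateau) * bump
}

#' Simulate a 13NN breathhold time-activity curve for one ROI
#'
#' The retention curve rises to a plateau proportional to aerated perfusion
#' `Q_r (1 - shunt)`; if the ROI shunts, an early transient peak of height
#' `Q_r * shunt` above the plateau appears and decays back before 30 s. By
#' construction [estimate_nn13_perfusion()] recovers
#' `plateau + (peak - plateau) = Q_r` (in activity units) exactly on the
#' noiseless curve.
#'
#' @param roi One row of a [build_phantom()] tibble (`q_r_true`,
#'   `shunt_true`).
#' @param frames Frame schedule spanning the 60-s breathhold; default
#'   [default_nn13_frames()].
#' @param activity_per_flow Activity (kBq/ml) per unit of regional flow;
#'   an arbitrary common scale that cancels in normalization.
#' @inheritParams simulate_fdg_tac
#' @return A `tac` tibble with `tracer = "nn13"`.
#' @export
simulate_nn13_tac <- function(roi, frames = default_nn13_frames(),
                              activity_per_flow = 0.05,
                              noise_scale = 0, noise_floor = 0.1, seed = NULL) {
  assert_cols(roi, c("q_r_true", "shunt_true"), "simulate_nn13_tac")
  stopifnot(nrow(roi) == 1)
  if (max(frames$frame_end_s) < 60) {
    cli::cli_abort("13NN frames must span the 60-s breathhold.")
  }
  peak <- roi$q_r_true * activity_per_flow
  plateau <- peak * (1 - roi$shunt_true)
  # exact frame averages of the piecewise-linear curve
  breaks <- c(0, 6, 12, 16, 26, 60)
  avg <- vapply(seq_len(nrow(frames)), function(i) {
    a <- frames$frame_start_s[i]; b <- frames$frame_end_s[i]
    pts <- sort(unique(c(a, b, breaks[breaks > a & breaks < b])))
    vals <- nn13_curve(pts, plateau, peak)
    sum((vals[-1] + vals[-length(vals)]) / 2 * diff(pts)) / (b - a)
  }, numeric(1))
  out <- tibble::tibble(
    frame_start_s = frames$frame_start_s,
    frame_end_s = frames$frame_end_s,
    activity = avg,
    tracer = "nn13"
  )
  with_seed_opt(seed, {
    out$activity <- add_tac_noise(out$activity, noise_scale, noise_floor)
  })
  class(out) <- c("tac", class(out))
  out
}

#' Simulate a complete two-condition PET study
#'
#' Generates phantoms, input functions, FDG and 13NN time-activity curves
#' and the hemodynamic context for `n_animals` animals under both
#' conditions. Regenerating with the same configuration (including its seed)
#' is bit-identical.
#'
#' @param config A [phantom_config()].
#' @return A list of class `study_bundle` with elements `truth` (all
#'   phantom rows), `tacs` (long format: one row per ROI x tracer x frame),
#'   `input_functions`, `hemodynamics` (cardiac output per animal-condition;
#'   the designated animal's injury value is `NA` when
#'   `config$missing_co` is set), `coupling_realized` (per condition), and
#'   `config`.
#' @examples
#' bundle <- simulate_study(phantom_config(n_animals = 1, seed = 3))
#' dplyr::count(bundle$truth, condition)
#' @export
simulate_study <- function(config = phantom_config()) {
  validate_phantom_config(config)
  conditions <- c("baseline", "injury")
  seeds <- derive_seeds(config$seed, config$n_animals * 2L + 1L)
  co_seed <- seeds[length(seeds)]

  truth <- list(); tacs <- list(); ifs <- list(); realized <- list()
  k <- 0L
  for (a in seq_len(config$n_animals)) {
    for (cond in conditions) {
      k <- k + 1L
      ph <- build_phantom(config, a, cond)
      if (is.null(realized[[cond]])) realized[[cond]] <- list()
      realized[[cond]][[a]] <- attr(ph, "coupling_realized")

      ifp <- config$input_function
      cp_times <- sort(unique(c(seq(0, 120, by = 2),
                                seq(125, max(config$fdg_frames$frame_end_s), by = 5))))
      input_fn <- make_input_function(
        cp_times,
        params = list(dose = ifp$dose[[cond]], cp_per_mbq = ifp$cp_per_mbq,
                      infusion_s = ifp$infusion_s, frac_fast = ifp$frac_fast,
                      thalf_fast_s = ifp$thalf_fast_s, thalf_slow_s = ifp$thalf_slow_s)
      )
      fdg_scale <- config$tac_noise$fdg_scale[[cond]]
      nn_scale <- config$tac_noise$nn13_scale
      floor <- config$tac_noise$floor

      roi_seeds <- derive_seeds(seeds[k], nrow(ph) * 2L)
      roi_tacs <- purrr::map_dfr(seq_len(nrow(ph)), function(i) {
        roi <- ph[i, ]
        fdg <- simulate_fdg_tac(roi, input_fn, config$fdg_frames,
                                noise_scale = fdg_scale, noise_floor = floor,
                                seed = roi_seeds[2 * i - 1])
        nn <- simulate_nn13_tac(roi, config$nn13_frames,
                                noise_scale = nn_scale, noise_floor = floor,
                                seed = roi_seeds[2 * i])
        dplyr::bind_rows(fdg, nn) |>
          dplyr::mutate(animal = roi$animal, condition = roi$condition,
                        roi_id = roi$roi_id, .before = 1)
      })

      truth[[k]] <- tibble::as_tibble(ph)
      tacs[[k]] <- roi_tacs
      ifs[[k]] <- dplyr::mutate(input_fn, animal = a, condition = cond, .before = 1)
    }
  }

  hemo <- with_seed_opt(co_seed, {
    purrr::map_dfr(seq_len(config$n_animals), function(a) {
      jit <- exp(rnorm(2, 0, config$cardiac_output_jitter_sd))
      tibble::tibble(
        animal = a,
        condition = conditions,
        co_l_min = config$cardiac_output[conditions] * jit
      )
    })
  })
  if (isTRUE(config$missing_co)) {
    hemo$co_l_min[hemo$animal == config$n_animals & hemo$condition == "injury"] <- NA_real_
  }

  structure(
    list(
      truth = dplyr::bind_rows(truth),
      tacs = dplyr::bind_rows(tacs),
      input_functions = dplyr::bind_rows(ifs),
      hemodynamics = hemo,
      coupling_realized = realized,
      config = config
    ),
    class = "study_bundle"
  )
}

#' @export
print.study_bundle <- function(x, ...) {
  cat("<study_bundle>\n")
  cat("  truth rows:", nrow(x$truth), "  TAC rows:", nrow(x$tacs), "\n")
  if (!is.null(x$config)) {
    cat("  animals:", x$config$n_animals,
        " ROIs/animal-condition:", x$config$n_layers * x$config$n_axial, "\n")
    cat("  seed:", x$config$seed, "\n")
  }
  invisible(x)
}

#' Write / read a study bundle as plain files
#'
#' The on-disk layout is a directory with a YAML `manifest.yaml` (counts,
#' seed, configuration summary) and CSV tables `truth.csv`, `tacs.csv`,
#' `input_functions.csv`, `hemodynamics.csv`.
#'
#' @param bundle A [simulate_study()] result.
#' @param dir Output directory (created if needed).
#' @return `write_study_bundle()` returns `dir` invisibly;
#'   `read_study_bundle()` returns a `study_bundle` (without the original
#'   configuration object; the manifest records its hash and seed).
#' @export
write_study_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "study_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(bundle$truth, file.path(dir, "truth.csv"))
  readr::write_csv(bundle$tacs, file.path(dir, "tacs.csv"))
  readr::write_csv(bundle$input_functions, file.path(dir, "input_functions.csv"))
  readr::write_csv(bundle$hemodynamics, file.path(dir, "hemodynamics.csv"))
  manifest <- list(
    created_by = paste0("perfvol ", as.character(utils::packageVersion("perfvol"))),
    seed = bundle$config$seed,
    n_animals = bundle$config$n_animals,
    n_rois = bundle$config$n_layers * bundle$config$n_axial,
    config_hash = rlang::hash(bundle$config),
    tables = c("truth.csv", "tacs.csv", "input_functions.csv", "hemodynamics.csv")
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' @rdname write_study_bundle
#' @export
read_study_bundle <- function(dir) {
  manifest <- yaml::read_yaml(file.path(dir, "manifest.yaml"))
  out <- list(
    truth = readr::read_csv(file.path(dir, "truth.csv"), show_col_types = FALSE),
    tacs = readr::read_csv(file.path(dir, "tacs.csv"), show_col_types = FALSE),
    input_functions = readr::read_csv(file.path(dir, "input_functions.csv"), show_col_types = FALSE),
    hemodynamics = readr::read_csv(file.path(dir, "hemodynamics.csv"), show_col_types = FALSE),
    manifest = manifest,
    config = NULL
  )
  class(out) <- "study_bundle"
  out
}
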