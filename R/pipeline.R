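# End-to-end pipeline: simulate -> fit kinetics -> regionalize -> analyze ->
# report. Every stage output is a plain tibble so stages are independently
# re-runnable and auditable.

#' Configure a pipeline run
#'
#' @param phantom A [phantom_config()].
#' @param kinetics List of kinetic-fitting options: `plateau_window_s`,
#'   `peak_window_s` (13NN windows), `shunt_definition`, `multistart`
#'   (data frame of Sokoloff starts).
#' @param stats List of statistical options: `kde_method`, `kde_bandwidth`,
#'   `bic_convention`, `n_strata`, `n_levels` (vertical profile levels).
#' @param seed Seed for the whole run (defaults to the phantom seed).
#' @return A list of class `run_config`.
#' @export
run_config <- function(phantom = phantom_config(),
                       kinetics = list(),
                       stats = list(),
                       seed = phantom$seed) {
  kinetics <- utils::modifyList(
    list(plateau_window_s = 15, peak_window_s = 30,
         shunt_definition = "absolute", multistart = default_multistart()),
    kinetics
  )
  stats <- utils::modifyList(
    list(kde_method = "asymptotic", kde_bandwidth = "plugin",
         bic_convention = "rss", n_strata = 3, n_levels = 5),
    stats
  )
  phantom$seed <- as.integer(seed)
  validate_phantom_config(phantom)
  structure(list(phantom = phantom, kinetics = kinetics, stats = stats,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' Fit both tracers for every ROI of a study bundle
#'
#' Runs the Sokoloff fit on each ROI's FDG curve (yielding the blood
#' fraction `f_b`) and the plateau/peak estimator on each 13NN curve
#' (yielding regional perfusion `q_r`), and joins the ground-truth gas
#' fraction and geometry needed downstream.
#'
#' @param bundle A [simulate_study()] bundle.
#' @param kinetics Kinetic options as in [run_config()].
#' @param progress Emit a progress message per animal-condition.
#' @return A tibble with one row per ROI: identifiers, `f_gas`, fitted
#'   `f_b`, `q_r`, `roi_volume_ml`, and the fit diagnostics `fdg_rss`,
#'   `fdg_converged`.
#' @export
fit_bundle_kinetics <- function(bundle, kinetics = list(), progress = FALSE) {
  stopifnot(inherits(bundle, "study_bundle"))
  kin <- utils::modifyList(
    list(plateau_window_s = 15, peak_window_s = 30,
         shunt_definition = "absolute", multistart = default_multistart()),
    kinetics
  )
  groups <- dplyr::distinct(bundle$truth, .data$animal, .data$condition)
  purrr::map_dfr(seq_len(nrow(groups)), function(gi) {
    a <- groups$animal[gi]; cond <- groups$condition[gi]
    if (progress) cli::cli_inform("Fitting kinetics: animal {a}, {cond}")
    input_fn <- dplyr::filter(bundle$input_functions,
                              .data$animal == a, .data$condition == cond)
    truth <- dplyr::filter(bundle$truth, .data$animal == a, .data$condition == cond)
    tacs <- dplyr::filter(bundle$tacs, .data$animal == a, .data$condition == cond)
    purrr::map_dfr(truth$roi_id, function(rid) {
      roi <- truth[truth$roi_id == rid, ]
      fdg <- tacs[tacs$roi_id == rid & tacs$tracer == "fdg", ]
      nn <- tacs[tacs$roi_id == rid & tacs$tracer == "nn13", ]
      if (all(abs(fdg$activity) < 1e-12)) {
        fb_fit <- list(estimate = c(f_b = 0, k1 = 0, k2 = 0, k3 = 0),
                       rss = 0, converged = TRUE)
      } else {
        fb_fit <- fit_sokoloff(fdg, input_fn, multistart = kin$multistart)
      }
      nn_est <- estimate_nn13_perfusion(nn, kin$plateau_window_s, kin$peak_window_s,
                                        kin$shunt_definition)
      tibble::tibble(
        animal = a, condition = cond, roi_id = rid,
        layer = roi$layer, axial_section = roi$axial_section,
        height_fraction = roi$height_fraction,
        f_gas = roi$f_gas_true,
        f_b = fb_fit$estimate[["f_b"]],
        q_r = nn_est$q_r,
        roi_volume_ml = roi$roi_volume_ml,
        fdg_rss = fb_fit$rss,
        fdg_converged = fb_fit$converged
      )
    })
  })
}

#' Compute the full regional table from fitted quantities
#'
#' Applies the normalization algebra ([tissue_fractions()] then
#' [normalize_metrics()]) per animal-condition.
#'
#' @param fits Output of [fit_bundle_kinetics()] (or any table with
#'   `animal`, `condition`, `f_gas`, `f_b`, `q_r`).
#' @return The input with `f_tis`, `f_tis_n`, `q_n`, `f_bn` added.
#' @export
regional_table <- function(fits) {
  fits |> tissue_fractions() |> normalize_metrics()
}

#' Per-level vertical profiles
#'
#' Groups ROIs into `n_levels` bands of relative height and summarizes the
#' normalized (and, when present, adjusted) quantities per band. Empty
#' levels are reported with `n = 0` rather than dropped.
#'
#' @param data Regional table with `height_fraction`, `q_n`, `f_bn`
#'   (optionally `q_a`, `f_ba`).
#' @param n_levels Number of height levels (default 5).
#' @return A tibble with one row per condition x level: means and sds.
#' @export
vertical_profiles <- function(data, n_levels = 5) {
  assert_cols(data, c("height_fraction", "q_n", "f_bn"), "vertical_profiles")
  breaks <- seq(0, 1, length.out = n_levels + 1)
  data$level <- pmin(pmax(findInterval(data$height_fraction, breaks,
                                       rightmost.closed = TRUE), 1L), n_levels)
  has_adj <- all(c("q_a", "f_ba") %in% names(data))
  groups <- intersect(c("condition"), names(data))
  grid <- if (length(groups)) {
    tidyr::expand_grid(dplyr::distinct(data, .data$condition),
                       level = seq_len(n_levels))
  } else {
    tibble::tibble(level = seq_len(n_levels))
  }
  summ <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(groups, "level")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      height_mid = mean(.data$height_fraction),
      q_n_mean = mean(.data$q_n), q_n_sd = sd(.data$q_n),
      f_bn_mean = mean(.data$f_bn), f_bn_sd = sd(.data$f_bn),
      q_a_mean = if (has_adj) mean(.data$q_a) else NA_real_,
      q_a_sd = if (has_adj) sd(.data$q_a) else NA_real_,
      f_ba_mean = if (has_adj) mean(.data$f_ba) else NA_real_,
      f_ba_sd = if (has_adj) sd(.data$f_ba) else NA_real_,
      .groups = "drop"
    )
  out <- dplyr::left_join(grid, summ, by = c(groups, "level"))
  out$n[is.na(out$n)] <- 0L
  out
}

#' Per-ROI longitudinal changes
#'
#' Pairs baseline and injury rows of the adjusted table by ROI and reports
#' the changes `delta_q_a` and `delta_f_ba` (the tabular analogue of the
#' per-layer comet display).
#'
#' @param adjusted Output of [adjust_longitudinal()].
#' @return One row per animal x ROI with baseline values and changes.
#' @export
longitudinal_changes <- function(adjusted) {
  assert_cols(adjusted, c("animal", "condition", "roi_id", "q_a", "f_ba"),
              "longitudinal_changes")
  empty <- tibble::tibble(
    animal = integer(), roi_id = integer(), height_fraction = numeric(),
    q_a_baseline = numeric(), q_a_injury = numeric(),
    f_ba_baseline = numeric(), f_ba_injury = numeric(),
    delta_q_a = numeric(), delta_f_ba = numeric()
  )
  if (nrow(adjusted) == 0 ||
      !all(c("baseline", "injury") %in% adjusted$condition)) {
    return(empty)
  }
  wide <- adjusted |>
    dplyr::select(dplyr::all_of(c("animal", "condition", "roi_id",
                                  "height_fraction", "q_a", "f_ba"))) |>
    tidyr::pivot_wider(names_from = "condition", values_from = c("q_a", "f_ba"))
  wide |>
    dplyr::mutate(
      delta_q_a = .data$q_a_injury - .data$q_a_baseline,
      delta_f_ba = .data$f_ba_injury - .data$f_ba_baseline
    )
}

#' Run the full analysis pipeline
#'
#' Simulates a study, fits both tracers per ROI, computes the regional
#' normalization algebra and the baseline-referenced adjustment, and runs
#' the statistical layer: the two-sample KDE test between the conditions'
#' F_bn-Q_n clouds, the six-model BIC zoo (both variable orientations), the
#' linear-vs-quadratic likelihood-ratio test per condition, stratified
#' linear fits, vertical profiles and the longitudinal change table.
#' Identical configuration (including seed) reproduces the bundle
#' bit-identically.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, every stage output is
#'   persisted as CSV (tables), YAML (config) and JSON-like YAML (test
#'   results), making each stage independently re-runnable.
#' @param progress Emit per-stage messages.
#' @return A list of class `report_bundle` with elements `bundle`, `fits`,
#'   `regional`, `adjusted`, `model_zoo`, `best_models`, `kde`, `lrt`,
#'   `stratified`, `profiles`, `longitudinal`, `provenance`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL, progress = FALSE) {
  stopifnot(inherits(config, "run_config"))
  say <- function(...) if (progress) cli::cli_inform(paste0(...))

  say("Stage 1/5: simulating study (seed ", config$seed, ")")
  bundle <- simulate_study(config$phantom)

  say("Stage 2/5: fitting tracer kinetics for ",
      nrow(dplyr::distinct(bundle$truth, .data$animal, .data$condition)),
      " animal-conditions")
  fits <- fit_bundle_kinetics(bundle, config$kinetics, progress = progress)
  n_bad <- sum(!fits$fdg_converged)
  if (n_bad > 0) say("  ", n_bad, " ROI fit(s) flagged as non-converged")

  say("Stage 3/5: regional normalization")
  regional <- regional_table(fits)
  adjusted <- adjust_longitudinal(regional, bundle$hemodynamics, quiet = !progress)

  say("Stage 4/5: statistics")
  clouds <- split(regional[, c("q_n", "f_bn")], regional$condition)
  # a noiseless cloud is exactly collinear and has no density to compare
  degenerate <- any(vapply(clouds, function(cl) {
    det(stats::cov(as.matrix(cl))) < 1e-12
  }, logical(1)))
  kde <- if (degenerate) {
    say("  KDE test skipped: a condition's cloud is (near-)collinear")
    NULL
  } else {
    kde_two_sample_test(clouds$baseline, clouds$injury,
                        method = config$stats$kde_method,
                        bandwidth = config$stats$kde_bandwidth,
                        seed = config$seed)
  }
  zoo <- purrr::map_dfr(names(clouds), function(cond) {
    fit_model_zoo(clouds[[cond]], orientation = "both",
                  convention = config$stats$bic_convention) |>
      dplyr::mutate(condition = cond, .before = 1)
  })
  lrt <- purrr::map(names(clouds), function(cond) {
    z <- zoo[zoo$condition == cond & grepl("^f_bn", zoo$orientation), ]
    likelihood_ratio_test(z[z$form == "linear", ], z[z$form == "quadratic", ])
  })
  names(lrt) <- names(clouds)
  stratified <- purrr::map_dfr(names(clouds), function(cond) {
    fit_stratified_linear(regional[regional$condition == cond, ],
                          n_strata = config$stats$n_strata,
                          convention = config$stats$bic_convention) |>
      dplyr::mutate(condition = cond, .before = 1)
  })

  say("Stage 5/5: report tables")
  profiles <- vertical_profiles(
    if (nrow(adjusted) > 0) adjusted else regional,
    config$stats$n_levels
  )
  longitudinal <- longitudinal_changes(adjusted)

  best <- zoo |>
    dplyr::group_by(.data$condition) |>
    dplyr::group_modify(~ best_model(.x)) |>
    dplyr::ungroup()

  report <- structure(
    list(
      bundle = bundle,
      fits = fits,
      regional = regional,
      adjusted = adjusted,
      model_zoo = zoo,
      best_models = best,
      kde = kde,
      lrt = lrt,
      stratified = stratified,
      profiles = profiles,
      longitudinal = longitudinal,
      provenance = list(
        seed = config$seed,
        config_hash = rlang::hash(config),
        package_version = as.character(utils::packageVersion("perfvol")),
        timestamp = NA_character_
      )
    ),
    class = "report_bundle"
  )
  if (!is.null(out_dir)) write_report_bundle(report, out_dir, config)
  report
}

#' @export
print.report_bundle <- function(x, ...) {
  cat("<report_bundle>\n")
  cat("  regional rows:", nrow(x$regional),
      " adjusted rows:", nrow(x$adjusted), "\n")
  if (!is.null(x$kde)) {
    cat("  KDE test p =", format.pval(x$kde$p_value, digits = 4), "\n")
  }
  bm <- x$best_models[grepl("^f_bn", x$best_models$orientation), ]
  for (i in seq_len(nrow(bm))) {
    cat("  best model (", bm$condition[i], "): ", bm$label[i], "\n", sep = "")
  }
  invisible(x)
}

# Persist every stage output as plain files.
write_report_bundle <- function(report, out_dir, config) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_study_bundle(report$bundle, file.path(out_dir, "bundle"))
  tables <- list(
    fits = report$fits, regional = report$regional, adjusted = report$adjusted,
    model_zoo = report$model_zoo, best_models = report$best_models,
    stratified = report$stratified, profiles = report$profiles,
    longitudinal = report$longitudinal
  )
  for (nm in names(tables)) {
    readr::write_csv(tables[[nm]], file.path(out_dir, paste0(nm, ".csv")))
  }
  results <- list(
    kde = if (is.null(report$kde)) {
      list(skipped = "degenerate (collinear) cloud")
    } else {
      list(statistic = report$kde$statistic, z = report$kde$z,
           p_value = report$kde$p_value, method = report$kde$method)
    },
    lrt = purrr::map(report$lrt, function(l) {
      list(chi_square = l$chi_square, df = l$df, p_value = l$p_value)
    }),
    provenance = report$provenance
  )
  yaml::write_yaml(results, file.path(out_dir, "results.yaml"))
  cfg <- config
  cfg$phantom$coupling_baseline <- unclass(cfg$phantom$coupling_baseline)
  cfg$phantom$coupling_injury <- unclass(cfg$phantom$coupling_injury)
  cfg$phantom$fdg_frames <- as.list(cfg$phantom$fdg_frames)
  cfg$phantom$nn13_frames <- as.list(cfg$phantom$nn13_frames)
  cfg$kinetics$multistart <- as.list(cfg$kinetics$multistart)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}
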