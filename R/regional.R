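# Regional quantities: ROI partitioning and the normalization algebra.
#
# Per animal-condition (30 ROIs):
#   F_tis   = 1 - F_gas - F_b
#   F_tis,n = F_tis / mean(F_tis)
#   Q_n     = Q_r / mean(Q_r) / F_tis,n
#   F_bn    = F_b / mean(F_b) / F_tis,n
# Longitudinal adjustment referenced to baseline:
#   injury:   Q_a = Q_n * CO_INJ / CO_BL,  F_ba = F_bn * V_B,INJ / V_B,BL
#   baseline: Q_a = Q_n,                   F_ba = F_bn
# where V_B = sum(F_b * ROI volume).

regional_groups <- function(data) {
  intersect(c("animal", "condition"), names(data))
}

#' Partition a lung mask into isogravitational ROIs
#'
#' Divides a 3-D lung mask into `n_layers` vertical layers using
#' isogravitational (constant-height) cuts and `n_axial` contiguous axial
#' sections, yielding `n_layers * n_axial` regions of interest. Vertical
#' cuts are placed at equal geometric height over the mask's bounding box
#' (isogravitational planes are geometric, not equal-count; an equal-count
#' alternative is available via `method = "count"`). Layer 1 is the most
#' dependent (lowest vertical index; dorsal for a supine animal).
#'
#' @param mask 3-D logical or 0/1 array (or a file path to a NIfTI volume,
#'   read via \pkg{RNifti} when installed).
#' @param n_layers Number of vertical layers (default 15).
#' @param n_axial Number of axial sections (default 2).
#' @param vertical_axis,axial_axis Array dimensions holding the vertical and
#'   axial directions (defaults 2 and 3).
#' @param method `"height"` (equal geometric height, default) or `"count"`
#'   (equal voxel counts per layer).
#' @return An integer array of the same dimension as `mask`: 0 outside the
#'   mask, otherwise the ROI label `(section - 1) * n_layers + layer`.
#' @examples
#' mask <- array(TRUE, dim = c(4, 30, 10))
#' labels <- partition_rois(mask, n_layers = 15, n_axial = 2)
#' length(setdiff(unique(as.vector(labels)), 0))
#' @export
partition_rois <- function(mask, n_layers = 15, n_axial = 2,
                           vertical_axis = 2, axial_axis = 3,
                           method = c("height", "count")) {
  method <- rlang::arg_match(method)
  if (is.character(mask) && length(mask) == 1) {
    if (!requireNamespace("RNifti", quietly = TRUE)) {
      cli::cli_abort("Reading NIfTI masks requires the {.pkg RNifti} package.")
    }
    mask <- as.array(RNifti::readNifti(mask))
  }
  if (!is.array(mask) || length(dim(mask)) != 3) {
    cli::cli_abort("{.arg mask} must be a 3-D array.")
  }
  if (vertical_axis == axial_axis) {
    cli::cli_abort("{.arg vertical_axis} and {.arg axial_axis} must differ.")
  }
  m <- mask > 0
  if (!any(m)) cli::cli_abort("{.arg mask} is empty.")

  idx <- which(m, arr.ind = TRUE)
  v <- idx[, vertical_axis]
  a <- idx[, axial_axis]
  v_range <- range(v)
  if (diff(v_range) + 1 < n_layers) {
    cli::cli_abort("Mask spans only {diff(v_range) + 1} voxel{?s} vertically; {n_layers} layers requested.")
  }

  if (method == "height") {
    # equal-height cuts over the bounding box; voxel assigned by its center
    rel <- (v - (v_range[1] - 0.5)) / (diff(v_range) + 1)
    layer <- pmin(pmax(ceiling(rel * n_layers), 1L), n_layers)
  } else {
    qs <- stats::quantile(v, probs = seq(0, 1, length.out = n_layers + 1), type = 1)
    layer <- pmin(pmax(findInterval(v, qs[-1], left.open = TRUE) + 1L, 1L), n_layers)
  }

  a_slices <- sort(unique(a))
  cuts <- ceiling(seq_along(a_slices) / (length(a_slices) / n_axial))
  cuts <- pmin(cuts, n_axial)
  section <- cuts[match(a, a_slices)]

  labels <- array(0L, dim = dim(mask))
  labels[m] <- as.integer((section - 1L) * n_layers + layer)
  labels
}

#' Tissue fraction and its normalization
#'
#' Adds `f_tis = 1 - f_gas - f_b` (exact arithmetic) and
#' `f_tis_n = f_tis / mean(f_tis)` per animal-condition group.
#'
#' @param data Tibble with columns `f_gas` and `f_b` (and optionally
#'   `animal`, `condition` defining normalization groups).
#' @return The input with `f_tis` and `f_tis_n` columns added.
#' @examples
#' tissue_fractions(tibble::tibble(f_gas = c(0.7, 0.6), f_b = c(0.1, 0.1)))
#' @export
tissue_fractions <- function(data) {
  assert_cols(data, c("f_gas", "f_b"), "tissue_fractions")
  bad <- which(data$f_gas + data$f_b > 1 + 1e-12)
  if (length(bad) > 0) {
    cli::cli_abort("F_gas + F_b exceeds 1 for row{?s} {bad}.")
  }
  if (any(data$f_gas < 0 | data$f_b < 0)) {
    cli::cli_abort("Fractions must be non-negative.")
  }
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(regional_groups(data)))) |>
    dplyr::mutate(
      f_tis = 1 - .data$f_gas - .data$f_b,
      f_tis_n = .data$f_tis / mean(.data$f_tis)
    ) |>
    dplyr::ungroup()
}

#' Normalized perfusion and blood volume
#'
#' Adds `q_n = q_r / mean(q_r) / f_tis_n` and
#' `f_bn = f_b / mean(f_b) / f_tis_n`, computed within each animal-condition
#' group over its ROIs.
#'
#' @param data Tibble with `q_r`, `f_b` and `f_tis_n` (run
#'   [tissue_fractions()] first), plus optional grouping columns `animal`,
#'   `condition`.
#' @return The input with `q_n` and `f_bn` columns added.
#' @examples
#' df <- tibble::tibble(q_r = c(2, 1, 1), f_b = c(0.2, 0.1, 0.1),
#'                      f_tis_n = c(1, 1, 1))
#' normalize_metrics(df)$q_n
#' @export
normalize_metrics <- function(data) {
  assert_cols(data, c("q_r", "f_b", "f_tis_n"), "normalize_metrics")
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(regional_groups(data)))) |>
    dplyr::mutate(
      q_n = {
        if (mean(.data$q_r) <= 0) {
          cli::cli_abort("mean(Q_r) is not positive; dead study.")
        }
        .data$q_r / mean(.data$q_r) / .data$f_tis_n
      },
      f_bn = {
        if (mean(.data$f_b) <= 0) {
          cli::cli_abort("mean(F_b) is not positive.")
        }
        .data$f_b / mean(.data$f_b) / .data$f_tis_n
      }
    ) |>
    dplyr::ungroup()
}

#' Total pulmonary blood volume in the field of view
#'
#' `V_B = sum(F_b * ROI volume)` per animal-condition.
#'
#' @param data Tibble with `f_b` and `roi_volume_ml` (plus optional grouping
#'   columns).
#' @return A tibble with one row per group and column `v_b_ml`.
#' @examples
#' total_blood_volume(tibble::tibble(f_b = c(0.1, 0.2),
#'                                   roi_volume_ml = c(100, 100)))
#' @export
total_blood_volume <- function(data) {
  assert_cols(data, c("f_b", "roi_volume_ml"), "total_blood_volume")
  if (any(data$roi_volume_ml <= 0)) cli::cli_abort("ROI volumes must be positive.")
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(regional_groups(data)))) |>
    dplyr::summarise(v_b_ml = sum(.data$f_b * .data$roi_volume_ml), .groups = "drop")
}

#' Longitudinal adjustment referenced to baseline
#'
#' Fills per-ROI adjusted perfusion and blood volume: baseline rows keep
#' `q_a = q_n`, `f_ba = f_bn`; injury rows are rescaled by the animal's
#' cardiac output ratio (`q_a = q_n * CO_INJ / CO_BL`) and total pulmonary
#' blood volume ratio (`f_ba = f_bn * V_B,INJ / V_B,BL`). Animals lacking a
#' cardiac output in either condition are excluded from the output (and
#' reported), mirroring the exclusion of unreliable hemodynamic
#' measurements.
#'
#' @param data Regional table with both conditions per animal: columns
#'   `animal`, `condition`, `q_n`, `f_bn`, `f_b`, `roi_volume_ml`.
#' @param hemodynamics Tibble `animal`, `condition`, `co_l_min` (l/min; `NA`
#'   marks a missing measurement).
#' @param quiet Suppress the exclusion message.
#' @return The rows of `data` for animals with complete hemodynamics, with
#'   `q_a` and `f_ba` columns added.
#' @export
adjust_longitudinal <- function(data, hemodynamics, quiet = FALSE) {
  assert_cols(data, c("animal", "condition", "q_n", "f_bn", "f_b", "roi_volume_ml"),
              "adjust_longitudinal")
  assert_cols(hemodynamics, c("animal", "condition", "co_l_min"), "adjust_longitudinal")

  co <- hemodynamics |>
    tidyr::pivot_wider(id_cols = "animal", names_from = "condition",
                       values_from = "co_l_min")
  if (!all(c("baseline", "injury") %in% names(co))) {
    cli::cli_abort("{.arg hemodynamics} must contain both conditions.")
  }
  vb <- total_blood_volume(data) |>
    tidyr::pivot_wider(id_cols = "animal", names_from = "condition",
                       values_from = "v_b_ml", names_prefix = "vb_")

  ratios <- co |>
    dplyr::left_join(vb, by = "animal") |>
    dplyr::mutate(
      co_ratio = .data$injury / .data$baseline,
      vb_ratio = .data$vb_injury / .data$vb_baseline
    )
  excluded <- ratios$animal[is.na(ratios$co_ratio) | is.na(ratios$vb_ratio)]
  kept <- ratios |> dplyr::filter(!.data$animal %in% excluded)
  if (any(kept$co_ratio <= 0, na.rm = TRUE) || any(kept$vb_ratio <= 0, na.rm = TRUE)) {
    cli::cli_abort("Cardiac output and blood volume ratios must be positive.")
  }
  if (length(excluded) > 0 && !quiet) {
    cli::cli_inform("Excluding animal{?s} {excluded} from the adjusted analysis (missing hemodynamics).")
  }

  data |>
    dplyr::filter(!.data$animal %in% excluded) |>
    dplyr::left_join(kept[, c("animal", "co_ratio", "vb_ratio")], by = "animal") |>
    dplyr::mutate(
      q_a = ifelse(.data$condition == "baseline", .data$q_n, .data$q_n * .data$co_ratio),
      f_ba = ifelse(.data$condition == "baseline", .data$f_bn, .data$f_bn * .data$vb_ratio)
    ) |>
    dplyr::select(-"co_ratio", -"vb_ratio")
}
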