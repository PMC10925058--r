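# broom-style tidiers for the package's fitted objects.

#' Tidy a Sokoloff fit
#'
#' @param x A [fit_sokoloff()] result.
#' @param ... Unused.
#' @return A tibble with one row per parameter (`term`, `estimate`).
#' @export
tidy.sokoloff_fit <- function(x, ...) {
  tibble::tibble(term = names(x$estimate), estimate = unname(x$estimate))
}

#' @rdname tidy.sokoloff_fit
#' @export
glance.sokoloff_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, converged = x$converged, n_frames = x$n_frames,
                 n_starts = x$n_starts)
}

#' Tidy a KDE two-sample test
#'
#' @param x A [kde_two_sample_test()] result.
#' @param ... Unused.
#' @return A one-row tibble with the statistic, null parameters and
#'   p-value.
#' @export
tidy.kde_test <- function(x, ...) {
  tibble::tibble(
    statistic = x$statistic, null_mean = x$null_mean, null_sd = x$null_sd,
    z = x$z, p_value = x$p_value, method = x$method, n1 = x$n1, n2 = x$n2
  )
}

#' @rdname tidy.kde_test
#' @export
glance.kde_test <- function(x, ...) tidy(x)

#' Tidy a likelihood-ratio test
#'
#' @param x A [likelihood_ratio_test()] result.
#' @param ... Unused.
#' @return A one-row tibble (`chi_square`, `df`, `p_value`, forms).
#' @export
tidy.lrt_result <- function(x, ...) {
  tibble::tibble(
    reduced = x$reduced, full = x$full,
    chi_square = x$chi_square, df = x$df, p_value = x$p_value
  )
}

#' Tidy an estimated 13NN perfusion
#'
#' @param x An [estimate_nn13_perfusion()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
tidy.nn13_estimate <- function(x, ...) {
  tibble::tibble(plateau = x$plateau, peak = x$peak,
                 shunt_component = x$shunt_component, q_r = x$q_r)
}
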