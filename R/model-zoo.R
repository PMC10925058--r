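# Six-model least-squares zoo with BIC ranking, likelihood-ratio tests of
# nested forms, and stratified piecewise-linear fits.

#' Bayesian information criterion for a least-squares fit
#'
#' Default convention counts the Gaussian error variance as a fitted
#' parameter and drops additive constants:
#' `BIC = n log(RSS / n) + (k + 1) log(n)`. The `"gaussian"` convention is
#' the full `-2 logLik + (k + 1) log(n)` with
#' `logLik = -n/2 (log(2 pi RSS / n) + 1)`; the two orderings are identical,
#' the values differ by `n (log(2 pi) + 1)`.
#'
#' @param rss Residual sum of squares (must be positive).
#' @param n Number of observations.
#' @param k Number of mean parameters of the model form.
#' @param convention `"rss"` (default) or `"gaussian"`.
#' @return The BIC value.
#' @examples
#' bic_score(0.35714, n = 4, k = 1)
#' @export
bic_score <- function(rss, n, k, convention = c("rss", "gaussian")) {
  convention <- rlang::arg_match(convention)
  if (rss <= 0) {
    cli::cli_abort(c(
      "BIC is undefined for RSS = 0 (exact fit).",
      i = "Handle exact interpolation separately; an exact fit dominates any BIC comparison."
    ))
  }
  base <- n * log(rss / n) + (k + 1) * log(n)
  if (convention == "gaussian") base + n * (log(2 * pi) + 1) else base
}

gaussian_loglik <- function(rss, n) {
  if (rss <= 0) return(Inf)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}

fit_one_form <- function(form, x, y, convention) {
  spec <- get_coupling_form(form)
  n <- length(x)
  coefs <- c(a = NA_real_, b = NA_real_, c = NA_real_)
  converged <- TRUE

  if (form %in% c("proportional", "linear", "quadratic_origin", "quadratic")) {
    fml <- switch(form,
      proportional = y ~ x + 0,
      linear = y ~ x,
      quadratic_origin = y ~ x + I(x^2) + 0,
      quadratic = y ~ x + I(x^2)
    )
    fit <- lm(fml)
    cf <- unname(coef(fit))
    coefs[seq_along(cf)] <- cf
    rss <- sum(fit$residuals^2)
  } else {
    # exponential forms: nonlinear least squares in the original space
    # (a log-linear fit would change the error model), log-space start
    y_pos <- pmax(y, 1e-8)
    if (form == "exp_rate") {
      start <- unname(coef(lm(log(y_pos) ~ x + 0)))
      resid_fn <- function(p) y - exp(p[1] * x)
    } else {
      ls <- coef(lm(log(y_pos) ~ x))
      start <- c(exp(ls[[1]]), ls[[2]])
      resid_fn <- function(p) y - p[1] * exp(p[2] * x)
    }
    nl <- tryCatch(
      minpack.lm::nls.lm(par = start, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL
    )
    if (is.null(nl)) {
      converged <- FALSE
      rss <- sum(resid_fn(start)^2)
      coefs[seq_along(start)] <- start
    } else {
      converged <- nl$info %in% 1:4
      rss <- sum(nl$fvec^2)
      coefs[seq_along(nl$par)] <- nl$par
    }
  }

  tibble::tibble(
    form = form,
    label = spec$label,
    a = coefs[["a"]], b = coefs[["b"]], c = coefs[["c"]],
    n = n,
    k = spec$k,
    rss = rss,
    log_lik = gaussian_loglik(rss, n),
    bic = if (rss <= 0) -Inf else bic_score(rss, n, spec$k, convention),
    converged = converged
  )
}

#' Fit the six-model zoo relating normalized blood volume and perfusion
#'
#' Fits all six candidate forms (`y = ax`, `y = a + bx`, `y = ax + bx^2`,
#' `y = a + bx + cx^2`, `y = e^(ax)`, `y = ae^(bx)`) by least squares —
#' polynomial forms exactly via [lm()], exponential forms by nonlinear least
#' squares in the original space with a log-space start — and ranks them by
#' BIC. Optionally fits both variable orientations (which of `F_bn`, `Q_n`
#' is the dependent variable).
#'
#' @param data Data frame containing the two variables.
#' @param x,y Column names of the independent and dependent variable
#'   (defaults `"q_n"` and `"f_bn"`).
#' @param orientation `"y_on_x"` (default), `"x_on_y"`, or `"both"`.
#' @param forms Character vector of forms to fit (default all six).
#' @param convention BIC convention, see [bic_score()].
#' @return A tibble of class `model_zoo`, one row per orientation x form,
#'   ordered by BIC within orientation, with columns `orientation`, `form`,
#'   `label`, coefficients `a`, `b`, `c`, `n`, `k`, `rss`, `log_lik`, `bic`,
#'   `converged`. An exact interpolation is reported with `bic = -Inf` (it
#'   dominates any comparison).
#' @examples
#' cloud <- simulate_coupling_cloud(phantom_config(seed = 1), "baseline")
#' zoo <- fit_model_zoo(cloud)
#' best_model(zoo)
#' @export
fit_model_zoo <- function(data, x = "q_n", y = "f_bn",
                          orientation = c("y_on_x", "x_on_y", "both"),
                          forms = coupling_form_names(),
                          convention = c("rss", "gaussian")) {
  orientation <- rlang::arg_match(orientation)
  convention <- rlang::arg_match(convention)
  assert_cols(data, c(x, y), "fit_model_zoo")
  forms <- match.arg(forms, coupling_form_names(), several.ok = TRUE)

  xv <- data[[x]]; yv <- data[[y]]
  keep <- is.finite(xv) & is.finite(yv)
  xv <- xv[keep]; yv <- yv[keep]
  if (length(xv) < 10) cli::cli_abort("At least 10 finite observations are required.")

  fit_orientation <- function(xx, yy, orient) {
    if (stats::sd(xx) == 0) {
      cli::cli_abort("Singular design: the independent variable is constant.")
    }
    purrr::map_dfr(forms, fit_one_form, x = xx, y = yy, convention = convention) |>
      dplyr::mutate(orientation = .env$orient, .before = 1) |>
      dplyr::arrange(.data$bic)
  }

  out <- switch(orientation,
    y_on_x = fit_orientation(xv, yv, paste0(y, " ~ ", x)),
    x_on_y = fit_orientation(yv, xv, paste0(x, " ~ ", y)),
    both = dplyr::bind_rows(
      fit_orientation(xv, yv, paste0(y, " ~ ", x)),
      fit_orientation(yv, xv, paste0(x, " ~ ", y))
    )
  )
  class(out) <- c("model_zoo", class(out))
  out
}

#' Best model of a fitted zoo
#'
#' Lowest BIC within each orientation; BIC ties (within `1e-6`) are broken
#' towards the form with fewer parameters.
#'
#' @param zoo A [fit_model_zoo()] result.
#' @return One row per orientation.
#' @export
best_model <- function(zoo) {
  assert_cols(zoo, c("orientation", "bic", "k"), "best_model")
  zoo |>
    dplyr::group_by(.data$orientation) |>
    dplyr::filter(.data$bic <= min(.data$bic) + 1e-6) |>
    dplyr::arrange(.data$k, .data$bic, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}

#' Likelihood-ratio test of two nested least-squares fits
#'
#' For nested Gaussian least-squares models,
#' `chi^2 = 2 (logLik_full - logLik_reduced) = n log(RSS_reduced / RSS_full)`
#' with `df = k_full - k_reduced`, compared against the upper chi-square
#' tail.
#'
#' @param fit_reduced,fit_full Single rows of a [fit_model_zoo()] result (or
#'   tibbles with `form`, `orientation`, `n`, `k`, `rss`). The forms must be
#'   nested and fitted to identical data.
#' @return A list of class `lrt_result` with `chi_square`, `df`, `p_value`.
#' @examples
#' cloud <- simulate_coupling_cloud(phantom_config(seed = 1), "injury")
#' zoo <- fit_model_zoo(cloud)
#' likelihood_ratio_test(zoo[zoo$form == "linear", ],
#'                       zoo[zoo$form == "quadratic", ])
#' @export
likelihood_ratio_test <- function(fit_reduced, fit_full) {
  for (f in list(fit_reduced, fit_full)) {
    assert_cols(f, c("form", "n", "k", "rss"), "likelihood_ratio_test")
    if (nrow(f) != 1) cli::cli_abort("Pass exactly one fit per argument (one zoo row).")
  }
  spec_red <- get_coupling_form(fit_reduced$form)
  if (!fit_full$form %in% spec_red$nests_in) {
    cli::cli_abort("{.val {fit_reduced$form}} is not nested in {.val {fit_full$form}}.")
  }
  if (fit_reduced$n != fit_full$n) {
    cli::cli_abort("The two fits use different numbers of observations.")
  }
  if (!is.null(fit_reduced$orientation) && !is.null(fit_full$orientation) &&
      fit_reduced$orientation != fit_full$orientation) {
    cli::cli_abort("The two fits have different variable orientations.")
  }
  chi_square <- max(0, fit_reduced$n * log(fit_reduced$rss / fit_full$rss))
  df <- fit_full$k - fit_reduced$k
  structure(
    list(
      chi_square = chi_square,
      df = df,
      p_value = stats::pchisq(chi_square, df, lower.tail = FALSE),
      reduced = fit_reduced$form,
      full = fit_full$form
    ),
    class = "lrt_result"
  )
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("<lrt_result> ", x$reduced, " vs ", x$full, "\n", sep = "")
  cat("  chi-square =", signif(x$chi_square, 5), " df =", x$df,
      " p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}

#' Stratified piecewise-linear fits along the vertical gradient
#'
#' Splits the data into `n_strata` groups by quantiles of a stratification
#' variable (by default the relative height) and fits an independent linear
#' model `y = a + bx` within each stratum — the piecewise-linear view of a
#' possibly curvilinear global relationship.
#'
#' @inheritParams fit_model_zoo
#' @param n_strata Number of strata (default 3).
#' @param strata_var Column defining the strata (default
#'   `"height_fraction"`).
#' @param min_points Minimum observations per stratum (default 5).
#' @return A tibble with one row per stratum: `stratum`, `n`,
#'   `x_mid` (mean of `x` in the stratum), `a`, `b`, `rss`, `bic`.
#' @export
fit_stratified_linear <- function(data, n_strata = 3, x = "q_n", y = "f_bn",
                                  strata_var = "height_fraction",
                                  min_points = 5,
                                  convention = c("rss", "gaussian")) {
  convention <- rlang::arg_match(convention)
  assert_cols(data, c(x, y, strata_var), "fit_stratified_linear")
  sv <- data[[strata_var]]
  stratum <- dplyr::ntile(sv, n_strata)
  counts <- table(factor(stratum, levels = seq_len(n_strata)))
  small <- names(counts)[counts < min_points]
  if (length(small) > 0) {
    cli::cli_abort("Strata with fewer than {min_points} points: {small}.")
  }
  purrr::map_dfr(seq_len(n_strata), function(s) {
    d <- data[stratum == s, ]
    fit <- fit_one_form("linear", d[[x]], d[[y]], convention)
    tibble::tibble(
      stratum = s,
      n = nrow(d),
      x_mid = mean(d[[x]]),
      a = fit$a, b = fit$b, rss = fit$rss, bic = fit$bic
    )
  })
}
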