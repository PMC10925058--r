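# Plasma FDG input function.

#' Construct a plasma input function
#'
#' Models the plasma FDG concentration C_p(t) for a constant-rate venous
#' infusion: a linear rise over the infusion (default 60 s) to a peak
#' proportional to the injected dose, followed by a bi-exponential decay.
#'
#' @param times Numeric vector of sample times (s), strictly increasing and
#'   starting at 0.
#' @param kind Input-function family; only `"infusion_biexp"` is currently
#'   implemented.
#' @param params List of parameters: `dose` (MBq), `cp_per_mbq` (kBq/ml peak
#'   plasma concentration per MBq), `infusion_s`, `frac_fast`,
#'   `thalf_fast_s`, `thalf_slow_s`.
#' @return A tibble of class `input_function` with columns `time_s` and `cp`
#'   (kBq/ml).
#' @examples
#' cp <- make_input_function(seq(0, 900, by = 1))
#' cp$cp[1] # zero before the infusion starts
#' @export
make_input_function <- function(times,
                                kind = "infusion_biexp",
                                params = list()) {
  if (length(times) < 2 || any(diff(times) <= 0)) {
    cli::cli_abort("{.arg times} must be strictly increasing.")
  }
  if (times[1] < 0) cli::cli_abort("{.arg times} must start at or after 0.")
  kind <- rlang::arg_match(kind)
  p <- utils::modifyList(
    list(dose = 40, cp_per_mbq = 0.5, infusion_s = 60,
         frac_fast = 0.6, thalf_fast_s = 120, thalf_slow_s = 1800),
    params
  )
  peak <- p$dose * p$cp_per_mbq
  l1 <- log(2) / p$thalf_fast_s
  l2 <- log(2) / p$thalf_slow_s
  cp <- ifelse(
    times <= p$infusion_s,
    peak * times / p$infusion_s,
    peak * (p$frac_fast * exp(-l1 * (times - p$infusion_s)) +
              (1 - p$frac_fast) * exp(-l2 * (times - p$infusion_s)))
  )
  out <- tibble::tibble(time_s = as.numeric(times), cp = pmax(cp, 0))
  class(out) <- c("input_function", class(out))
  out
}

as_input_function <- function(x, fn = "as_input_function") {
  assert_cols(x, c("time_s", "cp"), fn)
  if (any(diff(x$time_s) <= 0)) cli::cli_abort("Input function times must be strictly increasing.")
  if (any(x$cp < 0)) cli::cli_abort("Input function concentrations must be non-negative.")
  x
}
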