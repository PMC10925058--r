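# Registry of candidate F_bn ~ Q_n model forms.
#
# Six forms are compared when characterizing the perfusion / blood-volume
# coupling: proportional, linear, quadratic through the origin, full
# quadratic, and two exponentials. Each entry knows how to predict, how many
# mean parameters it has, and which forms it is nested in (for likelihood
# ratio tests).

coupling_forms <- function() {
  list(
    proportional = list(
      label = "y = ax", k = 1L, coefs = "a",
      predict = function(cf, x) cf[["a"]] * x,
      nests_in = c("linear", "quadratic_origin", "quadratic")
    ),
    linear = list(
      label = "y = a + bx", k = 2L, coefs = c("a", "b"),
      predict = function(cf, x) cf[["a"]] + cf[["b"]] * x,
      nests_in = "quadratic"
    ),
    quadratic_origin = list(
      label = "y = ax + bx^2", k = 2L, coefs = c("a", "b"),
      predict = function(cf, x) cf[["a"]] * x + cf[["b"]] * x^2,
      nests_in = "quadratic"
    ),
    quadratic = list(
      label = "y = a + bx + cx^2", k = 3L, coefs = c("a", "b", "c"),
      predict = function(cf, x) cf[["a"]] + cf[["b"]] * x + cf[["c"]] * x^2,
      nests_in = character()
    ),
    exp_rate = list(
      label = "y = e^(ax)", k = 1L, coefs = "a",
      predict = function(cf, x) exp(cf[["a"]] * x),
      nests_in = "exp_scaled"
    ),
    exp_scaled = list(
      label = "y = ae^(bx)", k = 2L, coefs = c("a", "b"),
      predict = function(cf, x) cf[["a"]] * exp(cf[["b"]] * x),
      nests_in = character()
    )
  )
}

coupling_form_names <- function() names(coupling_forms())

get_coupling_form <- function(form) {
  forms <- coupling_forms()
  if (!form %in% names(forms)) {
    cli::cli_abort(c(
      "Unknown model form {.val {form}}.",
      i = "Available forms: {.val {names(forms)}}."
    ))
  }
  forms[[form]]
}

#' Define a coupling model between normalized blood volume and perfusion
#'
#' A coupling model is a functional form plus coefficients relating the
#' normalized blood volume fraction `F_bn` to normalized perfusion `Q_n`.
#' The phantom generator uses one per condition; the defaults are a linear
#' relationship at baseline and a quadratic-through-origin relationship in
#' lung injury.
#'
#' @param form One of `"proportional"` (`y = ax`), `"linear"` (`y = a + bx`),
#'   `"quadratic_origin"` (`y = ax + bx^2`), `"quadratic"`
#'   (`y = a + bx + cx^2`), `"exp_rate"` (`y = e^(ax)`), or `"exp_scaled"`
#'   (`y = ae^(bx)`).
#' @param coefficients Named numeric vector of coefficients; names must match
#'   the form (`a`, `b`, `c` as applicable).
#' @return An object of class `coupling_model`.
#' @examples
#' m <- coupling_model("linear", c(a = 0.32, b = 0.690))
#' predict(m, c(0.5, 1, 1.5))
#' @export
coupling_model <- function(form, coefficients) {
  spec <- get_coupling_form(form)
  coefficients <- unlist(coefficients)
  if (!setequal(names(coefficients), spec$coefs)) {
    cli::cli_abort(
      "Form {.val {form}} needs coefficient{?s} {.field {spec$coefs}}, got {.field {names(coefficients)}}."
    )
  }
  structure(
    list(form = form, coefficients = coefficients[spec$coefs]),
    class = "coupling_model"
  )
}

#' @export
predict.coupling_model <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata[[1]] else newdata
  get_coupling_form(object$form)$predict(as.list(object$coefficients), x)
}

#' @export
print.coupling_model <- function(x, ...) {
  spec <- get_coupling_form(x$form)
  cf <- paste(names(x$coefficients), signif(x$coefficients, 4), sep = " = ", collapse = ", ")
  cat("<coupling_model> ", spec$label, "  [", cf, "]\n", sep = "")
  invisible(x)
}

# Rescale a coupling model by 1/c; valid because every registered polynomial
# form is linear in its coefficients (exponential forms are refused).
rescale_coupling <- function(model, c_factor) {
  if (model$form %in% c("exp_rate", "exp_scaled")) {
    cli::cli_abort("Exponential coupling forms cannot be rescaled linearly.")
  }
  coupling_model(model$form, model$coefficients / c_factor)
}
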