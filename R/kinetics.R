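# Sokoloff three-compartment FDG kinetics: forward model and inversion.
#
# Model (as used throughout): C_ROI(t) = F_b C_p(t) + C_e(t) + C_m(t) with
#   dC_e/dt = K1 C_p - (k2 + k3) C_e,   C_e(0) = 0
#   dC_m/dt = k3 C_e,                   C_m(0) = 0
# Rate constants are per minute; times are seconds. The vascular term is not
# scaled by (1 - F_b) and a single C_p drives both terms.
#
# With a piecewise-linear C_p the linear cascade has a closed-form solution
# on each segment; the solver steps exactly between the breakpoints of the
# input function (plus frame boundaries), so no ODE discretization error is
# introduced for C_e, and C_m is obtained from the exact per-step integrals
# of C_e.

# Stable evaluations of (1-e^-x)/x, (x-1+e^-x)/x^2, (x^2/2-x+1-e^-x)/x^3.
phi1 <- function(x) ifelse(x < 1e-5, 1 - x / 2 + x^2 / 6, -expm1(-x) / x)
phi2 <- function(x) ifelse(x < 1e-4, 1 / 2 - x / 6 + x^2 / 24, (x - 1 + exp(-x)) / x^2)
phi3 <- function(x) ifelse(x < 1e-3, 1 / 6 - x / 24 + x^2 / 120, (x^2 / 2 - x + 1 - exp(-x)) / x^3)

# Precompute the time grid and per-segment quantities shared by every
# evaluation of the forward model for a given input function and frame set.
sokoloff_grid <- function(input_function, frames, max_step_s = 2) {
  input_function <- as_input_function(input_function, "sokoloff_forward")
  t_in <- input_function$time_s
  t_end <- max(frames$frame_end_s)
  t_start <- min(frames$frame_start_s)
  if (t_end > max(t_in) + 1e-9 || t_start < min(t_in) - 1e-9) {
    cli::cli_abort("Input function does not cover the requested frames (needs [{t_start}, {t_end}] s).")
  }
  grid <- sort(unique(c(t_in, frames$frame_start_s, frames$frame_end_s)))
  grid <- grid[grid <= t_end + 1e-9]
  # subdivide so trapezoidal integration of the slowly varying C_m is exact
  # to well below reporting precision
  refined <- unlist(lapply(seq_len(length(grid) - 1), function(i) {
    n_sub <- max(1, ceiling((grid[i + 1] - grid[i]) / max_step_s))
    seq(grid[i], grid[i + 1], length.out = n_sub + 1)[-(n_sub + 1)]
  }))
  grid <- c(refined, grid[length(grid)])
  cp <- stats::approx(t_in, input_function$cp, xout = grid, rule = 2)$y

  h <- diff(grid)
  c0 <- cp[-length(cp)]
  m <- diff(cp) / h

  # map each segment / node to its frame for averaging
  seg_mid <- grid[-length(grid)] + h / 2
  seg_frame <- findInterval(seg_mid, frames$frame_start_s)
  seg_frame[seg_frame < 1 | seg_frame > nrow(frames)] <- NA
  in_frame <- !is.na(seg_frame) &
    seg_mid <= frames$frame_end_s[pmax(seg_frame, 1L)]
  seg_frame[!in_frame] <- NA
  list(grid = grid, cp = cp, h = h, c0 = c0, m = m,
       seg_frame = seg_frame, frames = frames)
}

# Evaluate the model on a precomputed grid. Returns instantaneous values at
# the grid nodes and exact frame averages.
sokoloff_eval <- function(par, g) {
  f_b <- par[["f_b"]]; k1 <- par[["k1"]] / 60; lam <- (par[["k2"]] + par[["k3"]]) / 60
  k3s <- par[["k3"]] / 60
  h <- g$h; c0 <- g$c0; m <- g$m
  x <- lam * h
  p1 <- h * phi1(x); p2 <- h^2 * phi2(x); p3 <- h^3 * phi3(x)

  a_seg <- k1 * (c0 * p1 + m * p2)            # forced increment of C_e per segment
  decay <- exp(-x)
  n_seg <- length(h)

  # C_e at nodes: C_e[j+1] = C_e[j] * decay[j] + a_seg[j], vectorized through
  # the cumulative product of the decay factors
  lp <- cumsum(x)                              # lam * (t_j+1 - t_0)
  # guard against overflow for extreme rate constants by chunked recursion
  if (max(lp) < 600) {
    ce <- c(0, exp(-lp) * cumsum(a_seg * exp(lp)))
  } else {
    ce <- numeric(n_seg + 1)
    for (j in seq_len(n_seg)) ce[j + 1] <- ce[j] * decay[j] + a_seg[j]
  }

  # exact integral of C_e over each segment, then C_m by accumulation
  int_ce <- ce[-length(ce)] * p1 + k1 * (c0 * p2 + m * p3)
  cm <- k3s * c(0, cumsum(int_ce))

  inst <- f_b * g$cp + ce + cm

  frames <- g$frames
  n_frames <- nrow(frames)
  ok <- !is.na(g$seg_frame)
  idx <- g$seg_frame[ok]
  # frame integral: C_p and C_e segments exactly, C_m by trapezoid
  int_cp <- (g$cp[-length(g$cp)] + g$cp[-1]) / 2 * h
  int_cm <- (cm[-length(cm)] + cm[-1]) / 2 * h
  tot <- f_b * int_cp + int_ce + int_cm
  frame_int <- vapply(seq_len(n_frames), function(f) sum(tot[ok][idx == f]), numeric(1))
  frame_avg <- frame_int / (frames$frame_end_s - frames$frame_start_s)

  list(inst = inst, frame_avg = frame_avg)
}

sokoloff_par <- function(f_b, k1, k2, k3) {
  par <- c(f_b = unname(f_b), k1 = unname(k1), k2 = unname(k2), k3 = unname(k3))
  if (any(par < 0) || f_b > 1) {
    cli::cli_abort("Sokoloff parameters must satisfy F_b in [0, 1] and rates >= 0.")
  }
  par
}

#' Sokoloff forward model: frame-averaged time-activity curve
#'
#' Simulates the ROI activity `C_ROI(t) = F_b C_p(t) + C_e(t) + C_m(t)` of the
#' three-compartment FDG model and averages it over each acquisition frame
#' (PET frames accumulate counts, so the model is integrated over the frame
#' and divided by its duration, not sampled at the midpoint).
#'
#' @param f_b Blood fraction (dimensionless, in `[0, 1]`).
#' @param k1 Transport rate constant plasma -> extravascular pool
#'   (ml/ml/min).
#' @param k2,k3 Efflux and phosphorylation rate constants (1/min).
#' @param input_function An [make_input_function()] tibble (`time_s`, `cp`);
#'   it must cover the requested frames.
#' @param frames Tibble with `frame_start_s`, `frame_end_s`.
#' @return A tibble of class `tac` with columns `frame_start_s`,
#'   `frame_end_s`, `activity` (kBq/ml) and `tracer = "fdg"`.
#' @seealso [sokoloff_curve()] for instantaneous values, [fit_sokoloff()]
#'   for the inverse problem.
#' @examples
#' cp <- make_input_function(seq(0, 900, 5))
#' tac <- sokoloff_forward(0.15, 0.005, 0.05, 0.01, cp, default_fdg_frames())
#' @export
sokoloff_forward <- function(f_b, k1, k2, k3, input_function, frames = default_fdg_frames()) {
  par <- sokoloff_par(f_b, k1, k2, k3)
  assert_cols(frames, c("frame_start_s", "frame_end_s"), "sokoloff_forward")
  g <- sokoloff_grid(input_function, frames)
  ev <- sokoloff_eval(par, g)
  out <- tibble::tibble(
    frame_start_s = frames$frame_start_s,
    frame_end_s = frames$frame_end_s,
    activity = ev$frame_avg,
    tracer = "fdg"
  )
  class(out) <- c("tac", class(out))
  out
}

#' Sokoloff model evaluated instantaneously
#'
#' @inheritParams sokoloff_forward
#' @param times Times (s) at which to evaluate `C_ROI(t)`; must be covered by
#'   the input function.
#' @return A tibble with `time_s` and `activity`.
#' @export
sokoloff_curve <- function(f_b, k1, k2, k3, input_function, times) {
  par <- sokoloff_par(f_b, k1, k2, k3)
  frames <- tibble::tibble(frame_start_s = min(times), frame_end_s = max(times))
  g <- sokoloff_grid(input_function, frames)
  ev <- sokoloff_eval(par, g)
  tibble::tibble(
    time_s = times,
    activity = stats::approx(g$grid, ev$inst, xout = times)$y
  )
}

default_multistart <- function() {
  expand.grid(f_b = c(0.05, 0.2), k1 = c(0.002, 0.01),
              k2 = c(0.02, 0.1), k3 = c(0.005, 0.02))
}

#' Fit the Sokoloff model to a measured time-activity curve
#'
#' Estimates the blood fraction `F_b` and rate constants `K1`, `k2`, `k3` by
#' bounded weighted nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}), minimizing the frame-duration-weighted residual sum of
#' squares between the measured curve and the frame-averaged forward model.
#' A fixed multistart grid guards against local minima; ties in RSS (within
#' `1e-6` relative) are broken towards the lower fitted `F_b`.
#'
#' @param tac Tibble with `frame_start_s`, `frame_end_s`, `activity`
#'   (at least 8 frames).
#' @param input_function The plasma input function covering the frames.
#' @param multistart Data frame of starting values (columns `f_b`, `k1`,
#'   `k2`, `k3`); default a 2^4 grid.
#' @param lower,upper Box constraints on `(f_b, k1, k2, k3)`.
#' @param control Passed to [minpack.lm::nls.lm.control()]; defaults use
#'   `ftol = ptol = 1e-10`.
#' @return An object of class `sokoloff_fit`: a list with `estimate`
#'   (named vector), `rss` (weighted), `converged`, `n_frames`, `fitted`
#'   (tibble) and `n_starts`. `tidy()` and `glance()` methods are provided.
#'   Non-convergence from every start is reported through
#'   `converged = FALSE` with the best attempt's parameters, never silently.
#' @examples
#' cp <- make_input_function(seq(0, 900, 5))
#' tac <- sokoloff_forward(0.15, 0.005, 0.05, 0.01, cp, default_fdg_frames())
#' fit <- fit_sokoloff(tac, cp)
#' tidy(fit)
#' @export
fit_sokoloff <- function(tac, input_function,
                         multistart = default_multistart(),
                         lower = c(0, 0, 0, 0),
                         upper = c(1, 0.5, 2, 2),
                         control = minpack.lm::nls.lm.control(ftol = 1e-10, ptol = 1e-10, maxiter = 200)) {
  assert_cols(tac, c("frame_start_s", "frame_end_s", "activity"), "fit_sokoloff")
  if (nrow(tac) < 8) cli::cli_abort("At least 8 frames are required to fit the Sokoloff model.")
  frames <- tac[, c("frame_start_s", "frame_end_s")]
  g <- sokoloff_grid(input_function, frames)
  w <- sqrt((tac$frame_end_s - tac$frame_start_s) / sum(tac$frame_end_s - tac$frame_start_s))
  obs <- tac$activity

  resid_fn <- function(p) {
    p <- pmin(pmax(p, lower), upper)
    names(p) <- c("f_b", "k1", "k2", "k3")
    w * (sokoloff_eval(p, g)$frame_avg - obs)
  }

  best <- NULL
  for (i in seq_len(nrow(multistart))) {
    start <- as.numeric(multistart[i, c("f_b", "k1", "k2", "k3")])
    fit <- tryCatch(
      minpack.lm::nls.lm(par = start, lower = lower, upper = upper,
                         fn = resid_fn, control = control),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(fit$fvec^2)
    conv <- fit$info %in% 1:4
    cand <- list(par = pmin(pmax(fit$par, lower), upper), rss = rss, converged = conv)
    if (is.null(best) ||
        cand$rss < best$rss * (1 - 1e-6) ||
        (abs(cand$rss - best$rss) <= 1e-6 * max(best$rss, 1e-300) &&
         cand$par[1] < best$par[1])) {
      best <- cand
    }
  }
  if (is.null(best)) {
    cli::cli_abort("Sokoloff fit failed from every starting point.")
  }
  names(best$par) <- c("f_b", "k1", "k2", "k3")
  fitted <- sokoloff_eval(c(best$par), g)$frame_avg
  structure(
    list(
      estimate = best$par,
      rss = best$rss,
      converged = best$converged,
      n_frames = nrow(tac),
      fitted = tibble::tibble(
        frame_start_s = tac$frame_start_s,
        frame_end_s = tac$frame_end_s,
        observed = obs,
        fitted = fitted
      ),
      n_starts = nrow(multistart)
    ),
    class = "sokoloff_fit"
  )
}

#' @export
print.sokoloff_fit <- function(x, ...) {
  cat("<sokoloff_fit> ", if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  print(round(x$estimate, 6))
  cat("weighted RSS:", signif(x$rss, 6), " frames:", x$n_frames, "\n")
  invisible(x)
}

#' Estimate regional perfusion from a 13NN breathhold curve
#'
#' Regional perfusion `Q_r` is read from the tracer-retention curve of a
#' 60-s apnea after an intravenous bolus of 13N-nitrogen in saline: the
#' plateau reached at the end of the breathhold reflects perfusion of
#' aerated alveoli, and an early transient peak above the plateau reflects
#' the shunting (non-aerated) fraction of regional blood flow. `Q_r` is the
#' plateau plus the peak height above the plateau (absolute height, in
#' plateau units; a relative variant `(peak - plateau)/peak` can be selected
#' with `shunt_definition = "relative"`).
#'
#' @param tac Tibble with `frame_start_s`, `frame_end_s`, `activity`
#'   spanning the breathhold.
#' @param plateau_window_s Length of the terminal window whose
#'   duration-weighted mean defines the plateau (default 15 s).
#' @param peak_window_s Length of the initial window searched for the peak
#'   (default 30 s); must not overlap the plateau window.
#' @param shunt_definition `"absolute"` (default): shunt component =
#'   `max(0, peak - plateau)` and `Q_r = plateau + shunt`; `"relative"`:
#'   the shunt fraction `(peak - plateau)/peak` scales the plateau so that
#'   `Q_r = plateau / (1 - shunt_fraction)`.
#' @return A list of class `nn13_estimate` with `plateau`, `peak`,
#'   `shunt_component`, `q_r`.
#' @examples
#' tac <- tibble::tibble(frame_start_s = seq(0, 58, 2), frame_end_s = seq(2, 60, 2),
#'                       activity = 5)
#' estimate_nn13_perfusion(tac)$q_r
#' @export
estimate_nn13_perfusion <- function(tac, plateau_window_s = 15, peak_window_s = 30,
                                    shunt_definition = c("absolute", "relative")) {
  assert_cols(tac, c("frame_start_s", "frame_end_s", "activity"), "estimate_nn13_perfusion")
  shunt_definition <- rlang::arg_match(shunt_definition)
  t0 <- min(tac$frame_start_s)
  t_end <- max(tac$frame_end_s)
  if (t_end - plateau_window_s < t0 + peak_window_s) {
    cli::cli_abort("Peak window [{t0}, {t0 + peak_window_s}] s and plateau window [{t_end - plateau_window_s}, {t_end}] s overlap.")
  }
  w_plat <- frame_overlap(tac$frame_start_s, tac$frame_end_s, t_end - plateau_window_s, t_end)
  plateau <- sum(tac$activity * w_plat) / sum(w_plat)
  mid <- (tac$frame_start_s + tac$frame_end_s) / 2
  in_peak <- mid <= t0 + peak_window_s
  peak <- max(tac$activity[in_peak])
  excess <- max(0, peak - plateau)
  if (shunt_definition == "absolute") {
    shunt_component <- excess
    q_r <- plateau + shunt_component
  } else {
    shunt_fraction <- if (peak > 0) excess / peak else 0
    shunt_component <- plateau * shunt_fraction / max(1 - shunt_fraction, 1e-12)
    q_r <- plateau + shunt_component
  }
  structure(
    list(plateau = plateau, peak = peak,
         shunt_component = shunt_component, q_r = q_r,
         shunt_definition = shunt_definition),
    class = "nn13_estimate"
  )
}

#' @export
print.nn13_estimate <- function(x, ...) {
  cat("<nn13_estimate> plateau:", signif(x$plateau, 5),
      " peak:", signif(x$peak, 5),
      " shunt component:", signif(x$shunt_component, 5),
      " Q_r:", signif(x$q_r, 5), "\n")
  invisible(x)
}
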