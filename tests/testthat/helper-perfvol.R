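# Shared fixtures, all generated in code.

# A small, fast configuration for tests that exercise plumbing rather than
# statistical power.
tiny_config <- function(seed = 101, ...) {
  phantom_config(n_animals = 1, seed = seed, ...)
}

# Sparse but adequate plasma input sampling used throughout the tests.
test_input_times <- function(t_end = 900) {
  sort(unique(c(seq(0, 120, by = 2), seq(125, t_end, by = 5))))
}

test_input_function <- function(t_end = 900, dose = 40) {
  make_input_function(test_input_times(t_end), params = list(dose = dose))
}

# Constant-in-time input function (for closed-form checks).
constant_input_function <- function(level = 1, t_end = 900) {
  out <- tibble::tibble(time_s = seq(0, t_end, by = 10), cp = level)
  class(out) <- c("input_function", class(out))
  out
}

# Reduced multistart grid: fine for noiseless fits where the optimum is
# global and sharp.
fast_multistart <- function() {
  expand.grid(f_b = 0.1, k1 = 0.005, k2 = 0.05, k3 = 0.01)
}

# A 13NN TAC with configurable plateau and peak on the default frames.
nn13_test_tac <- function(plateau, peak, frames = default_nn13_frames()) {
  roi <- tibble::tibble(q_r_true = peak, shunt_true = ifelse(peak > 0, 1 - plateau / peak, 0))
  simulate_nn13_tac(roi, frames, activity_per_flow = 1)
}
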