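# Two-sample multivariate kernel-density test.
#
# Tests whether two bivariate samples come from the same distribution via
# the integrated squared difference of their Gaussian kernel density
# estimates,
#   T = int (f1_hat - f2_hat)^2
#     = psi1(2 H1) + psi2(2 H2) - 2 psi12(H1 + H2),
# which is available in closed form because the convolution of two Gaussian
# kernels is Gaussian. Under the null the pair-degenerate part of T
# dominates and a CLT for degenerate U-statistics with shrinking bandwidth
# gives an asymptotic normal null with
#   mu0    = (4 pi)^-1 (n1^-1 |H1|^-1/2 + n2^-1 |H2|^-1/2)
#   sigma0^2 = 2 R(f) [ (8 pi)^-1 (n1^-2 |H1|^-1/2 + n2^-2 |H2|^-1/2)
#                       + 2 (n1 n2)^-1 (4 pi)^-1 |H1 + H2|^-1/2 ]
# where R(f) = int f^2 is estimated from the pooled sample by a
# leave-diagonal-out kernel functional estimate. A seeded permutation null
# (label reshuffling with the bandwidths held fixed) is provided as the
# resampling alternative.

# mean over all pairs (a_i, b_j) of the Gaussian kernel with covariance G
gauss_pair_mean <- function(a, b, g_mat) {
  k <- gauss_pair_matrix(a, b, g_mat)
  mean(k)
}

gauss_pair_matrix <- function(a, b, g_mat) {
  det_g <- g_mat[1, 1] * g_mat[2, 2] - g_mat[1, 2]^2
  if (det_g <= 0) cli::cli_abort("Bandwidth matrix is not positive definite.")
  d1 <- outer(a[, 1], b[, 1], "-")
  d2 <- outer(a[, 2], b[, 2], "-")
  qf <- (g_mat[2, 2] * d1^2 - 2 * g_mat[1, 2] * d1 * d2 + g_mat[1, 1] * d2^2) / det_g
  exp(-qf / 2) / (2 * pi * sqrt(det_g))
}

# R(f) = int f^2 from the pooled sample: U-statistic (diagonal excluded)
# with the pooled plug-in bandwidth doubled (density convolved with itself).
estimate_rf <- function(pooled, bandwidth_fn) {
  hp <- bandwidth_fn(pooled)
  k <- gauss_pair_matrix(pooled, pooled, 2 * hp)
  n <- nrow(pooled)
  (sum(k) - sum(diag(k))) / (n * (n - 1))
}

#' Two-sample kernel-density test for bivariate point clouds
#'
#' Tests the null hypothesis that two bivariate samples are drawn from the
#' same distribution using the integrated squared difference of their kernel
#' density estimates, computed exactly through Gaussian convolution over all
#' sample pairs, with an unconstrained plug-in bandwidth matrix per sample.
#' Inference is either asymptotic (normal null for the degenerate
#' U-statistic; default) or by seeded label permutation with the bandwidths
#' held fixed.
#'
#' @param x,y Numeric matrices or data frames with 2 columns (at least 20
#'   rows each).
#' @param method `"asymptotic"` (default) or `"permutation"`.
#' @param bandwidth `"plugin"` (default, [bandwidth_plugin()]) or
#'   `"normal_reference"`.
#' @param n_permutations Number of label permutations (>= 99; default 999).
#' @param seed Seed for the permutation draw.
#' @return An object of class `kde_test`: list with `statistic`, `null_mean`,
#'   `null_sd`, `z`, `p_value`, `H1`, `H2`, `method`, `n1`, `n2` (and
#'   `n_permutations` for the permutation method). `tidy()` and `glance()`
#'   methods are provided.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200), ncol = 2)
#' y <- matrix(rnorm(200), ncol = 2)
#' kde_two_sample_test(x, y)$p_value
#' @export
kde_two_sample_test <- function(x, y,
                                method = c("asymptotic", "permutation"),
                                bandwidth = c("plugin", "normal_reference"),
                                n_permutations = 999,
                                seed = NULL) {
  method <- rlang::arg_match(method)
  bandwidth <- rlang::arg_match(bandwidth)
  x <- as_bivariate_matrix(x, "x")
  y <- as_bivariate_matrix(y, "y")
  n1 <- nrow(x); n2 <- nrow(y)
  if (n1 < 20 || n2 < 20) cli::cli_abort("Each sample needs at least 20 observations.")
  if (any(apply(x, 2, stats::sd) == 0) || any(apply(y, 2, stats::sd) == 0)) {
    cli::cli_abort("Degenerate sample: a coordinate has zero variance.")
  }
  bw_fn <- switch(bandwidth, plugin = bandwidth_plugin,
                  normal_reference = bandwidth_normal_reference)
  h1 <- bw_fn(x)
  h2 <- bw_fn(y)

  psi1 <- gauss_pair_mean(x, x, 2 * h1)
  psi2 <- gauss_pair_mean(y, y, 2 * h2)
  psi12 <- gauss_pair_mean(x, y, h1 + h2)
  t_stat <- psi1 + psi2 - 2 * psi12

  det1 <- det(h1); det2 <- det(h2); det12 <- det(h1 + h2)
  mu0 <- (1 / (4 * pi)) * (1 / (n1 * sqrt(det1)) + 1 / (n2 * sqrt(det2)))

  if (method == "asymptotic") {
    pooled <- rbind(x, y)
    rf <- estimate_rf(pooled, bw_fn)
    var0 <- 2 * rf * (
      (1 / (8 * pi)) * (1 / (n1^2 * sqrt(det1)) + 1 / (n2^2 * sqrt(det2))) +
        2 / (n1 * n2 * 4 * pi * sqrt(det12))
    )
    z <- (t_stat - mu0) / sqrt(var0)
    p <- stats::pnorm(z, lower.tail = FALSE)
    out <- list(statistic = t_stat, null_mean = mu0, null_sd = sqrt(var0),
                z = z, p_value = p, H1 = h1, H2 = h2,
                method = "asymptotic", bandwidth = bandwidth, n1 = n1, n2 = n2)
  } else {
    if (n_permutations < 99) cli::cli_abort("Use at least 99 permutations.")
    pooled <- rbind(x, y)
    n <- n1 + n2
    m11 <- gauss_pair_matrix(pooled, pooled, 2 * h1)
    m22 <- gauss_pair_matrix(pooled, pooled, 2 * h2)
    m12 <- gauss_pair_matrix(pooled, pooled, h1 + h2)
    t_from_labels <- function(ind1) {
      u <- numeric(n); u[ind1] <- 1
      v <- 1 - u
      sum(u * (m11 %*% u)) / n1^2 + sum(v * (m22 %*% v)) / n2^2 -
        2 * sum(u * (m12 %*% v)) / (n1 * n2)
    }
    t_obs <- t_from_labels(seq_len(n1))
    perm_t <- with_seed_opt(seed %||% 1L, {
      vapply(seq_len(n_permutations), function(i) {
        t_from_labels(sample.int(n, n1))
      }, numeric(1))
    })
    p <- (1 + sum(perm_t >= t_obs)) / (n_permutations + 1)
    out <- list(statistic = t_obs, null_mean = mean(perm_t),
                null_sd = stats::sd(perm_t),
                z = (t_obs - mean(perm_t)) / stats::sd(perm_t),
                p_value = p, H1 = h1, H2 = h2,
                method = "permutation", bandwidth = bandwidth,
                n1 = n1, n2 = n2, n_permutations = n_permutations)
  }
  structure(out, class = "kde_test")
}

#' @export
print.kde_test <- function(x, ...) {
  cat("<kde_test> two-sample kernel-density test (", x$method, ")\n", sep = "")
  cat("  n1 =", x$n1, " n2 =", x$n2, "\n")
  cat("  T =", signif(x$statistic, 5), " z =", signif(x$z, 4),
      " p =", format.pval(x$p_value, digits = 4), "\n")
  invisible(x)
}
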