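#' Optimal trend coefficient for an a-priori genetic effect model
#'
#' The heterozygote score coefficient that maximizes the expected trend
#' statistic under the model-implied case (`p_i`), control (`q_i`) and
#' pooled (`nbar_i`) genotype frequencies. With the standardized contrasts
#' `d_i = (p_i - q_i) / nbar_i`, the optimal score vector is proportional to
#' `(d_0, d_1, d_2)`, and its affine normalization to the `(0, c, 1)` form is
#' \deqn{c^{opt} = \frac{d_1 - d_0}{d_2 - d_0}.}
#'
#' The coefficient is computed from a-priori model parameters only — never
#' from the observed table, which would invalidate the chi-square(1) null.
#'
#' @param model An [effect_model()].
#' @param n_cases,n_controls Planned numbers of cases and controls (only
#'   their ratio matters).
#' @return An object of class `optimal_coef`: a list with `c_optimal`,
#'   `d_scores`, `model` and `design`.
#' @examples
#' m <- effect_model(q = 0.4, rr = 1.25, cv_rr = 0.4)
#' optimal_coefficient(m, n_cases = 1000, n_controls = 1018)
#' @export
optimal_coefficient <- function(model, n_cases, n_controls) {
  stopifnot(inherits(model, "effect_model"))
  if (n_cases < 1 || n_controls < 1) {
    abort("`n_cases` and `n_controls` must both be at least 1.")
  }
  p <- case_freqs_general(model)
  q <- control_freqs(model$q, model$delta)
  nbar <- pooled_freqs_expected(p, q, n_cases, n_controls)
  if (any(nbar == 0)) abort("a pooled expected genotype frequency is zero.")
  d <- (p - q) / nbar
  if (abs(d[3L] - d[1L]) < 1e-12) {
    abort("optimal coefficient undefined/unbounded: homozygote contrasts coincide.")
  }
  c_opt <- unname((d[2L] - d[1L]) / (d[3L] - d[1L]))
  structure(
    list(c_optimal = c_opt, d_scores = unname(d), model = model,
         design = c(n_cases = n_cases, n_controls = n_controls)),
    class = "optimal_coef"
  )
}

#' @export
print.optimal_coef <- function(x, ...) {
  cat(sprintf("Optimal trend coefficient: c = %.4f\n", x$c_optimal))
  cat(sprintf("d scores (aa, Aa, AA): %s\n",
              paste(sprintf("%.4f", x$d_scores), collapse = ", ")))
  invisible(x)
}

#' Numeric maximizer of the expected trend statistic
#'
#' Independent check on [optimal_coefficient()]: builds the expected 2x3
#' table `(r * p_i, s * q_i)` (real-valued counts), evaluates the trend
#' chi-square as a function of the coefficient, and maximizes it by a
#' 1001-point grid scan over `bounds` followed by bounded golden-section
#' refinement.
#'
#' @inheritParams optimal_coefficient
#' @param bounds Search interval for the coefficient.
#' @return The maximizing coefficient (a single number). Warns when the
#'   optimum sits at a boundary of `bounds`.
#' @export
optimal_coefficient_numeric <- function(model, n_cases, n_controls,
                                        bounds = c(-10, 11)) {
  stopifnot(inherits(model, "effect_model"))
  p <- case_freqs_general(model)
  q <- control_freqs(model$q, model$delta)
  exp_cases <- matrix(n_cases * p, nrow = 1L)
  exp_controls <- matrix(n_controls * q, nrow = 1L)
  obj <- function(cc) z_trend_vec(exp_cases, exp_controls, cc)
  grid <- seq(bounds[1L], bounds[2L], length.out = 1001L)
  zg <- vapply(grid, obj, numeric(1))
  if (max(zg, na.rm = TRUE) < 1e-12) {
    abort("no association to optimize: the expected statistic is flat (null model).")
  }
  i <- which.max(zg)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(obj, lower = lo, upper = hi, maximum = TRUE, tol = 1e-9)
  c_hat <- opt$maximum
  if (min(abs(c_hat - bounds)) < 1e-3) {
    warn(sprintf("optimal coefficient sits at the search boundary (%.3f).", c_hat))
  }
  c_hat
}

#' Optimal trend test
#'
#' Runs the trend test at the model-derived optimal coefficient.
#'
#' @param counts A [genotype_counts()] object (the observed table).
#' @param model An [effect_model()] supplying the a-priori parameters.
#' @return A `trend_test` object with method `"optimal_trend"`.
#' @examples
#' gc <- genotype_counts(c(307, 509, 184), c(359, 522, 137))
#' m <- effect_model(q = 0.4, rr = 1.25, cv_rr = 0.4)
#' optimal_trend_test(gc, m)
#' @export
optimal_trend_test <- function(counts, model) {
  stopifnot(inherits(counts, "genotype_counts"))
  m <- stop_if_empty_margin(counts)
  oc <- optimal_coefficient(model, m$r, m$s)
  trend_test(counts, coef = oc$c_optimal, method = "optimal_trend")
}
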