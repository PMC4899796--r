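#' Genetic effect model with heterogeneous relative risks
#'
#' Five-parameter model for the effect of a biallelic marker on a
#' (possibly heterogeneous) disease:
#'
#' * `q` — frequency of the `A` allele in the non-diseased population;
#' * `delta` — Hardy-Weinberg disequilibrium coefficient of the non-diseased
#'   population (0 = Hardy-Weinberg equilibrium);
#' * `rr` — mean allele relative risk RR (multiplicative risk change per `A`
#'   allele, averaged over persons);
#' * `cv_rr` — coefficient of variation of the allele relative risk across
#'   persons (SD/mean), the model's measure of effect heterogeneity;
#' * `gamma` — genetic-model parameter on `[0, 1]`: 0 = autosomal recessive,
#'   0.5 = gene dosage, 1 = autosomal dominant. Genotype relative risks are
#'   `(1, RR^(2*gamma), RR^2)`.
#'
#' @param q Allele frequency in `(0, 1)`.
#' @param rr Mean allele relative risk, `> 0`.
#' @param cv_rr Coefficient of variation of the relative risk, `>= 0`.
#' @param delta Hardy-Weinberg disequilibrium coefficient of controls.
#' @param gamma Genetic-model parameter in `[0, 1]`.
#'
#' @return An object of class `effect_model`.
#' @examples
#' m <- effect_model(q = 0.4, rr = 1.25, cv_rr = 0.4)
#' case_freqs_general(m)
#' @export
effect_model <- function(q, rr, cv_rr = 0, delta = 0, gamma = 0.5) {
  for (nm in c("q", "rr", "cv_rr", "delta", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("`%s` must be a single finite number.", nm))
    }
  }
  if (q <= 0 || q >= 1) abort("`q` must lie strictly between 0 and 1.")
  if (rr <= 0) abort("`rr` must be positive.")
  if (cv_rr < 0) abort("`cv_rr` must be non-negative.")
  if (gamma < 0 || gamma > 1) abort("`gamma` must lie in [0, 1].")
  control_freqs(q, delta)  # errors if delta inadmissible for q
  structure(
    list(q = q, rr = rr, cv_rr = cv_rr, delta = delta, gamma = gamma),
    class = "effect_model"
  )
}

#' @export
print.effect_model <- function(x, ...) {
  cat(sprintf(
    "Genetic effect model: q = %g, Delta = %g, RR = %g, CV_RR = %g, gamma = %g\n",
    x$q, x$delta, x$rr, x$cv_rr, x$gamma))
  invisible(x)
}

#' Expected control genotype frequencies
#'
#' `((1-q)^2 + Delta, 2q(1-q) - 2*Delta, q^2 + Delta)`; at `delta = 0` these
#' are the Hardy-Weinberg proportions.
#'
#' @inheritParams effect_model
#' @return Named numeric vector (aa, Aa, AA) summing to 1.
#' @export
control_freqs <- function(q, delta = 0) {
  f <- c((1 - q)^2 + delta, 2 * q * (1 - q) - 2 * delta, q^2 + delta)
  if (any(f < 0) || any(f > 1)) {
    abort(sprintf("Delta = %g out of admissible range for q = %g.", delta, q))
  }
  setNames(f, GENOTYPES)
}

#' Mean and variance of the case allele parameter
#'
#' Under the model the case-side allele parameter `p` has mean
#' `p_bar = q*RR / (1 - q + q*RR)` and, by a Taylor approximation in the
#' heterogeneous relative risk, variance
#' `delta_var = (p_bar * (1 - p_bar) * CV_RR)^2`. Under Hardy-Weinberg
#' equilibrium and a gene-dosage model `p_bar` is the expected case allele
#' frequency and `delta_var` the Hardy-Weinberg disequilibrium coefficient
#' induced in the cases.
#'
#' @inheritParams effect_model
#' @return A list with elements `p_bar` and `delta_var`.
#' @export
case_allele_param <- function(q, rr, cv_rr = 0) {
  if (q <= 0 || q >= 1) abort("`q` must lie strictly between 0 and 1.")
  if (rr <= 0) abort("`rr` must be positive.")
  if (cv_rr < 0) abort("`cv_rr` must be non-negative.")
  p_bar <- q * rr / (1 - q + q * rr)
  delta_var <- (p_bar * (1 - p_bar) * cv_rr)^2
  list(p_bar = p_bar, delta_var = delta_var)
}

#' Expected case genotype frequencies (HWE controls, gene-dosage model)
#'
#' Closed form for the special case `delta = 0`, `gamma = 0.5`:
#' `((1-p)^2 + d, 2p(1-p) - 2d, p^2 + d)` with `p` and `d = Var(p)` from
#' [case_allele_param()]. The variance of the heterogeneous relative risk
#' reappears as Hardy-Weinberg disequilibrium among the cases.
#'
#' @inheritParams effect_model
#' @return Named numeric vector (aa, Aa, AA) summing to 1.
#' @export
case_freqs_special <- function(q, rr, cv_rr = 0) {
  par <- case_allele_param(q, rr, cv_rr)
  p <- par$p_bar; d <- par$delta_var
  if (d > p * (1 - p)) {
    abort(sprintf(
      "model outside admissible region: Var(p) = %.4g exceeds p(1-p) = %.4g.",
      d, p * (1 - p)))
  }
  f <- c((1 - p)^2 + d, 2 * p * (1 - p) - 2 * d, p^2 + d)
  if (any(f < 0) || any(f > 1)) abort("model outside admissible region.")
  setNames(f, GENOTYPES)
}

# Genotype-frequency map for the cases as a function of the allele
# parameter p, before averaging over the heterogeneity: control frequencies
# reweighted by the genotype relative risks (1, RR^(2*gamma), RR^2), with RR
# expressed through p by inverting p = q*RR/(1 - q + q*RR).
case_freq_map <- function(model) {
  qf <- control_freqs(model$q, model$delta)
  expo <- c(0, 2 * model$gamma, 2)
  q <- model$q
  function(p) {
    rr_p <- p * (1 - q) / (q * (1 - p))
    w <- qf * rr_p^expo
    w / sum(w)
  }
}

#' Expected case genotype frequencies under the general model
#'
#' For arbitrary Hardy-Weinberg disequilibrium `delta` and genetic-model
#' parameter `gamma`, the expected case genotype frequencies are obtained as
#' the second-order Taylor expectation of the genotype-frequency map
#' `g_i(p)` (see [case_freq_map] internals) about the mean allele parameter:
#' `p_i = g_i(p_bar) + g_i''(p_bar) * Var(p) / 2`, renormalized to the
#' simplex. At `gamma = 0.5`, `delta = 0` the map is quadratic in `p`, the
#' expansion is exact, and the result equals [case_freqs_special()].
#'
#' Second derivatives are computed by Richardson-extrapolated central finite
#' differences (steps `h` and `h/2`, `h = 1e-3 * max(1, |p_bar|)`), which
#' keeps the subtraction roundoff of the plain second difference out of the
#' Taylor term: accuracy is around `1e-9` on the curvature.
#'
#' @param model An [effect_model()].
#' @return Named numeric vector (aa, Aa, AA) summing to 1.
#' @export
case_freqs_general <- function(model) {
  stopifnot(inherits(model, "effect_model"))
  par <- case_allele_param(model$q, model$rr, model$cv_rr)
  p_bar <- par$p_bar; d <- par$delta_var
  if (d > p_bar * (1 - p_bar)) {
    abort("model outside admissible region: Var(p) exceeds p(1-p).")
  }
  g <- case_freq_map(model)
  h <- min(1e-3 * max(1, abs(p_bar)), p_bar / 2, (1 - p_bar) / 2)
  d2 <- function(hh) (g(p_bar + hh) - 2 * g(p_bar) + g(p_bar - hh)) / hh^2
  g2 <- (4 * d2(h / 2) - d2(h)) / 3
  f <- g(p_bar) + 0.5 * g2 * d
  if (any(f < -1e-12) || any(f > 1 + 1e-12)) {
    abort("model outside admissible region: a case genotype frequency left [0, 1].")
  }
  f <- pmin(pmax(f, 0), 1)
  setNames(f / sum(f), GENOTYPES)
}

#' Expected pooled genotype frequencies for a case-control design
#'
#' Sample-size-weighted mixture of the case and control genotype
#' frequencies: `(r * p_i + s * q_i) / (r + s)`.
#'
#' @param case_f,control_f Genotype frequency triples on the simplex.
#' @param n_cases,n_controls Numbers of cases (`r`) and controls (`s`).
#' @return Named numeric vector (aa, Aa, AA) summing to 1.
#' @export
pooled_freqs_expected <- function(case_f, control_f, n_cases, n_controls) {
  check_simplex(case_f, "case_f")
  check_simplex(control_f, "control_f")
  if (n_cases < 1 || n_controls < 1) {
    abort("`n_cases` and `n_controls` must both be at least 1.")
  }
  f <- (n_cases * case_f + n_controls * control_f) / (n_cases + n_controls)
  setNames(unname(f), GENOTYPES)
}

check_simplex <- function(f, what, tol = 1e-8) {
  if (length(f) != 3L || any(f < -tol) || any(f > 1 + tol) ||
      abs(sum(f) - 1) > tol) {
    abort(sprintf("`%s` must be a genotype frequency triple on the simplex.", what))
  }
  invisible(f)
}

#' Model-implied genotype frequencies as a tibble
#'
#' Convenience wrapper returning case, control and pooled expected genotype
#' frequencies for a design in one table.
#'
#' @param model An [effect_model()].
#' @param n_cases,n_controls Planned numbers of cases and controls.
#' @return A tibble with columns `genotype`, `cases`, `controls`, `pooled`.
#' @export
expected_freqs <- function(model, n_cases, n_controls) {
  p <- case_freqs_general(model)
  q <- control_freqs(model$q, model$delta)
  nbar <- pooled_freqs_expected(p, q, n_cases, n_controls)
  tibble::tibble(genotype = GENOTYPES,
                 cases = unname(p), controls = unname(q),
                 pooled = unname(nbar))
}
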