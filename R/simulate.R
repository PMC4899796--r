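#' Simulate a case-control genotype table under an effect model
#'
#' Cases are drawn multinomially at the model-implied expected case genotype
#' frequencies ([case_freqs_general()]), controls at the control frequencies
#' — the asymptotic regime the trend test targets. See
#' [sample_counts_individual()] for a generator that draws a relative risk
#' per subject instead of relying on the Taylor-approximated frequencies.
#'
#' @param model An [effect_model()].
#' @param n_cases,n_controls Numbers of cases and controls to draw.
#' @param seed Optional integer seed; when supplied the draw is reproducible
#'   and the global RNG state is left untouched.
#' @return A [genotype_counts()] object.
#' @export
sample_counts <- function(model, n_cases, n_controls, seed = NULL) {
  p <- case_freqs_general(model)
  q <- control_freqs(model$q, model$delta)
  draw <- function() {
    genotype_counts(cases = as.vector(rmultinom(1L, n_cases, p)),
                    controls = as.vector(rmultinom(1L, n_controls, q)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a table by drawing a relative risk per case subject
#'
#' Robustness generator that does not rely on the Taylor approximation:
#' each case receives its own allele relative risk from a positive family
#' with mean `RR` and coefficient of variation `CV_RR`, and a genotype drawn
#' with probability proportional to `q_i * GRR_i(RR)` where
#' `GRR = (1, RR^(2*gamma), RR^2)`. Controls are multinomial at the control
#' frequencies. At `cv_rr = 0` this coincides distributionally with
#' [sample_counts()].
#'
#' @inheritParams sample_counts
#' @param family `"lognormal"` (closed-form moment match) or `"gamma"`.
#' @return A [genotype_counts()] object.
#' @export
sample_counts_individual <- function(model, n_cases, n_controls,
                                     family = c("lognormal", "gamma"),
                                     seed = NULL) {
  family <- match.arg(family)
  qf <- control_freqs(model$q, model$delta)
  expo <- c(0, 2 * model$gamma, 2)
  draw <- function() {
    rr_s <- draw_rr(n_cases, model$rr, model$cv_rr, family)
    w <- outer(rr_s, expo, `^`) * rep(qf, each = n_cases)  # n_cases x 3
    pr <- w / rowSums(w)
    u <- runif(n_cases)
    g <- 1L + (u > pr[, 1L]) + (u > pr[, 1L] + pr[, 2L])
    genotype_counts(cases = tabulate(g, nbins = 3L),
                    controls = as.vector(rmultinom(1L, n_controls, qf)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

# Per-subject relative risks with mean rr and coefficient of variation cv.
draw_rr <- function(n, rr, cv, family) {
  if (cv == 0) return(rep(rr, n))
  switch(family,
    lognormal = {
      s2 <- log1p(cv^2)
      rlnorm(n, meanlog = log(rr) - s2 / 2, sdlog = sqrt(s2))
    },
    gamma = rgamma(n, shape = 1 / cv^2, scale = rr * cv^2)
  )
}

#' Sample size for the Cochran-Armitage trend test
#'
#' Per-group sample size (equal numbers of cases and controls) for the
#' trend test with gene-dosage scores `(0, 0.5, 1)` to reach a target power
#' at a two-sided significance level, from the noncentrality form
#' \deqn{n = \frac{(z_{1-\alpha/2}\sigma_0 + z_{1-\beta}\sigma_1)^2}{e^2},}
#' where `e` is the difference in mean scores between the case and control
#' genotype distributions, `sigma_0^2 = 2 * var` of the score under the
#' pooled (50:50) frequencies and `sigma_1^2` the sum of the case and
#' control score variances. No continuity correction; the result is
#' rounded up.
#'
#' @param model_alt An [effect_model()] describing the alternative.
#' @param alpha Two-sided significance level.
#' @param power Target power.
#' @return Integer sample size per group.
#' @examples
#' sample_size_ca(effect_model(q = 0.4, rr = 1.5), alpha = 0.05, power = 0.8)
#' @export
sample_size_ca <- function(model_alt, alpha = 0.05, power = 0.8) {
  stopifnot(inherits(model_alt, "effect_model"))
  x <- c(0, 0.5, 1)
  p <- case_freqs_general(model_alt)
  q <- control_freqs(model_alt$q, model_alt$delta)
  e <- sum(x * (p - q))
  if (abs(e) < 1e-12) {
    abort("sample size unbounded: the alternative carries no score trend.")
  }
  varx <- function(f) sum(x^2 * f) - sum(x * f)^2
  pooled <- (p + q) / 2
  s0 <- sqrt(2 * varx(pooled))
  s1 <- sqrt(varx(p) + varx(q))
  n <- (qnorm(1 - alpha / 2) * s0 + qnorm(power) * s1)^2 / e^2
  as.integer(ceiling(n))
}

#' Monte-Carlo power study of trend tests
#'
#' For each scenario row, simulates case-control tables under the scenario's
#' effect model and reports the empirical power (fraction of replicates with
#' p below `alpha`) of each requested test. Optimal coefficients are
#' computed once per scenario from the scenario's assumed model, never
#' re-estimated from simulated data. Scenarios are simulated on independent
#' seeded streams (`seed + row index`), so results do not depend on row
#' execution order.
#'
#' @param scenarios A data frame with one row per scenario and columns
#'   `q`, `rr`, `n_cases`, `n_controls`; optional `cv_rr`, `delta`, `gamma`
#'   (defaulted to 0, 0, 0.5) and `coef_model_cv` — the `cv_rr` assumed when
#'   deriving the optimal coefficient, when it should differ from the truth.
#' @param tests Character vector from `"optimal"`, `"cochran_armitage"`, or
#'   numeric coefficients given as strings convert with `as.numeric`; a
#'   named numeric vector of fixed coefficients is also accepted.
#' @param reps Number of Monte-Carlo replicates per scenario.
#' @param alpha Significance level.
#' @param seed Base integer seed.
#' @return A `power_table` tibble with one row per scenario x test:
#'   columns `rr`, `cv_rr`, `q`, `test`, `coefficient`, `n_per_group`,
#'   `power`, `se`, `reps`, `alpha`, `seed`.
#' @examples
#' \donttest{
#' sc <- tibble::tibble(q = 0.4, rr = 1.5, cv_rr = c(0, 0.8),
#'                      n_cases = 196, n_controls = 196)
#' power_study(sc, reps = 2000, seed = 1)
#' }
#' @export
power_study <- function(scenarios, tests = c("optimal", "cochran_armitage"),
                        reps = 10000, alpha = 0.05, seed = NULL) {
  if (!is.data.frame(scenarios)) abort("`scenarios` must be a data frame.")
  need <- c("q", "rr", "n_cases", "n_controls")
  if (!all(need %in% names(scenarios))) {
    abort(sprintf("`scenarios` must have columns %s.", paste(need, collapse = ", ")))
  }
  if (alpha <= 0 || alpha > 1) abort("`alpha` must lie in (0, 1].")
  scenarios <- dplyr::mutate(
    tibble::as_tibble(scenarios),
    cv_rr = if ("cv_rr" %in% names(scenarios)) .data$cv_rr else 0,
    delta = if ("delta" %in% names(scenarios)) .data$delta else 0,
    gamma = if ("gamma" %in% names(scenarios)) .data$gamma else 0.5
  )
  base_seed <- seed %||% as.integer(Sys.time()) %% 100000L
  crit <- qchisq(1 - alpha, df = 1)
  rows <- purrr::map(seq_len(nrow(scenarios)), function(i) {
    sc <- scenarios[i, ]
    truth <- effect_model(q = sc$q, rr = sc$rr, cv_rr = sc$cv_rr,
                          delta = sc$delta, gamma = sc$gamma)
    coefs <- resolve_test_coefs(tests, sc, truth)
    p <- case_freqs_general(truth)
    qf <- control_freqs(sc$q, sc$delta)
    withr::with_seed(base_seed + i, {
      cases <- t(rmultinom(reps, sc$n_cases, p))
      controls <- t(rmultinom(reps, sc$n_controls, qf))
      purrr::imap_dfr(coefs, function(cc, label) {
        z <- z_trend_vec(cases, controls, cc)
        pw <- mean(z > crit, na.rm = TRUE)
        tibble::tibble(
          rr = sc$rr, cv_rr = sc$cv_rr, q = sc$q, test = label,
          coefficient = cc, n_per_group = sc$n_cases,
          power = pw, se = sqrt(pw * (1 - pw) / reps),
          reps = reps, alpha = alpha, seed = base_seed + i)
      })
    })
  })
  structure(dplyr::bind_rows(rows), class = c("power_table", class(tibble::tibble())))
}

resolve_test_coefs <- function(tests, sc, truth) {
  if (is.numeric(tests)) {
    labels <- names(tests) %||% paste0("c=", tests)
    return(setNames(as.numeric(tests), labels))
  }
  coefs <- vapply(tests, function(t) {
    if (t == "cochran_armitage") return(0.5)
    if (t == "optimal") {
      cv_assumed <- if ("coef_model_cv" %in% names(sc) && !is.na(sc$coef_model_cv))
        sc$coef_model_cv else truth$cv_rr
      m <- effect_model(q = truth$q, rr = truth$rr, cv_rr = cv_assumed,
                        delta = truth$delta, gamma = truth$gamma)
      return(optimal_coefficient(m, sc$n_cases, sc$n_controls)$c_optimal)
    }
    suppressWarnings(v <- as.numeric(t))
    if (is.na(v)) abort(sprintf("unknown test descriptor `%s`.", t))
    v
  }, numeric(1))
  setNames(coefs, tests)
}

#' Plot a power table
#'
#' Empirical power against the heterogeneity of the relative risk, one line
#' per test, faceted by mean relative risk.
#'
#' @param object A `power_table` from [power_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @export
autoplot.power_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$cv_rr, y = .data$power,
                                       colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = pmax(.data$power - 2 * .data$se, 0),
      ymax = pmin(.data$power + 2 * .data$se, 1)), size = 0.2) +
    ggplot2::facet_wrap(ggplot2::vars(.data$rr), labeller = "label_both") +
    ggplot2::labs(x = expression(CV[RR]), y = "Empirical power",
                  colour = "Test") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Trend statistic as a function of the coefficient
#'
#' Curve of `Z(c)` over a coefficient range for one observed table, with
#' reference marks at the recessive (0), gene-dosage (0.5) and dominant (1)
#' coefficients.
#'
#' @param counts A [genotype_counts()] object.
#' @param range Coefficient range to sweep.
#' @return A ggplot object.
#' @export
plot_trend_curve <- function(counts, range = c(-1, 2)) {
  cc <- seq(range[1L], range[2L], length.out = 401L)
  z <- vapply(cc, function(c1) trend_test(counts, c1)$statistic, numeric(1))
  df <- tibble::tibble(coefficient = cc, statistic = z)
  ggplot2::ggplot(df, ggplot2::aes(.data$coefficient, .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(0, 0.5, 1), linetype = "dotted") +
    ggplot2::labs(x = "heterozygote coefficient c",
                  y = expression(Z(c))) +
    ggplot2::theme_minimal()
}
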