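#' Specification of a weighted multi-coefficient summary test
#'
#' A set of `m` trend coefficients with positive weights. The summary
#' statistic is the weighted sum of the `m` trend chi-squares; the weights
#' express the a-priori plausibility of each coefficient (equivalently, of
#' the effect model it derives from).
#'
#' @param coefficients Numeric vector of trend coefficients `c_1, ..., c_m`.
#' @param weights Positive weights `w_1, ..., w_m` (default all 1).
#' @return An object of class `summary_spec`.
#' @examples
#' summary_spec(c(0.5, 1, 0))            # dosage / dominant / recessive
#' summary_spec(c(0.8, 0.2), c(1, 1))
#' @export
summary_spec <- function(coefficients, weights = rep(1, length(coefficients))) {
  if (length(coefficients) < 1L || !is.numeric(coefficients) ||
      any(!is.finite(coefficients))) {
    abort("`coefficients` must be one or more finite numbers.")
  }
  if (length(weights) != length(coefficients) || any(!is.finite(weights)) ||
      any(weights <= 0)) {
    abort("`weights` must be positive and match `coefficients` in length.")
  }
  structure(list(coefficients = as.numeric(coefficients),
                 weights = as.numeric(weights)),
            class = "summary_spec")
}

#' Build a summary spec from a list of effect models
#'
#' Converts each model into its optimal coefficient for the given design.
#'
#' @param models A list of [effect_model()] objects.
#' @param n_cases,n_controls Design sizes used for the optimal coefficients.
#' @param weights Positive weights, one per model.
#' @return A [summary_spec()].
#' @export
summary_spec_from_models <- function(models, n_cases, n_controls,
                                     weights = rep(1, length(models))) {
  coefs <- vapply(models, function(m) {
    optimal_coefficient(m, n_cases, n_controls)$c_optimal
  }, numeric(1))
  summary_spec(coefs, weights)
}

#' Weighted summary trend statistic
#'
#' `W = sum_j w_j * Z(c_j)` over the spec's coefficients. With `m = 1` and
#' unit weight this is exactly the single trend statistic.
#'
#' @param counts A [genotype_counts()] object.
#' @param spec A [summary_spec()].
#' @return The statistic `W` (a single non-negative number).
#' @export
summary_statistic <- function(counts, spec) {
  stopifnot(inherits(spec, "summary_spec"))
  z <- vapply(seq_along(spec$coefficients), function(j) {
    res <- tryCatch(trend_test(counts, spec$coefficients[j]),
                    error = function(e) {
                      abort(sprintf("component c = %g failed: %s",
                                    spec$coefficients[j], conditionMessage(e)))
                    })
    res$statistic
  }, numeric(1))
  sum(spec$weights * z)
}

#' Null mixture weights of the summary statistic
#'
#' Under the null, each component trend chi-square is the square of a
#' standardized linear score statistic `U_j`, and the `U_j` are jointly
#' asymptotically normal with a correlation matrix `R` determined by the
#' pooled genotype frequencies: with scores `x^(j) = (0, c_j, 1)` and
#' observed pooled frequencies `nbar_i = n_i / n`,
#' `cov(U_j, U_k) propto sum_i nbar_i x_i^(j) x_i^(k) -
#' (sum_i nbar_i x_i^(j))(sum_i nbar_i x_i^(k))`.
#' The summary statistic `W = sum w_j U_j^2` is then asymptotically
#' distributed as `sum_k lambda_k chi^2_1` with `lambda_k` the eigenvalues
#' of `D^{1/2} R D^{1/2}`, `D = diag(w)`. Eigenvalues below `1e-12` are
#' clipped to zero; their sum equals `sum(w)` (trace identity).
#'
#' @inheritParams summary_statistic
#' @return Numeric vector of non-negative eigenvalues (length `m`).
#' @export
null_mixture <- function(counts, spec) {
  stopifnot(inherits(counts, "genotype_counts"), inherits(spec, "summary_spec"))
  nbar <- observed_pooled_freqs(counts)
  cc <- spec$coefficients
  m <- length(cc)
  scores <- rbind(0, cc, 1)                      # 3 x m, column j = x^(j)
  mu <- as.numeric(nbar %*% scores)              # E[x^(j)]
  cov <- crossprod(scores * nbar, scores) - tcrossprod(mu)
  sd <- sqrt(diag(cov))
  if (any(sd <= 0)) abort("degenerate score variance in a component.")
  R <- cov / tcrossprod(sd)
  ev_R <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_R) < -1e-10) abort("component correlation matrix is not PSD.")
  sw <- sqrt(spec$weights)
  M <- R * tcrossprod(sw)
  lambda <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
  lambda[lambda < 1e-12] <- 0
  lambda
}

#' Upper-tail probability of a nonnegative chi-square mixture
#'
#' `P(sum_k lambda_k chi^2_1 > q)` by numerical inversion of the
#' characteristic function (Imhof-type quadrature) to absolute accuracy
#' about `1e-8`. If the quadrature fails to converge, a Satterthwaite
#' moment-matched scaled chi-square is used instead and flagged in the
#' `method` attribute.
#'
#' @param q Observed statistic (non-negative).
#' @param lambda Non-negative mixture weights, not all zero.
#' @param method `"imhof"` (default, with fallback) or `"satterthwaite"`.
#' @return The p-value, with attribute `method` recording which route
#'   produced it.
#' @examples
#' mixture_pvalue(qchisq(0.95, 1), 1)       # 0.05
#' mixture_pvalue(5, c(1.6, 0.4))
#' @export
mixture_pvalue <- function(q, lambda, method = c("imhof", "satterthwaite")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0L) abort("all mixture weights are zero.")
  if (q < 0) abort("`q` must be non-negative.")
  if (q == 0) return(structure(1, method = method))
  p <- NULL
  used <- method
  if (method == "imhof") {
    p <- tryCatch(imhof_upper(q, lambda), error = function(e) NULL)
    if (is.null(p) || !is.finite(p)) {
      used <- "satterthwaite"
      warn("Imhof quadrature did not converge; using Satterthwaite approximation.")
    }
  }
  if (is.null(p) || used == "satterthwaite") {
    p <- satterthwaite_upper(q, lambda)
    used <- "satterthwaite"
  }
  p <- min(max(p, .Machine$double.xmin), 1)
  structure(p, method = used)
}

# Imhof (1961)-type characteristic-function inversion for P(Q > q),
# Q = sum lambda_k chi2_1:  p = 1/2 + (1/pi) int_0^inf sin(theta)/(u rho) du.
# The integrand oscillates with asymptotic phase slope -q/2, so the infinite
# range is summed half-period by half-period; the resulting alternating
# series is accelerated by repeated averaging (Euler transform), giving
# absolute accuracy around 1e-10 in a few dozen terms.
imhof_upper <- function(q, lambda, tol = 1e-9, max_terms = 400L) {
  f <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- 0.5 * (sum(lambda) - q)  # limiting value, continuity
    out
  }
  h <- pi / max(q / 2, 1e-8)
  S <- numeric(max_terms)
  acc <- NA_real_
  for (j in seq_len(max_terms)) {
    tj <- integrate(f, (j - 1) * h, j * h, rel.tol = 1e-12,
                    abs.tol = tol / 10, subdivisions = 200L)$value
    S[j] <- if (j == 1L) tj else S[j - 1L] + tj
    if (j >= 8L && j %% 4L == 0L) {
      v <- S[(j - min(j, 24L) + 1L):j]
      while (length(v) > 1L) v <- (v[-1L] + v[-length(v)]) / 2
      if (!is.na(acc) && abs(v - acc) < tol) return(0.5 + v / pi)
      acc <- v
    }
  }
  abort("quadrature failure: accelerated Imhof sum did not converge.")
}

# Moment-matched scaled chi-square: Q approx s * chi2_k with
# s = sum(l^2)/sum(l), k = sum(l)^2 / sum(l^2).
satterthwaite_upper <- function(q, lambda) {
  s <- sum(lambda^2) / sum(lambda)
  k <- sum(lambda)^2 / sum(lambda^2)
  pchisq(q / s, df = k, lower.tail = FALSE)
}

#' Weighted multi-coefficient summary trend test
#'
#' One single test across several candidate trend coefficients: computes
#' `W = sum_j w_j Z(c_j)`, derives the mixture-of-chi-squares null from the
#' observed pooled genotype frequencies, and returns its upper-tail
#' p-value. Because only the one summary statistic is referred to its null,
#' no multiple-testing adjustment is involved; the per-component results
#' are echoed for reporting only.
#'
#' @inheritParams summary_statistic
#' @return An object of class `summary_trend_test` with elements
#'   `statistic`, `eigenvalues`, `p.value`, `method`, `per_component`
#'   (a tibble), `spec`.
#' @examples
#' gc <- genotype_counts(c(307, 509, 184), c(359, 522, 137))
#' summary_trend_test(gc, summary_spec(c(0.5, 1, 0)))
#' @export
summary_trend_test <- function(counts, spec) {
  stopifnot(inherits(counts, "genotype_counts"), inherits(spec, "summary_spec"))
  per <- purrr::map(spec$coefficients, ~ trend_test(counts, .x))
  z <- vapply(per, `[[`, numeric(1), "statistic")
  W <- sum(spec$weights * z)
  lambda <- null_mixture(counts, spec)
  p <- mixture_pvalue(W, lambda)
  structure(
    list(statistic = W, eigenvalues = lambda, p.value = as.numeric(p),
         method = attr(p, "method"),
         per_component = dplyr::bind_rows(purrr::map(per, tidy)) |>
           dplyr::mutate(weight = spec$weights, .after = "coefficient"),
         spec = spec),
    class = c("summary_trend_test", "optrend_test")
  )
}

#' @export
print.summary_trend_test <- function(x, ...) {
  cat(sprintf("Summary trend test (m = %d): W = %.4f, p = %.3g [%s]\n",
              length(x$spec$coefficients), x$statistic, x$p.value, x$method))
  cat("Null mixture weights:",
      paste(sprintf("%.4f", x$eigenvalues), collapse = ", "), "\n")
  cat("Components:\n")
  print(as.data.frame(x$per_component), digits = 4)
  invisible(x)
}

#' Tidy/glance a summary trend test
#'
#' `tidy()` returns the per-component trend results; `glance()` the one-row
#' summary (W, p-value, mixture method).
#'
#' @param x A `summary_trend_test` object.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
#' @export
tidy.summary_trend_test <- function(x, ...) x$per_component

#' @rdname tidy.summary_trend_test
#' @exportS3Method generics::glance
#' @export
glance.summary_trend_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic,
                 m = length(x$spec$coefficients),
                 p.value = x$p.value, method = x$method)
}
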