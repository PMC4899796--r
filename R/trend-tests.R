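#' Generalized trend test for a 2x3 case-control genotype table
#'
#' Chi-square trend test with genotype scores `(0, c, 1)`, where the
#' heterozygote coefficient `c` may take any real value. With counts
#' `r_i` (cases), `s_i` (controls), margins `n_i`, `r`, `s`, `n` and scores
#' `x_i`, the statistic is
#' \deqn{Z(c) = \frac{n\,[n \sum x_i r_i - r \sum x_i n_i]^2}
#'   {r\,s\,[n \sum x_i^2 n_i - (\sum x_i n_i)^2]},}
#' asymptotically chi-square with 1 df under the null hypothesis of no
#' association. `c = 0.5` is the familiar Cochran-Armitage trend test;
#' `c = 0` and `c = 1` are the recessive and dominant contrasts.
#'
#' @param counts A [genotype_counts()] object.
#' @param coef The heterozygote score coefficient `c`.
#' @param method Label recorded on the result.
#' @return An object of class `trend_test` (also `optrend_test`) with
#'   elements `statistic`, `df`, `p.value`, `coefficient`, `method`.
#' @examples
#' gc <- genotype_counts(c(307, 509, 184), c(359, 522, 137))
#' trend_test(gc, coef = 0.5)   # Cochran-Armitage
#' @export
trend_test <- function(counts, coef = 0.5, method = "trend") {
  stopifnot(inherits(counts, "genotype_counts"))
  if (!is.numeric(coef) || length(coef) != 1L || !is.finite(coef)) {
    abort("`coef` must be a single finite number.")
  }
  m <- stop_if_empty_margin(counts)
  x <- c(0, coef, 1)
  n_i <- m$n_i
  sv <- m$n * sum(x^2 * n_i) - sum(x * n_i)^2
  if (sv <= 0) {
    abort("degenerate score variance: the pooled sample carries no score spread.")
  }
  num <- m$n * (m$n * sum(x * counts$cases) - m$r * sum(x * n_i))^2
  z <- num / (m$r * m$s * sv)
  new_trend_test(statistic = z, df = 1, coefficient = coef, method = method)
}

new_trend_test <- function(statistic, df, coefficient = NA_real_, method) {
  p <- pchisq(statistic, df = df, lower.tail = FALSE)
  flagged <- FALSE
  if (p <= 0) {  # never report exactly zero
    p <- .Machine$double.xmin
    flagged <- TRUE
  }
  structure(
    list(statistic = statistic, df = df, p.value = p,
         coefficient = coefficient, method = method,
         p_floored = flagged),
    class = c("trend_test", "optrend_test")
  )
}

#' Cochran-Armitage trend test
#'
#' The trend test at the gene-dosage scores `(0, 0.5, 1)`.
#'
#' @inheritParams trend_test
#' @return A `trend_test` object.
#' @export
cochran_armitage <- function(counts) {
  trend_test(counts, coef = 0.5, method = "cochran_armitage")
}

#' Pearson chi-square test with 2 degrees of freedom
#'
#' The undirected genotype-association comparator:
#' `sum((O - E)^2 / E)` over the six cells, no continuity correction.
#' Genotypes absent from the whole sample carry no information (their
#' observed and expected counts are both zero) and are dropped, with the
#' degrees of freedom reduced accordingly; at least two genotypes must be
#' observed.
#'
#' @inheritParams trend_test
#' @return A `trend_test` object with `df = 2` (fewer if a genotype column
#'   is empty) and no coefficient.
#' @export
pearson_2df <- function(counts) {
  stopifnot(inherits(counts, "genotype_counts"))
  m <- stop_if_empty_margin(counts)
  keep <- m$n_i > 0
  if (sum(keep) < 2L) {
    abort("zero column margin: fewer than two genotypes observed.")
  }
  obs <- rbind(counts$cases[keep], counts$controls[keep])
  expd <- outer(c(m$r, m$s), m$n_i[keep]) / m$n
  stat <- sum((obs - expd)^2 / expd)
  new_trend_test(statistic = stat, df = sum(keep) - 1L, method = "pearson_2df")
}

#' @export
print.trend_test <- function(x, ...) {
  cat(sprintf("%s: chi-square = %.4f, df = %d, p = %.3g", x$method,
              x$statistic, x$df, x$p.value))
  if (!is.na(x$coefficient)) cat(sprintf("  [c = %.4g]", x$coefficient))
  cat("\n")
  if (isTRUE(x$p_floored)) cat("note: p-value floored at double.xmin\n")
  invisible(x)
}

#' Tidy a trend_test result
#'
#' @param x A `trend_test` object.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `coefficient`, `statistic`, `df`,
#'   `p.value`.
#' @exportS3Method generics::tidy
#' @export
tidy.trend_test <- function(x, ...) {
  tibble::tibble(method = x$method, coefficient = x$coefficient,
                 statistic = x$statistic, df = as.integer(x$df),
                 p.value = x$p.value)
}

#' @rdname tidy.trend_test
#' @exportS3Method generics::glance
#' @export
glance.trend_test <- function(x, ...) tidy(x, ...)

# Vectorized trend statistic over many 2x3 tables (rows of case/control
# count matrices, genotypes in columns). Degenerate tables give NA.
# Used by the Monte-Carlo machinery; semantics identical to trend_test().
z_trend_vec <- function(cases, controls, coef) {
  r <- rowSums(cases); s <- rowSums(controls)
  n1 <- cases[, 2L] + controls[, 2L]
  n2 <- cases[, 3L] + controls[, 3L]
  n <- r + s
  tr <- coef * cases[, 2L] + cases[, 3L]
  tn <- coef * n1 + n2
  sv <- n * (coef^2 * n1 + n2) - tn^2
  z <- n * (n * tr - r * tn)^2 / (r * s * sv)
  z[sv <= 0] <- NA_real_
  z
}
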