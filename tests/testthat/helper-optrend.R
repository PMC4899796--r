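# Shared fixtures, built in code.

# ADPRT Val762Ala x lung cancer case-control table (1000 cases, 1018 controls)
adprt_counts <- function() {
  genotype_counts(cases = c(307, 509, 184), controls = c(359, 522, 137))
}

# The a-priori model used throughout the worked example: HWE controls at
# q = 0.4, gene-dosage, weak mean effect RR = 1.25, moderate heterogeneity
worked_model <- function(cv_rr = 0.4) {
  effect_model(q = 0.4, rr = 1.25, cv_rr = cv_rr, delta = 0, gamma = 0.5)
}

# Independent trend-statistic oracle for arbitrary genotype scores:
# stats::prop.trend.test's chi-square, which is the textbook score-based
# trend statistic and was written independently of this package.
trend_oracle <- function(counts, scores) {
  n_i <- counts$cases + counts$controls
  unname(stats::prop.trend.test(counts$cases, n_i, score = scores)$statistic)
}

# 99% binomial envelope half-width for an empirical rate
binom_envelope <- function(p, reps) stats::qnorm(0.995) * sqrt(p * (1 - p) / reps)
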