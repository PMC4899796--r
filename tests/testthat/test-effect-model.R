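test_that("control frequencies follow the HWD-shifted quadratics", {
  expect_equal(unname(control_freqs(0.4, 0)), c(0.36, 0.48, 0.16))
  expect_equal(unname(control_freqs(0.5, 0)), c(0.25, 0.50, 0.25))
  expect_equal(unname(control_freqs(0.4, 0.05)), c(0.41, 0.38, 0.21))
  expect_error(control_freqs(0.1, 0.5), "admissible range")
  expect_error(control_freqs(0.4, -0.2), "admissible range")
})

test_that("case allele parameter and its Taylor variance match the model", {
  par <- case_allele_param(0.4, 1.25, 0.4)
  expect_equal(par$p_bar, 0.5 / 1.1, tolerance = 1e-12)
  expect_equal(par$delta_var, (par$p_bar * (1 - par$p_bar) * 0.4)^2)
  expect_equal(signif(par$delta_var, 2), 0.0098)
  expect_equal(case_allele_param(0.37, 1, 0.9)$p_bar, 0.37)
  par2 <- case_allele_param(0.4, 2, 0)
  expect_equal(par2$p_bar, 0.8 / 1.4, tolerance = 1e-12)
  expect_equal(par2$delta_var, 0)
})

test_that("special-case case frequencies reproduce the worked example", {
  f <- case_freqs_special(0.4, 1.25, 0.4)
  expect_equal(unname(f), c(0.307356, 0.476197, 0.216447), tolerance = 1e-6)
  expect_equal(unname(round(f, 2)), c(0.31, 0.48, 0.22))
  expect_equal(sum(f), 1, tolerance = 1e-12)
  # null effect degenerates to the control distribution
  expect_equal(case_freqs_special(0.4, 1, 0), control_freqs(0.4, 0))
})

test_that("general construction reduces exactly to the quadratic special case", {
  for (q in c(0.2, 0.4, 0.6)) {
    for (rr in c(0.5, 0.8, 1.25, 2)) {
      for (cv in c(0, 0.4, 1)) {
        m <- effect_model(q = q, rr = rr, cv_rr = cv, delta = 0, gamma = 0.5)
        expect_equal(unname(case_freqs_general(m)),
                     unname(case_freqs_special(q, rr, cv)),
                     tolerance = 1e-8,
                     label = sprintf("q=%g rr=%g cv=%g", q, rr, cv))
      }
    }
  }
})

test_that("recessive and dominant endpoints match direct normalization", {
  # at CV = 0 the construction collapses to control frequencies reweighted
  # by the genotype relative risks (1, RR^(2*gamma), RR^2)
  m0 <- effect_model(q = 0.4, rr = 2, cv_rr = 0, gamma = 0)
  expect_equal(unname(case_freqs_general(m0)),
               c(0.36, 0.48, 0.64) / 1.48, tolerance = 1e-10)
  m1 <- effect_model(q = 0.4, rr = 2, cv_rr = 0, gamma = 1)
  expect_equal(unname(case_freqs_general(m1)),
               c(0.36, 1.92, 0.64) / 2.92, tolerance = 1e-10)
  # and agrees with the oracle at arbitrary gamma
  for (g in c(0.25, 0.7)) {
    m <- effect_model(q = 0.3, rr = 1.6, cv_rr = 0, gamma = g)
    grr <- 1.6^c(0, 2 * g, 2)
    w <- control_freqs(0.3, 0) * grr
    expect_equal(unname(case_freqs_general(m)), unname(w / sum(w)),
                 tolerance = 1e-10)
  }
})

test_that("finite-difference curvature agrees with the symbolic derivative", {
  grid <- list(
    list(q = 0.4, rr = 1.25, cv = 0.4, delta = 0, gamma = 0.5),
    list(q = 0.2, rr = 2, cv = 0.8, delta = 0.02, gamma = 0),
    list(q = 0.6, rr = 0.67, cv = 0.5, delta = -0.01, gamma = 1),
    list(q = 0.4, rr = 1.5, cv = 1, delta = 0, gamma = 0.25),
    list(q = 0.5, rr = 0.8, cv = 0.6, delta = 0.05, gamma = 0.75)
  )
  for (par in grid) {
    m <- effect_model(q = par$q, rr = par$rr, cv_rr = par$cv,
                      delta = par$delta, gamma = par$gamma)
    qf <- control_freqs(par$q, par$delta)
    p_bar <- case_allele_param(par$q, par$rr, par$cv)$p_bar
    g <- optrend:::case_freq_map(m)
    h <- 1e-3 * max(1, abs(p_bar))
    d2 <- function(hh) (g(p_bar + hh) - 2 * g(p_bar) + g(p_bar - hh)) / hh^2
    g2_fd <- (4 * d2(h / 2) - d2(h)) / 3
    for (i in 1:3) {
      e <- c(0, 2 * par$gamma, 2)
      expr <- substitute(
        qi * (p * (1 - q) / (q * (1 - p)))^ei /
          (q0 * (p * (1 - q) / (q * (1 - p)))^e0 +
           q1 * (p * (1 - q) / (q * (1 - p)))^e1 +
           q2 * (p * (1 - q) / (q * (1 - p)))^e2),
        list(qi = unname(qf[i]), ei = e[i], q0 = unname(qf[1]),
             q1 = unname(qf[2]), q2 = unname(qf[3]),
             e0 = e[1], e1 = e[2], e2 = e[3], q = par$q))
      d3 <- stats::deriv3(expr, "p")
      g2_sym <- attr(eval(d3, list(p = p_bar)), "hessian")[1, 1, 1]
      expect_equal(unname(g2_fd[[i]]), g2_sym, tolerance = 1e-6,
                   label = sprintf("g%d'' at q=%g gamma=%g", i - 1,
                                   par$q, par$gamma))
    }
  }
})

test_that("emitted frequency triples stay on the simplex", {
  for (q in c(0.2, 0.5, 0.8)) {
    for (rr in c(0.5, 1, 1.5)) {
      for (cv in c(0, 0.7)) {
        for (g in c(0, 0.5, 1)) {
          f <- case_freqs_general(effect_model(q, rr, cv, 0, g))
          expect_true(all(f >= 0 & f <= 1))
          expect_equal(sum(f), 1, tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the mean case allele parameter is monotone in RR and q", {
  p_rr <- vapply(c(1.1, 1.5, 2, 3),
                 function(rr) case_allele_param(0.4, rr, 0)$p_bar, numeric(1))
  expect_true(all(diff(p_rr) > 0))
  p_q <- vapply(c(0.1, 0.3, 0.5, 0.7),
                function(q) case_allele_param(q, 1.5, 0)$p_bar, numeric(1))
  expect_true(all(diff(p_q) > 0))
})

test_that("inadmissible models are hard errors, never clamped", {
  # large delta relative to q
  expect_error(effect_model(q = 0.05, rr = 1.2, delta = 0.3),
               "admissible range")
  # Var(p) beyond p(1-p): needs cv^2 * p(1-p) > 1, i.e. cv > 2
  expect_error(case_freqs_special(0.5, 1, 2.5), "admissible region")
  expect_error(case_freqs_general(effect_model(q = 0.5, rr = 1, cv_rr = 2.5)),
               "admissible region")
})

test_that("pooled expected frequencies mix cases and controls by design size", {
  p <- case_freqs_special(0.4, 1.25, 0.4)
  qf <- control_freqs(0.4, 0)
  nbar <- pooled_freqs_expected(p, qf, 1000, 1018)
  expect_equal(unname(nbar), c(0.33391, 0.47812, 0.18797), tolerance = 1e-5)
  expect_equal(sum(nbar), 1, tolerance = 1e-12)
  expect_equal(pooled_freqs_expected(p, p, 500, 500), setNames(unname(p), names(p)))
  expect_error(pooled_freqs_expected(p, qf, 1000, 0), "at least 1")
  expect_error(pooled_freqs_expected(c(0.5, 0.6, 0.2), qf, 10, 10), "simplex")
})

test_that("expected_freqs returns the three triples as a tidy table", {
  ef <- expected_freqs(worked_model(), 1000, 1018)
  expect_s3_class(ef, "tbl_df")
  expect_equal(ef$genotype, c("aa", "Aa", "AA"))
  expect_equal(colSums(ef[, c("cases", "controls", "pooled")]),
               c(cases = 1, controls = 1, pooled = 1), tolerance = 1e-12)
})
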