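test_that("seeded draws are reproducible and leave the RNG state alone", {
  m <- worked_model()
  a <- sample_counts(m, 500, 500, seed = 42)
  b <- sample_counts(m, 500, 500, seed = 42)
  expect_identical(a$cases, b$cases)
  expect_identical(a$controls, b$controls)
  d <- sample_counts(m, 500, 500, seed = 43)
  expect_false(identical(a$cases, d$cases) && identical(a$controls, d$controls))

  set.seed(1); before <- .Random.seed
  invisible(sample_counts_individual(m, 200, 200, seed = 9))
  expect_identical(.Random.seed, before)
})

test_that("large samples converge to the model-implied frequencies", {
  m <- worked_model()
  gc <- sample_counts(m, 1e6, 1e6, seed = 314)
  emp <- gc$cases / 1e6
  expect_lt(max(abs(emp - c(0.307356, 0.476197, 0.216447))), 0.002)
  emp_ctrl <- gc$controls / 1e6
  expect_lt(max(abs(emp_ctrl - c(0.36, 0.48, 0.16))), 0.002)
})

test_that("null models put cases and controls on the same distribution", {
  m <- effect_model(q = 0.4, rr = 1, cv_rr = 0)
  reps <- 2000
  withr::with_seed(77, {
    tot <- Reduce(`+`, lapply(seq_len(reps), function(i) {
      gc <- sample_counts(m, 100, 100)
      rbind(gc$cases, gc$controls)
    }))
  })
  expected <- reps * 100 * control_freqs(0.4, 0)
  se <- sqrt(reps * 100 * control_freqs(0.4, 0) * (1 - control_freqs(0.4, 0)))
  expect_true(all(abs(tot[1, ] - expected) < 3 * se))
  expect_true(all(abs(tot[2, ] - expected) < 3 * se))
})

test_that("per-subject relative risks have the requested moments", {
  for (family in c("lognormal", "gamma")) {
    withr::with_seed(123, {
      rr_s <- optrend:::draw_rr(1e5, rr = 1.5, cv = 0.6, family = family)
    })
    expect_lt(abs(mean(rr_s) / 1.5 - 1), 0.02)
    expect_lt(abs((sd(rr_s) / mean(rr_s)) / 0.6 - 1), 0.02)
  }
  expect_equal(optrend:::draw_rr(3, 2, 0, "lognormal"), rep(2, 3))
})

test_that("the individual-level generator matches the multinomial one at CV = 0", {
  m <- effect_model(q = 0.4, rr = 1.6, cv_rr = 0, gamma = 0.5)
  gc <- sample_counts_individual(m, 50000, 10, seed = 2718)
  target <- case_freqs_general(m)
  gof <- chisq.test(gc$cases, p = target)
  expect_gt(gof$p.value, 0.01)
})

test_that("heterogeneous draws shift case mass toward the reference homozygote", {
  # the protective tail of the per-subject RR mixture piles cases onto aa
  # and drains the heterozygote relative to the homogeneous model
  m <- effect_model(q = 0.4, rr = 1.25, cv_rr = 1)
  gc <- sample_counts_individual(m, 100000, 10, seed = 5)
  emp <- gc$cases / 100000
  hom <- case_freqs_general(effect_model(q = 0.4, rr = 1.25, cv_rr = 0))
  expect_gt(emp[[1]], hom[[1]])
  expect_lt(emp[[2]], hom[[2]])
  # the Taylor-based generator shows the same qualitative signature
  taylor <- case_freqs_general(m)
  expect_gt(taylor[[1]], hom[[1]])
  expect_lt(taylor[[2]], hom[[2]])
})

test_that("sample sizes shrink with effect size and blow up at the null", {
  n_by_rr <- vapply(c(1.25, 1.5, 2),
                    function(rr) sample_size_ca(effect_model(q = 0.4, rr = rr)),
                    integer(1))
  expect_true(all(diff(n_by_rr) < 0))
  expect_error(sample_size_ca(effect_model(q = 0.4, rr = 1, cv_rr = 0)),
               "unbounded")
})

test_that("power_study returns a tidy power table with exact bookkeeping", {
  sc <- tibble::tibble(q = 0.4, rr = 1.5, cv_rr = c(0, 0.8),
                       n_cases = 196, n_controls = 196)
  pt <- power_study(sc, reps = 2000, seed = 7)
  expect_s3_class(pt, "power_table")
  expect_equal(nrow(pt), 4)
  expect_setequal(unique(pt$test), c("optimal", "cochran_armitage"))
  expect_true(all(pt$power >= 0 & pt$power <= 1))
  expect_equal(pt$se, sqrt(pt$power * (1 - pt$power) / 2000))
  # identical seed reproduces identical powers
  pt2 <- power_study(sc, reps = 2000, seed = 7)
  expect_identical(pt$power, pt2$power)
  # alpha = 1 rejects everything
  pt3 <- power_study(sc[1, ], reps = 200, alpha = 1, seed = 7)
  expect_true(all(pt3$power == 1))
})

test_that("homogeneous scenarios give both tests the same power", {
  sc <- tibble::tibble(q = 0.4, rr = 1.5, cv_rr = 0,
                       n_cases = 196, n_controls = 196)
  pt <- power_study(sc, reps = 5000, seed = 31)
  pw <- setNames(pt$power, pt$test)
  se_comb <- sqrt(sum(pt$se^2))
  expect_lt(abs(pw[["optimal"]] - pw[["cochran_armitage"]]), 3 * se_comb)
})

test_that("fixed numeric coefficients are accepted as test descriptors", {
  sc <- tibble::tibble(q = 0.4, rr = 1.5, cv_rr = 0,
                       n_cases = 150, n_controls = 150)
  pt <- power_study(sc, tests = c(recessive = 0, dominant = 1),
                    reps = 500, seed = 3)
  expect_setequal(pt$test, c("recessive", "dominant"))
  expect_equal(pt$coefficient, c(0, 1))
})

test_that("the two-subtype population reproduces the marginal-risk reversal", {
  pop <- subtype_population(
    genotype_counts = c(250000, 500000, 250000),
    subtypes = data.frame(baseline = c(0.0001, 0.0020),
                          per_allele = c(10, 0.5)))
  s <- subtype_population_summary(pop)
  expect_equal(unname(s$marginal_risks), c(0.0021, 0.0020, 0.0105))
  expect_equal(round(100 * s$case_shares[[1]]), 73)
  expect_equal(sum(s$case_shares), 1)
  # the marginal risks are nothing like gene-dosage: Aa sits below aa
  expect_lt(s$marginal_risks[["Aa"]], s$marginal_risks[["aa"]])

  single <- subtype_population(c(100, 200, 100),
                               data.frame(baseline = 0.01, per_allele = 2))
  expect_equal(unname(subtype_population_summary(single)$marginal_risks),
               0.01 * c(1, 2, 4))

  twins <- subtype_population(c(100, 200, 100),
                              data.frame(baseline = c(0.01, 0.01),
                                         per_allele = c(2, 2)))
  expect_equal(unname(subtype_population_summary(twins)$case_shares),
               c(0.5, 0.5))

  expect_error(
    subtype_population(c(100, 100, 100),
                       data.frame(baseline = 0.3, per_allele = 2)),
    "leaves \\[0, 1\\]")
})

test_that("plot builders return ggplot objects", {
  sc <- tibble::tibble(q = 0.4, rr = 1.5, cv_rr = c(0, 0.5),
                       n_cases = 100, n_controls = 100)
  pt <- power_study(sc, reps = 200, seed = 2)
  expect_s3_class(autoplot(pt), "ggplot")
  expect_s3_class(plot_trend_curve(adprt_counts()), "ggplot")
})
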