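test_that("membership contingency cross-classifies correctly", {
  fx <- florida_fixtures()
  ids <- c(fx$membership$both, fx$membership$csss_only,
           fx$membership$fsss_only, sprintf("neg%02d", 1:41))
  m_csss <- ids %in% c(fx$membership$both, fx$membership$csss_only)
  m_fsss <- ids %in% c(fx$membership$both, fx$membership$fsss_only)
  ct <- membership_contingency(m_csss, m_fsss)
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(12, 7, 7, 41))

  same <- c(TRUE, FALSE, TRUE)
  ct2 <- membership_contingency(same, same)
  expect_equal(c(ct2$b, ct2$c), c(0, 0))
  ct3 <- membership_contingency(same, !same)
  expect_equal(c(ct3$a, ct3$d), c(0, 0))
  expect_error(membership_contingency(same, same[1:2]), "length")
})

test_that("exact McNemar follows the binomial closed form and is symmetric", {
  expect_equal(exact_mcnemar(c(12, 7, 7, 41)), 1)
  expect_equal(exact_mcnemar(c(10, 5, 0, 10)), 2 * 0.5^5)
  expect_equal(exact_mcnemar(c(10, 0, 0, 10)), 1)
  set.seed(19)
  for (i in 1:20) {
    b <- sample(0:10, 1); c <- sample(0:10, 1)
    expect_equal(exact_mcnemar(c(3, b, c, 5)), exact_mcnemar(c(3, c, b, 5)))
  }
})

test_that("kappa and PABAK reproduce published and hand-computed values", {
  st <- kappa_stats(c(12, 7, 7, 41))
  expect_equal(round(100 * st$Po, 1), 79.1)
  expect_equal(round(100 * st$Pe, 2), 59.37)
  expect_equal(round(st$kappa, 4), 0.4857)
  expect_equal(round(st$kappa_ci, 4), c(0.2462, 0.7253), tolerance = 1e-3)
  expect_equal(round(st$pabak, 4), 0.5821)
  expect_equal(round(st$pabak_ci, 4), c(0.3487, 0.7616))
  expect_equal(st$kappa_label, "Moderate agreement")
  expect_equal(st$pabak_label, "Moderate agreement")
  expect_lt(st$kappa_p, 5e-4)
  expect_lt(st$pabak_p, 1e-4)

  perfect <- kappa_stats(c(10, 0, 0, 10))
  expect_equal(perfect$kappa, 1)
  expect_equal(perfect$pabak, 1)
  hand <- kappa_stats(c(45, 5, 5, 45))
  expect_equal(hand$Po, 0.9)
  expect_equal(hand$Pe, 0.5)
  expect_equal(hand$kappa, 0.8)
  # kappa equals PABAK under balanced marginals at prevalence one half
  expect_equal(hand$kappa, hand$pabak)
})

test_that("agreement coefficients respect their analytic bounds", {
  set.seed(20)
  for (i in 1:50) {
    t <- sample(0:30, 4, replace = TRUE)
    if (sum(t) == 0) next
    st <- kappa_stats(t)
    expect_gte(st$pabak, -1); expect_lte(st$pabak, 1)
    if (!is.na(st$kappa)) {
      expect_lte(st$kappa, st$Po + 1e-12)
      expect_lte(st$kappa, 1)
    }
  }
})

test_that("proportion test matches the published calls and the Yates formula", {
  big <- proportion_test(214421, 705718, 179847, 705718)
  expect_lt(big$p_value, 1e-4)
  eq <- proportion_test(30, 100, 30, 100)
  expect_equal(eq$p_value, 1)
  # hand evaluation of the pooled continuity-corrected chi-square
  yates <- function(x1, n1, x2, n2) {
    n <- n1 + n2; x <- x1 + x2
    n * (abs(x1 * (n2 - x2) - x2 * (n1 - x1)) - n / 2)^2 /
      (n1 * n2 * x * (n - x))
  }
  got <- proportion_test(30, 100, 20, 100)
  expect_equal(got$statistic, yates(30, 100, 20, 100), tolerance = 1e-12)
  expect_equal(got$statistic, 2.16)
})

test_that("CLIC follows its closed form and monotonicities", {
  expect_equal(clic(10, exp(2))$value, -18)
  base <- clic(c(3, 4), 1000, 2)
  expect_equal(clic(c(6, 8), 1000, 2)$value - log(1000) * 2,
               2 * (base$value - log(1000) * 2))
  # decreasing in the LLR sum, increasing in n and population
  expect_lt(clic(c(3, 5), 1000, 2)$value, base$value)
  expect_gt(clic(c(3, 4), 1000, 3)$value, base$value)
  expect_gt(clic(c(3, 4), 2000, 2)$value, base$value)
  expect_error(clic(numeric(0), 10), "at least one")
  expect_error(clic(5, 0), "positive")
})

test_that("compare_scans assembles a coherent report on synthetic data", {
  d <- generate_region_data(scenario_suite()[["disk-hotspot"]], seed = 13)
  rc <- circular_scan(d$area, scan_config("circular", n_sim = 99, seed = 2))
  rf <- flexible_scan(d$area, scan_config("flexible", max_window = 5,
                                          n_sim = 99, seed = 2),
                      adjacency = d$adjacency)
  cmp <- compare_scans(rc, rf, d$area)
  ct <- cmp$contingency
  expect_equal(ct$a + ct$b + ct$c + ct$d, 100)
  expect_equal(ct$a + ct$c, sum(cluster_membership(rc)))
  expect_true(cmp$mcnemar_p >= 0 && cmp$mcnemar_p <= 1)
  expect_equal(cmp$method1$cases,
               sum(d$area$regions$cases[cluster_membership(rc)]))
  if (!is.null(cmp$method1$clic)) {
    expect_equal(cmp$method1$clic$magnitude, abs(cmp$method1$clic$value))
  }
})
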