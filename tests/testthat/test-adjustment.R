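test_that("intercept-only offset model reproduces indirect standardisation", {
  set.seed(14)
  n <- 30
  pop <- sample(1000:50000, n)
  area <- toy_area(x = runif(n), y = runif(n), population = pop,
                   cases = rpois(n, 0.04 * pop), ids = sprintf("a%02d", 1:n))
  m <- fit_poisson_offset(area, character())
  expect_equal(unname(m$fitted), null_expected(area), tolerance = 1e-8)
  expect_lt(abs(sum(m$fitted) - area$C), 1e-6 * area$C)
})

test_that("a binary covariate recovers the closed-form group rates", {
  set.seed(15)
  n <- 40
  grp <- rep(c(0, 1), each = n / 2)
  pop <- sample(5000:20000, n)
  cases <- rpois(n, pop * ifelse(grp == 1, 0.06, 0.03))
  area <- toy_area(x = runif(n), y = runif(n), population = pop,
                   cases = cases, ids = sprintf("b%02d", 1:n), grp = grp)
  m <- fit_poisson_offset(area, "grp")
  for (g in 0:1) {
    sel <- grp == g
    rate_hat <- m$fitted[sel] / pop[sel]
    rate_mle <- sum(cases[sel]) / sum(pop[sel])
    expect_true(all(abs(rate_hat - rate_mle) < 1e-7 * rate_mle))
  }
})

test_that("known coefficients are recovered within sampling error", {
  # Wald z-scores for (b0, b1) over repeated simulations should behave
  # like standard normals: 3-SE coverage misses should be rare events
  set.seed(16)
  n <- 200
  b0 <- -3.3; b1 <- 0.02
  miss <- 0L
  zs <- numeric(0)
  for (rep in 1:20) {
    hyp <- rnorm(n, 34.6, 5)
    pop <- sample(1e4:2e5, n)
    cases <- rpois(n, pop * exp(b0 + b1 * hyp))
    area <- toy_area(x = runif(n), y = runif(n), population = pop,
                     cases = cases, ids = sprintf("c%03d", 1:n),
                     hypertension = hyp)
    m <- fit_poisson_offset(area, "hypertension")
    z <- abs((m$coefficients - c(b0, b1)) / m$se)
    zs <- c(zs, z)
    if (any(z > 3)) miss <- miss + 1L
    # standardisation constraint holds on every fit
    expect_lt(abs(sum(m$fitted) - area$C), 1e-6 * area$C)
  }
  expect_lte(miss, 2L)        # ~0.5% chance per fit of a 3-SE miss
  expect_lt(mean(zs), 1.5)    # E|Z| is about 0.8 for a standard normal
})

test_that("a constant covariate changes no fitted value; collinearity errors", {
  set.seed(17)
  n <- 25
  pop <- sample(2000:9000, n)
  cases <- rpois(n, 0.05 * pop)
  x <- rnorm(n, 10, 2)
  area <- toy_area(x = runif(n), y = runif(n), population = pop,
                   cases = cases, ids = sprintf("d%02d", 1:n),
                   real = x, flat = rep(7, n), dup = 2 * x)
  m1 <- fit_poisson_offset(area, "real")
  expect_warning(m2 <- fit_poisson_offset(area, c("real", "flat")),
                 "constant")
  expect_equal(unname(m1$fitted), unname(m2$fitted), tolerance = 1e-8)
  expect_error(fit_poisson_offset(area, c("real", "dup")), "rank deficient")
})

test_that("null covariate effects make the adjusted scan the unadjusted one", {
  d <- generate_region_data(scenario_suite()[["null-10x10"]], seed = 23)
  cfg <- scan_config("circular", n_sim = 49, seed = 31)
  m0 <- fit_poisson_offset(d$area, character())
  r_adj <- adjusted_scan(d$area, m0, cfg)
  r_raw <- circular_scan(d$area, cfg)
  expect_identical(r_raw$repmax, r_adj$repmax)
  expect_equal(r_raw$candidates$llr, r_adj$candidates$llr)
  expect_equal(r_raw$candidates$p_value, r_adj$candidates$p_value)
})

test_that("published adjusted-cluster risk ratios are reproduced", {
  fx <- florida_fixtures()
  C <- unname(fx$totals["C"])
  rr <- risk_ratios(fx$adjusted$observed, fx$adjusted$expected, C)
  expect_equal(round(rr$rr_io, 2), fx$adjusted$pr_printed)
})

test_that("a covariate-explained hotspot disappears after adjustment", {
  d <- generate_region_data(scenario_suite()[["covariate-driven"]], seed = 41)
  cfg <- scan_config("circular", n_sim = 99, seed = 43)
  truth <- names(which(d$truth))
  r_u <- circular_scan(d$area, cfg)
  hit_u <- any(vapply(r_u$clusters$members,
                      function(m) length(intersect(m, truth)) > 0, NA))
  expect_true(hit_u)
  m <- fit_poisson_offset(d$area)
  r_a <- adjusted_scan(d$area, m, cfg)
  hit_a <- nrow(r_a$clusters) > 0 &&
    any(vapply(r_a$clusters$members,
               function(m2) length(intersect(m2, truth)) > 0, NA))
  expect_false(hit_a)
})
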