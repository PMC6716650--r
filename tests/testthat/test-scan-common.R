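test_that("null expected counts are proportional to population and sum to C", {
  area <- toy_area(x = 0:1, y = c(0, 0), population = c(100, 300),
                   cases = c(10, 30))
  expect_equal(null_expected(area), c(10, 30))

  eq <- toy_area(x = 0:3, y = rep(0, 4), population = rep(50, 4),
                 cases = c(1, 2, 3, 4))
  expect_equal(null_expected(eq), rep(2.5, 4))

  set.seed(3)
  n <- 67
  big <- toy_area(x = runif(n), y = runif(n),
                  population = sample(1e4:2.5e6, n),
                  cases = rep(1, n), ids = sprintf("r%02d", 1:n))
  e <- null_expected(big)
  expect_lt(abs(sum(e) - big$C), 1e-9 * big$C)
  expect_error(null_expected(big, rep(0, n)), "positive")
})

test_that("poisson_llr matches the closed form and the dpois oracle", {
  expect_equal(poisson_llr(10, 10, 100), 0)
  expect_equal(poisson_llr(0, 5, 100), 0)          # deficit zone, high-only
  expect_gt(poisson_llr(0, 5, 100, high_only = FALSE), 0)
  expect_equal(poisson_llr(74397, 48017.14, 705718), 6731.687,
               tolerance = 1e-6)
  # finite at c = C
  expect_true(is.finite(poisson_llr(100, 40, 100)))

  set.seed(11)
  C <- 1e5
  e <- runif(1000, 1, C - 1)
  c <- pmin(C, rpois(1000, e * runif(1000, 0.5, 2)))
  keep <- c > 0 & c < C
  got <- poisson_llr(c[keep], e[keep], C, high_only = FALSE)
  want <- oracle_llr(c[keep], e[keep], C)
  expect_equal(got, want, tolerance = 1e-9)

  expect_error(poisson_llr(5, 0, 10), "0 < e < C")
  expect_error(poisson_llr(5, 10, 10), "0 < e < C")
})

test_that("risk ratios reproduce both published conventions", {
  C <- 705718
  expect_equal(round(risk_ratios(74397, 48017.14, C)$rr_io, 2), 1.61)
  expect_equal(round(risk_ratios(112106, 73405.80, C)$oe, 2), 1.53)
  rr <- risk_ratios(50, 50, 1000)
  expect_equal(rr$rr_io, 1)
  expect_equal(rr$oe, 1)
})

test_that("Monte Carlo p-values follow the (1+r)/(1+R) rank convention", {
  # rank arithmetic against a brute-force count, including ties
  repmax <- c(5, 3, 3, 2, 8, 1, 3, 9, 2, 4, 6, 7, 1, 2, 5, 3, 8, 4, 10)
  stats <- c(0, 1, 3, 3.5, 10, 11)
  got <- arealscan:::p_from_repmax(stats, repmax)
  want <- (1 + vapply(stats, function(s) sum(repmax >= s), 0)) /
    (length(repmax) + 1)
  expect_equal(got, want)
  # observed ranked 2nd among 19 replicates -> p = 2/20
  expect_equal(arealscan:::p_from_repmax(9.5, repmax), 0.1)
})

test_that("monte_carlo_test conditions on C and bounds p correctly", {
  set.seed(5)
  area <- toy_area(x = runif(12), y = runif(12),
                   population = rep(1000, 12),
                   cases = rpois(12, 37), ids = sprintf("z%02d", 1:12))
  zones <- list(c("z01", "z02"), c("z05"), c("z07", "z08", "z09"))
  seen_totals <- NULL
  stat_spy <- function(CZ, ez, C, X, e_i) {
    seen_totals <<- c(seen_totals, colSums(X))
    arealscan:::llr_matrix(CZ, ez, C)
  }
  mc <- monte_carlo_test(area, zones, statistic = stat_spy,
                         n_sim = 50, seed = 9)
  # every replicate redistributes exactly C cases
  expect_length(seen_totals, 51)  # observed pass + 50 replicates
  expect_true(all(seen_totals == area$C))
  expect_true(all(mc$p >= 1 / 51 & mc$p <= 1))
  # a zero observed statistic can never beat a replicate
  mc0 <- monte_carlo_test(area, zones, n_sim = 19, seed = 1)
  expect_true(all(mc0$p[mc0$stat == 0] == 1))
  # reproducibility
  mc2 <- monte_carlo_test(area, zones, n_sim = 19, seed = 1)
  expect_identical(mc0$repmax, mc2$repmax)
  expect_error(monte_carlo_test(area, zones, n_sim = 0), "n_sim")
})

test_that("select_clusters enforces non-overlap, filters and ranks", {
  zones <- data.frame(llr = c(10, 8, 6),
                      p_value = c(0.001, 0.001, 0.001),
                      rr_io = c(1.5, 1.4, 1.15), oe = c(1.5, 1.4, 1.15))
  zones$members <- list(c("A", "B"), c("B", "C"), c("D"))
  out <- select_clusters(zones)
  # the statistic-8 zone overlaps the kept statistic-10 zone; the rr 1.15
  # zone fails the PR floor
  expect_equal(nrow(out), 1)
  expect_equal(out$llr, 10)
  expect_equal(out$rank, 1)

  # five disjoint strong zones all survive, primary = largest statistic
  tab <- florida_fixtures()$csss
  C <- 705718
  zc <- data.frame(llr = poisson_llr(tab$observed, tab$expected, C),
                   p_value = rep(0.001, 5),
                   risk_ratios(tab$observed, tab$expected, C))
  zc$members <- list("m1", "m2", "m3", "m4", "m5")
  kept <- select_clusters(zc)
  expect_equal(nrow(kept), 5)
  expect_equal(kept$llr[1], max(zc$llr))
  expect_true(all(diff(kept$llr) <= 0))
  # pairwise disjoint property
  all_members <- unlist(kept$members)
  expect_equal(anyDuplicated(all_members), 0)
})
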