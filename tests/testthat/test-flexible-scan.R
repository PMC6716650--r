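test_that("flexible enumeration on a path graph keeps only connected sets", {
  area <- toy_area(x = c(0, 1, 2), y = c(0, 0, 0),
                   population = c(10, 10, 10), cases = c(1, 1, 1))
  adj <- rbind(c("A", "B"), c("B", "C"))
  fam <- enumerate_flexible(area, K = 3, adjacency = adj)
  keys <- zone_key_set(fam$members, fam$ids)
  # of the 7 non-empty subsets only {A,C} is disconnected
  expect_setequal(keys, c("A", "B", "C", "A,B", "B,C", "A,B,C"))

  fam1 <- enumerate_flexible(area, K = 1, adjacency = adj)
  expect_setequal(zone_key_set(fam1$members, fam1$ids), c("A", "B", "C"))
})

test_that("flexible enumeration equals the exhaustive subset oracle", {
  for (seed in c(2, 13, 31)) {
    set.seed(seed)
    n <- 12
    area <- toy_area(x = runif(n), y = runif(n),
                     population = rep(100, n), cases = rpois(n, 4),
                     ids = sprintf("g%02d", 1:n))
    adj <- knn_adjacency(area, k = 3)
    K <- 4
    fam <- enumerate_flexible(area, K = K, adjacency = adj)
    want <- oracle_flexible_zones(area, K = K, adjacency = adj)
    expect_setequal(zone_key_set(fam$members, fam$ids),
                    zone_key_set(want, area$regions$id))
  }
  # rook lattice instance at n = 9, K = 9 (whole-grid neighbourhoods)
  d <- generate_region_data(simulation_scenario(
    lattice = list(type = "grid", nrow = 3, ncol = 3),
    population = list(type = "fixed", value = 100)), seed = 1)
  fam <- enumerate_flexible(d$area, K = 9, adjacency = d$adjacency)
  want <- oracle_flexible_zones(d$area, K = 9, adjacency = d$adjacency)
  expect_setequal(zone_key_set(fam$members, fam$ids),
                  zone_key_set(want, d$area$regions$id))
  expect_error(enumerate_flexible(d$area, K = 5, adjacency = d$adjacency,
                                  zone_budget = 10), "zone_budget")
})

test_that("flexible family contains the circular zones it should nest", {
  set.seed(4)
  n <- 14
  area <- toy_area(x = runif(n), y = runif(n),
                   population = rep(100, n), cases = rpois(n, 4),
                   ids = sprintf("h%02d", 1:n))
  K <- 5
  # fully connected adjacency: connectivity never rejects a subset
  adj <- t(utils::combn(area$regions$id, 2))
  flex <- zone_key_set(enumerate_flexible(area, K = K, adjacency = adj)$members,
                       area$regions$id)
  circ_fam <- enumerate_circular(area, 0.3)
  circ <- circ_fam$members[lengths(circ_fam$members) <= K]
  nb <- k_nearest(area, K)
  ids <- area$regions$id
  for (mem in circ) {
    centred <- any(vapply(mem, function(ctr) {
      all(ids[mem] %in% c(ids[ctr], nb[[ids[ctr]]]))
    }, NA))
    if (centred) {
      expect_true(paste(sort(ids[mem]), collapse = ",") %in% flex)
    }
  }
})

test_that("region mid-p agrees with Poisson tail sums", {
  # oracle: explicit tail summation of the Poisson pmf
  tail_sum <- function(c, e) sum(dpois((c + 1):(c + 400), e)) +
    0.5 * dpois(c, e)
  expect_equal(region_mid_p(10, 5), tail_sum(10, 5), tolerance = 1e-10)
  expect_equal(region_mid_p(10, 5), 0.02276166, tolerance = 1e-6)
  expect_gt(region_mid_p(5, 10), 0.9)
  expect_equal(region_mid_p(0, 1e-9), 0.5, tolerance = 1e-6)
  expect_gt(region_mid_p(0, 1e-9, mid_p = FALSE), 0.999)
})

test_that("restricted LLR kills zones with any cold member", {
  expect_equal(restricted_llr(5, list(c(0.01, 0.1)), alpha1 = 0.2), 5)
  expect_equal(restricted_llr(5, list(c(0.01, 0.5)), alpha1 = 0.2), 0)
  set.seed(6)
  llr <- runif(50, 0, 10)
  ps <- replicate(50, runif(sample(1:5, 1)), simplify = FALSE)
  r <- restricted_llr(llr, ps, alpha1 = 0.3)
  expect_true(all(r <= llr))
  expect_true(all(r == 0 | r == llr))
})

test_that("an L-shaped hotspot: flexible matches truth, circular overshoots", {
  d <- generate_region_data(scenario_suite()[["l-hotspot"]], seed = 2)
  truth <- names(which(d$truth))
  fam <- enumerate_flexible(d$area, K = 6, adjacency = d$adjacency)
  rf <- flexible_scan(d$area,
                      scan_config("flexible", max_window = 6, n_sim = 99,
                                  seed = 4),
                      zones = fam)
  rc <- circular_scan(d$area, scan_config("circular", n_sim = 99, seed = 4))
  expect_gte(nrow(rf$clusters), 1)
  jf <- jaccard(rf$clusters$members[[1]], truth)
  jc <- jaccard(rc$clusters$members[[1]], truth)
  expect_gte(jf, 0.8)
  expect_gt(jf, jc)
  # circular best zone drags in at least one non-hotspot region
  expect_gte(length(setdiff(rc$clusters$members[[1]], truth)), 1)
})

test_that("an all-deficit area yields no flexible clusters", {
  area <- toy_area(x = rep(1:3, 3), y = rep(1:3, each = 3),
                   population = rep(100, 9), cases = rep(0L, 9),
                   ids = sprintf("n%d", 1:9))
  area$regions$cases[1] <- 1L  # C must be positive for expected counts
  area <- study_area(area$regions, coordinate_mode = "planar")
  res <- flexible_scan(area, scan_config("flexible", max_window = 3,
                                         n_sim = 19, seed = 1))
  expect_equal(nrow(res$clusters), 0)
})
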