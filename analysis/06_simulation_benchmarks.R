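#!/usr/bin/env Rscript
# Step 6: operating characteristics of the two scan engines on the
# benchmark lattices: empirical size on null grids, localisation
# (Jaccard overlap with the embedded zone) on compact and L-shaped
# hotspots, and the effect of covariate adjustment on a covariate-driven
# hotspot. Smaller replicate counts than the test suite, meant as a
# narrative summary table.

suppressMessages(library(arealscan))
suite <- scenario_suite()
n_runs <- 50

bench <- function(scenario, method, K = 5, adjusted = FALSE) {
  d0 <- generate_region_data(scenario, seed = 1)
  dm <- region_distances(d0$area)
  famC <- enumerate_circular(d0$area, 0.13, dist_matrix = dm)
  famF <- if (method == "flexible") {
    enumerate_flexible(d0$area, K = K, adjacency = d0$adjacency,
                       dist_matrix = dm)
  } else NULL
  sig <- 0; jac <- numeric(n_runs)
  for (i in seq_len(n_runs)) {
    d <- generate_region_data(scenario, seed = 1000 + i)
    truth <- names(which(d$truth))
    if (method == "circular") {
      cfg <- scan_config("circular", n_sim = 199, seed = 5000 + i)
      r <- if (adjusted) {
        adjusted_scan(d$area, fit_poisson_offset(d$area), cfg,
                      dist_matrix = dm)
      } else circular_scan(d$area, cfg, zones = famC)
    } else {
      cfg <- scan_config("flexible", max_window = K, n_sim = 199,
                         seed = 5000 + i)
      r <- flexible_scan(d$area, cfg, zones = famF)
    }
    sig <- sig + (r$most_likely$p_value <= 0.05)
    jac[i] <- if (nrow(r$clusters) > 0 && length(truth) > 0) {
      max(vapply(r$clusters$members, function(m)
        length(intersect(m, truth)) / length(union(m, truth)), 0))
    } else NA
  }
  c(reject_rate = sig / n_runs, mean_jaccard = mean(jac, na.rm = TRUE))
}

rows <- rbind(
  cbind(scenario = "null-10x10", method = "circular",
        t(bench(suite[["null-10x10"]], "circular"))),
  cbind(scenario = "null-10x10", method = "flexible",
        t(bench(suite[["null-10x10"]], "flexible"))),
  cbind(scenario = "disk-hotspot", method = "circular",
        t(bench(suite[["disk-hotspot"]], "circular"))),
  cbind(scenario = "l-hotspot", method = "circular",
        t(bench(suite[["l-hotspot"]], "circular"))),
  cbind(scenario = "l-hotspot", method = "flexible",
        t(bench(suite[["l-hotspot"]], "flexible", K = 6))),
  cbind(scenario = "covariate-driven", method = "circular",
        t(bench(suite[["covariate-driven"]], "circular"))),
  cbind(scenario = "covariate-driven", method = "circular-adjusted",
        t(bench(suite[["covariate-driven"]], "circular", adjusted = TRUE))))
df <- as.data.frame(rows)
print(df, row.names = FALSE)
write.csv(df, "results/simulation_benchmarks.csv", row.names = FALSE)
cat("\nExpected pattern: ~5% rejections on the nulls; near-1 localisation\n",
    "for the compact hotspot; flexible beats circular on the L; the\n",
    "covariate-driven hotspot disappears after adjustment.\n")
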