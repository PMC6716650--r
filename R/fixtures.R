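#' Published Florida stroke-cluster summary tables
#'
#' Read-only transcriptions of the printed county-level results of a 2013
#' Florida BRFSS stroke-prevalence cluster analysis, bundled so that the
#' arithmetic of the package (risk ratios, log-likelihood ratios, agreement
#' statistics, the Cluster Information Criterion) can be checked against
#' published numbers without access to the original microdata.
#'
#' The bundle contains:
#' \describe{
#'   \item{`csss`}{The five circular-scan clusters: population, observed
#'     and expected cases (expected printed to 2 decimals), the printed
#'     prevalence ratio, county count and Monte Carlo p-value string.}
#'   \item{`fsss`}{The six flexible-scan clusters, same columns.}
#'   \item{`adjusted`}{The two covariate-adjusted circular-scan clusters
#'     (observed, adjusted expected, printed prevalence ratio).}
#'   \item{`contingency`}{The 2x2 county-membership contingency between
#'     the two methods: both-positive 12, each-method-only 7, both-negative
#'     41, over 67 counties.}
#'   \item{`membership`}{Named logical county lists behind the
#'     contingency: the 12 counties flagged by both methods and the 7
#'     flagged by each method alone.}
#'   \item{`totals`}{Study-area totals: 705,718 cases over a population of
#'     19,314,396, and per-method cluster case/population totals.}
#' }
#'
#' @return A named list of data frames and vectors as described above.
#' @examples
#' fx <- florida_fixtures()
#' sum(fx$csss$observed)  # 214421
#' @export
florida_fixtures <- function() {
  csss <- data.frame(
    cluster = 1:5,
    population = c(1314154, 549144, 2210618, 39770, 148189),
    observed = c(74397, 32949, 97622, 2784, 6669),
    expected = c(48017.14, 20064.86, 80772.54, 1453.12, 5414.59),
    pr_printed = c(1.61, 1.67, 1.24, 1.91, 1.23),
    n_regions = c(14L, 1L, 2L, 1L, 1L),
    p_value = rep("<0.001", 5L)
  )
  fsss <- data.frame(
    cluster = 1:6,
    population = c(2009003, 1074486, 139787, 56629, 148189, 11613),
    observed = c(112106, 50139, 7129, 3212, 6669, 592),
    expected = c(73405.80, 39260.00, 5107.60, 2069.14, 5414.60, 424.32),
    pr_printed = c(1.53, 1.28, 1.40, 1.55, 1.23, 1.40),
    n_regions = c(7L, 7L, 1L, 2L, 1L, 1L),
    p_value = rep("0.001", 6L)
  )
  adjusted <- data.frame(
    cluster = 1:2,
    observed = c(8052, 32949),
    expected = c(3207.44, 26527.38),
    pr_printed = c(2.53, 1.25),
    n_regions = c(1L, 1L),
    p_value = rep("<0.001", 2L)
  )
  both <- c("Bradford", "Brevard", "Citrus", "Columbia", "Dixie", "Levy",
            "Marion", "Martin", "Putnam", "Sumter", "Suwannee", "Union")
  csss_only <- c("Alachua", "Gilchrist", "Hernando", "Lafayette",
                 "Hillsborough", "Pinellas", "Okeechobee")
  fsss_only <- c("Baker", "Duval", "Franklin", "Hamilton", "Indian River",
                 "Lake", "Volusia")
  list(
    csss = csss,
    fsss = fsss,
    adjusted = adjusted,
    contingency = c(a = 12L, b = 7L, c = 7L, d = 41L),
    membership = list(both = both, csss_only = csss_only,
                      fsss_only = fsss_only, n_regions = 67L),
    totals = c(C = 705718, N = 19314396,
               cases_csss = 214421, cases_fsss = 179847,
               pop_csss = 4261875, pop_fsss = 3439707)
  )
}
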