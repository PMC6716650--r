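#' Region membership vector of a scan result
#'
#' A logical vector over the study-area regions: `TRUE` where the region
#' belongs to any reported cluster (i.e. after the significance and
#' prevalence-ratio filters).
#'
#' @param result A `scan_result`.
#' @return Named logical vector in region order.
#' @export
cluster_membership <- function(result) {
  stopifnot(inherits(result, "scan_result"))
  ids <- result$area_ids
  members <- unlist(result$clusters$members)
  stats::setNames(ids %in% members, ids)
}

#' 2x2 membership contingency between two cluster solutions
#'
#' Cross-classifies regions by cluster membership under two methods:
#' `a` = positive under both, `b` = method-2 only, `c` = method-1 only,
#' `d` = negative under both.
#'
#' @param m1,m2 Logical membership vectors of equal length over the same
#'   regions in the same order (e.g. from [cluster_membership()]).
#' @return An object of class `membership_contingency` with fields
#'   `a`, `b`, `c`, `d` and `n`.
#' @examples
#' membership_contingency(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
membership_contingency <- function(m1, m2) {
  if (length(m1) != length(m2)) {
    stop("membership vectors differ in length")
  }
  m1 <- as.logical(m1); m2 <- as.logical(m2)
  structure(list(a = sum(m1 & m2), b = sum(!m1 & m2),
                 c = sum(m1 & !m2), d = sum(!m1 & !m2),
                 n = length(m1)),
            class = "membership_contingency")
}

#' @export
print.membership_contingency <- function(x, ...) {
  m <- matrix(c(x$a, x$b, x$c, x$d), 2, 2, byrow = TRUE,
              dimnames = list(`method 2` = c("cluster +", "cluster -"),
                              `method 1` = c("cluster +", "cluster -")))
  print(m)
  invisible(x)
}

as_contingency <- function(t) {
  if (inherits(t, "membership_contingency")) return(t)
  if (is.numeric(t) && length(t) == 4L) {
    return(structure(list(a = t[[1]], b = t[[2]], c = t[[3]], d = t[[4]],
                          n = sum(t)), class = "membership_contingency"))
  }
  stop("expected a membership_contingency or a numeric (a, b, c, d)")
}

#' Exact McNemar test for paired binary classifications
#'
#' Two-sided exact test on the discordant cells of a 2x2 membership
#' contingency: with `m = b + c` discordant regions, under the null the
#' discordances split Binomial(m, 1/2), and
#' `p = min(1, 2 * P(X <= min(b, c)))`; `p = 1` when there are no
#' discordant pairs. Symmetric in `b` and `c`.
#'
#' @param t A `membership_contingency` or numeric `(a, b, c, d)`.
#' @return The two-sided exact p-value.
#' @examples
#' exact_mcnemar(c(12, 7, 7, 41))  # 1
#' @export
exact_mcnemar <- function(t) {
  t <- as_contingency(t)
  m <- t$b + t$c
  if (m == 0L) return(1)
  min(1, 2 * stats::pbinom(min(t$b, t$c), m, 0.5))
}

#' Cohen's kappa, PABAK and agreement summary for a 2x2 table
#'
#' Chance-corrected agreement between two binary cluster solutions.
#' `Po = (a+d)/n` is the observed agreement, `Pe` the agreement expected
#' from the marginals, `kappa = (Po - Pe)/(1 - Pe)` with the Fleiss
#' large-sample standard error `sqrt(Po(1-Po)/(n(1-Pe)^2))` for its
#' confidence interval. The prevalence-and-bias-adjusted kappa
#' (PABAK, the S coefficient) is `2*Po - 1`; its confidence interval is
#' the transformed exact (Clopper-Pearson) binomial interval of `Po`, and
#' its test against 0 the exact binomial test of `Po = 1/2`. Labels follow
#' the Landis-Koch bands (<0 none, 0-0.2 slight, 0.2-0.4 fair, 0.4-0.6
#' moderate, 0.6-0.8 substantial, 0.8-1 almost perfect).
#'
#' @param t A `membership_contingency` or numeric `(a, b, c, d)`.
#' @param conf_level Confidence level (default 0.95).
#' @return A list of class `agreement_stats`: `Po`, `Pe`, `kappa`,
#'   `kappa_ci`, `kappa_p`, `pabak`, `pabak_ci`, `pabak_p`, and
#'   interpretation labels for both coefficients.
#' @examples
#' kappa_stats(c(12, 7, 7, 41))$kappa  # 0.4857
#' @export
kappa_stats <- function(t, conf_level = 0.95) {
  t <- as_contingency(t)
  n <- t$n
  if (n <= 0) stop("empty contingency")
  Po <- (t$a + t$d) / n
  p1 <- (t$a + t$c) / n   # method-1 positive marginal
  p2 <- (t$a + t$b) / n   # method-2 positive marginal
  Pe <- p1 * p2 + (1 - p1) * (1 - p2)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  if (Pe >= 1) {
    kappa <- NA_real_
    kappa_ci <- c(NA_real_, NA_real_)
    kappa_p <- NA_real_
  } else {
    kappa <- (Po - Pe) / (1 - Pe)
    se <- sqrt(Po * (1 - Po) / (n * (1 - Pe)^2))
    kappa_ci <- kappa + c(-1, 1) * z * se
    # large-sample test of kappa = 0 (Fleiss null standard error)
    se0 <- sqrt((Pe + Pe^2 -
                   (p1 * p2 * (p1 + p2) +
                      (1 - p1) * (1 - p2) * (2 - p1 - p2))) /
                  (n * (1 - Pe)^2))
    kappa_p <- 2 * stats::pnorm(-abs(kappa / se0))
  }
  agree <- as.integer(round(Po * n))
  bt <- stats::binom.test(agree, n, p = 0.5, conf.level = conf_level)
  pabak <- 2 * Po - 1
  structure(list(Po = Po, Pe = Pe,
                 kappa = kappa, kappa_ci = kappa_ci, kappa_p = kappa_p,
                 kappa_label = landis_koch(kappa),
                 pabak = pabak, pabak_ci = 2 * as.numeric(bt$conf.int) - 1,
                 pabak_p = bt$p.value,
                 pabak_label = landis_koch(pabak),
                 n = n, conf_level = conf_level),
            class = "agreement_stats")
}

#' @export
print.agreement_stats <- function(x, ...) {
  cat("Observed agreement Po = ", sprintf("%.4f", x$Po),
      ", chance agreement Pe = ", sprintf("%.4f", x$Pe), "\n", sep = "")
  cat("Cohen's kappa = ", sprintf("%.4f", x$kappa), " (",
      100 * x$conf_level, "% CI ", sprintf("%.4f", x$kappa_ci[1]), ", ",
      sprintf("%.4f", x$kappa_ci[2]), "): ", x$kappa_label, "\n", sep = "")
  cat("PABAK = ", sprintf("%.4f", x$pabak), " (",
      100 * x$conf_level, "% CI ", sprintf("%.4f", x$pabak_ci[1]), ", ",
      sprintf("%.4f", x$pabak_ci[2]), "): ", x$pabak_label, "\n", sep = "")
  invisible(x)
}

#' Landis-Koch interpretation of an agreement coefficient
#'
#' @param kappa Agreement coefficient in \[-1, 1\].
#' @return A character label.
#' @export
landis_koch <- function(kappa) {
  if (is.na(kappa)) return(NA_character_)
  if (kappa < 0) return("No agreement")
  if (kappa <= 0.2) return("Slight agreement")
  if (kappa <= 0.4) return("Fair agreement")
  if (kappa <= 0.6) return("Moderate agreement")
  if (kappa <= 0.8) return("Substantial agreement")
  "Almost perfect agreement"
}

#' Two-sample proportion test with continuity correction
#'
#' Compares two binomial proportions with the pooled-variance chi-square
#' test and Yates continuity correction (the standard
#' `prop.test` in R), used to compare the share of cases or population
#' captured by two cluster solutions.
#'
#' @param x1,n1 Successes and trials in sample 1.
#' @param x2,n2 Successes and trials in sample 2.
#' @return A list with `statistic` (the corrected chi-square), `p_value`
#'   (two-sided), and the two sample `estimates`.
#' @export
proportion_test <- function(x1, n1, x2, n2) {
  if (n1 <= 0 || n2 <= 0) stop("sample sizes must be positive")
  ht <- stats::prop.test(c(x1, x2), c(n1, n2), correct = TRUE)
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       estimates = unname(ht$estimate))
}

#' Cluster Information Criterion
#'
#' A goodness-of-fit score for a set of significant clusters:
#' `-2 * sum(LLRs) + log(p) * n` with natural log, where `p` is the total
#' population in the cluster regions and `n` the number of significant
#' clusters. The signed value is negative whenever the likelihood term
#' dominates; the magnitude is also returned because published
#' comparisons quote the criterion as a positive number. Lower (in
#' magnitude-ranking: the method whose magnitude is smaller) indicates
#' the better fit.
#'
#' @param llrs Numeric vector of the clusters' log-likelihood ratios.
#' @param population Total population of the cluster regions (p > 0).
#' @param n Number of significant clusters; defaults to `length(llrs)`.
#' @return A list with `value` (signed), `magnitude`, `sum_llr`, `n` and
#'   `population`.
#' @examples
#' clic(10, exp(2))$value  # -18
#' @export
clic <- function(llrs, population, n = length(llrs)) {
  if (length(llrs) < 1L) stop("need at least one cluster LLR")
  if (n < 1L) stop("n must be >= 1")
  if (population <= 0) stop("cluster population must be positive")
  value <- -2 * sum(llrs) + log(population) * n
  list(value = value, magnitude = abs(value), sum_llr = sum(llrs),
       n = n, population = population)
}

#' Compare two cluster solutions over the same study area
#'
#' The full comparison battery for two scan results on the same regions:
#' membership contingency, exact McNemar test, Cohen's kappa and PABAK
#' with confidence intervals and Landis-Koch labels, two-sample
#' continuity-corrected proportion tests on the share of cases and of
#' population captured, and the Cluster Information Criterion for each
#' solution.
#'
#' @param result1,result2 `scan_result`s over the same study area.
#' @param area The common `study_area`.
#' @return A list of class `scan_comparison`.
#' @export
compare_scans <- function(result1, result2, area) {
  stopifnot(inherits(area, "study_area"))
  if (!identical(result1$area_ids, area$regions$id) ||
      !identical(result2$area_ids, area$regions$id)) {
    stop("results and area disagree on regions")
  }
  m1 <- cluster_membership(result1)
  m2 <- cluster_membership(result2)
  ct <- membership_contingency(m1, m2)
  sums <- function(result, m) {
    list(cases = sum(area$regions$cases[m]),
         population = sum(area$regions$population[m]),
         n_clusters = nrow(result$clusters),
         n_regions = sum(m),
         clic = if (nrow(result$clusters) > 0L) {
           clic(result$clusters$llr,
                sum(area$regions$population[m]),
                nrow(result$clusters))
         } else NULL)
  }
  s1 <- sums(result1, m1)
  s2 <- sums(result2, m2)
  structure(list(
    contingency = ct,
    mcnemar_p = exact_mcnemar(ct),
    agreement = kappa_stats(ct),
    cases_test = proportion_test(s1$cases, area$C, s2$cases, area$C),
    population_test = proportion_test(s1$population, area$N,
                                      s2$population, area$N),
    method1 = s1, method2 = s2,
    C = area$C, N = area$N
  ), class = "scan_comparison")
}

#' @export
print.scan_comparison <- function(x, ...) {
  cat("Cluster-solution comparison over", x$contingency$n, "regions\n")
  print(x$contingency)
  cat("Exact McNemar p =", format(x$mcnemar_p, digits = 4), "\n")
  print(x$agreement)
  cat("Case share: ", sprintf("%.1f%% vs %.1f%%",
      100 * x$method1$cases / x$C, 100 * x$method2$cases / x$C),
      " (p = ", format(x$cases_test$p_value, digits = 3), ")\n", sep = "")
  cat("Population share: ", sprintf("%.1f%% vs %.1f%%",
      100 * x$method1$population / x$N, 100 * x$method2$population / x$N),
      " (p = ", format(x$population_test$p_value, digits = 3), ")\n",
      sep = "")
  for (side in c("method1", "method2")) {
    s <- x[[side]]
    if (!is.null(s$clic)) {
      cat(side, ": ", s$n_clusters, " clusters, CLIC magnitude ",
          format(s$clic$magnitude, digits = 6), "\n", sep = "")
    }
  }
  invisible(x)
}
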