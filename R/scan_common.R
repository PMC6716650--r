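#' Scan configuration
#'
#' Collects the tuning parameters shared by the circular and flexible scan
#' statistics under the discrete Poisson model.
#'
#' @param scan `"circular"` or `"flexible"`.
#' @param max_window Window cap: for the circular scan, the maximum
#'   fraction of the total population a window may contain (default 0.13);
#'   for the flexible scan, the maximum number of regions per window
#'   (default 10).
#' @param n_sim Number of Monte Carlo replications (default 999, so the
#'   smallest attainable p-value is 0.001).
#' @param seed Integer seed for the replicate stream; `NULL` leaves the
#'   RNG state untouched.
#' @param alpha Significance level for reporting clusters (default 0.05).
#' @param pr_min Minimum prevalence ratio for a cluster to be reported
#'   (default 1.2); clusters at or below this are suppressed as low-risk.
#' @param alpha1 Restriction threshold for the flexible scan's restricted
#'   log-likelihood ratio: a region can only join a high cluster if its
#'   one-tailed mid-p under its own Poisson null is below `alpha1`
#'   (default 0.2).
#' @param pr_definition Which risk-ratio variant feeds the `pr_min` filter
#'   and the reported "prevalence ratio": `"rr_io"` (inside/outside
#'   relative risk, the circular-scan convention) or `"oe"`
#'   (observed/expected, the flexible-scan convention). Defaults follow the
#'   scan type.
#' @param zone_budget Hard cap on the number of candidate windows the
#'   flexible enumeration may produce (default 5e6); exceeding it is an
#'   error, since exhaustive flexible scanning is only practical for small
#'   to moderate cluster sizes.
#' @param mid_p Use the mid-p convention for the restriction (default
#'   `TRUE`); `FALSE` uses the plain upper tail probability.
#' @return A list of class `scan_config`.
#' @export
scan_config <- function(scan = c("circular", "flexible"),
                        max_window = NULL, n_sim = 999, seed = NULL,
                        alpha = 0.05, pr_min = 1.2, alpha1 = 0.2,
                        pr_definition = NULL, zone_budget = 5e6,
                        mid_p = TRUE) {
  scan <- match.arg(scan)
  if (is.null(max_window)) {
    max_window <- if (scan == "circular") 0.13 else 10L
  }
  if (is.null(pr_definition)) {
    pr_definition <- if (scan == "circular") "rr_io" else "oe"
  }
  pr_definition <- match.arg(pr_definition, c("rr_io", "oe"))
  if (scan == "circular" &&
      (max_window <= 0 || max_window >= 1)) {
    stop("circular max_window must be a population fraction in (0, 1)")
  }
  if (scan == "flexible" && max_window < 1) {
    stop("flexible max_window must be a region count >= 1")
  }
  if (n_sim < 1) stop("n_sim must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  structure(list(scan = scan, model = "poisson", max_window = max_window,
                 n_sim = as.integer(n_sim), seed = seed, alpha = alpha,
                 pr_min = pr_min, alpha1 = alpha1,
                 pr_definition = pr_definition, zone_budget = zone_budget,
                 mid_p = mid_p),
            class = "scan_config")
}

#' Expected counts under the constant-risk null
#'
#' Indirectly standardised expected counts: each region's share of the
#' total case count in proportion to its population (or to arbitrary
#' positive baseline weights, as used by the covariate-adjusted scan).
#'
#' @param area A `study_area`.
#' @param weights Optional positive per-region baseline weights replacing
#'   the raw populations (e.g. model-fitted expected counts).
#' @return Numeric vector `e_i = C * w_i / sum(w)`, summing to the total
#'   case count `C`.
#' @export
null_expected <- function(area, weights = NULL) {
  stopifnot(inherits(area, "study_area"))
  w <- if (is.null(weights)) area$regions$population else weights
  if (length(w) != nrow(area$regions)) {
    stop("weights must have one entry per region")
  }
  if (any(!is.finite(w)) || any(w <= 0)) stop("weights must be positive")
  if (sum(w) <= 0) stop("total weight must be positive")
  area$C * w / sum(w)
}

#' Poisson scan log-likelihood ratio
#'
#' The likelihood-ratio statistic of the Poisson scan: the maximised
#' alternative log-likelihood (distinct rates inside and outside the zone)
#' minus the null log-likelihood (a single rate everywhere), conditional
#' on the total case count. In closed form
#' `c*log(c/e) + (C-c)*log((C-c)/(C-e))`, with `0*log(0)` taken as 0.
#'
#' @param c Observed cases in the zone (vectorised).
#' @param e Expected cases in the zone under the null; must satisfy
#'   `0 < e < C`.
#' @param C Total cases in the study area.
#' @param high_only If `TRUE` (default) the statistic is 0 for zones at or
#'   below their expectation, so only excess-risk zones score.
#' @return Non-negative statistic(s), same length as `c`.
#' @export
poisson_llr <- function(c, e, C, high_only = TRUE) {
  if (any(e <= 0) || any(e >= C)) stop("need 0 < e < C")
  if (any(c < 0) || any(c > C)) stop("need 0 <= c <= C")
  out <- llr_kernel(c, e, C)
  if (high_only) {
    out[c <= e] <- 0
  } else {
    out[c == e] <- 0
  }
  out
}

# Vectorised/matrix closed form; e recycles along the first dimension.
llr_kernel <- function(c, e, C) {
  t1 <- c * log(c / e)
  t1[c == 0] <- 0
  r <- C - c
  t2 <- r * log(r / (C - e))
  t2[r == 0] <- 0
  t1 + t2
}

# High-cluster statistic for a zones x replicates count matrix;
# e_z recycles down columns.
llr_matrix <- function(cz, e_z, C) {
  out <- llr_kernel(cz, e_z, C)
  out[cz <= e_z] <- 0
  out
}

#' Risk ratios for a zone
#'
#' Both conventions for a scan cluster's "prevalence ratio": the
#' inside/outside relative risk `(c/e) / ((C-c)/(C-e))` and the
#' observed/expected ratio `c/e`. Both equal 1 when the zone sits exactly
#' at its expectation.
#'
#' @inheritParams poisson_llr
#' @return A data frame with columns `rr_io` and `oe`.
#' @export
risk_ratios <- function(c, e, C) {
  if (any(e <= 0) || any(e >= C)) stop("need 0 < e < C")
  if (any(c < 0) || any(c > C)) stop("need 0 <= c <= C")
  oe <- c / e
  outside <- (C - c) / (C - e)
  rr_io <- ifelse(c == C, Inf, oe / outside)
  data.frame(rr_io = rr_io, oe = oe)
}

# ---- zone families -------------------------------------------------------

new_zone_family <- function(members, area, type) {
  structure(list(members = members, ids = area$regions$id, type = type),
            class = "zone_family")
}

#' @export
print.zone_family <- function(x, ...) {
  cat("<zone_family> ", length(x$members), " ", x$type,
      " windows over ", length(x$ids), " regions (sizes ",
      min(lengths(x$members)), "-", max(lengths(x$members)), ")\n",
      sep = "")
  invisible(x)
}

# Sparse zones x regions indicator matrix.
zone_matrix <- function(family) {
  m <- family$members
  Matrix::sparseMatrix(i = rep.int(seq_along(m), lengths(m)),
                       j = unlist(m), x = 1,
                       dims = c(length(m), length(family$ids)))
}

# Canonical dedup key for a member index set.
zone_key <- function(members) paste(sort.int(members), collapse = ",")

# ---- Monte Carlo inference ----------------------------------------------

#' Monte Carlo test for a family of candidate zones
#'
#' Conditional Monte Carlo inference for the Poisson scan: the total case
#' count `C` is redistributed over regions as a multinomial with
#' probabilities proportional to the baseline weights (populations, or
#' adjusted expected counts), the maximum statistic over the *same* zone
#' family is recorded for each replicate, and each zone's p-value is the
#' rank of its observed statistic among the replicate maxima:
#' `p = (1 + #\{max_rep >= observed\}) / (n_sim + 1)`.
#'
#' @param area A `study_area`.
#' @param zones A `zone_family` (from [enumerate_circular()] or
#'   [enumerate_flexible()]) or a list of region-id character vectors.
#' @param statistic `"llr"` (the circular-scan statistic),
#'   `"restricted_llr"` (the flexible-scan statistic, with the region-wise
#'   restriction recomputed on every replicate), or a function
#'   `f(zone_cases, zone_expected, C, region_counts, region_expected)`
#'   returning a statistic matrix, for custom statistics.
#' @param n_sim Number of replicates.
#' @param seed Optional integer seed.
#' @param weights Optional baseline weights (see [null_expected()]).
#' @param alpha1,mid_p Restriction parameters for `"restricted_llr"`.
#' @return A list with `stat` (observed statistic per zone), `p` (Monte
#'   Carlo p-value per zone), `repmax` (the `n_sim` replicate maxima), and
#'   the per-zone aggregates `cases`, `expected`, `population`.
#' @export
monte_carlo_test <- function(area, zones, statistic = "llr",
                             n_sim = 999, seed = NULL, weights = NULL,
                             alpha1 = 0.2, mid_p = TRUE) {
  stopifnot(inherits(area, "study_area"))
  if (n_sim < 1) stop("n_sim must be >= 1")
  family <- as_zone_family(zones, area)
  n <- nrow(area$regions)
  cases <- area$regions$cases
  C <- area$C
  e_i <- null_expected(area, weights)
  Z <- zone_matrix(family)
  cz <- as.numeric(Z %*% cases)
  ez <- as.numeric(Z %*% e_i)
  nz <- as.numeric(Z %*% area$regions$population)

  restricted <- identical(statistic, "restricted_llr")
  stat_fun <- if (is.function(statistic)) statistic else NULL
  if (!is.function(statistic) && !restricted &&
      !identical(statistic, "llr")) {
    stop("statistic must be \"llr\", \"restricted_llr\" or a function")
  }
  eval_stats <- function(CZ, X) {
    if (!is.null(stat_fun)) return(stat_fun(CZ, ez, C, X, e_i))
    S <- llr_matrix(CZ, ez, C)
    if (restricted) {
      p_i <- region_mid_p(X, e_i, mid_p = mid_p)
      ncold <- as.matrix(Z %*% (p_i >= alpha1))
      S <- S * (ncold == 0)
    }
    S
  }
  obs <- eval_stats(matrix(cz, ncol = 1L), matrix(cases, ncol = 1L))[, 1L]

  if (!is.null(seed)) set.seed(seed)
  prob <- e_i / C
  nzones <- length(cz)
  chunk <- max(1L, min(n_sim, as.integer(2e7 / max(nzones, 1L))))
  repmax <- numeric(n_sim)
  done <- 0L
  while (done < n_sim) {
    m <- min(chunk, n_sim - done)
    X <- stats::rmultinom(m, C, prob)
    CZ <- as.matrix(Z %*% X)
    repmax[done + seq_len(m)] <- apply(eval_stats(CZ, X), 2L, max)
    done <- done + m
  }
  list(stat = obs, p = p_from_repmax(obs, repmax), repmax = repmax,
       cases = cz, expected = ez, population = nz)
}

# p = (1 + #{repmax >= stat}) / (R + 1), ties counted against the observed.
p_from_repmax <- function(stat, repmax) {
  sr <- sort(repmax)
  n_lt <- findInterval(stat, sr, left.open = TRUE)
  (1 + length(sr) - n_lt) / (length(sr) + 1)
}

as_zone_family <- function(zones, area) {
  if (inherits(zones, "zone_family")) {
    if (!identical(zones$ids, area$regions$id)) {
      stop("zone family was built for a different region ordering")
    }
    return(zones)
  }
  if (is.list(zones)) {
    members <- lapply(zones, function(ids) {
      idx <- match(as.character(ids), area$regions$id)
      if (anyNA(idx)) stop("zone refers to unknown region id(s)")
      idx
    })
    return(new_zone_family(members, area, type = "custom"))
  }
  stop("zones must be a zone_family or a list of region-id vectors")
}

#' Greedy selection of non-overlapping significant clusters
#'
#' Orders scored zones by descending statistic, keeps each zone only if it
#' shares no region with an already-kept zone, then drops clusters that
#' miss the significance level or the minimum prevalence-ratio filter, and
#' reassigns ranks 1..n (rank 1 = primary cluster).
#'
#' @param zones A data frame with a list-column `members` (region ids per
#'   zone) and numeric columns `llr`, `p_value`, `rr_io`, `oe`.
#' @param alpha Maximum Monte Carlo p-value to report.
#' @param pr_min Minimum prevalence ratio (strict) to report.
#' @param pr_definition `"rr_io"` or `"oe"`: which ratio the filter uses.
#' @return The filtered data frame with a leading `rank` column; zones
#'   with zero statistic are never reported.
#' @export
select_clusters <- function(zones, alpha = 0.05, pr_min = 1.2,
                            pr_definition = c("rr_io", "oe")) {
  pr_definition <- match.arg(pr_definition)
  stopifnot(is.data.frame(zones), "members" %in% names(zones))
  zones <- zones[order(-zones$llr), , drop = FALSE]
  keep <- logical(nrow(zones))
  used <- character(0)
  for (i in seq_len(nrow(zones))) {
    mem <- zones$members[[i]]
    if (zones$llr[i] > 0 && !any(mem %in% used)) {
      keep[i] <- TRUE
      used <- c(used, mem)
    }
  }
  out <- zones[keep, , drop = FALSE]
  pr <- out[[pr_definition]]
  out <- out[out$p_value <= alpha & pr > pr_min, , drop = FALSE]
  if (nrow(out) > 0L) out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

# ---- shared scan driver --------------------------------------------------

run_scan <- function(area, family, config, weights = NULL,
                     restricted = FALSE) {
  n <- nrow(area$regions)
  cases <- area$regions$cases
  pop <- area$regions$population
  C <- area$C
  e_i <- null_expected(area, weights)
  Z <- zone_matrix(family)
  cz <- as.numeric(Z %*% cases)
  ez <- as.numeric(Z %*% e_i)
  nz <- as.numeric(Z %*% pop)
  sizes <- lengths(family$members)

  if (restricted) {
    p_obs <- region_mid_p(cases, e_i, mid_p = config$mid_p)
    cold_obs <- as.numeric(Z %*% (p_obs >= config$alpha1))
    obs <- llr_matrix(matrix(cz, ncol = 1L), ez, C)[, 1L] *
      (cold_obs == 0)
  } else {
    obs <- llr_matrix(matrix(cz, ncol = 1L), ez, C)[, 1L]
  }

  if (!is.null(config$seed)) set.seed(config$seed)
  prob <- e_i / C
  nzones <- length(cz)
  n_sim <- config$n_sim
  chunk <- max(1L, min(n_sim, as.integer(2e7 / max(nzones, 1L))))
  repmax <- numeric(n_sim)
  done <- 0L
  while (done < n_sim) {
    m <- min(chunk, n_sim - done)
    X <- stats::rmultinom(m, C, prob)
    CZ <- as.matrix(Z %*% X)
    S <- llr_matrix(CZ, ez, C)
    if (restricted) {
      p_rep <- region_mid_p(X, e_i, mid_p = config$mid_p)
      ncold <- as.matrix(Z %*% (p_rep >= config$alpha1))
      S <- S * (ncold == 0)
    }
    repmax[done + seq_len(m)] <- apply(S, 2L, max)
    done <- done + m
  }

  # greedy non-overlap on all positive zones, then p-values for the kept
  ord <- order(-obs)
  keep <- integer(0)
  used <- logical(n)
  for (i in ord) {
    if (obs[i] <= 0) break
    mem <- family$members[[i]]
    if (!any(used[mem])) {
      keep <- c(keep, i)
      used[mem] <- TRUE
    }
  }
  rr <- if (length(keep) > 0L) {
    risk_ratios(cz[keep], ez[keep], C)
  } else {
    data.frame(rr_io = numeric(0), oe = numeric(0))
  }
  candidates <- data.frame(
    llr = obs[keep],
    cases = cz[keep],
    expected = ez[keep],
    population = nz[keep],
    n_regions = sizes[keep],
    rr_io = rr$rr_io,
    oe = rr$oe,
    p_value = if (length(keep) > 0L) p_from_repmax(obs[keep], repmax)
              else numeric(0)
  )
  candidates$members <- lapply(family$members[keep],
                               function(ix) family$ids[ix])
  clusters <- select_clusters(candidates, alpha = config$alpha,
                              pr_min = config$pr_min,
                              pr_definition = config$pr_definition)
  most_likely <- if (nrow(candidates) > 0L) {
    list(llr = candidates$llr[1L], p_value = candidates$p_value[1L],
         members = candidates$members[[1L]])
  } else {
    list(llr = 0, p_value = 1, members = character(0))
  }
  structure(list(clusters = clusters, candidates = candidates,
                 most_likely = most_likely, zone_count = nzones,
                 config = config, repmax = repmax,
                 method = if (restricted) "flexible" else "circular",
                 area_ids = area$regions$id, C = C, N = area$N),
            class = "scan_result")
}

#' @export
print.scan_result <- function(x, ...) {
  cat("<scan_result> ", x$method, " Poisson scan, ", x$zone_count,
      " candidate windows, ", x$config$n_sim, " Monte Carlo replicates\n",
      sep = "")
  cat("  most likely window: LLR = ", format(x$most_likely$llr, digits = 6),
      ", p = ", format(x$most_likely$p_value), "\n", sep = "")
  if (nrow(x$clusters) == 0L) {
    cat("  no clusters reported at alpha = ", x$config$alpha,
        ", PR > ", x$config$pr_min, "\n", sep = "")
  } else {
    df <- x$clusters
    df$members <- vapply(df$members, function(m) {
      if (length(m) > 4L) paste0(paste(m[1:4], collapse = ","), ",...")
      else paste(m, collapse = ",")
    }, "")
    print(df, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Serialise a cluster report
#'
#' Writes the reported clusters of a scan as delimited text or JSON with
#' one row per cluster: rank, population, observed and expected cases,
#' both risk-ratio variants, region count, Monte Carlo p-value and member
#' region ids.
#'
#' @param result A `scan_result`.
#' @param path Output path; format chosen by `format`.
#' @param format `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_cluster_report <- function(result, path, format = c("csv", "json")) {
  stopifnot(inherits(result, "scan_result"))
  format <- match.arg(format)
  df <- result$clusters
  if (nrow(df) > 0L) {
    df$member_ids <- vapply(df$members, paste, "", collapse = ";")
    df$members <- NULL
  }
  if (format == "csv") {
    utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  } else {
    payload <- list(method = result$method,
                    zone_count = result$zone_count,
                    n_sim = result$config$n_sim,
                    alpha = result$config$alpha,
                    pr_min = result$config$pr_min,
                    clusters = df)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}
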