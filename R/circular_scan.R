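#' Enumerate circular scan windows
#'
#' The discrete circular window family: for every region taken as a
#' centre, the nested sequence of zones obtained by adding the remaining
#' regions in order of ascending centroid distance, truncated as soon as
#' the cumulative population would exceed `max_pop_fraction` of the study
#' total. A region is in a window exactly when its centroid is; windows
#' that coincide as sets (reached from different centres) are emitted
#' once. Centres are processed in lexicographic id order and distance ties
#' are broken by id, so the family is invariant to the row order of the
#' input table.
#'
#' @param area A `study_area`.
#' @param max_pop_fraction Cap on each window's share of the total
#'   population (or of the total `weights`), in (0, 1).
#' @param dist_matrix Optional precomputed [region_distances()] output.
#' @param weights Optional positive baseline weights replacing the raw
#'   populations in the cap (used by the covariate-adjusted scan).
#' @return A `zone_family`.
#' @export
enumerate_circular <- function(area, max_pop_fraction = 0.13,
                               dist_matrix = NULL, weights = NULL) {
  stopifnot(inherits(area, "study_area"))
  if (max_pop_fraction <= 0 || max_pop_fraction >= 1) {
    stop("max_pop_fraction must be in (0, 1)")
  }
  w <- if (is.null(weights)) area$regions$population else weights
  cap <- max_pop_fraction * sum(w)
  ids <- area$regions$id
  n <- length(ids)
  if (all(w > cap)) {
    stop("population cap excludes every region; oversized region(s): ",
         paste(ids[w > cap], collapse = ", "))
  }
  if (is.null(dist_matrix)) dist_matrix <- region_distances(area)
  members <- vector("list", 0L)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (i in order(ids, method = "radix")) {
    others <- setdiff(seq_len(n), i)
    ord <- c(i, others[order(dist_matrix[i, others], ids[others],
                             method = "radix")])
    cum <- cumsum(w[ord])
    jmax <- findInterval(cap, cum)
    for (j in seq_len(jmax)) {
      mem <- sort.int(ord[seq_len(j)])
      key <- paste(mem, collapse = ",")
      if (is.null(seen[[key]])) {
        seen[[key]] <- TRUE
        members[[length(members) + 1L]] <- mem
      }
    }
  }
  new_zone_family(members, area, type = "circular")
}

#' Circular spatial scan statistic
#'
#' The full Kulldorff-style circular scan under the discrete Poisson
#' model: enumerate the centroid-anchored circular window family up to the
#' population cap, score each window with the high-cluster Poisson
#' log-likelihood ratio against indirectly standardised expected counts,
#' obtain p-values by conditional Monte Carlo (the total case count
#' redistributed multinomially over regions, the maximum statistic over
#' the same window family recorded per replicate), and report ranked
#' non-overlapping clusters passing the significance and prevalence-ratio
#' filters.
#'
#' @param area A `study_area`.
#' @param config A [scan_config()] with `scan = "circular"`.
#' @param zones Optional precomputed `zone_family` (reused across
#'   repeated scans of the same geometry).
#' @param weights Optional baseline weights replacing raw populations
#'   throughout (expected counts, replicate probabilities and the window
#'   cap); see [adjusted_scan()].
#' @param dist_matrix Optional precomputed distance matrix.
#' @return A `scan_result`: reported `clusters`, all disjoint scored
#'   `candidates`, the `most_likely` window with its p-value, replicate
#'   maxima, and the configuration used.
#' @examples
#' sc <- scenario_suite()[["disk-hotspot"]]
#' dat <- generate_region_data(sc, seed = 1)
#' res <- circular_scan(dat$area, scan_config("circular", n_sim = 99,
#'                                            seed = 1))
#' res$clusters
#' @export
circular_scan <- function(area, config = scan_config("circular"),
                          zones = NULL, weights = NULL,
                          dist_matrix = NULL) {
  stopifnot(inherits(area, "study_area"))
  if (config$scan != "circular") stop("config$scan must be \"circular\"")
  if (is.null(zones)) {
    zones <- enumerate_circular(area, config$max_window,
                                dist_matrix = dist_matrix,
                                weights = weights)
  }
  run_scan(area, zones, config, weights = weights, restricted = FALSE)
}
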