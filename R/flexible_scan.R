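#' Enumerate flexible (irregularly shaped) scan windows
#'
#' The flexible window family: all connected region subsets Z such that Z
#' contains a centre region i, has at most `K` members, and lies inside
#' {i} union the K-1 nearest neighbours of i. Connectivity is judged on
#' the supplied adjacency (explicit id pairs, e.g. polygon contiguity) or,
#' by default, on a symmetrised K-nearest-neighbour graph. Subsets are
#' enumerated by incremental growth with a forbidden-set rule so each
#' connected subset of a centre's neighbourhood is produced exactly once,
#' and duplicates across centres are removed canonically.
#'
#' @param area A `study_area`.
#' @param K Maximum number of regions per window.
#' @param adjacency Optional two-column matrix/data frame of region-id
#'   pairs defining the connectivity graph; defaults to
#'   [knn_adjacency()] with `k = K`.
#' @param neighbors Optional precomputed [k_nearest()] list for `K`.
#' @param dist_matrix Optional precomputed distance matrix.
#' @param zone_budget Abort (with an error) if the family would exceed
#'   this many windows; exhaustive flexible scanning is only practical for
#'   small to moderate window sizes.
#' @return A `zone_family`.
#' @examples
#' # a 3-region path graph yields 6 connected windows at K = 3:
#' # the 3 singletons, both edges, and the full path (the disconnected
#' # end-pair is rejected)
#' @export
enumerate_flexible <- function(area, K = 10, adjacency = NULL,
                               neighbors = NULL, dist_matrix = NULL,
                               zone_budget = 5e6) {
  stopifnot(inherits(area, "study_area"))
  K <- as.integer(K)
  n <- nrow(area$regions)
  if (K < 1L) stop("K must be >= 1")
  if (K > n) stop("K cannot exceed the number of regions")
  ids <- area$regions$id
  if (is.null(neighbors)) {
    if (is.null(dist_matrix)) dist_matrix <- region_distances(area)
    neighbors <- k_nearest(area, K, dist_matrix = dist_matrix)
  }
  if (is.null(adjacency)) {
    if (is.null(dist_matrix)) dist_matrix <- region_distances(area)
    adjacency <- knn_adjacency(area, k = K, dist_matrix = dist_matrix)
  }
  adj <- adjacency_list(adjacency, ids)

  members <- vector("list", 0L)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  count <- 0L
  emit <- function(set) {
    key <- paste(sort.int(set), collapse = ",")
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      count <<- count + 1L
      if (count > zone_budget) {
        stop("flexible window count exceeds zone_budget (", zone_budget,
             "); reduce K or supply a sparser adjacency")
      }
      members[[count]] <<- sort.int(set)
    }
  }
  for (i in order(ids, method = "radix")) {
    allowed <- c(i, match(neighbors[[ids[i]]], ids))
    in_allowed <- logical(n)
    in_allowed[allowed] <- TRUE
    grow <- function(set, ext, forbidden) {
      emit(set)
      if (length(set) == K) return()
      while (length(ext) > 0L) {
        v <- ext[1L]
        ext <- ext[-1L]
        nb <- adj[[v]]
        nb <- nb[in_allowed[nb] & !(nb %in% set) & !(nb %in% forbidden) &
                   !(nb %in% ext) & nb != v]
        grow(c(set, v), c(ext, nb), forbidden)
        forbidden <- c(forbidden, v)
      }
    }
    nb0 <- adj[[i]]
    grow(i, nb0[in_allowed[nb0]], integer(0))
  }
  new_zone_family(members[seq_len(count)], area, type = "flexible")
}

adjacency_list <- function(adjacency, ids) {
  adjacency <- as.matrix(adjacency)
  if (ncol(adjacency) != 2L) stop("adjacency must have two columns")
  a <- match(as.character(adjacency[, 1L]), ids)
  b <- match(as.character(adjacency[, 2L]), ids)
  if (anyNA(a) || anyNA(b)) stop("adjacency refers to unknown region ids")
  adj <- vector("list", length(ids))
  for (k in seq_along(a)) {
    adj[[a[k]]] <- c(adj[[a[k]]], b[k])
    adj[[b[k]]] <- c(adj[[b[k]]], a[k])
  }
  lapply(adj, function(v) sort.int(unique(v)))
}

#' One-tailed mid-p value for a single region
#'
#' The region-wise evidence of excess risk used by the restricted
#' log-likelihood ratio: `p_i = P(X > c_i) + 0.5 * P(X = c_i)` with
#' `X ~ Poisson(e_i)`. With `mid_p = FALSE` the plain upper tail
#' `P(X >= c_i)` is returned instead.
#'
#' @param c Observed count(s); vector or matrix.
#' @param e Expected count(s) under the null; recycled along the first
#'   dimension for matrix `c`.
#' @param mid_p Use the mid-p convention (default `TRUE`).
#' @return Values in (0, 1), same shape as `c`.
#' @export
region_mid_p <- function(c, e, mid_p = TRUE) {
  if (any(e <= 0)) stop("e must be positive")
  upper <- stats::ppois(c, e, lower.tail = FALSE)
  if (mid_p) upper + 0.5 * stats::dpois(c, e) else
    upper + stats::dpois(c, e)
}

#' Restricted log-likelihood ratio
#'
#' The flexible scan's statistic: the Poisson scan LLR of a zone times the
#' indicator that every member region is individually "hot" (its one-
#' tailed mid-p below the restriction threshold `alpha1`). Zones carrying
#' any region without individual evidence of excess risk score zero, which
#' prevents low-risk regions from riding inside an irregular cluster.
#'
#' @param llr Unrestricted zone LLR(s).
#' @param member_p A list (one element per zone) of member-region mid-p
#'   values, or a single numeric vector for one zone.
#' @param alpha1 Restriction threshold (default 0.2).
#' @return Restricted statistic(s), `<= llr` elementwise.
#' @export
restricted_llr <- function(llr, member_p, alpha1 = 0.2) {
  if (!is.list(member_p)) member_p <- list(member_p)
  ok <- vapply(member_p, function(p) all(p < alpha1), NA)
  llr * ok
}

#' Flexible spatial scan statistic
#'
#' The Tango-Takahashi-style flexible scan under the discrete Poisson
#' model: enumerate all connected windows of at most `K` regions inside
#' each centre's K-nearest neighbourhood, score them with the restricted
#' log-likelihood ratio (region-wise mid-p restriction at `alpha1`), run
#' conditional Monte Carlo inference with the restriction recomputed on
#' every replicate, and report ranked non-overlapping clusters passing the
#' significance and prevalence-ratio filters. By convention the reported
#' prevalence ratio is the observed/expected ratio.
#'
#' @param area A `study_area`.
#' @param config A [scan_config()] with `scan = "flexible"`; `max_window`
#'   is the region-count cap `K`.
#' @param zones Optional precomputed `zone_family`.
#' @param adjacency Optional explicit adjacency pairs (see
#'   [enumerate_flexible()]).
#' @param weights Optional baseline weights replacing raw populations.
#' @param dist_matrix Optional precomputed distance matrix.
#' @return A `scan_result`.
#' @export
flexible_scan <- function(area, config = scan_config("flexible"),
                          zones = NULL, adjacency = NULL, weights = NULL,
                          dist_matrix = NULL) {
  stopifnot(inherits(area, "study_area"))
  if (config$scan != "flexible") stop("config$scan must be \"flexible\"")
  if (is.null(zones)) {
    zones <- enumerate_flexible(area, K = config$max_window,
                                adjacency = adjacency,
                                dist_matrix = dist_matrix,
                                zone_budget = config$zone_budget)
  }
  run_scan(area, zones, config, weights = weights, restricted = TRUE)
}
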